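---
title: "Predicting diazotrophy from genome content: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting diazotrophy from genome content: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nifscan)
```

## The problem

Biological nitrogen fixation — the reduction of N~2~ to ammonia by
nitrogenase — is scattered across distant prokaryotic lineages, and
demonstrating it experimentally requires species-specific growth conditions.
Genome sequences offer a shortcut, but the common practice of screening for
*nifH* and/or *nifD* alone produces false positives: many genomes carry one
marker without the machinery to build a functional enzyme.

`nifscan` implements a gene-content criterion instead.  A genome is called a
predicted diazotroph when it encodes the co-occurring **minimum gene set**:
the structural subunits *nifH*, *nifD*, *nifK* plus the FeMo-cofactor
biosynthesis genes *nifE*, *nifN*, *nifB*.  Around that core the package
inventories nine further families (*nifU*, *nifS*, *nifV*, *nifQ* and the
alternative-nitrogenase G subunits *anfG*/*vnfG*), scores gene-neighbourhood
(synteny) evidence, types D-subunit sequences by their active-site ligand
environment, and triages the large halo of divergent nitrogenase-like
sequences that would otherwise contaminate the inventory.

## The homology screen

Each of 12 query families — keyed by the *A. vinelandii* DJ locus tags
Avin_01380 (NifH) through Avin_02600 (VnfG) — is aligned locally
(Smith–Waterman, BLOSUM62, gap open 11 / extend 1; an L-residue gap costs
`11 + L`) against every protein of the genome.  The retention statistic is
**identity over query length**: identical aligned residues divided by the
*full* query length, deliberately asymmetric so that short local matches to
a long query are penalised.  The default threshold is a weak 20%, refined by
everything downstream.  Each protein is assigned to the family with the
highest score; the margin to the runner-up is reported, and small margins
(default < 10% of the best score) flag the NifD/NifE and NifK/NifN
scaffold-paralogy ambiguity rather than hiding it.

E-values are not computed in built-in mode; when hits are imported from an
external search engine (12-column tabular format) their e-values are
preserved and a 10^-20^ cutoff gates the divergent-sequence collection step.
In built-in mode a score threshold (default 100) stands in: the bundled
NifD-vs-NifE alignment passes it comfortably, random proteins do not.

## Reference numbering and ligand profiles

All alpha-subunit positions are expressed in *A. vinelandii* NifD
(Avin_01390) numbering.  A subject is aligned globally (free end gaps) to
its family's reference, and positions are carried into NifD numbering by
composing with the reference-vs-reference alignment — the dual numbering
under which NifD Cys154 corresponds to NifE Cys124, and NifK Cys95 to NifN
Cys44.  Mapping through the assigned family's own template keeps the
tracked columns anchored even at ~30% identity to NifD itself.

The profile reads off: the FeMoco ligands Cys275 and His442, the catalytic
environment Gln191/His195, the homocitrate anchor Lys426, the subfamily
flanks 276/440/444/445, and the P-cluster cysteines (alpha 62/88/154; beta
70/95/153 in NifK numbering — only position 95 is part of the
core annotation; 70 and 153 are this package's documented defaults and are
configurable in the reference YAML).  Subfamily classification is a fixed
precedence: **V** (Ala276 + His445, the VnfD/AnfD signature), then **C**
(Gln276 + Asp440 + no aromatic at 444 — the thermophile-associated group
often lacking NifEN), then **CONVENTIONAL_AB** (Cys275 + His442 + aromatic
444; the A-vs-B sub-split is not computed because its defining residues are
not published as text), else **UNCLASSIFIED**.  The aromatic set is {F, W, Y};
histidine is deliberately excluded because it is handled separately at
position 445.  V is tested before C for determinism; their signatures are
disjoint at position 276, so the order matters only for malformed input.

## Classification rules

* `DIAZOTROPH_PREDICTED` — all six required families present (anywhere in
  the genome; synteny is evidence, not a requirement — the criterion demands
  co-occurrence, not co-location, and real gene sets are not always in a
  single region).
* `GROUP_C_CANDIDATE` — *nifH*, *nifD*, *nifK*, *nifB* present, missing only
  *nifE*/*nifN*.  When motif data are available the D subunit must carry the
  group-C signature (the exception is tied to that phylogenetically distinct
  enzyme form); in import mode the call is made on gene content alone and
  flagged low-confidence.  *nifV* is reported but not required — the source
  text mentions *nifB* and *nifV* together, but prints no rule for *nifV*,
  so the conservative choice is *nifB* only.
* `ORPHAN` — exactly one of *nifH*/*nifD*; the single-marker false-positive
  pattern that motivates the minimum-set criterion in the first place.
* `NEGATIVE` — everything else.

Mo/V/Fe systems are distinguished by the extra G subunit: V when *vnfG*
co-occurs (or a V-labeled D subunit co-clusters with a G hit), Fe likewise
via *anfG*, Mo when any D subunit lacks the V signature.  A genome with an
alternative system but no Mo system raises `hierarchy_violation`, because
alternative nitrogenases are only observed alongside the Mo enzyme.
Mo copy number is the number of disjoint synteny clusters containing both a
(non-V) *nifD* and a *nifK* locus — by construction a cluster-level notion,
so a deliberately dispersed gene set has copy number 0 even when the genome
is positive.

## Synteny

Adjacency works on the ordinal gene index (0-based position of the CDS along
its replicon), never on nucleotide distance, so coordinate-free protein
FASTA input still supports clustering.  Two nif loci join a cluster when at
most `max_gap` genes intervene; the default `max_gap = 2` is a declared
convention (gene-region contiguity is an inherently qualitative notion) chosen to
tolerate small ORFs inside operons while keeping clusters local.  Strand is
recorded but ignored: clustered nif regions are routinely transcribed from
mixed strands.  The report carries four flags: ≥3 required families in one
cluster, all six in one region, nifHDK contiguity, and nifDK-adjacent-nifEN.

## Divergent nitrogenase-like sequences

The Pfam nitrogenase-component-1 fold includes the dark-operative
protochlorophyllide reductase (DPOR) subunits and a broad outgroup of
nitrogenase-like proteins without complete FeMoco ligation.  Triage runs in
stages:

1. **Fusions** — a protein hitting an H-type query and a D/E-type query in
   essentially disjoint regions (interval overlap ≤ 10% of the shorter) is a
   NifH–D/E fusion; it is reported and excluded from pairing and export.
2. **DPOR subtraction** — every D/E/K/N-assigned protein is scored against
   bundled ChlB/BchB/ChlN/BchN references; a candidate whose best DPOR score
   reaches its best nitrogenase score is removed.  Comparative subtraction
   was chosen over a fixed cutoff to avoid database-version dependence.
3. **Candidates** — alpha-type (D/E) proteins whose ligand profile matches
   no conventional subfamily are nitrogenase-like candidates.  Beta-type
   (K/N) proteins become candidates only when co-located (within `max_gap`)
   with an alpha candidate: betas carry no subfamily motif of their own, so
   genomic context is the discriminating signal, mirroring the subtraction
   of known conventional sequences from the divergent-hit list.
4. **Pairing** — greedy nearest-neighbour pairing of alpha with beta
   candidates; a four-gene tandem yields two pairs; unpaired candidates are
   `NFLD_SINGLE` (the single-subunit archaeal NflD pattern).
5. **Ligand classes** — `GREEN` (Cys275 kept, His442 lost, 3 alpha
   P-cluster Cys), `YELLOW` (both FeMoco ligands lost, 3 Cys),
   `REDUCED_CYS` (fewer than 3 alpha Cys, with per-subunit counts such as
   the 2+1 pattern), `NFLD_SINGLE` passthrough.  The residual combination
   (His442 retained) is labelled `UNDETERMINED`; upstream conventional
   exclusion makes it unreachable in practice, but the function stays total.

Loci triaged as DPOR, fusion or candidate are removed from the diazotrophy
inventory *before* classification — the programmatic analogue of refining a
weak-threshold hit list.  Similarly, an *anfG*/*vnfG* hit with no
co-clustered D subunit is treated as spurious and dropped; isolated
G-subunit matches in random sequence do occur at the weak threshold, and a
G subunit is only meaningful as part of an alternative-nitrogenase operon.
Near-duplicate candidates can be collapsed (single linkage at 90% identity
over the shorter sequence; there is no canonical threshold for collapsing
near-duplicates, so 90% is an exposed default) and
exported as unaligned FASTA for external ClustalW/FastTree analysis; tree
building itself is out of scope.

## The synthetic-genome generator

Because the original genome census is not reproducible at desk scale (it
derives from a 2011 database snapshot of 999 bacterial and 93 archaeal
species), correctness is demonstrated on generated genomes with known
ground truth.  The generator implants mutated copies of the reference
families among random decoy proteins (uniform residue composition, length
lognormal with median 300, a typical prokaryotic protein length):

* implants are mutated to a target identity (default 50%, comfortably above
  the 20% screen but far from trivial) by exact-count substitution; ligand
  and signature columns are frozen, and the group-C deletion at 444 is the
  only indel, keeping position bookkeeping exact;
* fourteen scenarios cover the gene-content patterns seen in real
  diazotroph genomes: the complete
  set (clustered and dispersed), both orphan types, the group-C repertoire,
  V- and Fe-type alternative systems, a two-copy genome, green / yellow /
  reduced nitrogenase-like pairs, a single NflD, a NifH+NifE fusion, a
  DPOR-decoy genome (50 decoys derived from the DPOR references at 60%
  identity), and a pure-decoy negative;
* the standard evaluation cohort is 20 genomes (all scenarios, six
  repeated) with 200 decoys each — large enough that spurious-hit behaviour
  at the weak threshold is exercised and measured rather than assumed, and
  small enough to run in a couple of minutes on one CPU;
* every genome is emitted as GenBank, GFF3 + nucleotide FASTA and protein
  FASTA, with a JSON manifest recording each implanted locus and the
  expected analysis outcome.  Identical seeds give identical output.

What the generator does **not** emulate: evolutionary rate heterogeneity,
indel processes, codon-level mutation, genuine paralog families, or real
intergenic architecture.  Passing the closed loop therefore demonstrates
that the decision rules and their thresholds interact correctly — not that
the screen's sensitivity on real, anciently diverged sequences equals its
sensitivity on simulated 50%-identity implants.

A note on the bundled references: so that the package is self-contained and
network-independent, the reference FASTA files are deterministic synthetic
stand-ins (clearly marked in their filenames) carrying the annotated
residues at the annotated coordinates, with NifE/NifN derived from the
NifD/NifK scaffolds at ~35% identity and the DPOR references at ~40%.
Users reproducing the original census should drop in the true
*A. vinelandii* DJ sequences via `load_default_queries(fasta = ...)` —
every position in the metadata YAML refers to the real proteins.

## Numerical choices and degenerate inputs

* Alignment tie-breaks are pinned (best cell: smallest subject index, then
  smallest query index; traceback prefers diagonal, then query-gap, then
  subject-gap), so identical inputs give byte-identical outputs.
* Ambiguity codes X/B/Z/U are retained in sequences, scored as X, and never
  counted as identities.
* Sequences shorter than 100 residues are rejected as fragments by the
  position mapper; reference coverage below 50% flags all downstream labels
  low-confidence.
* Empty proteomes, empty gene sets and all-negative genomes flow through
  every stage without error; the classifier is total.
* When several assemblies share a species name the lexicographically
  smallest assembly identifier is kept, unless a representative is named
  explicitly — a deterministic stand-in for manual representative selection.

## A worked example

```{r example, eval = FALSE}
queries <- load_default_queries()
profile <- reference_profile(queries)
sim <- generate_genome("complete_set", seed = 101, n_decoys = 100,
                       queries = queries, profile = profile)
result <- scan_genome(sim$genome, queries, profile)
result$call$status        # "DIAZOTROPH_PREDICTED"
result$synteny_flags      # single_region TRUE for a clustered implant
result$mo_copies          # 1
```

The closed-loop evaluation used by the acceptance machinery is exported:

```{r cohort, eval = FALSE}
ev <- evaluate_cohort(seed = 1)
ev$n_call_match           # genomes whose every check matches the manifest
ev$n_dpor_removed         # DPOR decoys absent from all final outputs
```

Problem sizes here — 20 genomes, 200 decoys each, 50 motif variants per
kind, 1000 oracle alignment pairs — are the package's standard evaluation
conditions.

## Known limitations

* Sensitivity on real divergent sequences is not calibrated by the
  simulator (see above); the 20% screen is a deliberately weak convention,
  not an optimised threshold.
* The A-vs-B conventional subfamily split and tree-derived groupings are
  out of scope; `UNCLASSIFIED`/`UNDETERMINED` labels mark where motifs alone
  cannot decide.
* GenBank parsing covers the CDS/translation subset used by the fixtures
  and typical RefSeq flat files, not the full format; EMBL is unsupported.
* The e-value pathway is honoured only for imported hits; built-in mode
  substitutes a documented score threshold.
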