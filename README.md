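# nifscan

In-silico prediction of diazotrophy (biological nitrogen fixation) from
annotated prokaryotic genomes.

Experimentally demonstrating nitrogen fixation requires species-specific
conditions, so genome screens are the practical census tool — but the common
single-marker screens (*nifH* and/or *nifD* presence) misclassify genomes
that carry one marker without the rest of the machinery. `nifscan`
implements a gene-content criterion instead: a genome is a **predicted
diazotroph** when it encodes the co-occurring six-gene minimum set

> *nifH*, *nifD*, *nifK* (nitrogenase structural subunits) +
> *nifE*, *nifN*, *nifB* (FeMo-cofactor biosynthesis),

detected by protein homology against the *Azotobacter vinelandii* reference
proteins (Avin_01380 … Avin_02600) at ≥ 20 % amino-acid identity **over the
query length**, and refined with gene-neighbourhood (synteny) evidence.

Around that core the package provides:

* per-genome inventories of 12 nif gene families with per-species calls
  (`DIAZOTROPH_PREDICTED`, `GROUP_C_CANDIDATE`, `ORPHAN`, `NEGATIVE`),
  Mo-nitrogenase copy counts and Mo/V/Fe system typing via the extra
  AnfG/VnfG subunit;
* active-site ligand profiling of D-subunit sequences in *A. vinelandii*
  NifD numbering (FeMoco ligands Cys275/His442, Gln191/His195, Lys426,
  P-cluster cysteines) and subfamily classification (conventional, group C:
  Gln276 + Asp440 + no aromatic 444, group V: Ala276 + His445);
* triage of divergent nitrogenase-like sequences: subtraction of DPOR
  (ChlB/BchB/ChlN/BchN) homologs, NifH–D/E fusion detection, adjacent
  alpha/beta pairing, single-subunit NflD detection, and ligand classes
  (GREEN / YELLOW / REDUCED_CYS);
* a seeded synthetic-genome simulator producing GenBank / GFF3 / FASTA
  genomes with ground-truth manifests for every scenario, used as the
  package's closed-loop benchmark;
* readers for protein FASTA (generic or prodigal headers), GenBank flat
  files and GFF3 + genome FASTA; TSV/JSON reports; a 12-column tabular
  import path for hits computed by an external search engine.

The bundled reference FASTA files are deterministic *synthetic stand-ins*
(marked `_synthetic` in their filenames) that carry the annotated residues
at the annotated coordinates; substitute the real *A. vinelandii* DJ
proteins via `load_default_queries(fasta = ...)` for work on real genomes.

## Worked example

```r
library(nifscan)

queries <- load_default_queries()
profile <- reference_profile(queries)

# a synthetic positive genome: six-gene set at 50% identity among 100 decoys
sim <- generate_genome("complete_set", seed = 101, n_decoys = 100,
                       queries = queries, profile = profile)
res <- scan_genome(sim$genome, queries, profile)
res
#> nifscan result for sim_complete_set_101: DIAZOTROPH_PREDICTED
#>   families: nifH, nifD, nifK, nifE, nifN, nifB

res$synteny_flags
#> min3_contiguous   single_region  hdk_contiguous  dk_en_adjacent
#>            TRUE            TRUE            TRUE            TRUE
res$mo_copies
#> [1] 1
res$subtypes
#> [1] "Mo"
```

The call means: all six required families were found (none missing), they
lie in one contiguous gene region (the strongest synteny evidence), the
genome carries one Mo-nitrogenase copy and no alternative (V/Fe) system.
`write_report(res, "report.tsv")` emits the per-species table;
`write_report(res, "evidence.json", format = "json")` the full evidence.

A command-line front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/nifscan", package="nifscan"))') \
    scan genome.gbk --out report.tsv --json evidence.json
```

(subcommands: `scan`, `motifs`, `niflike`, `simulate`, `summary`).

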