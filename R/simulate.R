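SCENARIOS <- c("complete_set", "orphan_H", "orphan_D", "groupC_set",
               "alternative_V", "alternative_Fe", "two_mo_copies",
               "niflike_green", "niflike_yellow", "niflike_reduced",
               "nflD_single", "fusion_HD", "dpor_decoy", "negative")

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

random_protein <- function(len = NULL) {
  if (is.null(len))
    len <- max(50L, round(stats::rlnorm(1, meanlog = log(300), sdlog = 0.3)))
  paste(sample(AA20, len, TRUE), collapse = "")
}

#' Mutate a reference sequence to a target identity
#'
#' Substitutes exactly `round((1 - target_identity/100) * L)` positions
#' (uniformly chosen among the non-frozen ones, each to one of the 19 other
#' residues), then writes the `frozen_positions` letters exactly.  No indels
#' are introduced, so reference numbering is preserved; deletions are applied
#' separately by the motif-variant builder.
#'
#' @param family_seq reference amino-acid string.
#' @param target_identity percent identity aimed for (0-100).
#' @param seed integer seed (deterministic output).
#' @param frozen_positions named character vector `position -> letter` forced
#'   exactly, or an integer vector of positions frozen at their reference
#'   letters.
#' @return mutated amino-acid string.
#' @export
mutate_reference <- function(family_seq, target_identity, seed,
                             frozen_positions = NULL) {
  stopifnot(target_identity >= 0, target_identity <= 100)
  withr::with_seed(seed, {
    v <- strsplit(family_seq, "")[[1]]
    L <- length(v)
    if (is.null(frozen_positions)) {
      fr_pos <- integer(); fr_let <- character()
    } else if (is.null(names(frozen_positions))) {
      fr_pos <- as.integer(frozen_positions)
      fr_let <- v[fr_pos]
    } else {
      fr_pos <- as.integer(names(frozen_positions))
      fr_let <- as.character(frozen_positions)
    }
    k <- round((1 - target_identity / 100) * L)
    cand <- setdiff(seq_len(L), fr_pos)
    pick <- sample(cand, min(k, length(cand)))
    for (p in pick) v[p] <- sample(setdiff(AA20, v[p]), 1L)
    v[fr_pos] <- fr_let   # frozen letters set last and exactly
    paste(v, collapse = "")
  })
}

delete_positions <- function(seq, pos) {
  v <- strsplit(seq, "")[[1]]
  paste(v[-as.integer(pos)], collapse = "")
}

# frozen-position vectors (NifD numbering for alpha, NifK numbering for beta).
# Besides the signature letters themselves, two flanking residues on each
# side of every anchored column stay at their reference letters: the ligand
# and P-cluster positions sit inside conserved sequence blocks, and the
# conserved context is what keeps the position mapping unambiguous.
with_flanks <- function(forced, ref_seq, width = 2L) {
  pos <- as.integer(names(forced))
  fl <- sort(unique(unlist(lapply(pos, function(x)
    (x - width):(x + width)))))
  fl <- setdiff(fl[fl >= 1L & fl <= nchar(ref_seq)], pos)
  flanks <- stats::setNames(vapply(fl, function(x)
    substr(ref_seq, x, x), ""), fl)
  c(forced, flanks)
}

motif_freeze <- function(kind, profile, base_seq = profile$alpha_seq) {
  a <- profile$p_cluster_alpha
  cys3 <- stats::setNames(rep("C", 3), a)
  core <- c(`191` = "Q", `195` = "H", `426` = "K")
  ref_at <- function(pos) {
    stats::setNames(vapply(pos, function(x)
      substr(base_seq, x, x), ""), pos)
  }
  forced <- switch(kind,
    conventional = c(cys3, core, `275` = "C", `276` = "G", `440` = "S",
                     `442` = "H", `444` = "F", `445` = "E"),
    # wider flank block here: it anchors the single-column deletion at 444
    C = c(cys3, core, `275` = "C", `276` = "Q", `440` = "D", `442` = "H",
          `445` = "E", ref_at(c(438, 439, 441, 443, 446, 447, 448))),
    V = c(cys3, core, `275` = "C", `276` = "A", `440` = "S", `442` = "H",
          `444` = "F", `445` = "H"),
    green = c(cys3, `275` = "C", `276` = "G", `440` = "N", `442` = "A",
              `444` = "L", `445` = "T"),
    yellow = c(cys3, `275` = "A", `276` = "G", `440` = "N", `442` = "A",
               `444` = "L", `445` = "T"),
    reduced = c(stats::setNames(c("A", "C", "C"), a), `275` = "A",
                `276` = "G", `440` = "N", `442` = "A", `444` = "L",
                `445` = "T"),
    nflD = c(stats::setNames(c("A", "C", "C"), a), `275` = "A", `276` = "G",
             `440` = "N", `442` = "A", `444` = "L", `445` = "T"),
    stop("unknown motif kind: ", kind, call. = FALSE))
  with_flanks(forced, base_seq)
}

beta_freeze <- function(kind, profile, base_seq = profile$beta_seq) {
  b <- profile$p_cluster_beta
  forced <- switch(kind,
    conventional = , green = , yellow = stats::setNames(rep("C", 3), b),
    reduced = stats::setNames(c("A", "C", "A"), b),
    stop("no beta freeze for kind: ", kind, call. = FALSE))
  with_flanks(forced, base_seq)
}

#' Build a motif-variant alpha (and beta) sequence pair
#'
#' Generates mutated copies of the reference subunits with the subfamily /
#' ligand-class signature columns forced: `C` (Gln276, Asp440, deletion of
#' 444), `V` (Ala276, His445), `green` (Cys275 kept, His442 lost, 3 alpha
#' P-cluster Cys), `yellow` (both FeMoco ligands lost, 3 Cys), `reduced`
#' (2 alpha Cys + 1 beta Cys, the Mlab/Dhaf pattern), `nflD` (single
#' subunit, 2 alpha Cys), `conventional` (all ligands intact).
#'
#' @param kind one of conventional, C, V, green, yellow, reduced, nflD.
#' @param target_identity percent identity of the mutated copies.
#' @param seed integer seed.
#' @param queries reference query table.
#' @param profile reference profile.
#' @return list with `alpha` (sequence), `beta` (sequence or NULL),
#'   `alpha_base`, `beta_base` (source families), `kind`.
#' @export
make_motif_variant <- function(kind, target_identity = 50, seed = 1,
                               queries = load_default_queries(),
                               profile = reference_profile()) {
  qseq <- function(f) queries$sequence[queries$family == f]
  alpha_base <- switch(kind, green = , yellow = "nifE", "nifD")
  beta_base <- switch(kind, green = , yellow = "nifN",
                      reduced = , conventional = "nifK", NA)
  alpha <- mutate_reference(qseq(alpha_base), target_identity, seed,
                            motif_freeze(kind, profile, qseq(alpha_base)))
  if (kind == "C") alpha <- delete_positions(alpha, 444L)
  beta <- NULL
  if (!is.na(beta_base))
    beta <- mutate_reference(qseq(beta_base), target_identity, seed + 1L,
                             beta_freeze(kind, profile, qseq(beta_base)))
  list(alpha = alpha, beta = beta, alpha_base = alpha_base,
       beta_base = beta_base, kind = kind)
}

# implant blueprint for one scenario: list of blocks; each block is a list of
# implant entries (family = truth family used for the mutation, kind, seq)
scenario_blueprint <- function(scenario, target_identity, seed, queries,
                               profile) {
  qseq <- function(f) queries$sequence[queries$family == f]
  plain <- function(f, s_off) {
    list(family = f, kind = "plain",
         seq = mutate_reference(qseq(f), target_identity, seed + s_off))
  }
  conv_alpha <- function(f, s_off) {
    list(family = f, kind = "conventional",
         seq = mutate_reference(qseq(f), target_identity, seed + s_off,
                                motif_freeze("conventional", profile,
                                             qseq(f))))
  }
  conv_beta <- function(f, s_off) {
    list(family = f, kind = "conventional",
         seq = mutate_reference(qseq(f), target_identity, seed + s_off,
                                beta_freeze("conventional", profile,
                                            qseq(f))))
  }
  complete <- function(off = 0L) list(plain("nifH", 1L + off),
                                      conv_alpha("nifD", 2L + off),
                                      conv_beta("nifK", 3L + off),
                                      conv_alpha("nifE", 4L + off),
                                      conv_beta("nifN", 5L + off),
                                      plain("nifB", 6L + off))
  variant <- function(kind, off = 10L) {
    mv <- make_motif_variant(kind, target_identity, seed + off, queries,
                             profile)
    out <- list(list(family = mv$alpha_base, kind = kind, seq = mv$alpha))
    if (!is.null(mv$beta))
      out <- c(out, list(list(family = mv$beta_base,
                              kind = paste0(kind, "_beta"), seq = mv$beta)))
    out
  }
  switch(scenario,
    complete_set = list(complete()),
    orphan_H = list(list(plain("nifH", 1L))),
    orphan_D = list(list(conv_alpha("nifD", 1L))),
    groupC_set = list(c(list(plain("nifH", 1L)),
                        variant("C")[1],
                        list(conv_beta("nifK", 3L), plain("nifB", 4L),
                             plain("nifV", 5L)))),
    alternative_V = list(complete(),
                         c(variant("V")[1], list(plain("vnfG", 20L)))),
    alternative_Fe = list(complete(),
                          c(variant("V", off = 11L)[1],
                            list(plain("anfG", 21L)))),
    two_mo_copies = list(complete(),
                         list(plain("nifH", 31L), conv_alpha("nifD", 32L),
                              conv_beta("nifK", 33L))),
    niflike_green = list(variant("green")),
    niflike_yellow = list(variant("yellow")),
    niflike_reduced = list(variant("reduced")),
    nflD_single = list(variant("nflD")),
    fusion_HD = {
      h <- mutate_reference(qseq("nifH"), target_identity, seed + 1L)
      e <- make_motif_variant("green", target_identity, seed + 2L, queries,
                              profile)$alpha
      list(list(list(family = "nifH+nifE", kind = "fusion_HD",
                     seq = paste0(h, e))))
    },
    dpor_decoy = list(),
    negative = list(),
    stop("unknown scenario: ", scenario, call. = FALSE))
}

scenario_expectation <- function(scenario, arrangement) {
  clustered <- arrangement == "clustered"
  e <- list(call = "NEGATIVE", subtypes = list(), mo_copies = 0L,
            single_region = FALSE, min3_contiguous = FALSE,
            n_niflike_pairs = 0L, ligand_class = NULL, n_nfld_singles = 0L,
            n_fusions = 0L, n_dpor_decoys = 0L, orphan = FALSE)
  switch(scenario,
    complete_set = {
      e$call <- "DIAZOTROPH_PREDICTED"; e$subtypes <- list("Mo")
      e$mo_copies <- if (clustered) 1L else 0L
      e$single_region <- clustered; e$min3_contiguous <- clustered
    },
    orphan_H = { e$call <- "ORPHAN"; e$orphan <- TRUE },
    orphan_D = { e$call <- "ORPHAN"; e$orphan <- TRUE
                 e$subtypes <- list("Mo") },
    groupC_set = { e$call <- "GROUP_C_CANDIDATE"
                   e$subtypes <- list("Mo")
                   e$mo_copies <- if (clustered) 1L else 0L
                   e$min3_contiguous <- clustered },
    alternative_V = {
      e$call <- "DIAZOTROPH_PREDICTED"; e$subtypes <- list("Mo", "V")
      e$mo_copies <- if (clustered) 1L else 0L
      e$single_region <- clustered; e$min3_contiguous <- clustered
    },
    alternative_Fe = {
      e$call <- "DIAZOTROPH_PREDICTED"; e$subtypes <- list("Mo", "Fe")
      e$mo_copies <- if (clustered) 1L else 0L
      e$single_region <- clustered; e$min3_contiguous <- clustered
    },
    two_mo_copies = {
      e$call <- "DIAZOTROPH_PREDICTED"; e$subtypes <- list("Mo")
      e$mo_copies <- if (clustered) 2L else 0L
      e$single_region <- clustered
      e$min3_contiguous <- clustered
    },
    niflike_green = { e$n_niflike_pairs <- 1L; e$ligand_class <- "GREEN" },
    niflike_yellow = { e$n_niflike_pairs <- 1L; e$ligand_class <- "YELLOW" },
    niflike_reduced = { e$n_niflike_pairs <- 1L
                        e$ligand_class <- "REDUCED_CYS" },
    nflD_single = { e$n_nfld_singles <- 1L },
    fusion_HD = { e$n_fusions <- 1L },
    dpor_decoy = { e$n_dpor_decoys <- 50L },
    negative = { })
  e
}

SIM_PHYLA <- data.frame(
  domain = c("Bacteria", "Bacteria", "Archaea", "Bacteria"),
  phylum = c("Proteobacteria", "Firmicutes", "Euryarchaeota", "Cyanobacteria"))

#' Generate a seeded synthetic genome with ground truth
#'
#' Implants mutated copies of the reference nif families (per scenario) among
#' random decoy proteins and emits the genome in all supported formats plus a
#' manifest recording every implanted locus and the expected analysis
#' outcome.  Identical seed and configuration give byte-identical files.
#'
#' Scenarios: `r paste(SCENARIOS, collapse = ", ")`.
#'
#' @param scenario scenario name.
#' @param seed integer seed for this genome.
#' @param out_dir directory for on-disk output (`<species>.gbk`, `.gff3`,
#'   `.fna`, `.faa`, `_manifest.json`); `NULL` keeps everything in memory.
#' @param n_decoys number of random decoy proteins (length ~ lognormal,
#'   median 300).
#' @param target_identity percent identity of implants to their reference.
#' @param arrangement `"clustered"` (implants at consecutive gene indices) or
#'   `"dispersed"` (implants >= 10 genes apart).
#' @param queries,profile reference data.
#' @param taxonomy_index row of the built-in 4-phylum rotation to assign.
#' @return list with `genome` ([genome_annotation()]), `manifest` (list), and
#'   `paths` (when written to disk).
#' @export
generate_genome <- function(scenario, seed, out_dir = NULL, n_decoys = 200,
                            target_identity = 50,
                            arrangement = c("clustered", "dispersed"),
                            queries = load_default_queries(),
                            profile = reference_profile(),
                            taxonomy_index = NULL) {
  arrangement <- match.arg(arrangement)
  if (!scenario %in% SCENARIOS)
    stop("unknown scenario: ", scenario, call. = FALSE)
  blocks <- scenario_blueprint(scenario, target_identity, seed, queries,
                               profile)
  species <- sprintf("sim_%s_%d", scenario, seed)
  withr::with_seed(seed, {
    decoys <- vapply(seq_len(n_decoys), function(i) random_protein(), "")
    kinds <- rep("decoy", n_decoys)
    fams <- rep(NA_character_, n_decoys)
    if (scenario == "dpor_decoy") {
      dpor <- load_dpor_references()
      dd <- vapply(seq_len(50L), function(i) {
        src <- dpor$sequence[((i - 1L) %% nrow(dpor)) + 1L]
        mutate_reference(src, 60, seed + 100L + i)
      }, "")
      decoys <- c(decoys, dd)
      kinds <- c(kinds, rep("dpor_decoy", 50L))
      fams <- c(fams, rep(dpor$family, length.out = 50L))
      perm <- sample(length(decoys))
      decoys <- decoys[perm]; kinds <- kinds[perm]; fams <- fams[perm]
    }
    # final gene order: insert implant blocks into the decoy sequence
    if (arrangement == "dispersed")
      blocks <- unlist(lapply(blocks, function(b) lapply(b, list)),
                       recursive = FALSE)
    nb <- length(blocks)
    seq_all <- decoys; kind_all <- kinds; fam_all <- fams
    if (nb > 0L) {
      if (arrangement == "dispersed") {
        # implants sit >= 10 genes apart
        if (length(decoys) < 10L * nb)
          stop("too few decoys for a dispersed arrangement", call. = FALSE)
        s <- max(10L, floor(length(decoys) / (nb + 1L)))
        jit_max <- max(0L, min(3L, s - 10L))
        jit <- if (jit_max > 0L) sample(seq(-jit_max, jit_max), nb, TRUE)
          else rep(0L, nb)
        anchors <- s * seq_len(nb) + jit
      } else {
        anchors <- floor(length(decoys) * seq_len(nb) / (nb + 1L)) +
          sample(-3:3, nb, TRUE)
      }
      anchors <- pmax(1L, pmin(length(decoys) - 1L, anchors))
      ord <- order(anchors)
      blocks <- blocks[ord]; anchors <- sort(anchors)
      seq_all <- character(); kind_all <- character(); fam_all <- character()
      prev <- 0L
      for (b in seq_len(nb)) {
        idx <- (prev + 1L):anchors[b]
        seq_all <- c(seq_all, decoys[idx])
        kind_all <- c(kind_all, kinds[idx]); fam_all <- c(fam_all, fams[idx])
        for (im in blocks[[b]]) {
          seq_all <- c(seq_all, im$seq)
          kind_all <- c(kind_all, im$kind); fam_all <- c(fam_all, im$family)
        }
        prev <- anchors[b]
      }
      if (prev < length(decoys)) {
        idx <- (prev + 1L):length(decoys)
        seq_all <- c(seq_all, decoys[idx])
        kind_all <- c(kind_all, kinds[idx]); fam_all <- c(fam_all, fams[idx])
      }
    }
    n <- length(seq_all)
    locus <- sprintf("%s_%04d", species, seq_len(n))
    strand <- sample(c("+", "-"), n, TRUE, prob = c(0.7, 0.3))
    strand[kind_all != "decoy"] <- "+"
    lens_nt <- 3L * (nchar(seq_all) + 1L)
    spacer <- 20L
    start <- cumsum(c(1L, utils::head(lens_nt + spacer, -1L)))
    end <- start + lens_nt - 1L
    rec <- data.frame(protein_id = locus, locus_tag = locus,
                      replicon_id = "chr1", start = start, end = end,
                      strand = strand, sequence = seq_all)
    tax_i <- taxonomy_index %||% (seed %% nrow(SIM_PHYLA) + 1L)
    taxonomy <- as.list(SIM_PHYLA[tax_i, ])
    genome <- genome_annotation(rec, species, paste0(species, "_asm"),
                                taxonomy)
  })
  implant_rows <- genome$records[kind_all != "decoy", c("locus_tag",
                                                        "gene_index")]
  manifest <- list(
    species_name = species, assembly_id = paste0(species, "_asm"),
    scenario = scenario, seed = seed, arrangement = arrangement,
    target_identity = target_identity, n_decoys = n_decoys,
    taxonomy = genome$taxonomy,
    implants = data.frame(
      locus_tag = implant_rows$locus_tag,
      gene_index = implant_rows$gene_index,
      family = fam_all[kind_all != "decoy"],
      kind = kind_all[kind_all != "decoy"]),
    expected = scenario_expectation(scenario, arrangement))
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- write_genome_files(genome, out_dir)
    mpath <- file.path(out_dir, paste0(species, "_manifest.json"))
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths$manifest <- mpath
  }
  list(genome = genome, manifest = manifest, paths = paths)
}

#' Generate the standard 20-genome evaluation cohort
#'
#' All scenarios represented (six repeated), 50\% implant identity, 200
#' decoys per genome, clustered arrangement except one dispersed
#' complete-set genome.
#'
#' @param seed master seed; genome g uses `seed * 1000 + g`.
#' @param n_decoys,target_identity per-genome settings.
#' @param queries,profile reference data.
#' @return list of [generate_genome()] results, length 20.
#' @export
simulate_cohort <- function(seed, n_decoys = 200, target_identity = 50,
                            queries = load_default_queries(),
                            profile = reference_profile()) {
  plan <- data.frame(
    scenario = c(SCENARIOS, "complete_set", "niflike_green", "orphan_H",
                 "two_mo_copies", "negative", "complete_set"),
    arrangement = "clustered")
  plan$arrangement[nrow(plan)] <- "dispersed"
  lapply(seq_len(nrow(plan)), function(g) {
    generate_genome(plan$scenario[g], seed * 1000L + g,
                    n_decoys = n_decoys, target_identity = target_identity,
                    arrangement = plan$arrangement[g], queries = queries,
                    profile = profile, taxonomy_index = (g %% 4L) + 1L)
  })
}

#' Implant a nifH copy at an exact measured identity-over-query
#'
#' Searches over substitution counts (and mutation placements) until the
#' built-in local aligner measures exactly `target_n_identical` identities
#' against the query, i.e. a pinned identity-over-query-length percentage.
#' Used to probe threshold boundary semantics.
#'
#' @param target_n_identical desired identity count against the full query.
#' @param family query family (default nifH).
#' @param seed integer seed.
#' @param queries reference table.
#' @return list with `seq`, `measured_pid`, `n_identical`.
#' @export
implant_with_measured_identity <- function(target_n_identical,
                                           family = "nifH", seed = 1,
                                           queries = load_default_queries()) {
  qseq <- queries$sequence[queries$family == family]
  L <- nchar(qseq)
  measure <- function(s) align_local(qseq, s)$n_identical
  k <- L - target_n_identical
  for (attempt in 0:199) {
    s <- mutate_reference(qseq, 100 * (L - k) / L, seed + 7919L * attempt)
    nid <- measure(s)
    if (nid == target_n_identical)
      return(list(seq = s, measured_pid = 100 * nid / L, n_identical = nid))
    if (attempt %% 4L == 3L) k <- k + sign(nid - target_n_identical)
  }
  stop("could not pin identity count at ", target_n_identical, call. = FALSE)
}
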