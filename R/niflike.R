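#' Detect a NifH-D/E fusion from one protein's hit set
#'
#' A protein is a fusion candidate when distinct, essentially non-overlapping
#' regions of it hit an H-type query and a D/E-type query (subject-interval
#' overlap at most `overlap_tol` of the shorter interval).  Fused records are
#' excluded from subunit pairing and from the alignment export.
#'
#' @param hits_for_one_protein rows of the full hit table (`attr(assigned,
#'   "all_hits")`) sharing one `protein_id`.
#' @param overlap_tol maximum allowed fractional overlap (default 0.1).
#' @return logical.
#' @export
detect_fusion <- function(hits_for_one_protein, overlap_tol = 0.1) {
  h <- hits_for_one_protein
  hh <- h[h$family == "nifH", , drop = FALSE]
  hd <- h[h$family %in% ALPHA_FAMILIES, , drop = FALSE]
  if (nrow(hh) == 0L || nrow(hd) == 0L) return(FALSE)
  for (i in seq_len(nrow(hh))) {
    for (j in seq_len(nrow(hd))) {
      ov <- min(hh$subject_end[i], hd$subject_end[j]) -
        max(hh$subject_start[i], hd$subject_start[j]) + 1L
      shorter <- min(hh$subject_end[i] - hh$subject_start[i],
                     hd$subject_end[j] - hd$subject_start[j]) + 1L
      if (ov <= overlap_tol * shorter) return(TRUE)
    }
  }
  FALSE
}

# best local-alignment score of each sequence against the DPOR references
dpor_best_scores <- function(seqs, dpor_refs = load_dpor_references(),
                             matrix = "BLOSUM62", gap_open = 11,
                             gap_extend = 1) {
  if (!length(seqs)) return(numeric())
  best <- rep(0, length(seqs))
  for (k in seq_len(nrow(dpor_refs))) {
    b <- align_local_batch(dpor_refs$sequence[k], seqs, matrix, gap_open,
                           gap_extend)
    best <- pmax(best, b$score)
  }
  best
}

#' Drop candidates better explained by DPOR
#'
#' Comparative subtraction of protochlorophyllide-reductase homologs: a
#' candidate is dropped when its best score against the ChlB/BchB/ChlN/BchN
#' references is at least its best score against the nitrogenase-family
#' references.
#'
#' @param candidates data.frame with `score` (best nitrogenase-reference
#'   score) and `dpor_score` columns.
#' @return list with `retained` and `removed` data.frames.
#' @export
filter_dpor <- function(candidates) {
  drop <- candidates$dpor_score >= candidates$score
  list(retained = candidates[!drop, , drop = FALSE],
       removed = candidates[drop, , drop = FALSE])
}

#' Greedy pairing of adjacent alpha- and beta-like candidates
#'
#' Pairs each alpha-like candidate with the nearest unused beta-like
#' candidate on the same replicon within `max_gap` intervening genes
#' (equidistant ties prefer the lower gene index); each candidate joins at
#' most one pair, so a four-gene tandem `[alpha, beta, alpha, beta]` yields
#' two pairs.  Unpaired alpha/beta candidates are singles (NflD pattern).
#'
#' @param candidates data.frame with `subunit_type` ("alpha_like" /
#'   "beta_like"), `replicon_id`, `gene_index`.
#' @param max_gap adjacency tolerance (intervening genes).
#' @return list with `pairs` (data.frame `alpha_idx`, `beta_idx` row indices
#'   into `candidates`) and `singles` (row indices).
#' @export
pair_adjacent_subunits <- function(candidates, max_gap = 2) {
  alphas <- which(candidates$subunit_type == "alpha_like")
  betas <- which(candidates$subunit_type == "beta_like")
  alphas <- alphas[order(candidates$gene_index[alphas])]
  used_beta <- logical(length(candidates$gene_index))
  pairs <- list()
  for (a in alphas) {
    cand <- betas[!used_beta[betas] &
                    candidates$replicon_id[betas] == candidates$replicon_id[a]]
    if (!length(cand)) next
    d <- abs(candidates$gene_index[cand] - candidates$gene_index[a])
    cand <- cand[d <= max_gap + 1L]
    d <- d[d <= max_gap + 1L]
    if (!length(cand)) next
    pick <- cand[order(d, candidates$gene_index[cand])][1L]
    used_beta[pick] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(alpha_idx = a, beta_idx = pick)
  }
  paired <- unlist(pairs)
  singles <- setdiff(c(alphas, betas), paired)
  list(pairs = if (length(pairs)) as.data.frame(do.call(rbind, pairs))
       else data.frame(alpha_idx = integer(), beta_idx = integer()),
       singles = sort(singles))
}

#' Ligand class of a nitrogenase-like pair or single
#'
#' Figure-style classes driven by the alpha-subunit FeMoco positions and the
#' P-cluster cysteine counts: `REDUCED_CYS` when the alpha subunit conserves
#' fewer than three P-cluster cysteines (per-subunit counts are reported, e.g.
#' the 2+1 pattern); `GREEN` when Cys275 is present but His442 lost;
#' `YELLOW` when both FeMoco ligands are lost; `NFLD_SINGLE` passthrough for
#' single-subunit candidates; `UNDETERMINED` for the residual combination
#' (His442 retained), which conventional-sequence exclusion makes
#' unreachable in practice.
#'
#' @param alpha_profile [extract_ligand_profile()] of the alpha candidate.
#' @param single is this an unpaired (NflD) candidate?
#' @return character label.
#' @export
classify_ligand_class <- function(alpha_profile, single = FALSE) {
  if (single) return("NFLD_SINGLE")
  if (alpha_profile$p_cluster_cys_count < 3L) return("REDUCED_CYS")
  if (alpha_profile$has_C275 && !alpha_profile$has_H442) return("GREEN")
  if (!alpha_profile$has_C275 && !alpha_profile$has_H442) return("YELLOW")
  "UNDETERMINED"
}

#' Collapse near-identical sequences to representatives
#'
#' Single-linkage clustering at `threshold` percent identity over the shorter
#' sequence (shorter-as-query); each cluster is represented by its longest
#' member (ties: lexicographically smallest ID).
#'
#' @param seqs named character vector of sequences.
#' @param threshold percent identity for linkage (default 90).
#' @return named character vector of representatives.
#' @export
dedup_by_identity <- function(seqs, threshold = 90) {
  n <- length(seqs)
  if (n <= 1L) return(seqs)
  ids <- names(seqs) %||% as.character(seq_len(n))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shorter <- if (nchar(seqs[i]) <= nchar(seqs[j])) i else j
      longer <- if (shorter == i) j else i
      al <- align_local(seqs[[shorter]], seqs[[longer]])
      pid <- 100 * al$n_identical / nchar(seqs[[shorter]])
      if (pid >= threshold) parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  reps <- vapply(split(seq_len(n), comp), function(members) {
    lens <- nchar(seqs[members])
    members <- members[lens == max(lens)]
    members[order(ids[members])][1L]
  }, 1L)
  seqs[sort(reps)]
}

#' Export representative sequences for external alignment / tree building
#'
#' Writes an unaligned multi-FASTA suitable for ClustalW (Gonnet series
#' matrices) followed by FastTree (WAG + 20-category gamma), the external
#' pipeline this package delegates phylogenetics to.
#'
#' @param representatives named character vector of sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
export_alignment <- function(representatives, path) {
  if (!length(representatives)) {
    warning("no sequences to export; writing empty file", call. = FALSE)
    file.create(path)
    return(invisible(path))
  }
  aa <- Biostrings::AAStringSet(unlist(representatives))
  names(aa) <- names(representatives)
  Biostrings::writeXStringSet(aa, path, width = 60)
  invisible(path)
}

#' Triage divergent nitrogenase-like sequences in one genome
#'
#' Runs the full divergent-sequence workflow over a family-assigned hit
#' table: fusion detection (NifH fused to a D/E-like region), comparative
#' DPOR subtraction, selection of alpha-like candidates (D/E-assigned
#' proteins whose ligand profile matches no conventional subfamily),
#' co-located beta-like partners, greedy adjacent pairing, NflD singles and
#' ligand-class assignment.
#'
#' @param genome [genome_annotation()].
#' @param assigned [search_proteome()] output for this genome (carries the
#'   full hit table as an attribute).
#' @param profile reference profile.
#' @param dpor_refs DPOR reference table ([load_dpor_references()]).
#' @param max_gap synteny adjacency tolerance.
#' @param min_score minimum nitrogenase-reference alignment score for a
#'   divergent candidate (score-equivalent stand-in for an e-value gate; the
#'   bundled NifD-vs-NifE score passes it, random proteins do not).
#' @param matrix,gap_open,gap_extend scoring scheme.
#' @return list: `candidates` (data.frame with `subunit_type`,
#'   `ligand_class`, `cys_alpha`, `cys_beta`, `pair_partner`), `fusions`,
#'   `dpor_removed`, `alpha_labels` (subfamily per retained alpha locus tag),
#'   `excluded_locus_tags` (all loci to drop from the diazotrophy inventory).
#' @export
niflike_triage <- function(genome, assigned, profile = reference_profile(),
                           dpor_refs = load_dpor_references(), max_gap = 2,
                           min_score = 100, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  all_hits <- attr(assigned, "all_hits")
  rec <- genome$records
  seq_of <- stats::setNames(rec$sequence, rec$protein_id)
  empty_cand <- data.frame(protein_id = character(), locus_tag = character(),
                           replicon_id = character(), gene_index = integer(),
                           family = character(), subunit_type = character(),
                           ligand_class = character(), cys_alpha = integer(),
                           cys_beta = integer(), pair_partner = character())
  out <- list(candidates = empty_cand,
              fusions = assigned[0, , drop = FALSE],
              dpor_removed = assigned[0, , drop = FALSE],
              alpha_labels = character(), excluded_locus_tags = character())
  if (nrow(assigned) == 0L) return(out)

  fusion_ids <- unique(unlist(lapply(split(all_hits, all_hits$protein_id),
                                     function(h) if (detect_fusion(h))
                                       h$protein_id[1L] else NULL)))
  out$fusions <- assigned[assigned$protein_id %in% fusion_ids, , drop = FALSE]

  dekn <- assigned[assigned$family %in% DEKN_FAMILIES &
                     !(assigned$protein_id %in% fusion_ids), , drop = FALSE]
  if (nrow(dekn)) {
    dekn$dpor_score <- dpor_best_scores(seq_of[dekn$protein_id], dpor_refs,
                                        matrix, gap_open, gap_extend)
    fl <- filter_dpor(dekn)
    out$dpor_removed <- fl$removed
    dekn <- fl$retained
  }

  alpha <- dekn[dekn$family %in% ALPHA_FAMILIES, , drop = FALSE]
  labels <- character()
  alpha_profiles <- list()
  for (i in seq_len(nrow(alpha))) {
    s <- seq_of[[alpha$protein_id[i]]]
    lab <- "UNCLASSIFIED"; prof <- NULL
    if (nchar(s) >= 100L) {
      pm <- map_positions(s, profile, "alpha", alpha$family[i], matrix,
                          gap_open, gap_extend)
      prof <- extract_ligand_profile(pm, profile)
      lab <- classify_nifd_subfamily(prof)$label
    }
    labels[alpha$locus_tag[i]] <- lab
    alpha_profiles[[alpha$protein_id[i]]] <- prof
  }
  out$alpha_labels <- labels
  is_alpha_cand <- alpha$locus_tag %in%
    names(labels)[labels == "UNCLASSIFIED"] & alpha$score >= min_score
  alpha_cand <- alpha[is_alpha_cand, , drop = FALSE]
  # alpha loci that became candidates carry no conventional label downstream
  out$alpha_labels <- labels[!(names(labels) %in% alpha_cand$locus_tag)]

  beta <- dekn[dekn$family %in% BETA_FAMILIES, , drop = FALSE]
  near_alpha <- vapply(seq_len(nrow(beta)), function(i) {
    any(beta$replicon_id[i] == alpha_cand$replicon_id &
          abs(beta$gene_index[i] - alpha_cand$gene_index) <= max_gap + 1L)
  }, logical(1))
  beta_cand <- beta[near_alpha, , drop = FALSE]

  cand <- rbind(
    if (nrow(alpha_cand)) cbind(alpha_cand[, c("protein_id", "locus_tag",
                                               "replicon_id", "gene_index",
                                               "family")],
                                subunit_type = "alpha_like"),
    if (nrow(beta_cand)) cbind(beta_cand[, c("protein_id", "locus_tag",
                                             "replicon_id", "gene_index",
                                             "family")],
                               subunit_type = "beta_like"))
  if (is.null(cand) || nrow(cand) == 0L) {
    out$excluded_locus_tags <- unique(c(out$fusions$locus_tag,
                                        out$dpor_removed$locus_tag))
    return(out)
  }
  rownames(cand) <- NULL
  cand$cys_alpha <- NA_integer_; cand$cys_beta <- NA_integer_
  cand$ligand_class <- NA_character_; cand$pair_partner <- NA_character_
  for (i in which(cand$subunit_type == "alpha_like")) {
    prof <- alpha_profiles[[cand$protein_id[i]]]
    if (!is.null(prof)) cand$cys_alpha[i] <- prof$p_cluster_cys_count
  }
  for (i in which(cand$subunit_type == "beta_like")) {
    s <- seq_of[[cand$protein_id[i]]]
    if (nchar(s) >= 100L) {
      pm <- map_positions(s, profile, "beta", cand$family[i], matrix,
                          gap_open, gap_extend)
      cand$cys_beta[i] <- count_p_cluster_cys(pm, profile$p_cluster_beta,
                                              profile)
    }
  }
  pr <- pair_adjacent_subunits(cand, max_gap)
  for (k in seq_len(nrow(pr$pairs))) {
    a <- pr$pairs$alpha_idx[k]; b <- pr$pairs$beta_idx[k]
    cls <- classify_ligand_class(alpha_profiles[[cand$protein_id[a]]])
    cand$ligand_class[c(a, b)] <- cls
    cand$pair_partner[a] <- cand$locus_tag[b]
    cand$pair_partner[b] <- cand$locus_tag[a]
    cand$cys_beta[a] <- cand$cys_beta[b]
    cand$cys_alpha[b] <- cand$cys_alpha[a]
  }
  for (i in pr$singles) cand$ligand_class[i] <- "NFLD_SINGLE"
  out$candidates <- cand
  out$excluded_locus_tags <- unique(c(out$fusions$locus_tag,
                                      out$dpor_removed$locus_tag,
                                      cand$locus_tag))
  out
}
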