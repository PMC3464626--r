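#' Screen a proteome for nif-family homologs
#'
#' Aligns every query family against every protein (local alignment,
#' BLOSUM62, gap open 11 / extend 1 by default) and keeps pairs whose
#' identity-over-query-length reaches `min_pid` (a deliberately weak
#' >= 20\% screen).  Each protein is then assigned to the single family
#' with the highest alignment score; the margin to the runner-up family is
#' reported and hits with a margin below `ambiguity_tau * best_score` are
#' flagged ambiguous (this resolves the NifD/NifE and NifK/NifN
#' cross-similarity inherent to the scaffold paralogy).
#'
#' @param queries query table from [load_default_queries()] (or a compatible
#'   data.frame with `family`, `sequence`).
#' @param genome a [genome_annotation()].
#' @param min_pid retention threshold on identity over query length (percent).
#' @param matrix,gap_open,gap_extend scoring scheme (see [align_local()]).
#' @param ambiguity_tau fraction of the best score under which the
#'   best-vs-second margin flags the assignment as ambiguous.
#' @return data.frame of family-assigned hits (one row per protein):
#'   `protein_id`, `locus_tag`, `replicon_id`, `gene_index`, `family`,
#'   `pid_over_query`, `score`, `n_identical`, subject/query spans,
#'   `ambiguity_margin`, `ambiguous`.  The full per-(family, protein) hit
#'   table (before best-family collapse, sorted by protein then descending
#'   score) is attached as `attr(x, "all_hits")`.
#' @export
search_proteome <- function(queries, genome, min_pid = 20,
                            matrix = "BLOSUM62", gap_open = 11,
                            gap_extend = 1, ambiguity_tau = 0.1) {
  stopifnot(inherits(genome, "genome_annotation"))
  rec <- genome$records
  empty <- data.frame(protein_id = character(), locus_tag = character(),
                      replicon_id = character(), gene_index = integer(),
                      family = character(), pid_over_query = numeric(),
                      score = integer(), n_identical = integer(),
                      query_start = integer(), query_end = integer(),
                      subject_start = integer(), subject_end = integer(),
                      ambiguity_margin = numeric(), ambiguous = logical())
  if (nrow(rec) == 0L) {
    warning("empty proteome: no hits", call. = FALSE)
    attr(empty, "all_hits") <- empty[, seq_len(12)]
    return(empty)
  }
  hits <- list()
  for (k in seq_len(nrow(queries))) {
    fam <- queries$family[k]
    qseq <- queries$sequence[k]
    b <- align_local_batch(qseq, rec$sequence, matrix, gap_open, gap_extend)
    pid <- 100 * b$n_identical / nchar(qseq)
    keep <- which(pid >= min_pid)
    if (!length(keep)) next
    hits[[fam]] <- data.frame(
      protein_id = rec$protein_id[keep], locus_tag = rec$locus_tag[keep],
      replicon_id = rec$replicon_id[keep], gene_index = rec$gene_index[keep],
      family = fam, pid_over_query = pid[keep], score = b$score[keep],
      n_identical = b$n_identical[keep],
      query_start = b$query_start[keep], query_end = b$query_end[keep],
      subject_start = b$subject_start[keep], subject_end = b$subject_end[keep])
  }
  if (!length(hits)) {
    attr(empty, "all_hits") <- empty[, seq_len(12)]
    return(empty)
  }
  all_hits <- do.call(rbind, hits)
  all_hits <- all_hits[order(all_hits$protein_id, -all_hits$score,
                             match(all_hits$family, FAMILY_ORDER)), ,
                       drop = FALSE]
  rownames(all_hits) <- NULL
  assigned <- do.call(rbind, lapply(split(all_hits, all_hits$protein_id),
                                    assign_family,
                                    ambiguity_tau = ambiguity_tau))
  assigned <- assigned[order(assigned$replicon_id, assigned$gene_index), ,
                       drop = FALSE]
  rownames(assigned) <- NULL
  attr(assigned, "all_hits") <- all_hits
  assigned
}

#' Resolve the family assignment for one protein's hits
#'
#' The family with the highest alignment score wins; exact score ties break
#' deterministically by the fixed family order (nifH < nifD < nifK < nifE <
#' nifN < nifB < ...), and tied assignments are flagged ambiguous.
#'
#' @param hits_for_one_protein data.frame of hits sharing one `protein_id`.
#' @param ambiguity_tau margin fraction under which the call is flagged.
#' @return single-row data.frame with `ambiguity_margin` and `ambiguous`.
#' @export
assign_family <- function(hits_for_one_protein, ambiguity_tau = 0.1) {
  h <- hits_for_one_protein
  stopifnot(nrow(h) >= 1L, length(unique(h$protein_id)) == 1L)
  ord <- order(-h$score, match(h$family, FAMILY_ORDER))
  h <- h[ord, , drop = FALSE]
  best <- h[1L, , drop = FALSE]
  if (nrow(h) == 1L) {
    best$ambiguity_margin <- as.numeric(best$score)
    best$ambiguous <- FALSE
  } else {
    margin <- as.numeric(best$score - h$score[2L])
    best$ambiguity_margin <- margin
    best$ambiguous <- margin < ambiguity_tau * best$score
  }
  best
}

#' Import externally computed homology hits (tabular, "outfmt 6")
#'
#' Accepts the conventional 12-column tabular search format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`).  Query IDs must be reference locus tags or family
#' names.  The identity count is recovered as `round(pident/100 * length)`
#' and identity-over-query recomputed against the bundled query lengths;
#' because gapped columns are approximated this pathway carries an
#' `approximate_pid = TRUE` flag.  E-values are preserved (they gate the
#' nitrogenase-like collection step in import mode).
#'
#' @param path tabular file.
#' @param queries reference table from [load_default_queries()].
#' @param min_pid retention threshold (percent identity over query length).
#' @param ambiguity_tau see [search_proteome()].
#' @return family-assigned hit table (as [search_proteome()], without genome
#'   coordinates; `gene_index`/`replicon_id` are NA and synteny requires a
#'   coordinate-bearing genome source).
#' @export
import_tabular_hits <- function(path, queries = load_default_queries(),
                                min_pid = 20, ambiguity_tau = 0.1) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 12L)
    stop("expected 12 tab-separated columns, got ", ncol(tab), call. = FALSE)
  names(tab) <- cols
  fam <- queries$family[match(tab$qseqid, queries$reference_locus)]
  fam2 <- ifelse(tab$qseqid %in% queries$family, tab$qseqid, NA)
  fam <- ifelse(is.na(fam), fam2, fam)
  if (anyNA(fam))
    stop("query IDs not in the reference set: ",
         paste(unique(tab$qseqid[is.na(fam)]), collapse = ", "),
         call. = FALSE)
  qlen <- nchar(queries$sequence)[match(fam, queries$family)]
  nident <- round(tab$pident / 100 * tab$length)
  pid <- 100 * nident / qlen
  hits <- data.frame(protein_id = tab$sseqid, locus_tag = tab$sseqid,
                     replicon_id = NA_character_, gene_index = NA_integer_,
                     family = fam, pid_over_query = pid,
                     score = tab$bitscore, n_identical = nident,
                     query_start = tab$qstart, query_end = tab$qend,
                     subject_start = tab$sstart, subject_end = tab$send,
                     evalue = tab$evalue)
  hits <- hits[hits$pid_over_query >= min_pid, , drop = FALSE]
  hits <- hits[order(hits$protein_id, -hits$score,
                     match(hits$family, FAMILY_ORDER)), , drop = FALSE]
  rownames(hits) <- NULL
  assigned <- if (nrow(hits)) {
    out <- do.call(rbind, lapply(split(hits, hits$protein_id), assign_family,
                                 ambiguity_tau = ambiguity_tau))
    rownames(out) <- NULL
    out
  } else hits
  attr(assigned, "all_hits") <- hits
  attr(assigned, "approximate_pid") <- TRUE
  assigned
}
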