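#' Cluster nif-family loci by gene-order adjacency
#'
#' Two loci join the same cluster when they lie on the same replicon and at
#' most `max_gap` non-nif genes intervene (gene_index difference
#' `<= max_gap + 1`); clustering is the transitive closure of that relation,
#' so the result is a partition of the input loci.  Strand is ignored:
#' clustered nif regions in genomes are routinely transcribed from mixed
#' strands.
#'
#' @param loci data.frame with at least `replicon_id`, `gene_index`,
#'   `family`, `locus_tag` (e.g. rows of a [search_proteome()] result).
#' @param max_gap maximum number of intervening genes (default 2).
#' @return list of `synteny_cluster` objects, each a list with `replicon_id`,
#'   `members` (the loci rows ordered by gene_index), `families`, `span`.
#' @export
cluster_by_adjacency <- function(loci, max_gap = 2) {
  if (is.null(loci) || nrow(loci) == 0L) return(list())
  if (anyNA(loci$gene_index))
    stop("loci lack gene_index: use a coordinate-bearing input format ",
         "(FASTA with prodigal headers, GenBank or GFF3)", call. = FALSE)
  out <- list()
  for (rep_id in unique(loci$replicon_id)) {
    sub <- loci[loci$replicon_id == rep_id, , drop = FALSE]
    sub <- sub[order(sub$gene_index), , drop = FALSE]
    breaks <- c(0L, which(diff(sub$gene_index) > max_gap + 1L), nrow(sub))
    for (b in seq_len(length(breaks) - 1L)) {
      members <- sub[(breaks[b] + 1L):breaks[b + 1L], , drop = FALSE]
      rownames(members) <- NULL
      out[[length(out) + 1L]] <- structure(
        list(replicon_id = rep_id, members = members,
             families = unique(members$family),
             span = range(members$gene_index)),
        class = "synteny_cluster")
    }
  }
  out
}

#' Contiguity evidence flags for a set of synteny clusters
#'
#' Computes the recurring clustered nif-gene arrangements as booleans:
#' `min3_contiguous` (some cluster carries >= 3 distinct families of the
#' required set — the recurring pattern in known diazotrophs),
#' `single_region` (one cluster carries all six), `hdk_contiguous`
#' (nifH, nifD, nifK co-clustered) and `dk_en_adjacent` (nifD and nifK
#' co-clustered with nifE and nifN).
#'
#' @param clusters output of [cluster_by_adjacency()].
#' @param required_set required families (default six-gene minimum set).
#' @return named logical vector of the four flags.
#' @export
summarize_synteny <- function(clusters, required_set = minimum_gene_set()) {
  flags <- c(min3_contiguous = FALSE, single_region = FALSE,
             hdk_contiguous = FALSE, dk_en_adjacent = FALSE)
  for (cl in clusters) {
    fams <- intersect(cl$families, required_set)
    if (length(fams) >= 3L) flags["min3_contiguous"] <- TRUE
    if (all(required_set %in% cl$families)) flags["single_region"] <- TRUE
    if (all(c("nifH", "nifD", "nifK") %in% cl$families))
      flags["hdk_contiguous"] <- TRUE
    if (all(c("nifD", "nifK", "nifE", "nifN") %in% cl$families))
      flags["dk_en_adjacent"] <- TRUE
  }
  flags
}
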