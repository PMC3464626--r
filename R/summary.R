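positive_statuses <- function() "DIAZOTROPH_PREDICTED"

calls_table <- function(results) {
  rows <- lapply(results, function(r) {
    data.frame(species_name = r$species_name,
               status = r$call$status,
               domain = r$taxonomy$domain %||% NA_character_,
               phylum = r$taxonomy$phylum %||% NA_character_)
  })
  if (!length(rows))
    return(data.frame(species_name = character(), status = character(),
                      domain = character(), phylum = character()))
  do.call(rbind, rows)
}

#' Taxonomic distribution of diazotrophy calls
#'
#' Aggregates per-species calls into per-phylum counts: known diazotrophs
#' (from the optional literature metadata), newly predicted diazotrophs
#' (positive minimum-gene-set call, not in the known list) and total species
#' screened.  Species lacking taxonomy group under "unassigned".
#'
#' @param results list of `nifscan_result` (or a data.frame with columns
#'   `species_name`, `status`, `domain`, `phylum`).
#' @param known_metadata optional data.frame with a `species_name` column
#'   naming experimentally demonstrated diazotrophs.
#' @return data.frame: `domain`, `phylum`, `n_species_total`, `n_known`,
#'   `n_predicted`, `ratio` (a `"known+predicted / total"` string).
#' @export
per_phylum_counts <- function(results, known_metadata = NULL) {
  calls <- if (is.data.frame(results)) results else calls_table(results)
  if (nrow(calls) == 0L)
    return(data.frame(domain = character(), phylum = character(),
                      n_species_total = integer(), n_known = integer(),
                      n_predicted = integer(), ratio = character()))
  calls$domain[is.na(calls$domain)] <- "unassigned"
  calls$phylum[is.na(calls$phylum)] <- "unassigned"
  known <- if (!is.null(known_metadata)) known_metadata$species_name
    else character()
  calls$known <- calls$species_name %in% known
  calls$positive <- calls$status %in% positive_statuses()
  out <- do.call(rbind, lapply(split(calls, paste(calls$domain, calls$phylum,
                                                  sep = "\r")), function(g) {
    n_known <- sum(g$known)
    n_pred <- sum(g$positive & !g$known)
    data.frame(domain = g$domain[1], phylum = g$phylum[1],
               n_species_total = nrow(g), n_known = n_known,
               n_predicted = n_pred,
               ratio = sprintf("%d / %d", n_known + n_pred, nrow(g)))
  }))
  out <- out[order(out$domain, out$phylum), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overall fraction of (known or predicted) diazotrophs
#'
#' @param results as in [per_phylum_counts()].
#' @param n_total total number of species screened (default: number of
#'   results).
#' @param known_metadata optional known-diazotroph table.
#' @return percentage, `100 * (known + predicted) / n_total`.
#' @export
overall_fraction <- function(results, n_total = NULL, known_metadata = NULL) {
  calls <- if (is.data.frame(results)) results else calls_table(results)
  if (is.null(n_total)) n_total <- nrow(calls)
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  known <- if (!is.null(known_metadata)) known_metadata$species_name
    else character()
  n_pos <- sum(calls$status %in% positive_statuses() |
                 calls$species_name %in% known)
  100 * n_pos / n_total
}
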