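#' Scan one genome for diazotrophy evidence
#'
#' The full per-genome workflow: homology screen against the 12 query
#' families, divergent-sequence triage (fusions, DPOR subtraction,
#' nitrogenase-like candidates), inventory refinement, synteny clustering,
#' ligand-motif subfamily labelling, minimum-gene-set classification,
#' Mo-copy counting, alternative-system (V/Fe) detection and orphan
#' flagging.
#'
#' Loci triaged as DPOR homologs, fusions or nitrogenase-like candidates are
#' excluded from the diazotrophy inventory before classification — the
#' programmatic analogue of refining a weak-threshold hit list with the gene
#' set, G-subunit and synteny evidence.
#'
#' @param genome [genome_annotation()].
#' @param queries,profile,dpor_refs reference data (defaults: packaged
#'   bundle).
#' @param min_pid identity-over-query retention threshold (percent).
#' @param max_gap synteny adjacency tolerance (intervening genes).
#' @param required_set required families for the minimum-set rule.
#' @param matrix,gap_open,gap_extend scoring scheme.
#' @return `nifscan_result`: list with `species_name`, `assembly_id`,
#'   `taxonomy`, `call` (a `diazotroph_call`), `inventory`, `copy_counts`,
#'   `synteny_flags`, `mo_copies`, `subtypes`, `hierarchy_violation`,
#'   `alpha_labels`, `orphans`, `niflike`.
#' @export
scan_genome <- function(genome, queries = load_default_queries(),
                        profile = reference_profile(),
                        dpor_refs = load_dpor_references(), min_pid = 20,
                        max_gap = 2, required_set = minimum_gene_set(),
                        matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  assigned <- search_proteome(queries, genome, min_pid, matrix, gap_open,
                              gap_extend)
  tri <- niflike_triage(genome, assigned, profile, dpor_refs, max_gap,
                        matrix = matrix, gap_open = gap_open,
                        gap_extend = gap_extend)
  inv_loci <- assigned[!(assigned$locus_tag %in% tri$excluded_locus_tags), ,
                       drop = FALSE]
  # G-subunit (anfG/vnfG) hits are only meaningful alongside a co-clustered
  # D subunit; isolated G hits are spurious and dropped during refinement
  g_rows <- which(inv_loci$family %in% c("anfG", "vnfG"))
  if (length(g_rows)) {
    d_rows <- inv_loci[inv_loci$family %in% ALPHA_FAMILIES, , drop = FALSE]
    keep_g <- vapply(g_rows, function(i) {
      nrow(d_rows) > 0 &&
        any(d_rows$replicon_id == inv_loci$replicon_id[i] &
              abs(d_rows$gene_index - inv_loci$gene_index[i]) <= max_gap + 1L)
    }, logical(1))
    if (any(!keep_g))
      inv_loci <- inv_loci[-g_rows[!keep_g], , drop = FALSE]
  }
  inventory <- build_inventory(inv_loci, genome$species_name)
  clusters <- if (nrow(inv_loci)) cluster_by_adjacency(inv_loci, max_gap)
    else list()
  flags <- summarize_synteny(clusters, required_set)
  call <- classify_minimum_set(inventory, required_set, tri$alpha_labels)
  v_loci <- names(tri$alpha_labels)[tri$alpha_labels == "V"]
  mo <- count_mo_copies(clusters, v_loci)
  alt <- detect_alternative_systems(inventory, tri$alpha_labels, clusters)
  orphans <- detect_orphans(inventory)
  counts <- vapply(FAMILY_ORDER, function(f) sum(inv_loci$family == f), 0L)
  call$evidence <- list(synteny_flags = flags, mo_copies = mo,
                        subtypes = alt$subtypes, copy_counts = counts)
  structure(list(species_name = genome$species_name,
                 assembly_id = genome$assembly_id,
                 taxonomy = genome$taxonomy, call = call,
                 inventory = inventory, copy_counts = counts,
                 synteny_flags = flags, mo_copies = mo,
                 subtypes = alt$subtypes,
                 hierarchy_violation = alt$hierarchy_violation,
                 alpha_labels = tri$alpha_labels, orphans = orphans,
                 niflike = tri[c("candidates", "fusions", "dpor_removed")]),
            class = "nifscan_result")
}

#' @export
print.nifscan_result <- function(x, ...) {
  cat(sprintf("nifscan result for %s: %s\n", x$species_name, x$call$status))
  present <- names(x$copy_counts)[x$copy_counts > 0]
  cat("  families:", if (length(present)) paste(present, collapse = ", ")
      else "none", "\n")
  if (nrow(x$niflike$candidates))
    cat("  nitrogenase-like candidates:", nrow(x$niflike$candidates), "\n")
  invisible(x)
}

#' Scan several genomes, keeping one representative per species
#'
#' When multiple assemblies share a species name, the lexicographically
#' smallest `assembly_id` is kept (override by naming assemblies in
#' `representatives`).
#'
#' @param genomes list of [genome_annotation()] objects.
#' @param representatives optional named character vector
#'   `species_name -> assembly_id`.
#' @param ... passed to [scan_genome()].
#' @return list of `nifscan_result`, one per species, sorted by species name.
#' @export
scan_genomes <- function(genomes, representatives = NULL, ...) {
  sp <- vapply(genomes, function(g) g$species_name, "")
  asm <- vapply(genomes, function(g) g$assembly_id, "")
  keep <- vapply(split(seq_along(genomes), sp), function(idx) {
    species <- sp[idx[1L]]
    if (!is.null(representatives) && species %in% names(representatives)) {
      hit <- idx[asm[idx] == representatives[[species]]]
      if (length(hit)) return(hit[1L])
    }
    idx[order(asm[idx])][1L]
  }, 1L)
  res <- lapply(genomes[keep], scan_genome, ...)
  res[order(vapply(res, function(r) r$species_name, ""))]
}
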