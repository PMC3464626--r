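#' Build a per-species gene inventory from family-assigned hits
#'
#' @param assigned family-assigned hit table ([search_proteome()] /
#'   [import_tabular_hits()] output), optionally already refined (divergent
#'   nitrogenase-like and DPOR loci removed).
#' @param species_name species the hits belong to.
#' @return `gene_inventory`: list with `species_name` and `loci` (one row per
#'   locus with its assigned family).
#' @export
build_inventory <- function(assigned, species_name) {
  structure(list(species_name = species_name, loci = assigned),
            class = "gene_inventory")
}

inventory_families <- function(inventory) {
  if (inherits(inventory, "gene_inventory")) unique(inventory$loci$family)
  else unique(as.character(inventory))
}

#' @export
print.gene_inventory <- function(x, ...) {
  cat(sprintf("gene_inventory for %s: %d loci (%s)\n", x$species_name,
              nrow(x$loci), paste(sort(unique(x$loci$family)), collapse = ", ")))
  invisible(x)
}

#' Apply the minimum-gene-set diazotrophy criterion
#'
#' Classification rule (a total function of gene content, plus an optional
#' motif condition):
#' \itemize{
#'   \item `DIAZOTROPH_PREDICTED` — every required family (default nifH,
#'     nifD, nifK, nifE, nifN, nifB) has at least one locus;
#'   \item `GROUP_C_CANDIDATE` — nifH, nifD, nifK and nifB present and the
#'     only missing required families are nifE and/or nifN (the
#'     hyperthermophile pattern lacking the NifEN scaffold).  When D-subunit
#'     subfamily labels are supplied, at least one D locus must carry the
#'     group-C ligand signature; without motif data the call is made on gene
#'     content alone and flagged `low_confidence`;
#'   \item `ORPHAN` — exactly one of nifH/nifD present and the other absent
#'     (the single-marker false-positive pattern);
#'   \item `NEGATIVE` — anything else.
#' }
#'
#' @param inventory a `gene_inventory`, or simply a character vector of
#'   present families.
#' @param required_set required families (default the six-gene minimum set).
#' @param d_subfamily_labels optional character vector of subfamily labels
#'   ("CONVENTIONAL_AB", "C", "V", "UNCLASSIFIED") for the D-type loci in the
#'   inventory; `NULL` means no motif data available.
#' @return `diazotroph_call`: list with `status`, `missing_families`,
#'   `present_families`, `low_confidence`, `evidence` (filled by the
#'   pipeline).
#' @export
classify_minimum_set <- function(inventory, required_set = minimum_gene_set(),
                                 d_subfamily_labels = NULL) {
  present <- inventory_families(inventory)
  required_set <- unique(as.character(required_set))
  missing <- setdiff(required_set, present)
  low_conf <- FALSE
  if (length(missing) == 0L) {
    status <- "DIAZOTROPH_PREDICTED"
  } else if (all(c("nifH", "nifD", "nifK", "nifB") %in% present) &&
             all(missing %in% c("nifE", "nifN"))) {
    if (is.null(d_subfamily_labels)) {
      status <- "GROUP_C_CANDIDATE"; low_conf <- TRUE
    } else if (any(d_subfamily_labels == "C")) {
      status <- "GROUP_C_CANDIDATE"
    } else {
      status <- if (xor("nifH" %in% present, "nifD" %in% present))
        "ORPHAN" else "NEGATIVE"
    }
  } else if (xor("nifH" %in% present, "nifD" %in% present)) {
    status <- "ORPHAN"
  } else {
    status <- "NEGATIVE"
  }
  structure(list(status = status, missing_families = missing,
                 present_families = sort(present), low_confidence = low_conf,
                 evidence = list()),
            class = "diazotroph_call")
}

#' @export
print.diazotroph_call <- function(x, ...) {
  cat(sprintf("diazotroph call: %s (missing: %s)\n", x$status,
              if (length(x$missing_families))
                paste(x$missing_families, collapse = ", ") else "none"))
  invisible(x)
}

#' Count Mo-nitrogenase copies from synteny clusters
#'
#' A copy is a disjoint synteny cluster carrying at least one nifD and one
#' nifK locus (nifH may be shared or distal); D loci carrying the
#' alternative-nitrogenase (group V) ligand signature are excluded, so Vnf/Anf
#' clusters do not inflate the Mo count.
#'
#' @param clusters [cluster_by_adjacency()] output over the inventory loci.
#' @param v_labeled_loci locus tags of D-type loci labeled subfamily V.
#' @return integer copy count.
#' @export
count_mo_copies <- function(clusters, v_labeled_loci = character()) {
  n <- 0L
  for (cl in clusters) {
    m <- cl$members
    has_d <- any(m$family == "nifD" & !(m$locus_tag %in% v_labeled_loci))
    has_k <- any(m$family == "nifK")
    if (has_d && has_k) n <- n + 1L
  }
  n
}

#' Detect Mo / V / Fe nitrogenase systems
#'
#' The additional G subunit distinguishes the alternative systems: V
#' (vanadium) is reported when a vnfG hit is present or a V-labeled D subunit
#' co-clusters with a G-subunit hit assigned to vnfG; Fe likewise via anfG.
#' Mo is reported when at least one D-subunit locus does not carry the V
#' signature.  `hierarchy_violation` flags genomes with an alternative system
#' but no Mo system (alternative nitrogenases were only observed alongside
#' the Mo-dependent enzyme).
#'
#' @param inventory `gene_inventory` (post-refinement).
#' @param d_labels named character vector: subfamily label per D-type locus
#'   tag.
#' @param clusters synteny clusters over the inventory loci.
#' @return list with `subtypes` (subset of "Mo", "V", "Fe") and
#'   `hierarchy_violation`.
#' @export
detect_alternative_systems <- function(inventory, d_labels = NULL,
                                       clusters = list()) {
  loci <- inventory$loci
  subtypes <- character()
  v_loci <- names(d_labels)[d_labels == "V"]
  g_fams <- c(V = "vnfG", Fe = "anfG")
  for (sub in names(g_fams)) {
    gfam <- g_fams[[sub]]
    if (gfam %in% loci$family) {
      subtypes <- c(subtypes, sub)
    } else if (length(v_loci)) {
      # a V-labeled D co-clustered with any G hit of this family
      for (cl in clusters) {
        m <- cl$members
        if (any(m$locus_tag %in% v_loci) && any(m$family == gfam))
          subtypes <- c(subtypes, sub)
      }
    }
  }
  mo <- any(loci$family == "nifD" & !(loci$locus_tag %in% v_loci))
  if (mo) subtypes <- c("Mo", subtypes)
  subtypes <- unique(subtypes)
  list(subtypes = subtypes,
       hierarchy_violation = length(setdiff(subtypes, "Mo")) > 0 && !mo)
}

#' Flag orphan nifH / nifD hits
#'
#' Single-marker surveys that rely on nifH or nifD alone misreport these
#' genomes as diazotrophic; the orphan report makes the pattern explicit.
#'
#' @param inventory `gene_inventory`.
#' @return data.frame with zero or one row: `species_name`, `orphan_type`
#'   ("orphan_nifH" or "orphan_nifD", naming the gene that is present),
#'   `note`.
#' @export
detect_orphans <- function(inventory) {
  present <- inventory_families(inventory)
  has_h <- "nifH" %in% present; has_d <- "nifD" %in% present
  if (xor(has_h, has_d)) {
    data.frame(species_name = inventory$species_name,
               orphan_type = if (has_h) "orphan_nifH" else "orphan_nifD",
               note = paste("single-marker hit without its partner;",
                            "nifH- or nifD-only screens may falsely",
                            "indicate diazotrophy"))
  } else {
    data.frame(species_name = character(), orphan_type = character(),
               note = character())
  }
}
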