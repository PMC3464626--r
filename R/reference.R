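
ref_file <- function(name) {
  path <- system.file("extdata", name, package = "nifscan")
  if (!nzchar(path)) stop("packaged asset not found: ", name, call. = FALSE)
  path
}

read_family_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  id <- sub("\\s.*$", "", headers)
  fam <- sub("^.*family=(\\S+).*$", "\\1", headers)
  data.frame(family = fam, reference_locus = id,
             sequence = as.character(aa), row.names = NULL)
}

#' Reference metadata (families, locus tags, annotated positions)
#'
#' @param config optional path to a user YAML overriding the packaged
#'   metadata (same schema).
#' @return named list mirroring the packaged YAML.
#' @export
reference_meta <- function(config = NULL) {
  path <- if (is.null(config)) ref_file("reference_meta.yaml") else config
  meta <- yaml::read_yaml(path)
  needed <- c("families", "minimum_gene_set", "ligand_positions",
              "flank_positions", "p_cluster_alpha", "p_cluster_beta_nifK")
  missing <- setdiff(needed, names(meta))
  if (length(missing))
    stop("reference config is missing fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  meta
}

#' Load the 12 default query families
#'
#' Reads the packaged reference FASTA (synthetic stand-ins for the
#' *A. vinelandii* DJ proteins, one per family, keyed by locus tag) and
#' validates the NifD reference profile: the annotated ligand residues
#' (Cys275, His442, Gln191, His195, Lys426 and the three alpha P-cluster
#' cysteines) must be present at their annotated coordinates.
#'
#' @param fasta optional path to an alternative reference FASTA whose headers
#'   carry `family=<name>` tokens.
#' @param config optional metadata YAML (see [reference_meta()]).
#' @return data.frame with columns `family`, `reference_locus`, `sequence`,
#'   ordered as `r paste(FAMILY_ORDER, collapse = ", ")`.
#' @export
load_default_queries <- function(fasta = NULL, config = NULL) {
  meta <- reference_meta(config)
  path <- if (is.null(fasta)) ref_file("avin_reference_synthetic.faa") else fasta
  q <- read_family_fasta(path)
  expected <- names(meta$families)
  missing <- setdiff(expected, q$family)
  if (length(missing))
    stop("reference set is missing families: ",
         paste(missing, collapse = ", "), call. = FALSE)
  dup <- q$family[duplicated(q$family)]
  if (length(dup))
    stop("duplicated families in reference set: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(!nzchar(q$sequence))) stop("empty reference sequence", call. = FALSE)
  q <- q[match(intersect(FAMILY_ORDER, q$family), q$family), , drop = FALSE]
  rownames(q) <- NULL
  validate_reference_profile(q, meta)
  attr(q, "meta") <- meta
  q
}

validate_reference_profile <- function(queries, meta) {
  nifd <- queries$sequence[queries$family == "nifD"]
  if (length(nifd) != 1L) stop("reference set must contain nifD", call. = FALSE)
  checks <- rbind(
    c(meta$ligand_positions$femoco_cys, "C"),
    c(meta$ligand_positions$femoco_his, "H"),
    c(meta$ligand_positions$gln, "Q"),
    c(meta$ligand_positions$his, "H"),
    c(meta$ligand_positions$lys_homocitrate, "K"),
    cbind(meta$p_cluster_alpha, "C"))
  for (i in seq_len(nrow(checks))) {
    pos <- as.integer(checks[i, 1]); aa <- checks[i, 2]
    got <- substr(nifd, pos, pos)
    if (!identical(got, aa))
      stop(sprintf("reference validation failed: nifD position %d is '%s', expected '%s'",
                   pos, got, aa), call. = FALSE)
  }
  nifk <- queries$sequence[queries$family == "nifK"]
  if (length(nifk) == 1L) {
    pos <- as.integer(meta$p_cluster_beta_nifK)
    got <- vapply(pos, function(p) substr(nifk, p, p), "")
    if (any(got != "C"))
      stop(sprintf("reference validation failed: nifK position %d is '%s', expected 'C'",
                   pos[got != "C"][1], got[got != "C"][1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' The NifD/NifK reference numbering profile
#'
#' Bundles the alpha (NifD, Avin_01390 numbering) and beta (NifK) reference
#' sequences with their annotated ligand, flank and P-cluster positions.
#' All alpha-subunit positions elsewhere in the package are expressed in this
#' NifD numbering; NifE/NifN sequences are mapped onto the same coordinates by
#' alignment (dual numbering, e.g. alpha-C154 = NifE C124).
#'
#' @inheritParams load_default_queries
#' @param queries optionally a pre-loaded query table from
#'   [load_default_queries()].
#' @return list with `alpha_seq`, `beta_seq`, `ligand_positions`,
#'   `flank_positions`, `p_cluster_alpha`, `p_cluster_beta`, `aromatic`,
#'   `acidic`, `tracked_positions`, `dual_numbering_notes`.
#' @export
reference_profile <- function(queries = NULL, fasta = NULL, config = NULL) {
  if (is.null(queries)) queries <- load_default_queries(fasta, config)
  meta <- attr(queries, "meta")
  if (is.null(meta)) meta <- reference_meta(config)
  lig <- lapply(meta$ligand_positions, as.integer)
  alpha_seq <- queries$sequence[queries$family == "nifD"]
  beta_seq <- queries$sequence[queries$family == "nifK"]
  qseq <- function(f) {
    s <- queries$sequence[queries$family == f]
    if (length(s)) s else NULL
  }
  # family templates for position mapping: a NifE/NifN-assigned sequence is
  # aligned to its own family reference, then carried into NifD/NifK
  # numbering through the reference-vs-reference alignment (dual numbering)
  alpha_templates <- Filter(Negate(is.null),
                            list(nifD = alpha_seq, nifE = qseq("nifE")))
  beta_templates <- Filter(Negate(is.null),
                           list(nifK = beta_seq, nifN = qseq("nifN")))
  template_map <- function(ref, tmpl_list) {
    lapply(tmpl_list, function(tmpl) {
      if (identical(tmpl, ref)) seq_len(nchar(ref))
      else align_overlap(ref, tmpl)$map
    })
  }
  list(alpha_seq = alpha_seq,
       beta_seq = beta_seq,
       alpha_templates = alpha_templates,
       beta_templates = beta_templates,
       alpha_template_maps = template_map(alpha_seq, alpha_templates),
       beta_template_maps = template_map(beta_seq, beta_templates),
       ligand_positions = lig,
       flank_positions = as.integer(meta$flank_positions),
       p_cluster_alpha = as.integer(meta$p_cluster_alpha),
       p_cluster_beta = as.integer(meta$p_cluster_beta_nifK),
       aromatic = as.character(meta$aromatic_residues),
       acidic = as.character(meta$acidic_residues),
       tracked_positions = sort(unique(c(unlist(lig, use.names = FALSE),
                                         as.integer(meta$flank_positions)))),
       dual_numbering_notes = meta$dual_numbering_notes)
}

#' Load the DPOR (protochlorophyllide reductase) reference sequences
#'
#' ChlB, BchB, ChlN and BchN stand-ins used to subtract DPOR homologs during
#' nitrogenase-like triage.
#'
#' @param fasta optional alternative FASTA path.
#' @return data.frame with `family` (chlB/bchB/chlN/bchN), `reference_locus`,
#'   `sequence`.
#' @export
load_dpor_references <- function(fasta = NULL) {
  path <- if (is.null(fasta)) ref_file("dpor_reference_synthetic.faa") else fasta
  d <- read_family_fasta(path)
  if (nrow(d) < 1L) stop("no DPOR references found", call. = FALSE)
  d
}

#' The minimum gene set for diazotrophy prediction
#'
#' Default: the six co-occurring families nifH, nifD, nifK, nifE, nifN, nifB.
#'
#' @param config optional metadata YAML.
#' @return character vector of required families.
#' @export
minimum_gene_set <- function(config = NULL) {
  as.character(reference_meta(config)$minimum_gene_set)
}

#' Cardinality of a required gene set
#'
#' @param set character vector of family names (default: the packaged
#'   six-gene minimum set).
#' @return integer count of distinct required families.
#' @export
minimum_set_size <- function(set = minimum_gene_set()) {
  set <- unique(as.character(set))
  if (length(set) == 0L) stop("empty required set", call. = FALSE)
  unknown <- setdiff(set, FAMILY_ORDER)
  if (length(unknown))
    stop("unknown families in required set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  length(set)
}
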