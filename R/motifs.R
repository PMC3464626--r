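#' Map a subject sequence onto reference (NifD/NifK) numbering
#'
#' Globally aligns the subject to the reference subunit sequence with free
#' end gaps (same scoring scheme as the homology screen) and records, for
#' every reference position, the aligned subject position.  Reference
#' positions aligned to a gap are ABSENT (0).  Coverage is the fraction of
#' reference positions aligned to a subject residue; below 50\% all
#' downstream labels are flagged low-confidence.
#'
#' @param subject_seq amino-acid string, length >= 100 (shorter inputs are
#'   rejected as fragments).
#' @param profile reference profile from [reference_profile()].
#' @param subunit `"alpha"` (NifD numbering) or `"beta"` (NifK numbering).
#' @param template_family optional family whose reference sequence is used as
#'   the alignment template (`"nifE"` for NifE-assigned sequences, `"nifN"`
#'   for NifN-assigned ones); the template-vs-subject map is composed with
#'   the reference-vs-template map, so positions are always reported in
#'   NifD/NifK numbering.  Default: the reference itself.
#' @param matrix,gap_open,gap_extend scoring scheme.
#' @return `position_map` list: `map` (integer vector over reference
#'   positions; 0 = ABSENT), `score`, `coverage`, `low_confidence`,
#'   `subject_seq`, `subunit`.
#' @export
map_positions <- function(subject_seq, profile = reference_profile(),
                          subunit = c("alpha", "beta"),
                          template_family = NULL, matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1) {
  subunit <- match.arg(subunit)
  if (nchar(subject_seq) < 100L)
    stop("fragment: subject shorter than 100 residues", call. = FALSE)
  ref <- if (subunit == "alpha") profile$alpha_seq else profile$beta_seq
  templates <- if (subunit == "alpha") profile$alpha_templates
    else profile$beta_templates
  tmaps <- if (subunit == "alpha") profile$alpha_template_maps
    else profile$beta_template_maps
  default_fam <- if (subunit == "alpha") "nifD" else "nifK"
  tf <- template_family %||% default_fam
  if (!tf %in% names(templates)) tf <- default_fam
  if (tf == default_fam || is.null(tmaps[[tf]])) {
    al <- align_overlap(ref, subject_seq, matrix, gap_open, gap_extend)
    map <- al$map
  } else {
    al <- align_overlap(templates[[tf]], subject_seq, matrix, gap_open,
                        gap_extend)
    tmap <- tmaps[[tf]]                       # reference pos -> template pos
    map <- ifelse(tmap == 0L, 0L, al$map[pmax(tmap, 1L)])
    map[tmap == 0L] <- 0L
  }
  coverage <- sum(map > 0L) / nchar(ref)
  structure(list(map = map, score = al$score, coverage = coverage,
                 low_confidence = coverage < 0.5,
                 subject_seq = toupper(subject_seq), subunit = subunit),
            class = "position_map")
}

# residue of the subject at a reference-numbered position ("ABSENT" when the
# reference column is gapped or unmapped)
residue_at <- function(position_map, ref_pos) {
  sp <- position_map$map[ref_pos]
  ifelse(is.na(sp) | sp == 0L, "ABSENT",
         substring(position_map$subject_seq, sp, sp))
}

#' Extract the ligand-environment profile of an alpha-type subunit
#'
#' Reads the residues found at the reference-numbered FeMoco ligand positions
#' (Cys275, His442), the catalytic environment (Gln191, His195), the
#' homocitrate anchor (Lys426), the subfamily flank positions
#' (276, 440, 444, 445) and the three alpha P-cluster cysteine positions
#' (62, 88, 154), and derives the classification flags.
#'
#' @param position_map alpha-subunit [map_positions()] result.
#' @param profile reference profile (for position annotation and residue
#'   classes).
#' @return `ligand_profile` list: `residues` (named by reference position),
#'   `p_cluster_cys_count`, flags `has_C275`, `has_H442`, `aromatic_444`,
#'   `acidic_445`, and `low_confidence`.
#' @export
extract_ligand_profile <- function(position_map,
                                   profile = reference_profile()) {
  stopifnot(inherits(position_map, "position_map"),
            position_map$subunit == "alpha")
  pos <- sort(unique(c(profile$tracked_positions, profile$p_cluster_alpha)))
  res <- vapply(pos, function(p) residue_at(position_map, p), "")
  names(res) <- as.character(pos)
  lig <- profile$ligand_positions
  cys_count <- count_p_cluster_cys(position_map, profile$p_cluster_alpha)
  structure(list(
    residues = res,
    p_cluster_cys_count = cys_count,
    has_C275 = identical(res[[as.character(lig$femoco_cys)]], "C"),
    has_H442 = identical(res[[as.character(lig$femoco_his)]], "H"),
    aromatic_444 = res[["444"]] %in% profile$aromatic,
    acidic_445 = res[["445"]] %in% profile$acidic,
    low_confidence = position_map$low_confidence),
    class = "ligand_profile")
}

#' Count conserved P-cluster cysteines
#'
#' @param position_map a [map_positions()] result (alpha or beta subunit).
#' @param positions reference-numbered cysteine positions; defaults to the
#'   alpha set \{62, 88, 154\} for alpha maps and \{70, 95, 153\} (NifK
#'   numbering) for beta maps.
#' @param profile reference profile used for the defaults.
#' @return integer count of positions carrying C in the subject.
#' @export
count_p_cluster_cys <- function(position_map, positions = NULL,
                                profile = reference_profile()) {
  if (is.null(positions))
    positions <- if (position_map$subunit == "alpha")
      profile$p_cluster_alpha else profile$p_cluster_beta
  sum(vapply(positions, function(p) residue_at(position_map, p), "") == "C")
}

#' Classify a NifD-family sequence into ligand subfamilies
#'
#' Decision order (fixed for determinism; the V and C signatures are disjoint
#' at position 276, so order only matters for malformed inputs):
#' \enumerate{
#'   \item `V` — alternative-nitrogenase type (VnfD/AnfD): Ala at 276 and His
#'     replacing the acidic residue at 445;
#'   \item `C` — the thermophile-associated third subfamily: Gln at 276, Asp
#'     at 440, and no aromatic residue corresponding to position 444;
#'   \item `CONVENTIONAL_AB` — FeMoco ligands Cys275 and His442 present plus
#'     the aromatic at 444 (the A/B subfamilies are not sub-split);
#'   \item `UNCLASSIFIED` — everything else; such sequences are candidate
#'     nitrogenase-like proteins and are handed to the divergent-sequence
#'     triage.
#' }
#'
#' @param ligand_profile an [extract_ligand_profile()] result.
#' @return `subfamily_label` list with `label` and `rationale` (plus
#'   `low_confidence` passthrough).
#' @export
classify_nifd_subfamily <- function(ligand_profile) {
  stopifnot(inherits(ligand_profile, "ligand_profile"))
  r <- ligand_profile$residues
  out <- if (identical(r[["276"]], "A") && identical(r[["445"]], "H")) {
    list(label = "V", rationale = "Ala276 with His445 (alternative-nitrogenase D subunit)")
  } else if (identical(r[["276"]], "Q") && identical(r[["440"]], "D") &&
             !ligand_profile$aromatic_444) {
    list(label = "C", rationale = "Gln276, Asp440, no aromatic residue at 444")
  } else if (ligand_profile$has_C275 && ligand_profile$has_H442 &&
             ligand_profile$aromatic_444) {
    list(label = "CONVENTIONAL_AB",
         rationale = "FeMoco ligands Cys275/His442 with aromatic 444")
  } else {
    list(label = "UNCLASSIFIED",
         rationale = "no subfamily signature; candidate nitrogenase-like sequence")
  }
  out$low_confidence <- isTRUE(ligand_profile$low_confidence)
  class(out) <- "subfamily_label"
  out
}

#' Profile and classify many alpha-subunit sequences
#'
#' Convenience wrapper: maps each sequence onto NifD numbering, extracts the
#' ligand profile and assigns the subfamily label.
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param profile reference profile.
#' @return data.frame with one row per sequence: residues at the nine tracked
#'   positions, P-cluster Cys count, flags and subfamily label.
#' @export
motif_table <- function(seqs, profile = reference_profile()) {
  rows <- lapply(seq_along(seqs), function(i) {
    pm <- map_positions(seqs[[i]], profile, "alpha")
    lp <- extract_ligand_profile(pm, profile)
    lab <- classify_nifd_subfamily(lp)
    resdf <- as.data.frame(as.list(lp$residues), check.names = FALSE)
    names(resdf) <- paste0("pos", names(lp$residues))
    cbind(data.frame(protein_id = names(seqs)[i] %||% as.character(i)),
          resdf,
          data.frame(cys_alpha = lp$p_cluster_cys_count,
                     has_C275 = lp$has_C275, has_H442 = lp$has_H442,
                     aromatic_444 = lp$aromatic_444,
                     acidic_445 = lp$acidic_445,
                     subfamily = lab$label,
                     low_confidence = lab$low_confidence))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
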