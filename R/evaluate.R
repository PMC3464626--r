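compare_to_manifest <- function(result, manifest) {
  ex <- manifest$expected
  cand <- result$niflike$candidates
  classes <- setdiff(unique(stats::na.omit(cand$ligand_class)), "NFLD_SINGLE")
  n_pairs <- sum(cand$subunit_type == "alpha_like" &
                   !is.na(cand$pair_partner))
  n_singles <- sum(cand$ligand_class == "NFLD_SINGLE", na.rm = TRUE)
  dpor_tags <- manifest$implants$locus_tag[manifest$implants$kind ==
                                             "dpor_decoy"]
  dpor_removed <- sum(!(dpor_tags %in% c(result$inventory$loci$locus_tag,
                                         cand$locus_tag)))
  data.frame(
    species_name = manifest$species_name,
    scenario = manifest$scenario,
    call = result$call$status, expected_call = ex$call,
    call_ok = identical(result$call$status, ex$call),
    mo_ok = result$mo_copies == ex$mo_copies,
    subtypes_ok = setequal(result$subtypes, unlist(ex$subtypes)),
    synteny_ok = result$synteny_flags[["single_region"]] == ex$single_region,
    pairs_ok = n_pairs == ex$n_niflike_pairs &&
      (is.null(ex$ligand_class) || identical(classes, ex$ligand_class)),
    singles_ok = n_singles == ex$n_nfld_singles,
    fusions_ok = nrow(result$niflike$fusions) == ex$n_fusions,
    n_dpor_expected = ex$n_dpor_decoys,
    n_dpor_removed = dpor_removed)
}

#' Closed-loop evaluation of the pipeline on a simulated cohort
#'
#' Generates the standard seeded cohort ([simulate_cohort()]), runs
#' [scan_genome()] on every genome and compares every outcome with the
#' generator's ground-truth manifest: the diazotrophy call, Mo copy count,
#' subtype set, synteny flag, nitrogenase-like pairs and classes, NflD
#' singles, fusions and DPOR-decoy removal.
#'
#' @param seed master seed.
#' @param n_decoys,target_identity cohort settings (see [simulate_cohort()]).
#' @return list: `per_genome` (one comparison row per genome), `n_genomes`,
#'   `n_call_match` (genomes whose every check passed), `n_dpor_expected`,
#'   `n_dpor_removed`, `fusion_errors`, `nfld_errors`.
#' @export
evaluate_cohort <- function(seed, n_decoys = 200, target_identity = 50) {
  queries <- load_default_queries()
  profile <- reference_profile(queries)
  dpor <- load_dpor_references()
  cohort <- simulate_cohort(seed, n_decoys, target_identity, queries, profile)
  rows <- lapply(cohort, function(g) {
    r <- scan_genome(g$genome, queries, profile, dpor)
    compare_to_manifest(r, g$manifest)
  })
  per_genome <- do.call(rbind, rows)
  all_ok <- per_genome$call_ok & per_genome$mo_ok & per_genome$subtypes_ok &
    per_genome$synteny_ok & per_genome$pairs_ok & per_genome$singles_ok &
    per_genome$fusions_ok &
    (per_genome$n_dpor_removed == per_genome$n_dpor_expected)
  list(per_genome = per_genome, n_genomes = nrow(per_genome),
       n_call_match = sum(all_ok),
       n_dpor_expected = sum(per_genome$n_dpor_expected),
       n_dpor_removed = sum(per_genome$n_dpor_removed),
       fusion_errors = sum(!per_genome$fusions_ok),
       nfld_errors = sum(!per_genome$singles_ok))
}
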