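mk_calls <- function(status, phylum, species = NULL,
                     domain = rep("Bacteria", length(status))) {
  data.frame(species_name = species %||%
               paste0("sp", seq_along(status)),
             status = status, domain = domain, phylum = phylum)
}

test_that("phylum counts split known from newly predicted species", {
  calls <- mk_calls(rep("DIAZOTROPH_PREDICTED", 3), rep("Firmicutes", 3))
  known <- data.frame(species_name = "sp1")
  out <- per_phylum_counts(calls, known)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_known, 1L)
  expect_equal(out$n_predicted, 2L)
  expect_equal(out$n_species_total, 3L)
  expect_equal(out$ratio, "3 / 3")
})

test_that("empty call sets summarize to empty tables", {
  expect_equal(nrow(per_phylum_counts(list())), 0L)
})

test_that("per-phylum totals sum to the overall positive count", {
  set.seed(60)
  calls <- mk_calls(sample(c("DIAZOTROPH_PREDICTED", "NEGATIVE", "ORPHAN"),
                           40, TRUE),
                    sample(c("Proteobacteria", "Firmicutes",
                             "Euryarchaeota"), 40, TRUE),
                    domain = sample(c("Bacteria", "Archaea"), 40, TRUE))
  out <- per_phylum_counts(calls)
  expect_equal(sum(out$n_known + out$n_predicted),
               sum(calls$status == "DIAZOTROPH_PREDICTED"))
  expect_equal(sum(out$n_species_total), 40L)
})

test_that("the overall fraction reproduces the census arithmetic", {
  calls <- mk_calls(c(rep("DIAZOTROPH_PREDICTED", 149),
                      rep("NEGATIVE", 1092 - 149)),
                    rep("various", 1092))
  expect_equal(round(overall_fraction(calls, 1092), 1), 13.6)
  none <- mk_calls(rep("NEGATIVE", 10), rep("x", 10))
  expect_equal(overall_fraction(none), 0)
  all_pos <- mk_calls(rep("DIAZOTROPH_PREDICTED", 5), rep("x", 5))
  expect_equal(overall_fraction(all_pos), 100)
})

test_that("species missing taxonomy group under unassigned", {
  calls <- data.frame(species_name = c("a", "b"),
                      status = c("DIAZOTROPH_PREDICTED", "NEGATIVE"),
                      domain = c(NA, "Bacteria"),
                      phylum = c(NA, "Firmicutes"))
  out <- per_phylum_counts(calls)
  expect_true("unassigned" %in% out$phylum)
})

test_that("duplicate assemblies collapse to one representative per species", {
  q <- test_queries(); p <- test_profile(); d <- test_dpor()
  g1 <- generate_genome("orphan_H", 9, n_decoys = 8, queries = q,
                        profile = p)$genome
  g2 <- g1; g2$assembly_id <- "zzz_later"
  g3 <- g1; g3$assembly_id <- "aaa_first"
  res <- scan_genomes(list(g1, g2, g3), queries = q, profile = p,
                      dpor_refs = d)
  expect_length(res, 1L)
  expect_equal(res[[1]]$assembly_id, "aaa_first")
})
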