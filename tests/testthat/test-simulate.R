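test_that("mutating to 100 percent identity returns the input", {
  s <- qseq("nifH")
  expect_identical(mutate_reference(s, 100, seed = 1), s)
})

test_that("mutation hits the identity target with frozen columns intact", {
  p <- test_profile()
  s <- qseq("nifD")
  m <- mutate_reference(s, 60, seed = 9, frozen_positions = c(`275` = "C",
                                                              `442` = "H"))
  expect_identical(substr(m, 275, 275), "C")
  expect_identical(substr(m, 442, 442), "H")
  obs <- 100 * sum(strsplit(s, "")[[1]] == strsplit(m, "")[[1]]) / nchar(s)
  expect_gte(obs, 58); expect_lte(obs, 62)
})

test_that("generation is deterministic for identical configurations", {
  q <- test_queries(); p <- test_profile()
  g1 <- generate_genome("alternative_V", 31, n_decoys = 12, queries = q,
                        profile = p)
  g2 <- generate_genome("alternative_V", 31, n_decoys = 12, queries = q,
                        profile = p)
  expect_identical(g1$genome$records, g2$genome$records)
  expect_identical(g1$manifest, g2$manifest)
  g3 <- generate_genome("alternative_V", 32, n_decoys = 12, queries = q,
                        profile = p)
  expect_false(identical(g1$genome$records$sequence,
                         g3$genome$records$sequence))
})

test_that("unknown scenarios are rejected", {
  expect_error(generate_genome("no_such_scenario", 1), "unknown scenario")
})

test_that("clustered and dispersed arrangements place implants as declared", {
  q <- test_queries(); p <- test_profile()
  cl <- generate_genome("complete_set", 8, n_decoys = 60, queries = q,
                        profile = p, arrangement = "clustered")
  idx <- sort(cl$manifest$implants$gene_index)
  expect_equal(idx, seq(min(idx), length.out = 6))
  di <- generate_genome("complete_set", 8, n_decoys = 60, queries = q,
                        profile = p, arrangement = "dispersed")
  didx <- sort(di$manifest$implants$gene_index)
  expect_true(all(diff(didx) >= 10))
})

test_that("decoy proteomes keep the spurious hit rate near zero", {
  q <- test_queries(); p <- test_profile()
  sim <- generate_genome("negative", 123, n_decoys = 200, queries = q,
                         profile = p)
  h <- search_proteome(q, sim$genome)
  # measured, not assumed: at the weak 20% screen a few multi-domain-sized
  # random decoys may graze a short query; the rate must stay marginal
  expect_lte(nrow(h), 2L)
})

test_that("motif variants close the loop through the classifier", {
  q <- test_queries(); p <- test_profile()
  lab_of <- function(kind, seed) {
    mv <- make_motif_variant(kind, 50, seed, q, p)
    pm <- map_positions(mv$alpha, p, "alpha", mv$alpha_base)
    classify_nifd_subfamily(extract_ligand_profile(pm, p))$label
  }
  expect_equal(lab_of("C", 101), "C")
  expect_equal(lab_of("V", 102), "V")
  expect_equal(lab_of("conventional", 103), "CONVENTIONAL_AB")
  mv <- make_motif_variant("yellow", 50, 104, q, p)
  pm <- map_positions(mv$alpha, p, "alpha", mv$alpha_base)
  expect_equal(classify_ligand_class(extract_ligand_profile(pm, p)),
               "YELLOW")
})

test_that("the pinned-identity implant probes the exact threshold boundary", {
  q <- test_queries()
  at20 <- implant_with_measured_identity(58, "nifH", seed = 11, queries = q)
  expect_equal(at20$measured_pid, 20)
  below <- implant_with_measured_identity(52, "nifH", seed = 12, queries = q)
  expect_lt(below$measured_pid, 18.1)
})
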