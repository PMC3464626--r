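test_that("identical sequences align with full identity", {
  s <- "MSREEVESLIQEVLEVYPEKARKDRNKHLAVNDPAVTQSKKCIISNKKSQPGLMTVRGCA"
  al <- align_local(s, s)
  expect_equal(al$n_identical, nchar(s))
  expect_equal(percent_identity_over_query(al), 100)
  expect_equal(al$query_start, 1L)
  expect_equal(al$subject_end, nchar(s))
  expect_identical(al$aligned_query, al$aligned_subject)
})

test_that("percent identity is computed over the full query length", {
  al <- list(n_identical = 20L)
  expect_equal(percent_identity_over_query(al, 100), 20)
  expect_equal(percent_identity_over_query(list(n_identical = 0L), 50), 0)
  expect_error(percent_identity_over_query(al), "query_length")
})

test_that("ambiguous residues score but never count as identities", {
  al <- align_local("ACDEFXHIKL", "ACDEFXHIKL")
  expect_equal(al$n_identical, 9L)
})

test_that("empty sequences are rejected", {
  expect_error(align_local("", "ACD"), "non-empty")
  expect_error(align_local("ACD", ""), "non-empty")
})

test_that("the two independent oracles agree on tiny strings", {
  mat <- score_matrix("BLOSUM62")
  set.seed(42)
  ab <- c("A", "C", "G", "W")
  for (i in 1:25) {
    q <- random_aa(sample(1:4, 1), ab)
    s <- random_aa(sample(1:4, 1), ab)
    expect_equal(oracle_enumerate_score(q, s, mat),
                 oracle_local_score(q, s, mat),
                 info = paste(q, s))
  }
})

test_that("compiled aligner matches the exhaustive DP oracle on short pairs", {
  mat <- score_matrix("BLOSUM62")
  set.seed(7)
  ab <- c("A", "C", "G", "W")
  for (i in 1:200) {
    q <- random_aa(sample(2:8, 1), ab)
    s <- random_aa(sample(2:8, 1), ab)
    expect_equal(align_local(q, s)$score, oracle_local_score(q, s, mat),
                 info = paste(q, s))
  }
})

test_that("compiled aligner agrees with an independent library implementation", {
  suppressMessages(requireNamespace("Biostrings"))
  set.seed(99)
  for (i in 1:40) {
    q <- random_aa(sample(10:60, 1))
    s <- random_aa(sample(10:60, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(align_local(q, s)$score, max(ref, 0))
  }
})

test_that("alignment output is deterministic", {
  set.seed(5)
  q <- random_aa(80); s <- random_aa(90)
  a1 <- align_local(q, s); a2 <- align_local(q, s)
  expect_identical(a1[names(a1) != "query_length"],
                   a2[names(a2) != "query_length"])
})

test_that("unknown scoring matrix raises a configuration error", {
  expect_error(align_local("ACD", "ACD", matrix = "NOSUCH62"), "unknown")
})
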