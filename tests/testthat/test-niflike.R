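test_that("fusion detection requires separated H and D/E hit intervals", {
  h <- data.frame(protein_id = "p", family = c("nifH", "nifE"),
                  subject_start = c(1L, 300L), subject_end = c(280L, 730L))
  expect_true(detect_fusion(h))
  overlap <- data.frame(protein_id = "p", family = c("nifH", "nifE"),
                        subject_start = c(1L, 100L),
                        subject_end = c(280L, 500L))
  expect_false(detect_fusion(overlap))
  only_d <- data.frame(protein_id = "p", family = "nifD",
                       subject_start = 1L, subject_end = 400L)
  expect_false(detect_fusion(only_d))
  only_h <- data.frame(protein_id = "p", family = "nifH",
                       subject_start = 1L, subject_end = 280L)
  expect_false(detect_fusion(only_h))
})

test_that("a concatenated NifH+NifE open reading frame is flagged in a scan", {
  q <- test_queries(); p <- test_profile(); d <- test_dpor()
  fused <- paste0(mutate_reference(qseq("nifH"), 55, 1),
                  make_motif_variant("green", 55, 2, q, p)$alpha)
  g <- toy_genome(c(fus = fused, d1 = random_aa(260), d2 = random_aa(300)))
  r <- scan_genome(g, q, p, d)
  expect_equal(nrow(r$niflike$fusions), 1L)
  expect_equal(r$call$status, "NEGATIVE")
  expect_false("fus" %in% r$inventory$loci$protein_id)
})

test_that("comparative DPOR filtering drops DPOR-like, keeps nitrogenase", {
  q <- test_queries(); d <- test_dpor()
  seqs <- c(bchB_self = d$sequence[d$family == "bchB"],
            nifD_self = qseq("nifD"))
  nif_score <- vapply(seqs, function(s)
    max(vapply(c("nifD", "nifE", "nifK", "nifN"), function(f)
      align_local(qseq(f), s)$score, 0L)), 0L)
  cand <- data.frame(id = names(seqs), score = nif_score,
                     dpor_score = nifscan:::dpor_best_scores(seqs, d))
  fl <- filter_dpor(cand)
  expect_equal(fl$removed$id, "bchB_self")
  expect_equal(fl$retained$id, "nifD_self")
})

test_that("seeded DPOR decoys are fully removed, nitrogenase copies never", {
  q <- test_queries(); p <- test_profile(); d <- test_dpor()
  set.seed(606)
  dpor_seqs <- vapply(1:50, function(i)
    mutate_reference(d$sequence[((i - 1) %% 4) + 1], 60, 606 + i), "")
  nif_seqs <- vapply(1:10, function(i)
    mutate_reference(qseq(c("nifD", "nifK")[(i %% 2) + 1]), 55, 700 + i), "")
  all_seqs <- c(dpor_seqs, nif_seqs)
  nif_score <- vapply(all_seqs, function(s)
    max(vapply(c("nifD", "nifK"), function(f)
      align_local(qseq(f), s)$score, 0L)), 0L)
  cand <- data.frame(kind = rep(c("dpor", "nif"), c(50, 10)),
                     score = nif_score,
                     dpor_score = nifscan:::dpor_best_scores(all_seqs, d))
  fl <- filter_dpor(cand)
  expect_equal(sum(fl$removed$kind == "dpor"), 50L)
  expect_equal(sum(fl$removed$kind == "nif"), 0L)
})

test_that("adjacent alpha/beta candidates pair greedily and exhaustively", {
  mk <- function(types, idx) data.frame(
    subunit_type = types, replicon_id = "c", gene_index = idx,
    locus_tag = paste0("L", seq_along(idx)))
  pr <- pair_adjacent_subunits(mk(c("alpha_like", "beta_like"), 0:1))
  expect_equal(nrow(pr$pairs), 1L)
  expect_length(pr$singles, 0L)

  tandem <- pair_adjacent_subunits(
    mk(c("alpha_like", "beta_like", "alpha_like", "beta_like"), 0:3))
  expect_equal(nrow(tandem$pairs), 2L)
  expect_length(tandem$singles, 0L)

  aa <- pair_adjacent_subunits(mk(c("alpha_like", "alpha_like"), 0:1))
  expect_equal(nrow(aa$pairs), 0L)
  expect_length(aa$singles, 2L)

  far <- pair_adjacent_subunits(mk(c("alpha_like", "beta_like"), c(0L, 30L)))
  expect_equal(nrow(far$pairs), 0L)
  expect_length(far$singles, 2L)
})

test_that("pairing output partitions the candidates", {
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    cand <- data.frame(
      subunit_type = sample(c("alpha_like", "beta_like"), n, TRUE),
      replicon_id = sample(c("a", "b"), n, TRUE),
      gene_index = sort(sample(0:20, n)),
      locus_tag = paste0("L", 1:n))
    pr <- pair_adjacent_subunits(cand)
    touched <- c(pr$pairs$alpha_idx, pr$pairs$beta_idx, pr$singles)
    expect_setequal(touched, seq_len(n))
    expect_equal(anyDuplicated(touched), 0L)
  }
})

test_that("ligand classes are mutually exclusive and total", {
  prof <- function(c275, h442, cys) {
    structure(list(has_C275 = c275, has_H442 = h442,
                   p_cluster_cys_count = cys), class = "ligand_profile")
  }
  expect_equal(classify_ligand_class(prof(TRUE, FALSE, 3L)), "GREEN")
  expect_equal(classify_ligand_class(prof(FALSE, FALSE, 3L)), "YELLOW")
  expect_equal(classify_ligand_class(prof(FALSE, FALSE, 2L)), "REDUCED_CYS")
  expect_equal(classify_ligand_class(prof(TRUE, FALSE, 3L), single = TRUE),
               "NFLD_SINGLE")
  combos <- expand.grid(c275 = c(TRUE, FALSE), h442 = c(TRUE, FALSE),
                        cys = 0:3)
  labs <- vapply(seq_len(nrow(combos)), function(i)
    classify_ligand_class(prof(combos$c275[i], combos$h442[i],
                               combos$cys[i])), "")
  expect_true(all(labs %in% c("GREEN", "YELLOW", "REDUCED_CYS",
                              "UNDETERMINED")))
})

test_that("near-identical sequences deduplicate to the longest representative", {
  s <- random_aa(200)
  two_same <- c(b_id = s, a_id = s)
  rep1 <- dedup_by_identity(two_same)
  expect_length(rep1, 1L)
  expect_equal(names(rep1), "a_id")

  distinct <- c(x = random_aa(200), y = random_aa(200))
  expect_length(dedup_by_identity(distinct), 2L)
  expect_length(dedup_by_identity(character()), 0L)
})

test_that("alignment export writes FASTA that reads back intact", {
  reps <- c(seq1 = random_aa(120), seq2 = random_aa(150),
            seq3 = random_aa(90))
  tmp <- tempfile(fileext = ".faa")
  export_alignment(reps, tmp)
  back <- Biostrings::readAAStringSet(tmp)
  expect_setequal(names(back), names(reps))
  expect_equal(as.character(back[["seq2"]]), reps[["seq2"]])
  tmp2 <- tempfile(fileext = ".faa")
  expect_warning(export_alignment(character(), tmp2), "empty")
  expect_true(file.exists(tmp2))
})
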