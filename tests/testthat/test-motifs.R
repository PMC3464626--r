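test_that("the reference maps onto itself as the identity", {
  p <- test_profile()
  pm <- map_positions(p$alpha_seq, p, "alpha")
  expect_equal(pm$map, seq_len(nchar(p$alpha_seq)))
  expect_equal(pm$coverage, 1)
  expect_false(pm$low_confidence)
})

test_that("the bundled reference carries the annotated ligand environment", {
  p <- test_profile()
  pm <- map_positions(p$alpha_seq, p, "alpha")
  lp <- extract_ligand_profile(pm, p)
  expect_identical(unname(lp$residues[c("275", "442", "191", "195", "426")]),
                   c("C", "H", "Q", "H", "K"))
  expect_equal(lp$p_cluster_cys_count, 3L)
  expect_true(lp$has_C275 && lp$has_H442 && lp$aromatic_444 && lp$acidic_445)
  expect_equal(classify_nifd_subfamily(lp)$label, "CONVENTIONAL_AB")
  # beta reference: three P-cluster cysteines in NifK numbering
  bm <- map_positions(p$beta_seq, p, "beta")
  expect_equal(count_p_cluster_cys(bm, profile = p), 3L)
})

test_that("a deletion at 444 maps to ABSENT and keeps neighbours aligned", {
  p <- test_profile()
  del <- paste0(substr(p$alpha_seq, 1, 443),
                substr(p$alpha_seq, 445, nchar(p$alpha_seq)))
  pm <- map_positions(del, p, "alpha")
  expect_equal(pm$map[[444]], 0L)
  expect_equal(pm$map[[443]], 443L)
  expect_equal(pm$map[[445]], 444L)   # successor shifts left by one
  lp <- extract_ligand_profile(pm, p)
  expect_identical(unname(lp$residues[["444"]]), "ABSENT")
  expect_false(lp$aromatic_444)
})

test_that("short fragments and unrelated sequences are flagged", {
  p <- test_profile()
  expect_error(map_positions(random_aa(80), p), "fragment")
  set.seed(8)
  pm <- map_positions(random_aa(400), p, "alpha")
  expect_true(pm$low_confidence)
})

test_that("an all-alanine sequence shows no ligands", {
  p <- test_profile()
  pm <- map_positions(strrep("A", 492), p, "alpha")
  lp <- extract_ligand_profile(pm, p)
  expect_equal(lp$p_cluster_cys_count, 0L)
  expect_false(lp$has_C275 || lp$has_H442)
})

test_that("subfamily signatures classify by the stated precedence", {
  q <- test_queries(); p <- test_profile()
  classify_seq <- function(s, template = "nifD") {
    pm <- map_positions(s, p, "alpha", template)
    classify_nifd_subfamily(extract_ligand_profile(pm, p))$label
  }
  v <- make_motif_variant("V", 60, seed = 3, q, p)
  expect_equal(classify_seq(v$alpha), "V")
  cc <- make_motif_variant("C", 60, seed = 4, q, p)
  expect_equal(classify_seq(cc$alpha), "C")
  conv <- make_motif_variant("conventional", 60, seed = 5, q, p)
  expect_equal(classify_seq(conv$alpha), "CONVENTIONAL_AB")
  # losing Cys275 alone voids the conventional signature
  s <- p$alpha_seq
  substr(s, 275, 275) <- "A"
  expect_equal(classify_seq(s), "UNCLASSIFIED")
})

test_that("mutations outside the tracked positions never change the label", {
  p <- test_profile()
  tracked <- sort(unique(c(p$tracked_positions, p$p_cluster_alpha)))
  set.seed(77)
  free <- setdiff(seq_len(nchar(p$alpha_seq)), tracked)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:15) {
    v <- strsplit(p$alpha_seq, "")[[1]]
    for (pos in sample(free, 60))
      v[pos] <- sample(setdiff(aa20, v[pos]), 1)
    pm <- map_positions(paste(v, collapse = ""), p, "alpha")
    lab <- classify_nifd_subfamily(extract_ligand_profile(pm, p))$label
    expect_equal(lab, "CONVENTIONAL_AB")
  }
})

test_that("NifE-assigned sequences profile through the dual numbering", {
  q <- test_queries(); p <- test_profile()
  g <- make_motif_variant("green", 50, seed = 21, q, p)
  pm <- map_positions(g$alpha, p, "alpha", template_family = "nifE")
  lp <- extract_ligand_profile(pm, p)
  expect_true(lp$has_C275)
  expect_false(lp$has_H442)
  expect_equal(lp$p_cluster_cys_count, 3L)
})

test_that("motif_table aggregates residues, counts and labels", {
  p <- test_profile()
  tab <- motif_table(c(ref = p$alpha_seq), p)
  expect_equal(tab$subfamily, "CONVENTIONAL_AB")
  expect_equal(tab$cys_alpha, 3L)
  expect_equal(tab$pos275, "C")
})
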