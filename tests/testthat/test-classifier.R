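REQ <- c("nifH", "nifD", "nifK", "nifE", "nifN", "nifB")

all_subsets <- function(set) {
  lapply(0:(2^length(set) - 1), function(mask)
    set[bitwAnd(mask, 2^(seq_along(set) - 1)) > 0])
}

# independent truth-table oracle written straight from the stated rule
oracle_status <- function(present) {
  if (all(REQ %in% present)) return("DIAZOTROPH_PREDICTED")
  missing <- setdiff(REQ, present)
  if (all(c("nifH", "nifD", "nifK", "nifB") %in% present) &&
      all(missing %in% c("nifE", "nifN"))) return("GROUP_C_CANDIDATE")
  if (xor("nifH" %in% present, "nifD" %in% present)) return("ORPHAN")
  "NEGATIVE"
}

test_that("minimum-set classification matches the brute-force truth table", {
  subsets <- all_subsets(REQ)
  statuses <- vapply(subsets, function(p)
    classify_minimum_set(p, REQ)$status, "")
  oracle <- vapply(subsets, oracle_status, "")
  expect_identical(statuses, oracle)
  expect_equal(sum(statuses == "DIAZOTROPH_PREDICTED"), 1L)
  full <- which(vapply(subsets, length, 1L) == 6L)
  expect_equal(statuses[full], "DIAZOTROPH_PREDICTED")
})

test_that("adding one gene never demotes a call", {
  rank <- c(NEGATIVE = 0, ORPHAN = 0, GROUP_C_CANDIDATE = 1,
            DIAZOTROPH_PREDICTED = 2)
  n_checked <- 0L
  for (p in all_subsets(REQ)) {
    before <- classify_minimum_set(p, REQ)$status
    for (g in setdiff(REQ, p)) {
      after <- classify_minimum_set(c(p, g), REQ)$status
      expect_gte(rank[[after]], rank[[before]])
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, 192L)
})

test_that("canonical genome patterns classify as expected", {
  expect_equal(classify_minimum_set(REQ)$status, "DIAZOTROPH_PREDICTED")
  expect_equal(classify_minimum_set("nifH")$status, "ORPHAN")
  expect_equal(classify_minimum_set("nifD")$status, "ORPHAN")
  expect_equal(classify_minimum_set(c("nifH", "nifD", "nifK", "nifB",
                                      "nifV"))$status, "GROUP_C_CANDIDATE")
  expect_equal(classify_minimum_set(character())$status, "NEGATIVE")
  call <- classify_minimum_set(REQ)
  expect_length(call$missing_families, 0)
})

test_that("group C demands a C-motif D subunit when motif data exist", {
  content <- c("nifH", "nifD", "nifK", "nifB")
  expect_equal(classify_minimum_set(content, REQ,
                                    d_subfamily_labels = c(x = "C"))$status,
               "GROUP_C_CANDIDATE")
  expect_equal(classify_minimum_set(content, REQ,
               d_subfamily_labels = c(x = "CONVENTIONAL_AB"))$status,
               "NEGATIVE")
  no_motif <- classify_minimum_set(content, REQ)
  expect_equal(no_motif$status, "GROUP_C_CANDIDATE")
  expect_true(no_motif$low_confidence)
})

test_that("orphan detection names the present marker gene", {
  inv_d <- build_inventory(data.frame(family = "nifD", locus_tag = "a"),
                           "spD")
  expect_equal(detect_orphans(inv_d)$orphan_type, "orphan_nifD")
  inv_h <- build_inventory(data.frame(family = "nifH", locus_tag = "a"),
                           "spH")
  expect_equal(detect_orphans(inv_h)$orphan_type, "orphan_nifH")
  inv_both <- build_inventory(data.frame(family = c("nifH", "nifD"),
                                         locus_tag = c("a", "b")), "sp2")
  expect_equal(nrow(detect_orphans(inv_both)), 0L)
  inv_none <- build_inventory(data.frame(family = character(),
                                         locus_tag = character()), "sp0")
  expect_equal(nrow(detect_orphans(inv_none)), 0L)
})

test_that("alternative systems follow the G subunit and the V motif", {
  loci <- function(fams) data.frame(
    family = fams, locus_tag = paste0("L", seq_along(fams)),
    replicon_id = "c", gene_index = seq_along(fams) - 1L)
  mo_only <- build_inventory(loci(REQ), "mo")
  a <- detect_alternative_systems(mo_only)
  expect_setequal(a$subtypes, "Mo")
  expect_false(a$hierarchy_violation)

  fe_only <- build_inventory(loci("anfG"), "fe")
  a <- detect_alternative_systems(fe_only)
  expect_setequal(a$subtypes, "Fe")
  expect_true(a$hierarchy_violation)

  vnf <- build_inventory(loci(c(REQ, "nifD", "vnfG")), "v")
  labels <- c(L7 = "V")
  cl <- cluster_by_adjacency(vnf$loci)
  a <- detect_alternative_systems(vnf, labels, cl)
  expect_setequal(a$subtypes, c("Mo", "V"))
  expect_false(a$hierarchy_violation)
})

test_that("Mo copy counting excludes V-labeled subunits and is order-stable", {
  loci <- data.frame(
    family = c("nifH", "nifD", "nifK", "nifH", "nifD", "nifK"),
    locus_tag = paste0("L", 1:6), replicon_id = "c",
    gene_index = c(0:2, 40:42))
  cl <- cluster_by_adjacency(loci)
  expect_equal(count_mo_copies(cl), 2L)
  expect_equal(count_mo_copies(cl, v_labeled_loci = "L5"), 1L)
  # reversal of gene order and replicon relabeling leave the count unchanged
  rev_loci <- loci
  rev_loci$gene_index <- max(loci$gene_index) - loci$gene_index
  rev_loci$replicon_id <- "plasmid_7"
  expect_equal(count_mo_copies(cluster_by_adjacency(rev_loci)), 2L)
  no_d <- loci[loci$family != "nifD", ]
  expect_equal(count_mo_copies(cluster_by_adjacency(no_d)), 0L)
})
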