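# Independent alignment oracles and shared fixtures.

# Plain-R affine-gap Smith-Waterman (score only), written independently of
# the compiled kernel.  Gap of length L costs open + L * ext.
oracle_local_score <- function(q, s, mat, open = 11, ext = 1) {
  qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
  n <- length(qv); m <- length(sv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
      d <- max(M[i, j], Ix[i, j], Iy[i, j], 0) + mat[qv[i], sv[j]]
      M[i + 1, j + 1] <- max(d, 0)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Exhaustive enumeration of every local alignment of tiny strings: all
# substring pairs x all gapped global alignments of those substrings.
oracle_enumerate_score <- function(q, s, mat, open = 11, ext = 1) {
  qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
  glob <- function(a, b, state) {
    # best global alignment of vectors a, b; state: 0 aligned, 1 in-ix, 2 in-iy
    if (!length(a) && !length(b)) return(0)
    best <- -1e9
    if (length(a) && length(b))
      best <- max(best, mat[a[1], b[1]] + glob(a[-1], b[-1], 0))
    if (length(a)) {
      cost <- if (state == 1) ext else open + ext
      best <- max(best, glob(a[-1], b, 1) - cost)
    }
    if (length(b)) {
      cost <- if (state == 2) ext else open + ext
      best <- max(best, glob(a, b[-1], 2) - cost)
    }
    best
  }
  best <- 0
  for (i0 in seq_along(qv)) for (i1 in i0:length(qv))
    for (j0 in seq_along(sv)) for (j1 in j0:length(sv)) {
      a <- qv[i0:i1]; b <- sv[j0:j1]
      # local alignments start and end on aligned pairs
      sc <- mat[a[1], b[1]] +
        (if (length(a) > 1 || length(b) > 1) glob(a[-1], b[-1], 0) else 0)
      best <- max(best, sc)
    }
  best
}

ref_cache <- new.env(parent = emptyenv())

test_queries <- function() {
  if (is.null(ref_cache$queries)) ref_cache$queries <- load_default_queries()
  ref_cache$queries
}

test_profile <- function() {
  if (is.null(ref_cache$profile))
    ref_cache$profile <- reference_profile(test_queries())
  ref_cache$profile
}

test_dpor <- function() {
  if (is.null(ref_cache$dpor)) ref_cache$dpor <- load_dpor_references()
  ref_cache$dpor
}

qseq <- function(fam) {
  q <- test_queries()
  q$sequence[q$family == fam]
}

random_aa <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, TRUE), collapse = "")
}

# minimal in-memory genome from named protein sequences (file order = gene order)
toy_genome <- function(seqs, species = "toy", replicon = "c1") {
  rec <- data.frame(protein_id = names(seqs), locus_tag = names(seqs),
                    replicon_id = replicon, start = NA_integer_,
                    end = NA_integer_, strand = "+",
                    sequence = unname(unlist(seqs)))
  genome_annotation(rec, species)
}
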