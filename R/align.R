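#' @useDynLib nifscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.matrix_cache <- new.env(parent = emptyenv())

#' Protein scoring matrix used by the built-in aligner
#'
#' Returns a BLOSUM-family substitution matrix (from \pkg{Biostrings}) extended
#' with a `U` (selenocysteine) row/column that scores like `X`.  Ambiguous
#' residues (`X`, `B`, `Z`, `U`) are scored by the matrix but never counted as
#' identities.
#'
#' @param name matrix name, e.g. `"BLOSUM62"` (default) or `"BLOSUM45"`.
#' @return integer matrix with single-letter dimnames.
#' @export
score_matrix <- function(name = "BLOSUM62") {
  if (!is.character(name) || length(name) != 1L)
    stop("matrix name must be a single string", call. = FALSE)
  if (!is.null(.matrix_cache[[name]])) return(.matrix_cache[[name]])
  env <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = env)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || is.null(env[[name]]))
    stop("unknown scoring matrix: ", name, call. = FALSE)
  m <- env[[name]]
  if (!"U" %in% rownames(m)) {
    m <- rbind(m, U = m["X", ])
    m <- cbind(m, U = m[, "X"])
    m["U", "U"] <- m["X", "X"]
  }
  storage.mode(m) <- "integer"
  .matrix_cache[[name]] <- m
  m
}

resolve_matrix <- function(matrix) {
  if (is.character(matrix)) score_matrix(matrix) else {
    stopifnot(is.matrix(matrix), !is.null(dimnames(matrix)))
    storage.mode(matrix) <- "integer"
    matrix
  }
}

#' Optimal local protein alignment (affine gaps)
#'
#' Smith-Waterman alignment under `score + gap_open + L * gap_extend` gap
#' costs (the usual protein-search convention: an L-residue gap costs
#' `gap_open + L * gap_extend`).  Traceback is deterministic: among equal-score
#' cells the one with the smallest subject index, then smallest query index,
#' is chosen.
#'
#' @param query,subject amino-acid strings (non-empty).
#' @param matrix scoring matrix name or integer matrix with dimnames.
#' @param gap_open,gap_extend gap penalties (positive numbers).
#' @return a `nif_alignment` list: `score`, `n_identical`, `query_start/end`,
#'   `subject_start/end` (1-based, 0 when the best alignment is empty), and the
#'   gapped `aligned_query` / `aligned_subject` strings.
#' @export
align_local <- function(query, subject, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(subject))
    stop("query and subject must be non-empty sequences", call. = FALSE)
  m <- resolve_matrix(matrix)
  r <- cpp_align_local(toupper(query), toupper(subject), m,
                       rownames(m), colnames(m),
                       as.integer(gap_open), as.integer(gap_extend), TRUE)
  r$query_length <- nchar(query)
  class(r) <- "nif_alignment"
  r
}

#' @export
print.nif_alignment <- function(x, ...) {
  cat(sprintf("local alignment: score %d, %d identities, query %d-%d, subject %d-%d\n",
              x$score, x$n_identical, x$query_start, x$query_end,
              x$subject_start, x$subject_end))
  invisible(x)
}

# Vectorised local alignment of one query against many subjects (no strings).
align_local_batch <- function(query, subjects, matrix = "BLOSUM62",
                              gap_open = 11, gap_extend = 1) {
  m <- resolve_matrix(matrix)
  if (length(subjects) == 0L)
    return(data.frame(score = integer(), n_identical = integer(),
                      query_start = integer(), query_end = integer(),
                      subject_start = integer(), subject_end = integer()))
  cpp_align_local_batch(toupper(query), toupper(subjects), m,
                        rownames(m), colnames(m),
                        as.integer(gap_open), as.integer(gap_extend))
}

# Global alignment with free end gaps; used for reference-position mapping.
align_overlap <- function(ref, subject, matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1) {
  if (!nzchar(ref) || !nzchar(subject))
    stop("sequences must be non-empty", call. = FALSE)
  m <- resolve_matrix(matrix)
  cpp_align_overlap(toupper(ref), toupper(subject), m,
                    rownames(m), colnames(m),
                    as.integer(gap_open), as.integer(gap_extend))
}

#' Percent identity over the query length
#'
#' The screening statistic of the genome census: the number of identical aligned
#' residues divided by the *full query length* (not the alignment length), as
#' a percentage.  This is deliberately asymmetric: short local matches to a
#' long query are penalised.
#'
#' @param alignment a `nif_alignment` (or any list with `n_identical`).
#' @param query_length full length of the query protein; defaults to the
#'   length recorded in the alignment.
#' @return numeric percentage in `[0, 100]`.
#' @export
percent_identity_over_query <- function(alignment, query_length = NULL) {
  if (is.null(query_length)) query_length <- alignment$query_length
  if (is.null(query_length) || query_length <= 0)
    stop("query_length must be a positive integer", call. = FALSE)
  100 * alignment$n_identical / query_length
}
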