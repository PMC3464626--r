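AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "B", "Z", "U")

#' Construct a genome annotation
#'
#' The internal unit of analysis: one species/assembly with an ordered table
#' of protein-coding records.  `gene_index` is the 0-based ordinal position of
#' the CDS along its replicon and is the adjacency coordinate used by all
#' synteny logic (nucleotide coordinates are retained but not used for
#' clustering, so coordinate-free FASTA input still supports synteny).
#'
#' @param records data.frame with columns `protein_id`, `locus_tag`,
#'   `replicon_id`, `gene_index`, `start`, `end`, `strand`, `sequence`.
#'   `start`/`end` are 1-based inclusive nucleotide coordinates (NA allowed).
#' @param species_name,assembly_id identifiers for the genome.
#' @param taxonomy optional list with `domain` and `phylum`.
#' @param renumber if `TRUE` (default) gene_index is (re)assigned per replicon
#'   from the given order (or by `start` when coordinates are present).
#' @return object of class `genome_annotation`.
#' @export
genome_annotation <- function(records, species_name, assembly_id = species_name,
                              taxonomy = NULL, renumber = TRUE) {
  needed <- c("protein_id", "locus_tag", "replicon_id", "start", "end",
              "strand", "sequence")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("records are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  records$sequence <- toupper(sub("\\*+$", "", records$sequence))
  if (any(!nzchar(records$sequence)))
    stop("empty protein sequence for record(s): ",
         paste(records$protein_id[!nzchar(records$sequence)], collapse = ", "),
         call. = FALSE)
  bad <- vapply(strsplit(records$sequence, ""),
                function(v) any(!v %in% AA_ALPHABET), logical(1))
  if (any(bad))
    stop("non-amino-acid characters in sequence of: ",
         paste(records$protein_id[bad], collapse = ", "), call. = FALSE)
  if (any(!is.na(records$start) & !is.na(records$end) &
          records$start > records$end))
    stop("start > end in record coordinates", call. = FALSE)
  dup <- records$protein_id[duplicated(records$protein_id)]
  if (length(dup))
    stop("duplicate protein IDs: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (renumber || is.null(records$gene_index)) {
    ord <- order(records$replicon_id,
                 ifelse(is.na(records$start), seq_len(nrow(records)),
                        records$start))
    records <- records[ord, , drop = FALSE]
    records$gene_index <- stats::ave(seq_len(nrow(records)),
                                     records$replicon_id,
                                     FUN = function(i) seq_along(i) - 1L)
  }
  rownames(records) <- NULL
  structure(list(species_name = species_name, assembly_id = assembly_id,
                 taxonomy = taxonomy, records = records),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %s (%s), %d proteins on %d replicon(s)\n",
              x$species_name, x$assembly_id, nrow(x$records),
              length(unique(x$records$replicon_id))))
  invisible(x)
}

#' Read a protein FASTA into a genome annotation
#'
#' @param path FASTA file of protein sequences.
#' @param header_dialect `"generic"` (ID only; gene order = file order, no
#'   nucleotide coordinates) or `"prodigal"` (`id # start # end # strand #...`
#'   headers; the replicon is the ID with its trailing `_<n>` stripped).
#' @param species_name,assembly_id genome identifiers (default: file stem).
#' @param taxonomy optional list with `domain`, `phylum`.
#' @return [genome_annotation()].
#' @export
read_protein_fasta <- function(path, header_dialect = c("generic", "prodigal"),
                               species_name = NULL, assembly_id = NULL,
                               taxonomy = NULL) {
  header_dialect <- match.arg(header_dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  aa <- tryCatch(Biostrings::readAAStringSet(path), error = function(e)
    stop("malformed FASTA '", path, "': ", conditionMessage(e), call. = FALSE))
  if (length(aa) == 0L) stop("no records in FASTA file: ", path, call. = FALSE)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate IDs in FASTA: ", paste(dup, collapse = ", "),
         call. = FALSE)
  stem <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(species_name)) species_name <- stem
  if (is.null(assembly_id)) assembly_id <- stem
  if (header_dialect == "prodigal") {
    parts <- strsplit(headers, "\\s*#\\s*")
    ok <- lengths(parts) >= 4L
    if (any(!ok))
      stop("prodigal-style header lacks '# start # end # strand' fields: ",
           headers[!ok][1], call. = FALSE)
    start <- as.integer(vapply(parts, `[`, "", 2L))
    end <- as.integer(vapply(parts, `[`, "", 3L))
    strand <- ifelse(vapply(parts, `[`, "", 4L) %in% c("-1", "-"), "-", "+")
    replicon <- sub("_[0-9]+$", "", ids)
  } else {
    start <- NA_integer_; end <- NA_integer_; strand <- "+"
    replicon <- "unplaced"
  }
  rec <- data.frame(protein_id = ids, locus_tag = ids, replicon_id = replicon,
                    start = start, end = end, strand = strand,
                    sequence = as.character(aa))
  genome_annotation(rec, species_name, assembly_id, taxonomy)
}

# --- minimal GenBank flat-file support (CDS + /translation subset) ----------

#' Read a GenBank flat file
#'
#' Minimal parser for the CDS/translation subset of the GenBank flat-file
#' format (one or more LOCUS records).  CDS features without a /translation
#' qualifier are skipped with a warning; the skip count is available as
#' `attr(x, "load_report")`.
#'
#' @param path GenBank flat file.
#' @param species_name,assembly_id optional overrides (default: ORGANISM line
#'   and file stem).
#' @return [genome_annotation()] with taxonomy filled from the ORGANISM
#'   lineage when it follows the `Domain; Phylum; ...` convention.
#' @export
read_genbank <- function(path, species_name = NULL, assembly_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines)))
    stop("no LOCUS records in GenBank file: ", path, call. = FALSE)
  recs <- list(); skipped <- 0L
  organism <- NULL; lineage <- NULL
  locus <- NULL; i <- 1L; n <- length(lines)
  feat <- NULL; in_features <- FALSE; in_lineage <- FALSE
  finish_feat <- function() {
    if (is.null(feat)) return()
    if (is.null(feat$translation)) {
      skipped <<- skipped + 1L
    } else {
      recs[[length(recs) + 1L]] <<- data.frame(
        protein_id = feat$protein_id %||% feat$locus_tag %||%
          paste0("cds_", length(recs) + 1L),
        locus_tag = feat$locus_tag %||% feat$protein_id %||%
          paste0("cds_", length(recs) + 1L),
        replicon_id = locus, start = feat$start, end = feat$end,
        strand = feat$strand, sequence = feat$translation)
    }
    feat <<- NULL
  }
  while (i <= n) {
    ln <- lines[i]
    if (grepl("^LOCUS", ln)) {
      finish_feat(); in_features <- FALSE
      locus <- strsplit(trimws(sub("^LOCUS", "", ln)), "\\s+")[[1]][1]
    } else if (grepl("^\\s*ORGANISM", ln)) {
      organism <- organism %||% trimws(sub("^\\s*ORGANISM", "", ln))
      in_lineage <- TRUE; lineage_txt <- ""
    } else if (in_lineage && grepl("^ {10,}", ln) && !grepl("^FEATURES", ln)) {
      lineage_txt <- paste(lineage_txt, trimws(ln))
      if (grepl("\\.\\s*$", ln)) {
        lineage <- lineage %||% trimws(strsplit(sub("\\.$", "",
                   trimws(lineage_txt)), ";")[[1]])
        in_lineage <- FALSE
      }
    } else if (grepl("^FEATURES", ln)) {
      in_lineage <- FALSE; in_features <- TRUE
    } else if (grepl("^ORIGIN", ln) || grepl("^//", ln)) {
      finish_feat(); in_features <- FALSE
    } else if (in_features && grepl("^ {5}\\S", ln)) {
      finish_feat()
      key <- strsplit(trimws(ln), "\\s+")[[1]]
      if (identical(key[1], "CDS")) {
        loc <- key[2]
        # absorb continuation lines of the location
        while (i < n && grepl("^ {21}[^/]", lines[i + 1]) &&
               !grepl("^ {21}/", lines[i + 1])) {
          i <- i + 1L; loc <- paste0(loc, trimws(lines[i]))
        }
        strand <- if (grepl("complement", loc)) "-" else "+"
        nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
        feat <- list(start = min(nums), end = max(nums), strand = strand)
      }
    } else if (in_features && !is.null(feat) && grepl("^ {21}/", ln)) {
      q <- sub("^ {21}/", "", ln)
      if (grepl("^locus_tag=", q)) {
        feat$locus_tag <- gsub("\"", "", sub("^locus_tag=", "", q))
      } else if (grepl("^protein_id=", q)) {
        feat$protein_id <- gsub("\"", "", sub("^protein_id=", "", q))
      } else if (grepl("^translation=", q)) {
        tr <- sub("^translation=\"?", "", q)
        while (!grepl("\"\\s*$", tr) && i < n) {
          i <- i + 1L; tr <- paste0(tr, trimws(lines[i]))
        }
        feat$translation <- gsub("\"", "", tr)
      }
    }
    i <- i + 1L
  }
  finish_feat()
  if (!length(recs))
    stop("no CDS features with translations in: ", path, call. = FALSE)
  records <- do.call(rbind, recs)
  stem <- sub("\\.[^.]*$", "", basename(path))
  taxonomy <- NULL
  if (!is.null(lineage) && length(lineage) >= 2L)
    taxonomy <- list(domain = lineage[1], phylum = lineage[2])
  g <- genome_annotation(records,
                         species_name %||% organism %||% stem,
                         assembly_id %||% stem, taxonomy)
  if (skipped > 0L)
    warning(skipped, " CDS feature(s) without a translation were skipped",
            call. = FALSE)
  attr(g, "load_report") <- list(n_loaded = nrow(g$records),
                                 n_skipped = skipped)
  g
}

#' Read a GFF3 annotation plus genome FASTA
#'
#' CDS features are translated from the nucleotide sequence with the standard
#' genetic code (bacterial table 11 coincides with the standard code for
#' internal codons); minus-strand features are reverse-complemented first.
#' CDS whose translation fails (out-of-frame length, missing contig) are
#' skipped with a warning.
#'
#' @param gff_path GFF3 file with CDS features.
#' @param fasta_path nucleotide FASTA of the replicons named in column 1.
#' @param species_name,assembly_id optional identifiers (default: file stem).
#' @param taxonomy optional list with `domain`, `phylum`.
#' @return [genome_annotation()].
#' @export
read_gff3 <- function(gff_path, fasta_path, species_name = NULL,
                      assembly_id = NULL, taxonomy = NULL) {
  if (!file.exists(gff_path)) stop("file not found: ", gff_path, call. = FALSE)
  if (!file.exists(fasta_path)) stop("file not found: ", fasta_path, call. = FALSE)
  gr <- rtracklayer::import(gff_path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in GFF3: ", gff_path, call. = FALSE)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  skipped <- 0L; recs <- list()
  ids <- if (!is.null(gr$ID)) gr$ID else paste0("cds_", seq_along(gr))
  lt <- if (!is.null(gr$locus_tag)) gr$locus_tag else ids
  for (k in seq_along(gr)) {
    chrom <- as.character(GenomicRanges::seqnames(gr[k]))
    st <- GenomicRanges::start(gr[k]); en <- GenomicRanges::end(gr[k])
    if (!chrom %in% names(genome) || (en - st + 1L) %% 3L != 0L) {
      skipped <- skipped + 1L; next
    }
    dna <- Biostrings::subseq(genome[[chrom]], st, en)
    if (as.character(GenomicRanges::strand(gr[k])) == "-")
      dna <- Biostrings::reverseComplement(dna)
    prot <- tryCatch(
      as.character(Biostrings::translate(dna, if.fuzzy.codon = "X")),
      error = function(e) NULL)
    if (is.null(prot)) { skipped <- skipped + 1L; next }
    prot <- sub("\\*$", "", prot)
    recs[[length(recs) + 1L]] <- data.frame(
      protein_id = ids[k], locus_tag = lt[k], replicon_id = chrom,
      start = st, end = en,
      strand = as.character(GenomicRanges::strand(gr[k])),
      sequence = prot)
  }
  if (!length(recs))
    stop("no translatable CDS features in: ", gff_path, call. = FALSE)
  stem <- sub("\\.[^.]*$", "", basename(gff_path))
  g <- genome_annotation(do.call(rbind, recs), species_name %||% stem,
                         assembly_id %||% stem, taxonomy)
  if (skipped > 0L)
    warning(skipped, " CDS feature(s) could not be translated and were skipped",
            call. = FALSE)
  attr(g, "load_report") <- list(n_loaded = nrow(g$records),
                                 n_skipped = skipped)
  g
}
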