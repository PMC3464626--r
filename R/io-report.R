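result_row <- function(r) {
  counts <- as.list(r$copy_counts)
  names(counts) <- paste0("n_", names(counts))
  cbind(data.frame(species_name = r$species_name,
                   assembly_id = r$assembly_id,
                   call = r$call$status,
                   missing_families = paste(r$call$missing_families,
                                            collapse = ","),
                   stringsAsFactors = FALSE),
        as.data.frame(counts),
        as.data.frame(as.list(r$synteny_flags)),
        data.frame(mo_copies = r$mo_copies,
                   subtypes = paste(r$subtypes, collapse = ","),
                   hierarchy_violation = r$hierarchy_violation,
                   n_niflike = nrow(r$niflike$candidates),
                   n_fusions = nrow(r$niflike$fusions),
                   n_dpor_removed = nrow(r$niflike$dpor_removed),
                   orphan_type = if (nrow(r$orphans)) r$orphans$orphan_type
                     else ""))
}

#' Write a scan report
#'
#' `tsv`: one row per species (deterministic column order, rows sorted by
#' species name) with the call, per-family copy counts, synteny flags,
#' subtypes and triage counts.  `json`: the full evidence structure,
#' re-loadable with [read_evidence()].
#'
#' @param results a `nifscan_result` or list thereof.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(results, "nifscan_result")) results <- list(results)
  results <- results[order(vapply(results, function(r) r$species_name, ""))]
  if (format == "tsv") {
    rows <- lapply(results, result_row)
    tab <- if (length(rows)) do.call(rbind, rows) else result_row_template()
    ok <- tryCatch({
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) stop("cannot write report to '", path, "': ",
                                conditionMessage(e), call. = FALSE))
  } else {
    payload <- lapply(results, result_evidence)
    tryCatch(jsonlite::write_json(payload, path, auto_unbox = TRUE,
                                  digits = NA, pretty = TRUE, null = "null"),
             error = function(e) stop("cannot write report to '", path,
                                      "': ", conditionMessage(e),
                                      call. = FALSE))
  }
  invisible(path)
}

result_row_template <- function() {
  tmpl <- data.frame(species_name = character(), assembly_id = character(),
                     call = character(), missing_families = character())
  for (f in FAMILY_ORDER) tmpl[[paste0("n_", f)]] <- integer()
  for (f in c("min3_contiguous", "single_region", "hdk_contiguous",
              "dk_en_adjacent")) tmpl[[f]] <- logical()
  tmpl$mo_copies <- integer(); tmpl$subtypes <- character()
  tmpl$hierarchy_violation <- logical(); tmpl$n_niflike <- integer()
  tmpl$n_fusions <- integer(); tmpl$n_dpor_removed <- integer()
  tmpl$orphan_type <- character()
  tmpl
}

result_evidence <- function(r) {
  list(species_name = r$species_name, assembly_id = r$assembly_id,
       taxonomy = r$taxonomy,
       call = list(status = r$call$status,
                   missing_families = as.list(r$call$missing_families),
                   low_confidence = r$call$low_confidence),
       copy_counts = as.list(r$copy_counts),
       synteny_flags = as.list(r$synteny_flags),
       mo_copies = r$mo_copies, subtypes = as.list(r$subtypes),
       hierarchy_violation = r$hierarchy_violation,
       alpha_labels = as.list(r$alpha_labels),
       orphans = r$orphans,
       inventory = r$inventory$loci[, intersect(c("protein_id", "locus_tag",
                                                  "replicon_id", "gene_index",
                                                  "family", "pid_over_query",
                                                  "ambiguous"),
                                                names(r$inventory$loci))],
       niflike = r$niflike)
}

#' Re-load a JSON evidence file
#'
#' @param path file written by [write_report(format = "json")].
#' @return list of per-species evidence records.
#' @export
read_evidence <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

# ---- synthetic-genome writers (GenBank / GFF3 / nucleotide + protein FASTA)

reverse_translate <- function(protein) {
  paste0(paste(CODON_OF[strsplit(protein, "")[[1]]], collapse = ""), "TAA")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

wrap60 <- function(s) {
  paste(substring(s, seq(1, nchar(s), 60), pmin(seq(1, nchar(s), 60) + 59,
                                                nchar(s))), collapse = "\n")
}

build_contig <- function(records) {
  segs <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    cds <- reverse_translate(records$sequence[i])
    segs[i] <- if (records$strand[i] == "-") revcomp_chr(cds) else cds
  }
  spacer <- "ACGTACGTACGTACGTACGT"
  contig <- character(0)
  pos <- 1L
  pieces <- character(0)
  for (i in seq_len(nrow(records))) {
    if (records$start[i] > pos)
      pieces <- c(pieces, substr(paste(rep(spacer, 100), collapse = ""), 1,
                                 records$start[i] - pos))
    pieces <- c(pieces, segs[i])
    pos <- records$end[i] + 1L
  }
  paste(pieces, collapse = "")
}

write_genome_files <- function(genome, out_dir) {
  rec <- genome$records
  stem <- file.path(out_dir, genome$species_name)
  contig <- build_contig(rec)
  # protein FASTA (file order = gene order, so generic re-reading preserves it)
  aa <- Biostrings::AAStringSet(rec$sequence)
  names(aa) <- rec$protein_id
  Biostrings::writeXStringSet(aa, paste0(stem, ".faa"), width = 60)
  # nucleotide FASTA
  writeLines(c(">chr1", wrap60(contig)), paste0(stem, ".fna"))
  # GFF3
  gff <- c("##gff-version 3",
           sprintf("chr1\tnifscan_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s",
                   rec$start, rec$end, rec$strand, rec$protein_id,
                   rec$locus_tag))
  writeLines(gff, paste0(stem, ".gff3"))
  # GenBank flat file
  con <- file(paste0(stem, ".gbk"), "w")
  on.exit(close(con))
  lineage <- if (!is.null(genome$taxonomy))
    sprintf("            %s; %s.", genome$taxonomy$domain,
            genome$taxonomy$phylum) else "            Bacteria; Unknown."
  cat(sprintf("LOCUS       chr1 %d bp    DNA     linear BCT\n",
              nchar(contig)),
      sprintf("DEFINITION  synthetic genome %s.\n", genome$species_name),
      sprintf("SOURCE      %s\n", genome$species_name),
      sprintf("  ORGANISM  %s\n", genome$species_name),
      lineage, "\n",
      "FEATURES             Location/Qualifiers\n", sep = "", file = con)
  for (i in seq_len(nrow(rec))) {
    loc <- sprintf("%d..%d", rec$start[i], rec$end[i])
    if (rec$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    cat(sprintf("     CDS             %s\n", loc), file = con)
    cat(sprintf("                     /locus_tag=\"%s\"\n", rec$locus_tag[i]),
        file = con)
    cat(sprintf("                     /protein_id=\"%s\"\n",
                rec$protein_id[i]), file = con)
    tr <- rec$sequence[i]
    tr_lines <- substring(tr, seq(1, nchar(tr), 44),
                          pmin(seq(1, nchar(tr), 44) + 43, nchar(tr)))
    if (length(tr_lines) == 1L) {
      cat(sprintf("                     /translation=\"%s\"\n", tr_lines),
          file = con)
    } else {
      cat(sprintf("                     /translation=\"%s\n", tr_lines[1]),
          file = con)
      mid <- tr_lines[-c(1, length(tr_lines))]
      if (length(mid))
        cat(sprintf("                     %s\n", mid), sep = "", file = con)
      cat(sprintf("                     %s\"\n", tr_lines[length(tr_lines)]),
          file = con)
    }
  }
  cat("ORIGIN\n", file = con)
  starts <- seq(1, nchar(contig), 60)
  for (s in starts) {
    chunk <- substr(contig, s, min(s + 59, nchar(contig)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
    cat(sprintf("%9d %s\n", s, paste(tolower(tens), collapse = " ")),
        file = con)
  }
  cat("//\n", file = con)
  list(faa = paste0(stem, ".faa"), fna = paste0(stem, ".fna"),
       gff3 = paste0(stem, ".gff3"), gbk = paste0(stem, ".gbk"))
}
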