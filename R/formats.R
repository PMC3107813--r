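# Reading peptide / nucleotide FASTA and writing the three result files:
# ePST FASTA, the 14-column TSV report, and a GFF3 evidence track.
#
# FASTA parsing goes through Biostrings (gzip handled transparently); the
# GFF3 writer emits the nine columns directly so that identical inputs give
# byte-identical output files.

# Coerce assorted inputs to the canonical record tibble (id, desc, seq).
as_record_tbl <- function(x, type = c("nucleotide", "peptide")) {
  type <- match.arg(type)
  if (is.data.frame(x)) {
    x <- as_tibble(x)
    if (!all(c("id", "seq") %in% names(x))) {
      abort("record table must have columns 'id' and 'seq'")
    }
    if (is.null(x$desc)) x$desc <- x$id
    x$seq <- unname(if (type == "nucleotide") normalize_nt(x$seq) else toupper(x$seq))
    return(x[, c("id", "desc", "seq")])
  }
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    return(as_record_tbl(tibble(id = ids, desc = ids, seq = unname(x)), type))
  }
  abort("records must be a data frame (id, desc, seq) or a character vector")
}

.read_fasta <- function(path, type) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("cannot parse FASTA file '%s': %s",
                                      path, conditionMessage(e)))
  )
  if (length(set) == 0L) abort(sprintf("no FASTA records in '%s'", path))
  desc <- names(set)
  seqs <- unname(as.character(set))
  seqs <- gsub("[[:space:]]", "", seqs)
  ids <- sub("\\s.*$", "", desc)

  # uniquify duplicate ids with a numeric suffix
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)]
    for (d in unique(dup)) {
      at <- which(ids == d)
      ids[at[-1]] <- paste0(d, ".", seq_along(at[-1]) + 1L)
      pg_log("warning", sprintf(
        "duplicate FASTA id '%s' in '%s': renamed to %s",
        d, path, paste(ids[at[-1]], collapse = ", ")))
    }
  }

  if (type == "peptide") {
    seqs <- toupper(seqs)
    bad <- grepl("[*0-9]", seqs)
    if (any(bad)) {
      for (i in which(bad)) {
        pg_log("warning", sprintf(
          "skipping peptide record '%s': sequence contains '*' or digits", ids[i]))
      }
      warn(sprintf("%d peptide record(s) with '*' or digits skipped on read",
                   sum(bad)))
      ids <- ids[!bad]; desc <- desc[!bad]; seqs <- seqs[!bad]
    }
    if (length(seqs) == 0L) abort(sprintf("no usable peptide records in '%s'", path))
  } else {
    seqs <- normalize_nt(seqs)
  }
  tibble(id = ids, desc = desc, seq = seqs)
}

#' Read a peptide FASTA file
#'
#' Ids are the first whitespace-delimited header token; sequences are
#' uppercased with intra-line whitespace stripped. Records containing `'*'`
#' or digits are skipped with a logged warning; duplicate ids get a
#' uniquifying suffix.
#'
#' @param path Path to a FASTA file (gzip accepted).
#' @return Tibble with columns `id`, `desc` (full header), `seq`.
#' @export
read_peptide_fasta <- function(path) .read_fasta(path, "peptide")

#' Read a nucleotide FASTA file
#'
#' Sequences are normalized to uppercase DNA (`U` mapped to `T`); ids are
#' the first header token and duplicates get a uniquifying suffix.
#'
#' @inheritParams read_peptide_fasta
#' @return Tibble with columns `id`, `desc`, `seq`.
#' @export
read_nucleotide_fasta <- function(path) .read_fasta(path, "nucleotide")

.epst_fasta_header <- function(epsts) {
  sprintf("epst|%s|%s|%d-%d|%s|%+d",
          epsts$peptide_id, epsts$record_id, epsts$epst_start, epsts$epst_end,
          epsts$strand, epsts$frame)
}

#' Write ePSTs as a FASTA file
#'
#' One record per ePST with header
#' `epst|<peptide_id>|<record_id>|<start>-<end>|<strand>|<frame>` and the
#' coding-strand nucleotide sequence wrapped at 60 columns.
#'
#' @param epsts ePST tibble from one of the `extend_*()` functions.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epst_fasta <- function(epsts, path) {
  if (nrow(epsts) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(epsts$epst_nt)
  names(set) <- .epst_fasta_header(epsts)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Build the detailed per-ePST report table
#'
#' One row per ePST with the 14 reported fields: peptide id and sequence,
#' the full FASTA header of the matched record, the mapping start/end of the
#' reverse-translated peptide, strand, reading frame, the reverse-translated
#' peptide nucleotides, the longer 5'-stop-to-3'-stop context, the ePST
#' nucleotides with their start/end and length, and the translated ePST.
#'
#' @param epsts ePST tibble.
#' @param records Nucleotide record tibble (for the full headers).
#' @return Tibble with 14 columns in report order.
#' @export
epst_report <- function(epsts, records) {
  records <- as_record_tbl(records, "nucleotide")
  tibble(
    peptide_id = epsts$peptide_id,
    peptide_seq = epsts$peptide_seq,
    record_header = records$desc[match(epsts$record_id, records$id)],
    map_start = epsts$nt_start,
    map_end = epsts$nt_end,
    strand = epsts$strand,
    frame = sprintf("%+d", epsts$frame),
    peptide_nt = epsts$coding_nt,
    stop_to_stop_nt = epsts$stop_to_stop_nt,
    epst_nt = epsts$epst_nt,
    epst_start = epsts$epst_start,
    epst_end = epsts$epst_end,
    epst_length = nchar(epsts$epst_nt),
    epst_protein = epsts$epst_protein
  )
}

#' Write the detailed TSV report
#'
#' @param rows Report tibble from [epst_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epst_tsv <- function(rows, path) {
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

.gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x
}

#' Write ePSTs as a GFF3 evidence track
#'
#' One `protein_match` feature per ePST (source `pgmap`), with 1-based
#' inclusive forward-strand coordinates (`start <= end` on both strands),
#' phase `0` in the codon-aware modes and `.` in fixed-length mode, and
#' attributes `ID` (unique per feature), `Name` (the peptide id) and
#' `Target` (`<peptide_id> 1 <peptide length>`).
#'
#' @param epsts ePST tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epst_gff3 <- function(epsts, path) {
  lines <- "##gff-version 3"
  if (nrow(epsts) > 0L) {
    phase <- ifelse(epsts$mode == "fixed", ".", "0")
    ids <- sprintf("epst%05d", seq_len(nrow(epsts)))
    attrs <- sprintf("ID=%s;Name=%s;Target=%s 1 %d",
                     ids, .gff3_escape(epsts$peptide_id),
                     .gff3_escape(epsts$peptide_id), nchar(epsts$peptide_seq))
    lines <- c(lines, paste(
      .gff3_escape(epsts$record_id), "pgmap", "protein_match",
      epsts$epst_start, epsts$epst_end, ".", epsts$strand, phase, attrs,
      sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
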