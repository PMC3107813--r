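# Genetic code tables in the layout of the NCBI toolkit: a 64-character
# ncbieaa string assigns one amino acid (or '*') to every codon in TCAG
# nesting order (TTT, TTC, ..., GGG), and a parallel sncbieaa string marks
# initiation codons with 'M'.

.codon_bases <- c("T", "C", "A", "G")

#' All 64 unambiguous codons in NCBI table order
#'
#' TCAG nesting with the first base varying slowest: TTT first, GGG last.
#' This is the order the `ncbieaa`/`sncbieaa` strings of an NCBI genetic
#' code table file are written in.
#'
#' @return Character vector of 64 codons.
#' @export
ncbi_codon_order <- function() {
  out <- character(64L)
  k <- 0L
  for (b1 in .codon_bases) for (b2 in .codon_bases) for (b3 in .codon_bases) {
    k <- k + 1L
    out[k] <- paste0(b1, b2, b3)
  }
  out
}

new_genetic_code <- function(name, id, aa_table, start_codons) {
  stopifnot(length(aa_table) == 64L)
  stop_codons <- names(aa_table)[aa_table == "*"]
  if (length(intersect(start_codons, stop_codons)) > 0L) {
    abort(sprintf("genetic code '%s' (id %d): start and stop codon sets overlap",
                  name, id))
  }
  structure(
    list(name = name, id = as.integer(id), aa_table = aa_table,
         start_codons = sort(start_codons), stop_codons = sort(stop_codons)),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> id %d: %s\n", x$id, x$name))
  cat("  starts:", paste(x$start_codons, collapse = " "), "\n")
  cat("  stops: ", paste(x$stop_codons, collapse = " "), "\n")
  invisible(x)
}

#' Parse an NCBI-format genetic code table file
#'
#' Reads the `genetic_code_table` format of the NCBI toolkit: entries carry a
#' `name`, an integer `id`, a 64-character `ncbieaa` amino-acid string and a
#' 64-character `sncbieaa` string whose `M` positions flag initiation codons.
#' Both the braced gc.prt block layout (with `-- Base1/2/3` comment rows) and
#' a simplified dialect of bare `key value` lines separated by blank lines are
#' accepted; `--` comment lines are ignored either way.
#'
#' @param text Character: contents of the file (single string or lines), or
#'   the path of an existing file.
#' @return A list of `genetic_code` objects, each with fields `name`, `id`,
#'   `aa_table` (named character of all 64 codons), `start_codons`,
#'   `stop_codons`.
#' @examples
#' path <- system.file("extdata", "genetic_code_table.txt", package = "pgmap")
#' codes <- parse_code_table(path)
#' codes[[1]]
#' @export
parse_code_table <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- lines[!grepl("^\\s*--", lines)]
  blob <- paste(lines, collapse = "\n")

  entries <- if (grepl("\\{", blob)) {
    # gc.prt block layout: entries are inner { ... } groups
    m <- gregexpr("\\{[^{}]*\\}", blob)[[1]]
    if (m[1] == -1L) character(0) else regmatches(blob, gregexpr("\\{[^{}]*\\}", blob))[[1]]
  } else {
    # simplified dialect: blank-line-separated key/value blocks
    blocks <- strsplit(blob, "\n\\s*\n")[[1]]
    blocks[nzchar(trimws(blocks))]
  }
  if (length(entries) == 0L) {
    abort("no genetic code entries found in table text")
  }

  grab <- function(entry, key, what) {
    # quoted value first, then bare token(s) up to end of line / comma
    pat_q <- sprintf("%s\\s+\"([^\"]*)\"", key)
    m <- regmatches(entry, regexec(pat_q, entry))[[1]]
    if (length(m) == 2L) return(m[2])
    pat_b <- sprintf("%s\\s+([^,\n]+)", key)
    m <- regmatches(entry, regexec(pat_b, entry))[[1]]
    if (length(m) == 2L) return(trimws(m[2]))
    abort(sprintf("malformed genetic code entry (%s): missing field '%s'",
                  what, key))
  }

  codons <- ncbi_codon_order()
  codes <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    label <- sprintf("entry %d", i)
    name <- grab(e, "name", label)
    label <- sprintf("entry %d ('%s')", i, name)
    id <- suppressWarnings(as.integer(grab(e, "\\bid", label)))
    if (is.na(id)) abort(sprintf("malformed genetic code entry (%s): bad id", label))
    ncbieaa <- grab(e, "ncbieaa", label)
    sncbieaa <- grab(e, "sncbieaa", label)
    if (nchar(ncbieaa) != 64L) {
      abort(sprintf("malformed genetic code entry (%s): ncbieaa has %d characters, expected 64",
                    label, nchar(ncbieaa)))
    }
    if (nchar(sncbieaa) != 64L) {
      abort(sprintf("malformed genetic code entry (%s): sncbieaa has %d characters, expected 64",
                    label, nchar(sncbieaa)))
    }
    aa <- strsplit(ncbieaa, "")[[1]]
    names(aa) <- codons
    starts <- codons[strsplit(sncbieaa, "")[[1]] == "M"]
    codes[[i]] <- new_genetic_code(name, id, aa, starts)
  }
  ids <- vapply(codes, `[[`, 0L, "id")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate genetic code ids in table: %s",
                  paste(ids[duplicated(ids)], collapse = ", ")))
  }
  codes
}

#' Select a genetic code by NCBI id
#'
#' @param codes List of `genetic_code` objects from [parse_code_table()].
#' @param id Integer NCBI translation table id.
#' @return The matching `genetic_code`.
#' @export
select_code <- function(codes, id) {
  if (length(codes) == 0L) abort("empty genetic code list")
  ids <- vapply(codes, `[[`, 0L, "id")
  hit <- which(ids == as.integer(id))
  if (length(hit) == 0L) {
    abort(sprintf("genetic code %s not found; available: %s",
                  id, paste(sort(ids), collapse = ", ")))
  }
  codes[[hit[1]]]
}

#' Serialize genetic codes back to the NCBI block layout
#'
#' Inverse of [parse_code_table()]; mainly used to check that parsing is
#' lossless.
#'
#' @param codes List of `genetic_code` objects.
#' @return Character vector of lines.
#' @export
format_code_table <- function(codes) {
  codons <- ncbi_codon_order()
  out <- "Genetic-code-table ::= {"
  for (code in codes) {
    sn <- ifelse(codons %in% code$start_codons, "M", "-")
    out <- c(out,
      " {",
      sprintf('  name "%s" ,', code$name),
      sprintf('  id %d ,', code$id),
      sprintf('  ncbieaa  "%s",', paste(code$aa_table[codons], collapse = "")),
      sprintf('  sncbieaa "%s"', paste(sn, collapse = "")),
      " } ,")
  }
  out[length(out)] <- " }"
  c(out, "}")
}

normalize_nt <- function(seq) {
  chartr("uU", "TT", toupper(seq))
}

#' Translate one codon
#'
#' Input is uppercased and `U` mapped to `T` before lookup. Any codon
#' containing a character outside `A/C/G/T` (ambiguity codes, gaps)
#' translates to `'X'`, which can never match a peptide residue — the tool
#' reports exact matches only.
#'
#' @param code A `genetic_code`.
#' @param codon A 3-letter nucleotide string.
#' @return Single amino-acid letter (`'*'` for stop, `'X'` for ambiguous).
#' @export
translate_codon <- function(code, codon) {
  codon <- normalize_nt(codon)
  if (nchar(codon) != 3L) {
    abort(sprintf("codon '%s' has length %d, expected 3", codon, nchar(codon)))
  }
  aa <- unname(code$aa_table[codon])
  if (is.na(aa)) "X" else aa
}

# Vectorized translation of a normalized uppercase DNA string from a given
# 0-based offset; trailing 1-2 nt are dropped. Workhorse for six-frame
# translation: one substring() call yields all codons, then a table lookup.
translate_nt <- function(code, seq, offset = 0L) {
  n <- nchar(seq)
  if (n - offset < 3L) return("")
  starts <- seq.int(offset + 1L, by = 3L, length.out = (n - offset) %/% 3L)
  aa <- code$aa_table[substring(seq, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
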