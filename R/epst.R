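# ePST generation: extend each exact peptide match into an expressed
# Protein Sequence Tag.
#
# All extension logic operates in coding-strand space: for a minus-strand
# match the record is reverse-complemented, the match coordinates are
# transformed, the extension runs identically, and the final span is mapped
# back to forward coordinates. In the codon-aware modes (prokaryotic and
# eukaryotic signal-bounded) the ePST always starts and ends on an in-frame
# codon boundary, so its length is divisible by 3 and the peptide occurs
# within its translation.

new_splice_site_set <- function(donors, acceptors, source) {
  structure(list(donors = sort(unique(as.integer(donors))),
                 acceptors = sort(unique(as.integer(acceptors))),
                 source = source),
            class = "splice_site_set")
}

#' @export
print.splice_site_set <- function(x, ...) {
  cat(sprintf("<splice_site_set> source=%s: %d donor(s), %d acceptor(s)\n",
              x$source, length(x$donors), length(x$acceptors)))
  invisible(x)
}

#' Canonical splice site signals of a sequence
#'
#' Scans one strand of a record for the canonical intron boundary
#' dinucleotides: every `GT` is a putative donor (position of its first
#' base) and every `AG` a putative acceptor (position of its second base).
#' Positions are reported in the space of the strand scanned, i.e. in
#' coding-strand coordinates when `strand = "-"` (positions on the reverse
#' complement). The scan is not frame-restricted.
#'
#' @param record A nucleotide sequence string or a one-row record tibble.
#' @param strand `"+"` (scan the sequence as given) or `"-"` (scan its
#'   reverse complement).
#' @return A `splice_site_set` with integer position vectors `donors` and
#'   `acceptors`, `source = "canonical"`.
#' @export
canonical_splice_sites <- function(record, strand = "+") {
  seq <- if (is.character(record)) record else record$seq
  seq <- normalize_nt(seq)
  if (strand == "-") seq <- reverse_complement(seq)
  gt <- gregexpr("GT", seq, fixed = TRUE)[[1]]
  ag <- gregexpr("AG", seq, fixed = TRUE)[[1]]
  donors <- if (gt[1] == -1L) integer(0) else as.integer(gt)
  acceptors <- if (ag[1] == -1L) integer(0) else as.integer(ag) + 1L
  new_splice_site_set(donors, acceptors, "canonical")
}

#' Parse GeneSplicer splice-site predictions
#'
#' Accepts the standard five-column GeneSplicer prediction output:
#' whitespace-delimited rows `end5 end3 score confidence site_type` with
#' `site_type` either `donor` or `acceptor`. Donor rows contribute
#' `min(end5, end3)`; acceptor rows contribute `max(end5, end3)` (both ends
#' are given in forward-strand coordinates, in either order). Malformed rows
#' are logged and skipped; a file with no parseable row is an error.
#'
#' @param text File path or character vector of lines.
#' @return A `splice_site_set` in forward-strand coordinates,
#'   `source = "genesplicer"`.
#' @export
parse_genesplicer <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  lines <- trimws(unlist(strsplit(text, "\n", fixed = TRUE)))
  lines <- lines[nzchar(lines)]
  donors <- integer(0); acceptors <- integer(0); n_bad <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    e5 <- suppressWarnings(as.integer(f[1]))
    e3 <- suppressWarnings(as.integer(f[2]))
    type <- if (length(f) >= 5L) tolower(f[5]) else NA_character_
    if (length(f) < 5L || is.na(e5) || is.na(e3) ||
        !type %in% c("donor", "acceptor")) {
      n_bad <- n_bad + 1L
      pg_log("warning", sprintf("skipping malformed GeneSplicer row: '%s'", ln))
      next
    }
    if (type == "donor") donors <- c(donors, min(e5, e3))
    else acceptors <- c(acceptors, max(e5, e3))
  }
  if (length(donors) + length(acceptors) == 0L) {
    abort("no parseable GeneSplicer rows found; is this the right file?")
  }
  new_splice_site_set(donors, acceptors, "genesplicer")
}

# Mirror forward-strand splice positions into reverse-complement space.
# A donor marks the first base of a 2-base signal [p, p+1]; its mirrored
# first base is L - p. An acceptor marks the last base of [a-1, a]; its
# mirrored last base is L - a + 2.
mirror_splice_sites <- function(sites, L) {
  d <- L - sites$donors
  a <- L - sites$acceptors + 2L
  new_splice_site_set(d[d >= 1L & d <= L], a[a >= 1L & a <= L], sites$source)
}

# ---- coding-strand-space primitives ------------------------------------

.coding_view <- function(strand, nt_start, nt_end, record_seq) {
  L <- nchar(record_seq)
  if (strand == "+") {
    list(cs = record_seq, L = L, s = nt_start, e = nt_end)
  } else {
    list(cs = reverse_complement(record_seq), L = L,
         s = L - nt_end + 1L, e = L - nt_start + 1L)
  }
}

.to_forward <- function(strand, L, s, e) {
  if (strand == "+") c(s, e) else c(L - e + 1L, L - s + 1L)
}

# 5'/3' in-frame stop-to-stop context around a match (stops included when
# present; truncated at the outermost complete in-frame codon otherwise).
.stop_to_stop_cs <- function(cs, L, s, e, code) {
  stops <- code$stop_codons
  q <- s - 3L; from <- ((s - 1L) %% 3L) + 1L
  while (q >= 1L) {
    if (substr(cs, q, q + 2L) %in% stops) { from <- q; break }
    q <- q - 3L
  }
  q <- e + 1L; to <- e + 3L * ((L - e) %/% 3L)
  while (q + 2L <= L) {
    if (substr(cs, q, q + 2L) %in% stops) { to <- q + 2L; break }
    q <- q + 3L
  }
  substr(cs, from, to)
}

# Prokaryotic rule: 3' to the first in-frame stop (included); 5' locate the
# first in-frame stop strictly upstream, then scan back downstream from just
# after it for the first start codon at/before the peptide start; fall back
# to the peptide start itself.
.extend_prok_cs <- function(cs, L, s, e, code) {
  stops <- code$stop_codons; starts <- code$start_codons
  q <- e + 1L; end <- e + 3L * ((L - e) %/% 3L); b3 <- "sequence_end"
  while (q + 2L <= L) {
    if (substr(cs, q, q + 2L) %in% stops) { end <- q + 2L; b3 <- "stop_codon"; break }
    q <- q + 3L
  }
  q <- s - 3L; scan_from <- ((s - 1L) %% 3L) + 1L
  while (q >= 1L) {
    if (substr(cs, q, q + 2L) %in% stops) { scan_from <- q + 3L; break }
    q <- q - 3L
  }
  st <- s; b5 <- "peptide_start"
  q <- scan_from
  while (q <= s) {
    if (substr(cs, q, q + 2L) %in% starts) { st <- q; b5 <- "start_codon"; break }
    q <- q + 3L
  }
  list(start = st, end = end, b5 = b5, b3 = b3)
}

# Eukaryotic signal-bounded rule: nearest-wins among stop codon / splice
# signal (3') and start codon / stop codon / splice signal (5'), scanning
# codon-by-codon outward from the peptide. Donor/acceptor positions are in
# coding-strand space. A 5' stop codon is not included; a 5' start codon and
# the 3' stop codon are.
.extend_euk_cs <- function(cs, L, s, e, code, donors, acceptors) {
  stops <- code$stop_codons; starts <- code$start_codons
  d <- donors[donors > e]
  d <- if (length(d)) min(d) else Inf
  a <- acceptors[acceptors < s]
  a <- if (length(a)) max(a) else -Inf

  q <- e + 1L; end <- e; b3 <- NA_character_
  repeat {
    if (q + 2L > L) { b3 <- "sequence_end"; break }
    if (d <= q + 2L) { b3 <- "splice_donor"; break }
    if (substr(cs, q, q + 2L) %in% stops) { end <- q + 2L; b3 <- "stop_codon"; break }
    end <- q + 2L
    q <- q + 3L
  }

  q <- s - 3L; st <- s; b5 <- NA_character_
  repeat {
    if (q < 1L) { b5 <- "sequence_end"; break }
    if (a >= q) { b5 <- "splice_acceptor"; break }
    cod <- substr(cs, q, q + 2L)
    if (cod %in% stops) { b5 <- "stop_codon"; break }
    if (cod %in% starts) { st <- q; b5 <- "start_codon"; break }
    st <- q
    q <- q - 3L
  }
  list(start = st, end = end, b5 = b5, b3 = b3)
}

.extend_fixed_cs <- function(L, s, e, n) {
  list(start = max(1L, s - n), end = min(L, e + n),
       b5 = if (s - n < 1L) "sequence_end" else "fixed_length",
       b3 = if (e + n > L) "sequence_end" else "fixed_length")
}

# ---- user-facing extension over a match table --------------------------

.epst_row <- function(match_row, record_seq, code, ext, mode, fixed_frame_anchor = NULL) {
  cv <- .coding_view(match_row$strand, match_row$nt_start, match_row$nt_end, record_seq)
  st <- ext$start; en <- ext$end
  nt_seq <- substr(cv$cs, st, en)
  if (mode == "fixed") {
    # translate from the first complete codon of the peptide's frame
    p <- st + (cv$s - st) %% 3L
    prot <- translate_nt(code, substr(cv$cs, p, en), 0L)
  } else {
    prot <- translate_nt(code, nt_seq, 0L)
  }
  fwd <- .to_forward(match_row$strand, cv$L, st, en)
  tibble(
    peptide_id = match_row$peptide_id,
    peptide_seq = match_row$peptide_seq,
    record_id = match_row$record_id,
    strand = match_row$strand,
    frame = match_row$frame,
    nt_start = match_row$nt_start,
    nt_end = match_row$nt_end,
    coding_nt = match_row$coding_nt,
    epst_start = as.integer(fwd[1]),
    epst_end = as.integer(fwd[2]),
    epst_nt = nt_seq,
    epst_protein = prot,
    stop_to_stop_nt = .stop_to_stop_cs(cv$cs, cv$L, cv$s, cv$e, code),
    boundary_5 = ext$b5,
    boundary_3 = ext$b3,
    mode = mode
  )
}

.empty_epst <- function() {
  tibble(peptide_id = character(), peptide_seq = character(),
         record_id = character(), strand = character(), frame = integer(),
         nt_start = integer(), nt_end = integer(), coding_nt = character(),
         epst_start = integer(), epst_end = integer(), epst_nt = character(),
         epst_protein = character(), stop_to_stop_nt = character(),
         boundary_5 = character(), boundary_3 = character(), mode = character())
}

.extend_matches <- function(matches, records, fn, mode) {
  records <- as_record_tbl(records, "nucleotide")
  if (nrow(matches) == 0L) return(.empty_epst())
  out <- vector("list", nrow(matches))
  for (i in seq_len(nrow(matches))) {
    m <- matches[i, ]
    ri <- match(m$record_id, records$id)
    if (is.na(ri)) abort(sprintf("match references unknown record '%s'", m$record_id))
    out[[i]] <- fn(m, records$seq[ri])
  }
  bind_rows(out)
}

#' Extend peptide matches into prokaryotic ePSTs
#'
#' The reverse-translated peptide is extended 3' to the first in-frame stop
#' codon, which is included in the ePST. On the 5' side, the first in-frame
#' stop upstream of the peptide is located and the ePST starts at the first
#' in-frame start codon downstream of that stop (at or before the peptide
#' start); if no start codon intervenes, the peptide start itself opens the
#' ePST. A contig end before a stop codon truncates the ePST at the last
#' complete codon (`boundary = "sequence_end"`).
#'
#' @param matches Match tibble from [map_peptides()].
#' @param records Nucleotide record tibble the matches refer to.
#' @param code A `genetic_code`.
#' @return An ePST tibble: the match columns plus `epst_start`, `epst_end`
#'   (1-based forward-strand), `epst_nt` (coding strand), `epst_protein`,
#'   `stop_to_stop_nt` (the longer 5' stop to 3' stop context),
#'   `boundary_5`, `boundary_3`, `mode`.
#' @export
extend_prokaryotic <- function(matches, records, code) {
  .extend_matches(matches, records, function(m, seq) {
    cv <- .coding_view(m$strand, m$nt_start, m$nt_end, seq)
    ext <- .extend_prok_cs(cv$cs, cv$L, cv$s, cv$e, code)
    .epst_row(m, seq, code, ext, "prokaryote")
  }, "prokaryote")
}

#' Extend peptide matches into signal-bounded eukaryotic ePSTs
#'
#' Scanning codon-by-codon outward from the peptide, the 3' boundary is the
#' first in-frame stop codon (included) or the last complete codon before
#' the first downstream splice donor, whichever comes first; the 5' boundary
#' is the nearest of an in-frame start codon (included), an in-frame stop
#' codon (excluded), or the closest upstream splice acceptor. Sequence ends
#' truncate with `boundary = "sequence_end"`.
#'
#' @inheritParams extend_prokaryotic
#' @param sites Splice-site handling: `"canonical"` (default; every `GT` /
#'   `AG` dinucleotide on the coding strand), `"none"` (ignore splice
#'   signals), or a `splice_site_set` from [parse_genesplicer()] holding
#'   forward-strand positions, which are mirrored into coding-strand space
#'   for minus-strand matches.
#' @return An ePST tibble (see [extend_prokaryotic()]).
#' @export
extend_eukaryotic_signal <- function(matches, records, code, sites = "canonical") {
  records <- as_record_tbl(records, "nucleotide")
  site_cache <- new.env(parent = emptyenv())
  get_sites <- function(record_id, strand, seq) {
    key <- paste0(record_id, strand)
    if (!is.null(site_cache[[key]])) return(site_cache[[key]])
    ss <- if (inherits(sites, "splice_site_set")) {
      if (strand == "+") sites else mirror_splice_sites(sites, nchar(seq))
    } else if (identical(sites, "none")) {
      new_splice_site_set(integer(0), integer(0), "none")
    } else if (identical(sites, "canonical")) {
      canonical_splice_sites(seq, strand)
    } else {
      abort("`sites` must be \"canonical\", \"none\", or a splice_site_set")
    }
    site_cache[[key]] <- ss
    ss
  }
  .extend_matches(matches, records, function(m, seq) {
    cv <- .coding_view(m$strand, m$nt_start, m$nt_end, seq)
    ss <- get_sites(m$record_id, m$strand, seq)
    ext <- .extend_euk_cs(cv$cs, cv$L, cv$s, cv$e, code, ss$donors, ss$acceptors)
    .epst_row(m, seq, code, ext, "eukaryote_signal")
  }, "eukaryote_signal")
}

#' Extend peptide matches by a fixed nucleotide length
#'
#' Each match span grows by `n_nt` nucleotides on both sides, clamped at the
#' record ends (clamped sides are flagged `sequence_end`). No codon-boundary
#' guarantee is made; `epst_protein` is translated from the first complete
#' codon of the peptide's frame inside the span. A codon count can be passed
#' as `3 * n_codons`.
#'
#' @inheritParams extend_prokaryotic
#' @param n_nt Non-negative integer extension in nucleotides; `n_nt = 0`
#'   returns exactly the reverse-translated peptide span.
#' @return An ePST tibble (see [extend_prokaryotic()]).
#' @export
extend_fixed <- function(matches, records, code, n_nt) {
  n_nt <- as.integer(n_nt)
  if (is.na(n_nt) || n_nt < 0L) abort("`n_nt` must be a non-negative integer")
  .extend_matches(matches, records, function(m, seq) {
    cv <- .coding_view(m$strand, m$nt_start, m$nt_end, seq)
    ext <- .extend_fixed_cs(cv$L, cv$s, cv$e, n_nt)
    .epst_row(m, seq, code, ext, "fixed")
  }, "fixed")
}
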