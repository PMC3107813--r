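# Six-frame translation and exact peptide-to-genome mapping.
#
# Coordinate conventions (documented because downstream frame labels depend
# on them):
#   * all emitted nucleotide coordinates are 1-based, inclusive, on the
#     forward strand;
#   * frame +k translates the forward sequence from 0-based offset k-1;
#   * frame -k translates the reverse complement from 0-based offset k-1;
#   * a span [s, e] on the reverse complement of a record of length L maps
#     to forward coordinates [L - e + 1, L - s + 1].

.iupac_fwd <- "ACGTRYSWKMBDHVN"
.iupac_rev <- "TGCAYRSWMKVHDBN"

#' Reverse complement of a DNA string
#'
#' Complements all IUPAC nucleotide letters (N stays N, R pairs with Y, ...)
#' and reverses. Input is normalized (uppercase, U to T) first.
#'
#' @param seq A DNA string.
#' @return The reverse complement.
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_nt(seq)
  bad <- regexpr(sprintf("[^%s]", .iupac_fwd), seq)
  if (bad != -1L) {
    abort(sprintf("unknown nucleotide character '%s' at position %d",
                  substr(seq, bad, bad), bad))
  }
  stringi::stri_reverse(chartr(.iupac_fwd, .iupac_rev, seq))
}

.frame_order <- c(1L, 2L, 3L, -1L, -2L, -3L)

#' Translate a nucleotide record in all six reading frames
#'
#' @param records Tibble of nucleotide records (`id`, `desc`, `seq`) as read
#'   by [read_nucleotide_fasta()]; a single named/plain character vector is
#'   also accepted.
#' @param code A `genetic_code`.
#' @return Tibble with one row per record x frame (frame order
#'   +1, +2, +3, -1, -2, -3): `record_id`, `frame` (signed integer), `strand`,
#'   `offset` (0-2, into the strand being read), `protein` (may contain `'*'`
#'   and `'X'`), `source_length`. Records shorter than 3 nt in a frame give an
#'   empty protein.
#' @export
translate_frames <- function(records, code) {
  records <- as_record_tbl(records, "nucleotide")
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    fwd <- records$seq[i]
    rev <- reverse_complement(fwd)
    L <- nchar(fwd)
    prot <- character(6L)
    for (k in 0:2) {
      prot[k + 1L] <- translate_nt(code, fwd, k)
      prot[k + 4L] <- translate_nt(code, rev, k)
    }
    if (all(!nzchar(prot))) {
      pg_log("debug", sprintf("record '%s' is shorter than one codon in every frame",
                              records$id[i]))
    }
    out[[i]] <- tibble(
      record_id = records$id[i],
      frame = .frame_order,
      strand = rep(c("+", "-"), each = 3L),
      offset = rep(0:2, 2L),
      protein = prot[c(1:3, 4:6)],
      source_length = L
    )
  }
  bind_rows(out)
}

#' Map a protein-coordinate span back to forward genome coordinates
#'
#' @param frame One row of [translate_frames()] output (or a list with
#'   `strand`, `offset`, `source_length`, `protein`).
#' @param prot_start 0-based index of the first residue of the span.
#' @param prot_len Number of residues.
#' @return Named list `nt_start`, `nt_end` (1-based inclusive, forward
#'   strand), `strand`.
#' @export
protein_to_genome_span <- function(frame, prot_start, prot_len) {
  plen <- nchar(frame$protein)
  if (prot_start < 0L || prot_len < 0L || prot_start + prot_len > plen) {
    abort(sprintf("protein span [%d, %d) out of range for frame of length %d",
                  prot_start, prot_start + prot_len, plen))
  }
  s <- frame$offset + 3L * prot_start + 1L
  e <- s + 3L * prot_len - 1L
  if (frame$strand == "-") {
    L <- frame$source_length
    tmp <- L - e + 1L
    e <- L - s + 1L
    s <- tmp
  }
  list(nt_start = as.integer(s), nt_end = as.integer(e), strand = frame$strand)
}

.valid_aa <- "ACDEFGHIKLMNPQRSTVWY"

# Split peptides into usable and skipped, with reasons.
validate_peptides <- function(peptides) {
  peptides <- as_record_tbl(peptides, "peptide")
  pat <- sprintf("[^%s]", .valid_aa)
  bad_at <- regexpr(pat, peptides$seq)
  reason <- ifelse(
    bad_at != -1L,
    sprintf("invalid amino-acid letter '%s' at position %d",
            substr(peptides$seq, bad_at, bad_at), bad_at),
    NA_character_
  )
  reason[!nzchar(peptides$seq)] <- "empty sequence"
  skipped <- tibble(peptide_id = peptides$id[!is.na(reason)],
                    reason = reason[!is.na(reason)])
  if (nrow(skipped) > 0L) {
    for (j in seq_len(nrow(skipped))) {
      pg_log("warning", sprintf("skipping peptide '%s': %s",
                                skipped$peptide_id[j], skipped$reason[j]))
    }
    warn(sprintf("%d peptide(s) skipped (invalid sequence); see attr(, 'skipped')",
                 nrow(skipped)))
  }
  list(ok = peptides[is.na(reason), , drop = FALSE], skipped = skipped)
}

#' Map peptides exactly onto nucleotide records in all six frames
#'
#' Builds one Aho-Corasick automaton over the peptide set and scans the six
#' frame translations of every record. Matching is exact at the residue
#' level (no I/L folding); case is normalized at ingest. Peptides containing
#' letters outside the 20 standard amino acids are skipped with a warning
#' and listed in the `skipped` attribute, not an error.
#'
#' @param peptides Peptide records (`id`, `desc`, `seq` tibble, or named
#'   character vector).
#' @param records Nucleotide records (`id`, `desc`, `seq` tibble).
#' @param code A `genetic_code`.
#' @return Tibble with one row per exact occurrence: `peptide_id`,
#'   `peptide_seq`, `record_id`, `strand`, `frame`, `nt_start`, `nt_end`
#'   (1-based inclusive forward-strand coordinates of the reverse-translated
#'   peptide), `coding_nt` (nucleotides on the coding strand; its translation
#'   equals `peptide_seq`). Rows are ordered by record, then frame
#'   (+1, +2, +3, -1, -2, -3), then position along the frame. Attribute
#'   `skipped` is a tibble of rejected peptides and reasons.
#' @examples
#' code <- select_code(parse_code_table(
#'   system.file("extdata", "genetic_code_table.txt", package = "pgmap")), 1)
#' recs <- tibble::tibble(id = "r1", desc = "r1", seq = "ATGAAACCCTGA")
#' map_peptides(c(kp = "KP"), recs, code)
#' @export
map_peptides <- function(peptides, records, code) {
  records <- as_record_tbl(records, "nucleotide")
  val <- validate_peptides(peptides)
  empty <- tibble(peptide_id = character(), peptide_seq = character(),
                  record_id = character(), strand = character(),
                  frame = integer(), nt_start = integer(), nt_end = integer(),
                  coding_nt = character())
  if (nrow(val$ok) == 0L) {
    attr(empty, "skipped") <- val$skipped
    return(empty)
  }
  aut <- build_automaton(tibble(id = val$ok$id, pattern = val$ok$seq))

  frames <- translate_frames(records, code)
  out <- vector("list", nrow(frames))
  for (i in seq_len(nrow(frames))) {
    fr <- frames[i, ]
    if (!nzchar(fr$protein)) next
    hits <- find_matches(aut, fr$protein)
    if (nrow(hits) == 0L) next
    hits <- hits[order(hits$start, hits$keyword_id), ]
    plen <- hits$end - hits$start
    cs_start <- fr$offset + 3L * hits$start + 1L
    cs_end <- cs_start + 3L * plen - 1L
    rec_seq <- records$seq[match(fr$record_id, records$id)]
    coding <- if (fr$strand == "+") rec_seq else reverse_complement(rec_seq)
    if (fr$strand == "+") {
      nt_start <- cs_start; nt_end <- cs_end
    } else {
      nt_start <- fr$source_length - cs_end + 1L
      nt_end <- fr$source_length - cs_start + 1L
    }
    out[[i]] <- tibble(
      peptide_id = hits$keyword_id,
      peptide_seq = substring(fr$protein, hits$start + 1L, hits$end),
      record_id = fr$record_id,
      strand = fr$strand,
      frame = fr$frame,
      nt_start = as.integer(nt_start),
      nt_end = as.integer(nt_end),
      coding_nt = substring(coding, cs_start, cs_end)
    )
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) res <- empty
  attr(res, "skipped") <- val$skipped
  res
}
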