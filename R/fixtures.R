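# Synthetic fixture generator: genomes with peptides planted inside ORFs
# whose boundaries are known by construction, so end-to-end runs can be
# checked against an exact truth table.
#
# Construction guarantees (per cassette, in coding orientation):
#   prokaryote: [stop][filler, no stop/start][ATG][filler, no stop/start]
#               [peptide codons][filler, no stop][stop]
#     -> expected ePST runs from the ATG through the 3' stop.
#   eukaryote:  [AG][C/T-only filler codons][peptide codons]
#               [C/T-only filler codons, first starts with C][GT]
#     C/T-only fillers can contain no stop codon, no start codon, and no
#     GT/AG dinucleotide (junctions included), so the planted signals are
#     the nearest donor/acceptor and the expected ePST is exactly the
#     filler-bounded span.
# The genome background is rejection-sampled: a draw is discarded unless
# every peptide occurs exactly once across all six frame translations.

.sample_filler <- function(code, n, exclude_starts = TRUE) {
  pool <- ncbi_codon_order()
  pool <- pool[!pool %in% code$stop_codons]
  if (exclude_starts) pool <- pool[!pool %in% code$start_codons]
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

.ct_codons <- function() {
  # all codons over {C,T}: never a stop/start, never contain A or G
  as.vector(outer(outer(c("C", "T"), c("C", "T"), paste0), c("C", "T"), paste0))
}

.reverse_translate <- function(code, peptide) {
  by_aa <- split(names(code$aa_table), unname(code$aa_table))
  paste(vapply(strsplit(peptide, "")[[1]],
               function(a) sample(by_aa[[a]], 1L), ""), collapse = "")
}

.sample_peptide_set <- function(n, len_range) {
  repeat {
    peps <- vapply(seq_len(n), function(i) {
      paste(sample(strsplit(.valid_aa, "")[[1]],
                   sample(len_range[1]:len_range[2], 1L), replace = TRUE),
            collapse = "")
    }, "")
    # distinct, and no peptide a substring of another
    if (anyDuplicated(peps)) next
    nested <- any(vapply(seq_len(n), function(i) {
      any(vapply(seq_len(n)[-i], function(j) grepl(peps[i], peps[j], fixed = TRUE),
                 TRUE))
    }, TRUE))
    if (!nested) return(peps)
  }
}

.build_cassette <- function(code, peptide, mode) {
  pep_nt <- .reverse_translate(code, peptide)
  if (mode == "prokaryote") {
    s5 <- sample(code$stop_codons, 1L)
    s3 <- sample(code$stop_codons, 1L)
    j1 <- .sample_filler(code, sample(2:5, 1L))
    j2 <- .sample_filler(code, sample(1:4, 1L))
    j3 <- .sample_filler(code, sample(1:4, 1L), exclude_starts = FALSE)
    seq <- paste0(s5, j1, "ATG", j2, pep_nt, j3, s3)
    atg_at <- 3L + nchar(j1) + 1L
    pep_at <- atg_at + 3L + nchar(j2)
    list(seq = seq,
         pep_rel = c(pep_at, pep_at + nchar(pep_nt) - 1L),
         epst_rel = c(atg_at, nchar(seq)),
         boundary_5 = "start_codon", boundary_3 = "stop_codon")
  } else {
    ct <- .ct_codons()
    k1 <- sample(1:4, 1L); k2 <- sample(1:4, 1L)
    f1 <- paste(sample(ct, k1, replace = TRUE), collapse = "")
    f2 <- paste(c(sample(grep("^C", ct, value = TRUE), 1L),
                  if (k2 > 1L) sample(ct, k2 - 1L, replace = TRUE)),
                collapse = "")
    seq <- paste0("AG", f1, pep_nt, f2, "GT")
    pep_at <- 2L + nchar(f1) + 1L
    list(seq = seq,
         pep_rel = c(pep_at, pep_at + nchar(pep_nt) - 1L),
         epst_rel = c(3L, 2L + nchar(f1) + nchar(pep_nt) + nchar(f2)),
         boundary_5 = "splice_acceptor", boundary_3 = "splice_donor")
  }
}

#' Generate a synthetic genome with planted, truth-tagged peptides
#'
#' Builds a single-record genome in which each peptide's reverse translation
#' sits inside a planted ORF (prokaryote mode: known 5' stop, start codon
#' and 3' stop) or between planted GT/AG splice signals (eukaryote mode), on
#' a random strand and frame. The background is rejection-sampled so that no
#' peptide occurs anywhere outside its planted site in any reading frame.
#' The returned truth table states, for every peptide, the expected match
#' coordinates, strand, frame, and ePST boundaries - an oracle by
#' construction for the mapper and the extension rules.
#'
#' @param n_peptides Number of peptides to plant.
#' @param genome_length Total genome length in nucleotides; must leave room
#'   for all cassettes.
#' @param mode `"prokaryote"` or `"eukaryote"` cassette layout.
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @param dir If non-`NULL`, write `genome.fasta`, `peptides.fasta` and
#'   `truth.tsv` into this directory.
#' @param code A `genetic_code`; the bundled standard code when `NULL`.
#' @param peptide_len Length range for sampled peptides.
#' @return List with tibbles `genome`, `peptides` (record tables), `truth`
#'   (peptide_id, peptide_seq, strand, frame, nt_start, nt_end, epst_start,
#'   epst_end, boundary_5, boundary_3), and `paths` (when `dir` is given).
#' @export
generate_fixture <- function(n_peptides, genome_length,
                             mode = c("prokaryote", "eukaryote"),
                             seed = 1L, dir = NULL, code = NULL,
                             peptide_len = c(7L, 15L)) {
  mode <- match.arg(mode)
  n_peptides <- as.integer(n_peptides)
  genome_length <- as.integer(genome_length)
  if (is.null(code)) {
    code <- select_code(parse_code_table(
      system.file("extdata", "genetic_code_table.txt", package = "pgmap")), 1L)
  }
  withr::with_seed(as.integer(seed), {
    for (attempt in 1:25) {
      peps <- .sample_peptide_set(n_peptides, peptide_len)
      cassettes <- lapply(peps, function(p) .build_cassette(code, p, mode))
      strands <- ifelse(runif(n_peptides) < 0.5, "+", "-")
      lens <- vapply(cassettes, function(x) nchar(x$seq), 0L)
      slack <- genome_length - sum(lens)
      if (slack < n_peptides + 1L) {
        abort(sprintf(
          "infeasible packing: %d nt of cassettes + %d gaps exceed genome_length %d",
          sum(lens), n_peptides + 1L, genome_length))
      }
      # n+1 gaps of >=1 nt summing to slack
      cuts <- sort(sample(slack - 1L, n_peptides))
      gaps <- diff(c(0L, cuts, slack))
      bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
      pieces <- character(2L * n_peptides + 1L)
      pos <- integer(n_peptides)  # forward start of each cassette
      cursor <- 0L
      for (i in seq_len(n_peptides)) {
        pieces[2L * i - 1L] <- bg(gaps[i])
        cursor <- cursor + gaps[i]
        pos[i] <- cursor + 1L
        pieces[2L * i] <- if (strands[i] == "+") cassettes[[i]]$seq
                          else reverse_complement(cassettes[[i]]$seq)
        cursor <- cursor + lens[i]
      }
      pieces[2L * n_peptides + 1L] <- bg(gaps[n_peptides + 1L])
      genome_seq <- paste(pieces, collapse = "")
      stopifnot(nchar(genome_seq) == genome_length)

      # truth coordinates on the forward strand
      rel_to_fwd <- function(i, rel) {
        if (strands[i] == "+") {
          c(pos[i] - 1L + rel[1], pos[i] - 1L + rel[2])
        } else {
          c(pos[i] - 1L + lens[i] - rel[2] + 1L,
            pos[i] - 1L + lens[i] - rel[1] + 1L)
        }
      }
      L <- genome_length
      truth <- lapply(seq_len(n_peptides), function(i) {
        ca <- cassettes[[i]]
        pep_fwd <- rel_to_fwd(i, ca$pep_rel)
        epst_fwd <- rel_to_fwd(i, ca$epst_rel)
        frame <- if (strands[i] == "+") ((pep_fwd[1] - 1L) %% 3L) + 1L
                 else -(((L - pep_fwd[2]) %% 3L) + 1L)
        tibble(peptide_id = sprintf("pep%03d", i), peptide_seq = peps[i],
               record_id = "fixture_genome", strand = strands[i],
               frame = frame,
               nt_start = pep_fwd[1], nt_end = pep_fwd[2],
               epst_start = epst_fwd[1], epst_end = epst_fwd[2],
               boundary_5 = ca$boundary_5, boundary_3 = ca$boundary_3)
      })
      truth <- bind_rows(truth)

      # rejection step: every peptide exactly once over all six frames
      aut <- build_automaton(tibble(id = truth$peptide_id, pattern = peps))
      frames <- translate_frames(
        tibble(id = "fixture_genome", desc = "fixture_genome", seq = genome_seq),
        code)
      counts <- integer(n_peptides); names(counts) <- truth$peptide_id
      for (k in seq_len(nrow(frames))) {
        h <- find_matches(aut, frames$protein[k])
        if (nrow(h) > 0L) {
          tb <- table(h$keyword_id)
          counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
        }
      }
      if (all(counts == 1L)) break
      pg_log("debug", sprintf(
        "fixture attempt %d rejected (spurious or missing occurrences)", attempt))
      if (attempt == 25L) {
        abort("could not generate a clean fixture in 25 attempts; increase genome_length")
      }
    }

    genome <- tibble(id = "fixture_genome",
                     desc = sprintf("fixture_genome synthetic %s fixture (seed %d)",
                                    mode, as.integer(seed)),
                     seq = genome_seq)
    peptides <- tibble(id = truth$peptide_id, desc = truth$peptide_id,
                       seq = truth$peptide_seq)
    paths <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(genome = file.path(dir, "genome.fasta"),
                    peptides = file.path(dir, "peptides.fasta"),
                    truth = file.path(dir, "truth.tsv"))
      gset <- Biostrings::BStringSet(genome$seq); names(gset) <- genome$desc
      Biostrings::writeXStringSet(gset, paths$genome, width = 60L)
      pset <- Biostrings::BStringSet(peptides$seq); names(pset) <- peptides$id
      Biostrings::writeXStringSet(pset, paths$peptides, width = 60L)
      readr::write_tsv(truth, paths$truth, progress = FALSE)
    }
    list(genome = genome, peptides = peptides, truth = truth, paths = paths)
  })
}
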