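pep_kp_match <- function(record_seq, std = std_code()) {
  recs <- tibble::tibble(id = "r", desc = "r", seq = record_seq)
  list(m = map_peptides(c(kp = "KP"), recs, std), recs = recs)
}

test_that("prokaryotic extension finds 5' stop, start codon and 3' stop", {
  std <- std_code()
  x <- pep_kp_match("TAAATGAAACCCTGA")  # TAA | ATG AAA CCC TGA, KP at 7-12
  expect_identical(c(x$m$nt_start, x$m$nt_end), c(7L, 12L))
  ep <- extend_prokaryotic(x$m, x$recs, std)
  expect_identical(c(ep$epst_start, ep$epst_end), c(4L, 15L))
  expect_identical(ep$epst_nt, "ATGAAACCCTGA")
  expect_identical(ep$epst_protein, "MKP*")
  expect_identical(ep$boundary_5, "start_codon")
  expect_identical(ep$boundary_3, "stop_codon")

  # no start codon between the 5' stop and the peptide: peptide start used
  x <- pep_kp_match("TAAAAACCCTGA")  # KP at 4-9
  ep <- extend_prokaryotic(x$m, x$recs, std)
  expect_identical(c(ep$epst_start, ep$epst_end), c(4L, 12L))
  expect_identical(ep$boundary_5, "peptide_start")

  # no downstream stop: truncate at the last complete codon
  x <- pep_kp_match("ATGAAACCC")
  ep <- extend_prokaryotic(x$m, x$recs, std)
  expect_identical(c(ep$epst_start, ep$epst_end), c(1L, 9L))
  expect_identical(ep$boundary_5, "start_codon")
  expect_identical(ep$boundary_3, "sequence_end")
})

test_that("prokaryotic extension is strand-invariant", {
  std <- std_code()
  fwd <- "TAAATGAAACCCTGA"
  x <- pep_kp_match(fwd)
  ep_f <- extend_prokaryotic(x$m, x$recs, std)
  y <- pep_kp_match(reverse_complement(fwd))
  ep_r <- extend_prokaryotic(y$m, y$recs, std)
  L <- nchar(fwd)
  expect_identical(ep_r$strand, "-")
  expect_identical(ep_r$epst_start, L - ep_f$epst_end + 1L)
  expect_identical(ep_r$epst_end, L - ep_f$epst_start + 1L)
  expect_identical(ep_r$epst_nt, ep_f$epst_nt)        # coding strand
  expect_identical(ep_r$epst_protein, ep_f$epst_protein)
})

test_that("canonical splice site scan finds every GT and AG dinucleotide", {
  ss <- canonical_splice_sites("AAGTAA")
  expect_identical(ss$donors, 3L)      # GT at 3-4
  expect_identical(ss$acceptors, 3L)   # AG at 2-3, acceptor = second base
  ss <- canonical_splice_sites("CCCCCC")
  expect_length(ss$donors, 0L)
  expect_length(ss$acceptors, 0L)
  withr::local_seed(21L)
  for (i in 1:10) {
    s <- random_dna(300)
    ss <- canonical_splice_sites(s)
    naive_gt <- sum(substring(s, 1:299, 2:300) == "GT")
    naive_ag <- sum(substring(s, 1:299, 2:300) == "AG")
    expect_length(ss$donors, naive_gt)
    expect_length(ss$acceptors, naive_ag)
  }
  # minus strand: sites of the reverse complement
  ss <- canonical_splice_sites("AAGTAA", strand = "-")
  rc <- reverse_complement("AAGTAA")  # TTACTT
  expect_identical(ss$donors, canonical_splice_sites(rc)$donors)
})

test_that("GeneSplicer predictions parse with donor/acceptor column mapping", {
  ss <- parse_genesplicer(c("202 203 11.3 High donor",
                            "115 114 7.1 Medium acceptor",
                            "not a data row"))
  expect_identical(ss$donors, 202L)
  expect_identical(ss$acceptors, 115L)
  expect_identical(ss$source, "genesplicer")
  expect_error(parse_genesplicer("junk only"), "no parseable")
})

test_that("eukaryotic signal extension stops at stops, starts and splice signals", {
  std <- std_code()
  # with no splice sites in range the 5' scan reaches the in-frame ATG
  x <- pep_kp_match("TAAATGAAACCCTGA")
  ep <- extend_eukaryotic_signal(x$m, x$recs, std, sites = "none")
  expect_identical(c(ep$epst_start, ep$epst_end), c(4L, 15L))
  expect_identical(ep$boundary_5, "start_codon")
  expect_identical(ep$boundary_3, "stop_codon")

  # a 5' stop codon bounds the ePST without being included
  x <- pep_kp_match("TAACCCAAACCCTGA")  # KP at 7-12, CCC between stop and pep
  ep <- extend_eukaryotic_signal(x$m, x$recs, std, sites = "none")
  expect_identical(c(ep$epst_start, ep$epst_end), c(4L, 15L))
  expect_identical(ep$boundary_5, "stop_codon")

  # planted donor before any in-frame stop: end at last codon before the GT
  # r = TAC CCC AAACCC AAA GTC: KP at 7-12, donor GT at 16
  x <- pep_kp_match("TACCCCAAACCCAAAGTC")
  sites <- parse_genesplicer("16 17 9.9 High donor")
  ep <- extend_eukaryotic_signal(x$m, x$recs, std, sites = sites)
  expect_identical(ep$boundary_3, "splice_donor")
  expect_identical(ep$epst_end, 15L)

  # planted acceptor inside the 5' scan range before any start/stop codon
  sites <- parse_genesplicer("4 5 9.9 High acceptor")
  ep <- extend_eukaryotic_signal(x$m, x$recs, std, sites = sites)
  expect_identical(ep$boundary_5, "splice_acceptor")
  expect_identical(ep$epst_start, 7L)

  # canonical mode on the same record: the GT at 16 is a donor, and with no
  # upstream AG/start/stop the 5' scan runs off the record start
  ep <- extend_eukaryotic_signal(x$m, x$recs, std, sites = "canonical")
  expect_identical(ep$boundary_3, "splice_donor")
  expect_identical(ep$epst_end, 15L)
  expect_identical(ep$boundary_5, "sequence_end")
  expect_identical(ep$epst_start, 1L)
})

test_that("fixed-length extension clamps at record ends and keeps the frame", {
  std <- std_code()
  x <- pep_kp_match("TAAATGAAACCCTGA")  # KP at 7-12, L = 15
  ep0 <- extend_fixed(x$m, x$recs, std, 0L)
  expect_identical(c(ep0$epst_start, ep0$epst_end), c(7L, 12L))
  expect_identical(ep0$epst_nt, x$m$coding_nt)
  expect_identical(ep0$epst_protein, "KP")
  expect_identical(unique(c(ep0$boundary_5, ep0$boundary_3)), "fixed_length")

  ep3 <- extend_fixed(x$m, x$recs, std, 3L)
  expect_identical(c(ep3$epst_start, ep3$epst_end), c(4L, 15L))

  epbig <- extend_fixed(x$m, x$recs, std, 100L)
  expect_identical(c(epbig$epst_start, epbig$epst_end), c(1L, 15L))
  expect_identical(unique(c(epbig$boundary_5, epbig$boundary_3)), "sequence_end")
  # translation still starts at the peptide's frame within the span
  expect_match(epbig$epst_protein, "KP", fixed = TRUE)

  expect_error(extend_fixed(x$m, x$recs, std, -1L), "non-negative")
})

test_that("codon-aware ePSTs keep frame, contain the peptide and end at one stop", {
  std <- std_code()
  withr::local_seed(77L)
  fx <- generate_fixture(6, 3500, mode = "prokaryote", seed = 19L)
  m <- map_peptides(fx$peptides, fx$genome, std)
  for (ep_tbl in list(extend_prokaryotic(m, fx$genome, std),
                      extend_eukaryotic_signal(m, fx$genome, std, "none"))) {
    expect_identical(nrow(ep_tbl), nrow(m))
    expect_true(all(nchar(ep_tbl$epst_nt) %% 3L == 0L))
    expect_true(all(ep_tbl$epst_start <= ep_tbl$nt_start))
    expect_true(all(ep_tbl$epst_end >= ep_tbl$nt_end))
    # peptide always found in the six-frame translation of its own ePST
    for (j in seq_len(nrow(ep_tbl))) {
      fr <- translate_frames(c(e = ep_tbl$epst_nt[j]), std)
      expect_true(any(vapply(fr$protein, grepl, TRUE,
                             pattern = ep_tbl$peptide_seq[j], fixed = TRUE)))
      n_stops <- lengths(regmatches(ep_tbl$epst_protein[j],
                                    gregexpr("*", ep_tbl$epst_protein[j],
                                             fixed = TRUE)))
      if (ep_tbl$boundary_3[j] == "stop_codon") {
        expect_identical(n_stops, 1L)
        expect_match(ep_tbl$epst_protein[j], "\\*$")
      } else {
        expect_identical(n_stops, 0L)
      }
      if (ep_tbl$boundary_5[j] == "start_codon") {
        expect_true(substr(ep_tbl$epst_nt[j], 1, 3) %in% std$start_codons)
      }
    }
  }
})

test_that("generator-planted ORF boundaries are recovered exactly", {
  std <- std_code()
  for (spec in list(list(mode = "prokaryote", seed = 5L),
                    list(mode = "eukaryote", seed = 6L))) {
    fx <- generate_fixture(8, 4500, mode = spec$mode, seed = spec$seed)
    m <- map_peptides(fx$peptides, fx$genome, std)
    ep <- if (spec$mode == "prokaryote") extend_prokaryotic(m, fx$genome, std)
          else extend_eukaryotic_signal(m, fx$genome, std, "canonical")
    cmp <- dplyr::left_join(fx$truth, ep, by = "peptide_id",
                            suffix = c(".want", ".got"))
    expect_identical(cmp$nt_start.got, cmp$nt_start.want)
    expect_identical(cmp$nt_end.got, cmp$nt_end.want)
    expect_identical(cmp$strand.got, cmp$strand.want)
    expect_identical(cmp$frame.got, cmp$frame.want)
    expect_identical(cmp$epst_start.got, cmp$epst_start.want)
    expect_identical(cmp$epst_end.got, cmp$epst_end.want)
    expect_identical(cmp$boundary_5.got, cmp$boundary_5.want)
    expect_identical(cmp$boundary_3.got, cmp$boundary_3.want)
  }
})
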