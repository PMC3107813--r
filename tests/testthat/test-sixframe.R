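test_that("reverse complement handles IUPAC letters and is an involution", {
  expect_identical(reverse_complement("ATGC"), "GCAT")
  expect_identical(reverse_complement("AANN"), "NNTT")
  expect_identical(reverse_complement("augc"), "GCAT")  # normalized first
  expect_error(reverse_complement("ATQC"), "'Q' at position 3")
  withr::local_seed(11L)
  for (i in 1:20) {
    s <- random_dna(sample(1:200, 1L))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("six-frame translation follows the +1..+3/-1..-3 offset convention", {
  std <- std_code()
  fr <- translate_frames(c(r = "ATGAAACCCTGA"), std)
  expect_identical(nrow(fr), 6L)
  expect_identical(fr$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
  expect_identical(fr$protein[fr$frame == 1L], "MKP*")
  # frame -1 translates the reverse complement TCAGGGTTTCAT from offset 0
  expect_identical(fr$protein[fr$frame == -1L], "SGFH")
  expect_identical(fr$protein[fr$frame == 2L], "*NP")   # TGAAACCCT -> offset 1
  expect_true(all(nchar(fr$protein) ==
                    (fr$source_length - fr$offset) %/% 3L))

  short <- translate_frames(c(s = "ATGAA"), std)
  expect_identical(short$protein[short$frame == 1L], "M")  # trailing AA dropped
  expect_identical(short$protein[short$frame == 3L], "E")  # GAA
  shorter <- translate_frames(c(s = "ATGA"), std)
  expect_identical(shorter$protein[shorter$frame == 3L], "")  # < 1 codon left
})

test_that("protein spans map back to forward genome coordinates", {
  std <- std_code()
  fr <- translate_frames(c(r = "ATGAAACCCTGA"), std)
  f1 <- fr[fr$frame == 1L, ]
  expect_identical(protein_to_genome_span(f1, 1L, 2L),
                   list(nt_start = 4L, nt_end = 9L, strand = "+"))
  f2 <- fr[fr$frame == 2L, ]
  expect_identical(protein_to_genome_span(f2, 0L, 1L),
                   list(nt_start = 2L, nt_end = 4L, strand = "+"))
  fm1 <- fr[fr$frame == -1L, ]
  sp <- protein_to_genome_span(fm1, 1L, 2L)
  expect_identical(sp, list(nt_start = 4L, nt_end = 9L, strand = "-"))
  # verify by translating the reverse complement of that forward slice
  slice <- substr("ATGAAACCCTGA", sp$nt_start, sp$nt_end)
  expect_identical(translate_frames(c(x = reverse_complement(slice)), std)$protein[1],
                   substr(fm1$protein, 2, 3))
  expect_error(protein_to_genome_span(f1, 3L, 2L), "out of range")
})

test_that("peptides map with correct strand, frame, coordinates and coding slice", {
  std <- std_code()
  m <- map_peptides(c(kp = "KP"), c(r = "ATGAAACCCTGA"), std)
  expect_identical(nrow(m), 1L)
  expect_identical(m$frame, 1L)
  expect_identical(m$strand, "+")
  expect_identical(c(m$nt_start, m$nt_end), c(4L, 9L))
  expect_identical(m$coding_nt, "AAACCC")

  # same peptide on the reverse complement record: frame -1, mirrored coords
  m2 <- map_peptides(c(kp = "KP"), c(r = "TCAGGGTTTCAT"), std)
  expect_identical(nrow(m2), 1L)
  expect_identical(m2$frame, -1L)
  expect_identical(m2$strand, "-")
  expect_identical(c(m2$nt_start, m2$nt_end), c(4L, 9L))
  expect_identical(m2$coding_nt, "AAACCC")
})

test_that("invalid peptides are skipped with a warning, not an error", {
  std <- std_code()
  peps <- tibble::tibble(id = c("ok", "badX", "badstar"),
                         desc = c("ok", "badX", "badstar"),
                         seq = c("KP", "KBP", "K*P"))
  expect_warning(m <- map_peptides(peps, c(r = "ATGAAACCCTGA"), std),
                 "skipped")
  expect_identical(unique(m$peptide_id), "ok")
  sk <- attr(m, "skipped")
  expect_setequal(sk$peptide_id, c("badX", "badstar"))
  expect_match(sk$reason[sk$peptide_id == "badX"], "position 2")
})

test_that("every emitted match translates back to its peptide (self-consistency)", {
  std <- std_code()
  withr::local_seed(202L)
  for (rep in 1:15) {
    seq <- random_dna(sample(300:900, 1L))
    recs <- tibble::tibble(id = "r", desc = "r", seq = seq)
    fr <- translate_frames(recs, std)
    # sample peptides from the record's own translations: guaranteed hits
    peps <- character(0)
    for (i in seq_len(nrow(fr))) {
      prot <- gsub("[*X]", "#", fr$protein[i])
      segs <- strsplit(prot, "#", fixed = TRUE)[[1]]
      segs <- segs[nchar(segs) >= 6L]
      if (length(segs)) {
        s <- segs[sample(length(segs), 1L)]
        at <- sample(nchar(s) - 5L, 1L)
        peps <- c(peps, substr(s, at, at + 5L))
      }
    }
    peps <- unique(peps)
    if (length(peps) == 0L) next
    names(peps) <- sprintf("p%d", seq_along(peps))
    m <- map_peptides(peps, recs, std)
    expect_gte(nrow(m), length(peps))
    for (j in seq_len(nrow(m))) {
      slice <- substr(seq, m$nt_start[j], m$nt_end[j])
      if (m$strand[j] == "-") slice <- reverse_complement(slice)
      expect_identical(slice, m$coding_nt[j])
      expect_identical(translate_frames(c(x = slice), std)$protein[1],
                       m$peptide_seq[j])
      # exactness: no in-frame stop can sit inside a match
      expect_false(grepl("*", translate_frames(c(x = slice), std)$protein[1],
                         fixed = TRUE))
    }
  }
})

test_that("mapping against the reverse complement mirrors coordinates and strands", {
  std <- std_code()
  withr::local_seed(303L)
  for (rep in 1:10) {
    seq <- random_dna(sample(200:600, 1L))
    L <- nchar(seq)
    fr <- translate_frames(c(r = seq), std)
    prot <- gsub("[*X]", "#", fr$protein[1])
    segs <- strsplit(prot, "#", fixed = TRUE)[[1]]
    segs <- segs[nchar(segs) >= 5L]
    if (length(segs) == 0L) next
    pep <- substr(segs[1], 1, 5)
    m_fwd <- map_peptides(c(p = pep), c(r = seq), std)
    m_rev <- map_peptides(c(p = pep), c(r = reverse_complement(seq)), std)
    expect_identical(nrow(m_fwd), nrow(m_rev))
    mirrored <- sort(paste(L - m_rev$nt_end + 1L, L - m_rev$nt_start + 1L,
                           chartr("+-", "-+", m_rev$strand)))
    expect_identical(sort(paste(m_fwd$nt_start, m_fwd$nt_end, m_fwd$strand)),
                     mirrored)
  }
})
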