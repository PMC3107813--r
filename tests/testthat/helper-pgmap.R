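# Shared test helpers: independent oracles and tiny generators.

extdata <- function(...) system.file("extdata", ..., package = "pgmap")

std_code <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- select_code(parse_code_table(extdata("genetic_code_table.txt")), 1L)
    }
    memo
  }
})

# Independent multi-pattern matching oracle: per-keyword naive substring
# scan over every start position (finds overlapping and nested hits).
naive_scan <- function(keywords, text) {
  if (is.character(keywords)) {
    keywords <- tibble::tibble(id = names(keywords) %||% keywords,
                               pattern = unname(keywords))
  }
  n <- nchar(text)
  rows <- list()
  for (k in seq_len(nrow(keywords))) {
    m <- nchar(keywords$pattern[k])
    if (m > n) next
    starts <- 1:(n - m + 1L)
    hit <- substring(text, starts, starts + m - 1L) == keywords$pattern[k]
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        keyword_id = keywords$id[k],
        start = starts[hit] - 1L,
        end = starts[hit] - 1L + m)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(keyword_id = character(), start = integer(),
                          end = integer()))
  }
  out[order(out$end, out$keyword_id), ]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptide <- function(n) {
  paste(sample(aa_alphabet, n, replace = TRUE), collapse = "")
}

# Local channel catfish virus genome (not bundled; see README). Tests that
# need the full genome fail informatively when it is absent.
ccv_genome_path <- function() {
  opt <- getOption("pgmap.ccv_genome", "")
  if (nzchar(opt) && file.exists(opt)) return(opt)
  p <- extdata("NC_001493.1.fasta")
  if (nzchar(p) && file.exists(p)) return(p)
  ""
}
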