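# Aho-Corasick multi-pattern exact matching over amino-acid text.
#
# The machine is the classical keyword trie with failure links. Construction
# is linear in the total pattern length; after the breadth-first pass we also
# materialize the full deterministic transition table (delta), so the scan is
# a single table lookup per text character with no inner failure-link loop.
# The alphabet is the 26 uppercase letters plus one catch-all column for any
# other character ('*', 'X', digits, ...), which simply resets to the root:
# such characters occur in six-frame translations but never in a peptide.

.ac_alpha_size <- 27L

# map characters to 1..27; anything outside A-Z -> 27
.ac_codes <- function(text) {
  v <- utf8ToInt(text) - 64L
  v[v < 1L | v > 26L] <- .ac_alpha_size
  v
}

#' Build an Aho-Corasick automaton from a keyword set
#'
#' @param keywords The peptides to search for: a data frame with columns
#'   `id` and `pattern`, or a character vector of patterns (names, if any,
#'   become ids; otherwise the patterns themselves do). Duplicate patterns
#'   under different ids are allowed and share an output state.
#' @return An object of class `ac_automaton` with fields `n_states`, `goto`
#'   (trie edges, states x 26 integer matrix, 0 = no edge), `fail`, `output`
#'   (list of keyword indices per state), `delta` (dense transition table),
#'   `depth`, and `keywords` (tibble `id`, `pattern`, `length`).
#' @examples
#' aut <- build_automaton(c(he = "HE", she = "SHE", his = "HIS", hers = "HERS"))
#' find_matches(aut, "USHERS")
#' @export
build_automaton <- function(keywords) {
  if (is.character(keywords)) {
    ids <- names(keywords) %||% keywords
    ids[!nzchar(ids)] <- keywords[!nzchar(ids)]
    keywords <- tibble(id = ids, pattern = unname(keywords))
  }
  keywords <- as_tibble(keywords)
  if (nrow(keywords) == 0L) abort("keyword set is empty")
  keywords$pattern <- toupper(keywords$pattern)
  bad <- !nzchar(keywords$pattern)
  if (any(bad)) {
    abort(sprintf("empty pattern for keyword id(s): %s",
                  paste(keywords$id[bad], collapse = ", ")))
  }
  bad <- grepl("[*[:space:]]", keywords$pattern)
  if (any(bad)) {
    abort(sprintf("pattern contains '*' or whitespace for keyword id(s): %s",
                  paste(keywords$id[bad], collapse = ", ")))
  }
  keywords$length <- nchar(keywords$pattern)

  max_states <- sum(keywords$length) + 1L
  goto <- matrix(0L, nrow = max_states, ncol = 26L)
  depth <- integer(max_states)
  output <- vector("list", max_states)
  n_states <- 1L  # state 1 is the root

  for (k in seq_len(nrow(keywords))) {
    s <- 1L
    for (cc in .ac_codes(keywords$pattern[k])) {
      nxt <- goto[s, cc]
      if (nxt == 0L) {
        n_states <- n_states + 1L
        nxt <- n_states
        goto[s, cc] <- nxt
        depth[nxt] <- depth[s] + 1L
      }
      s <- nxt
    }
    output[[s]] <- c(output[[s]], k)
  }

  goto <- goto[seq_len(n_states), , drop = FALSE]
  depth <- depth[seq_len(n_states)]
  output <- output[seq_len(n_states)]

  # BFS: failure links and dense transitions over the 26-letter alphabet
  fail <- integer(n_states)
  fail[1L] <- 1L
  delta <- matrix(1L, nrow = n_states, ncol = .ac_alpha_size)
  queue <- integer(n_states)
  qh <- 1L; qt <- 0L
  for (cc in 1:26) {
    t <- goto[1L, cc]
    if (t != 0L) {
      fail[t] <- 1L
      delta[1L, cc] <- t
      qt <- qt + 1L; queue[qt] <- t
    }
  }
  while (qh <= qt) {
    s <- queue[qh]; qh <- qh + 1L
    for (cc in 1:26) {
      t <- goto[s, cc]
      if (t != 0L) {
        f <- delta[fail[s], cc]
        fail[t] <- f
        # note: assigning c(NULL, NULL) would delete the list element
        if (length(output[[f]])) output[[t]] <- c(output[[t]], output[[f]])
        delta[s, cc] <- t
        qt <- qt + 1L; queue[qt] <- t
      } else {
        delta[s, cc] <- delta[fail[s], cc]
      }
    }
  }

  structure(
    list(n_states = n_states, goto = goto, fail = fail, output = output,
         delta = delta, depth = depth, keywords = keywords),
    class = "ac_automaton"
  )
}

#' @export
print.ac_automaton <- function(x, ...) {
  cat(sprintf("<ac_automaton> %d keywords, %d states (total pattern length %d)\n",
              nrow(x$keywords), x$n_states, sum(x$keywords$length)))
  invisible(x)
}

#' Find all keyword occurrences in a text
#'
#' Reports every occurrence of every keyword, including overlapping and
#' nested matches, in one left-to-right pass over the text. Each character
#' is consumed exactly once (dense-transition scan).
#'
#' @param automaton An `ac_automaton` from [build_automaton()].
#' @param text The string to scan; characters outside the automaton's
#'   alphabet (e.g. `'*'`, `'X'`) reset match progress and can never lie
#'   inside a hit.
#' @param counter If `TRUE`, attach the number of scan steps as attribute
#'   `steps` (equals `nchar(text)`; used to assert the linear-scan property).
#' @return Tibble with columns `keyword_id`, `start`, `end` (0-based,
#'   half-open), ordered by `end` then `keyword_id`.
#' @export
find_matches <- function(automaton, text, counter = FALSE) {
  empty <- tibble(keyword_id = character(), start = integer(), end = integer())
  n <- nchar(text)
  if (n == 0L) {
    if (counter) attr(empty, "steps") <- 0L
    return(empty)
  }
  codes <- .ac_codes(toupper(text))
  delta <- automaton$delta
  output <- automaton$output
  has_out <- lengths(output) > 0L

  hit_k <- integer(0)
  hit_end <- integer(0)
  s <- 1L
  steps <- 0L
  for (i in seq_len(n)) {
    s <- delta[s, codes[i]]
    steps <- steps + 1L
    if (has_out[s]) {
      ks <- output[[s]]
      hit_k <- c(hit_k, ks)
      hit_end <- c(hit_end, rep.int(i, length(ks)))
    }
  }
  if (length(hit_k) == 0L) {
    if (counter) attr(empty, "steps") <- steps
    return(empty)
  }
  kw <- automaton$keywords
  res <- tibble(
    keyword_id = kw$id[hit_k],
    start = hit_end - kw$length[hit_k],
    end = hit_end
  )
  res <- res[order(res$end, res$keyword_id), ]
  if (counter) attr(res, "steps") <- steps
  res
}
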