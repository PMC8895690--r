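#' Build a trie (prefix dictionary) over a lexicon
#'
#' Realised as a hashed prefix index: every word maps to its frequency and
#' every proper prefix is registered, which supports the same membership /
#' prefix / frequency queries as a pointer trie while scanning a sentence
#' left to right.
#'
#' @param lex a `lexicon`.
#' @return an object of class `lex_trie`.
#' @export
build_trie <- function(lex) {
  stopifnot(inherits(lex, "lexicon"))
  words <- names(lex$entries)
  freq_env <- new.env(parent = emptyenv(), size = length(words) * 2L)
  pref_env <- new.env(parent = emptyenv(), size = length(words) * 4L)
  for (i in seq_along(words)) {
    w <- words[i]
    assign(w, lex$entries[[i]], envir = freq_env)
    n <- nchar(w)
    k <- 1L
    while (k <= n) {
      assign(substr(w, 1L, k), TRUE, envir = pref_env)
      k <- k + 1L
    }
  }
  structure(
    list(freq = freq_env, prefixes = pref_env,
         max_len = max(nchar(words)), total_count = lex$total_count),
    class = "lex_trie"
  )
}

#' Trie queries
#'
#' `trie_member()` tests full-word membership, `trie_freq()` returns a word's
#' frequency (NA when absent), `trie_prefix()` tests whether the string is a
#' prefix of any lexicon word (including full words).
#'
#' @param trie a `lex_trie`.
#' @param w character string.
#' @export
trie_member <- function(trie, w) {
  vapply(w, function(x) exists(x, envir = trie$freq, inherits = FALSE), NA)
}

#' @rdname trie_member
#' @export
trie_freq <- function(trie, w) {
  vapply(w, function(x) {
    if (exists(x, envir = trie$freq, inherits = FALSE)) get(x, envir = trie$freq) else NA_real_
  }, 0)
}

#' @rdname trie_member
#' @export
trie_prefix <- function(trie, w) {
  vapply(w, function(x) exists(x, envir = trie$prefixes, inherits = FALSE), NA)
}

#' @export
print.lex_trie <- function(x, ...) {
  cat(sprintf("<lex_trie> %d words, longest %d symbols\n",
              length(ls(x$freq)), x$max_len))
  invisible(x)
}
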