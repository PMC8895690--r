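#' Construct a lexicon
#'
#' A lexicon maps words (strings over a finite symbol alphabet) to positive
#' integer frequencies. Segmentation probabilities are word frequencies
#' normalised by the lexicon's total count.
#'
#' @param entries named numeric vector, word -> frequency (positive).
#' @return An object of class `lexicon` with elements `entries` (named
#'   integer vector) and `total_count`.
#' @export
lexicon <- function(entries) {
  if (length(entries) == 0L) stop("lexicon must contain at least one word")
  words <- names(entries)
  if (is.null(words) || any(!nzchar(words))) stop("every lexicon word must be non-empty")
  if (anyDuplicated(words)) stop("duplicate words in lexicon")
  freq <- as.numeric(entries)
  if (any(!is.finite(freq)) || any(freq <= 0)) stop("frequencies must be positive")
  structure(
    list(entries = stats::setNames(freq, words), total_count = sum(freq)),
    class = "lexicon"
  )
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> %d words, total count %g\n", length(x$entries), x$total_count))
  show <- utils::head(sort(x$entries, decreasing = TRUE), 5L)
  cat("  top:", paste(sprintf("%s(%g)", names(show), show), collapse = " "), "\n")
  invisible(x)
}

#' Generate a seeded Zipf lexicon over a finite alphabet
#'
#' Word lengths are drawn in 1..4; frequencies follow a Zipf law with the
#' given exponent, so low-rank words dominate as in natural-language
#' dictionaries.
#'
#' @param alphabet_size number of distinct symbols (>= 2, at most 52).
#' @param n_words number of distinct words (>= 1).
#' @param zipf_exponent Zipf exponent (frequency of rank r ~ r^-s).
#' @param seed integer seed; output is a pure function of the arguments.
#' @return a `lexicon`.
#' @export
generate_lexicon <- function(alphabet_size, n_words, zipf_exponent = 1, seed = 1L) {
  if (alphabet_size < 2L) stop("alphabet_size must be >= 2")
  if (n_words < 1L) stop("n_words must be >= 1")
  if (alphabet_size > 52L) stop("alphabet_size must be <= 52")
  alph <- c(letters, LETTERS)[seq_len(alphabet_size)]
  s <- as.numeric(alphabet_size)
  if (n_words > s + s^2 + s^3 + s^4) stop("n_words exceeds the number of distinct words of length <= 4")
  withr::with_seed(seed, {
    words <- character(0)
    while (length(words) < n_words) {
      need <- n_words - length(words)
      lens <- sample(1:4, 2L * need + 8L, replace = TRUE, prob = c(0.15, 0.45, 0.30, 0.10))
      new <- vapply(lens, function(L) paste(sample(alph, L, replace = TRUE), collapse = ""), "")
      words <- unique(c(words, new))
    }
    words <- words[seq_len(n_words)]
    freq <- pmax(1, round(1e4 * seq_len(n_words)^(-zipf_exponent)))
    lexicon(stats::setNames(freq, words))
  })
}

#' Read / write a lexicon as a two-column tab-separated text file
#'
#' Format: `word<TAB>count`, UTF-8, one entry per line.
#'
#' @param x a `lexicon`.
#' @param path file path.
#' @export
write_lexicon <- function(x, path) {
  stopifnot(inherits(x, "lexicon"))
  writeLines(sprintf("%s\t%g", names(x$entries), x$entries), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  tab <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                           col.names = c("word", "count"),
                           colClasses = c("character", "numeric"),
                           encoding = "UTF-8")
  lexicon(stats::setNames(tab$count, tab$word))
}

lexicon_alphabet <- function(lex) {
  sort(unique(unlist(strsplit(names(lex$entries), "", fixed = TRUE))))
}
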