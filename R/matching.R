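#' Token-level Levenshtein edit distance
#'
#' Minimum number of token insertions, deletions and substitutions (unit
#' cost each) transforming one token sequence into the other. Distances are
#' computed over tokens, not raw symbols, so synonym conversion upstream is
#' respected.
#'
#' @param a,b character vectors of tokens.
#' @return non-negative integer.
#' @export
edit_distance <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L) return(nb)
  if (nb == 0L) return(na)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    cur[1L] <- i
    for (j in seq_len(nb)) {
      cost <- if (a[i] == b[j]) 0L else 1L
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' Default deviation message for unmatched questions
#' @export
deviation_message <- function() "You have deviated from the correct process"

#' Matching pipeline configuration
#'
#' Bundles the components needed to normalise free text and the routing
#' thresholds: exact match at distance 0, candidate set below
#' `max_candidate_distance`, deviation at or above it.
#'
#' @param lexicon a `lexicon`.
#' @param hmm optional `hmm_model` for OOV word formation.
#' @param vectors optional `vector_model` for synonym conversion.
#' @param qualifiers negation qualifier words.
#' @param rules rule patterns (NULL to disable).
#' @param similarity_threshold cosine threshold for synonym replacement.
#' @param max_candidate_distance routing bound (default 5).
#' @param message deviation response string.
#' @export
match_pipeline <- function(lexicon, hmm = NULL, vectors = NULL,
                           qualifiers = default_qualifiers(),
                           rules = default_rules(),
                           similarity_threshold = 0.7,
                           max_candidate_distance = 5L,
                           message = deviation_message()) {
  stopifnot(inherits(lexicon, "lexicon"))
  structure(list(lexicon = lexicon, trie = build_trie(lexicon), hmm = hmm,
                 vectors = vectors, qualifiers = qualifiers, rules = rules,
                 similarity_threshold = similarity_threshold,
                 max_candidate_distance = as.integer(max_candidate_distance),
                 message = message),
            class = "match_pipeline")
}

#' Normalise free text to canonical tokens
#'
#' Segmentation, then synonym conversion of each token onto the nearest
#' standard term (when a vector model is configured), with the negation
#' annotation attached as an attribute (negation is metadata; it does not
#' enter edit distance).
#'
#' @param text character scalar.
#' @param pipeline a `match_pipeline`.
#' @return character vector of tokens with attribute `negation`.
#' @export
normalize_question <- function(text, pipeline) {
  stopifnot(inherits(pipeline, "match_pipeline"))
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("text must be a non-empty string")
  seg <- segment(text, pipeline$trie, hmm = pipeline$hmm, rules = pipeline$rules)
  tokens <- seg$tokens
  if (!is.null(pipeline$vectors) && length(pipeline$vectors$standard_terms)) {
    tokens <- vapply(tokens, function(w)
      nearest_standard_term(w, pipeline$vectors,
                            pipeline$similarity_threshold)$word, "")
    tokens <- unname(tokens)
  }
  attr(tokens, "negation") <- annotate_negation(tokens, pipeline$qualifiers)
  tokens
}

#' Route a free-text question onto the standard question library
#'
#' The text is normalised and its token edit distance to every library
#' question computed. Distance 0 returns the question and its answer
#' (EXACT); a smallest distance strictly between 0 and the candidate bound
#' returns all questions under the bound, ascending, ties by question id
#' (CANDIDATES, the learner must reconfirm); otherwise the configured
#' deviation message is returned (DEVIATED).
#'
#' @param text character scalar (already-normalised token vectors are also
#'   accepted).
#' @param library a `question_library`.
#' @param pipeline a `match_pipeline`.
#' @return class `match_result`: `outcome` ("EXACT", "CANDIDATES",
#'   "DEVIATED"), `matched` (library row or NULL), `candidates` (data.frame
#'   question_id, distance), `message`, `distance`.
#' @export
match_question <- function(text, library, pipeline) {
  stopifnot(inherits(library, "question_library"), nrow(library) > 0L)
  tokens <- if (is.character(text) && length(text) == 1L)
    normalize_question(text, pipeline) else as.character(text)
  d <- vapply(library$canonical_tokens,
              function(q) edit_distance(tokens, q), 0L)
  dmin <- min(d)
  bound <- pipeline$max_candidate_distance
  if (dmin == 0L) {
    i <- which(d == 0L)[1L]
    res <- list(outcome = "EXACT", matched = library[i, ],
                candidates = data.frame(question_id = library$question_id[i],
                                        distance = 0L),
                message = NULL, distance = 0L)
  } else if (dmin < bound) {
    keep <- which(d < bound)
    ord <- keep[order(d[keep], library$question_id[keep])]
    res <- list(outcome = "CANDIDATES", matched = NULL,
                candidates = data.frame(question_id = library$question_id[ord],
                                        distance = d[ord]),
                message = NULL, distance = dmin)
  } else {
    res <- list(outcome = "DEVIATED", matched = NULL,
                candidates = data.frame(question_id = character(0),
                                        distance = integer(0)),
                message = pipeline$message, distance = dmin)
  }
  res$tokens <- tokens
  class(res) <- "match_result"
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s (min distance %d)\n", x$outcome, x$distance))
  if (x$outcome == "CANDIDATES") print(x$candidates)
  if (x$outcome == "DEVIATED") cat("  ", x$message, "\n")
  invisible(x)
}
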