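#' Default negation qualifier list
#'
#' Qualifier words that flip the polarity of the clinical findings that
#' follow them within the same clause (denial, negation, "not excluding",
#' "without", "not", "not seen", "none"). In a deployment these come from a
#' curated one-word-per-line file; see [read_qualifiers()].
#' @export
default_qualifiers <- function() {
  c("no", "not", "without", "denies", "none", "unseen", "excluding")
}

#' Read a qualifier list (one word per line, UTF-8)
#' @param path file path.
#' @export
read_qualifiers <- function(path) {
  q <- readLines(path, encoding = "UTF-8")
  q[nzchar(trimws(q))]
}

#' Annotate token polarity from negation qualifiers
#'
#' Scope is the clause-bounded forward window: after a qualifier, following
#' tokens are negated until the next clause break; a second qualifier in the
#' same clause flips polarity back (flip-on-repeat). Qualifier and break
#' tokens themselves keep polarity "affirmed".
#'
#' @param tokens character vector of tokens.
#' @param qualifiers qualifier word list.
#' @param clause_breaks tokens that end a clause.
#' @return class `negation_annotation`: list with `polarity` (per token,
#'   "affirmed"/"negated") and `qualifier_hits` (list of qualifier token and
#'   its scope token indices).
#' @export
annotate_negation <- function(tokens, qualifiers = default_qualifiers(),
                              clause_breaks = c(".", ",", ";")) {
  polarity <- rep("affirmed", length(tokens))
  hits <- list()
  negated <- FALSE
  scope_open <- integer(0)
  close_scopes <- function(hits, scope_open, upto) {
    for (h in scope_open)
      hits[[h]]$scope <- hits[[h]]$scope[hits[[h]]$scope <= upto]
    hits
  }
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (tok %in% clause_breaks) {
      negated <- FALSE
      scope_open <- integer(0)
    } else if (tok %in% qualifiers) {
      negated <- !negated
      rest <- if (i < length(tokens)) (i + 1L):length(tokens) else integer(0)
      hits[[length(hits) + 1L]] <- list(qualifier = tok, scope = rest)
      scope_open <- c(scope_open, length(hits))
    } else if (negated) {
      polarity[i] <- "negated"
    }
  }
  # trim scopes at clause breaks
  brk <- which(tokens %in% clause_breaks)
  for (h in seq_along(hits)) {
    start <- if (length(hits[[h]]$scope)) hits[[h]]$scope[1L] else NA_integer_
    if (!is.na(start)) {
      nb <- brk[brk >= start]
      if (length(nb)) hits[[h]]$scope <- hits[[h]]$scope[hits[[h]]$scope < nb[1L]]
    }
  }
  structure(list(polarity = polarity, qualifier_hits = hits),
            class = "negation_annotation")
}
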