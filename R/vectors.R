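#' Train word vectors from a token corpus
#'
#' Count-based distributional embedding: a symmetric co-occurrence matrix
#' within `window` tokens is reweighted to positive pointwise mutual
#' information and factorised by truncated SVD; vectors are the left
#' singular vectors scaled by the singular values, which preserves the
#' cosine geometry of the PPMI rows at full rank. Words sharing context
#' distributions therefore end close in cosine.
#' A tiny seeded jitter breaks exact symmetries so no word has a zero
#' vector; results are otherwise deterministic.
#'
#' @param corpus list of token character vectors.
#' @param dim embedding dimension (>= 2; capped at vocabulary size).
#' @param window symmetric context window in tokens.
#' @param seed integer seed.
#' @param standard_terms subset of the vocabulary flagged canonical.
#' @return class `vector_model`: `vocabulary`, `vectors` (row per word),
#'   `standard_terms`.
#' @export
train_vectors <- function(corpus, dim = 16L, window = 2L, seed = 1L,
                          standard_terms = character(0)) {
  stopifnot(length(corpus) > 0L, dim >= 2L, window >= 1L)
  vocab <- sort(unique(unlist(corpus)))
  if (length(vocab) < 2L) stop("vocabulary must contain at least 2 words")
  V <- length(vocab)
  C <- matrix(0, V, V, dimnames = list(vocab, vocab))
  for (sent in corpus) {
    idx <- match(sent, vocab)
    n <- length(idx)
    for (i in seq_len(n)) {
      lo <- max(1L, i - window); hi <- min(n, i + window)
      for (j in lo:hi) {
        if (j != i) C[idx[i], idx[j]] <- C[idx[i], idx[j]] + 1
      }
    }
  }
  total <- sum(C)
  if (total == 0) stop("corpus has no co-occurrences; sentences too short")
  pi_ <- rowSums(C) / total
  pj_ <- colSums(C) / total
  pmi <- log(pmax(C / total, .Machine$double.xmin) / outer(pi_, pj_))
  ppmi <- pmax(pmi, 0)
  ppmi[C == 0] <- 0
  d_eff <- min(dim, V)
  sv <- svd(ppmi, nu = d_eff, nv = 0)
  vec <- sv$u %*% diag(sv$d[seq_len(d_eff)], d_eff)
  # deterministic sign convention + seeded jitter against zero vectors
  for (k in seq_len(d_eff)) {
    piv <- which.max(abs(vec[, k]))
    if (vec[piv, k] < 0) vec[, k] <- -vec[, k]
  }
  vec <- vec + withr::with_seed(seed, matrix(stats::rnorm(V * d_eff, 0, 1e-8), V, d_eff))
  rownames(vec) <- vocab
  missing_std <- setdiff(standard_terms, vocab)
  if (length(missing_std))
    warning("standard terms absent from corpus vocabulary: ",
            paste(missing_std, collapse = ", "))
  structure(list(vocabulary = vocab, vectors = vec,
                 standard_terms = intersect(standard_terms, vocab)),
            class = "vector_model")
}

#' @export
print.vector_model <- function(x, ...) {
  cat(sprintf("<vector_model> %d words x %d dims, %d standard terms\n",
              nrow(x$vectors), ncol(x$vectors), length(x$standard_terms)))
  invisible(x)
}

#' Cosine similarity between two vectors
#' @param a,b numeric vectors of equal length.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Nearest standard term to a word
#'
#' Looks up the argmax-cosine standard term. Standard words map to
#' themselves with similarity 1; out-of-vocabulary words pass through
#' unchanged; an in-vocabulary word is replaced only when the best
#' similarity reaches `threshold`, otherwise it also passes through.
#'
#' @param word character scalar.
#' @param model a `vector_model` with non-empty `standard_terms`.
#' @param threshold minimum cosine for replacement (default 0.7).
#' @return list with `word` (the output token), `standard` (best standard
#'   term or NA), `similarity`, `replaced` (logical).
#' @export
nearest_standard_term <- function(word, model, threshold = 0.7) {
  if (length(model$standard_terms) == 0L) stop("standard term set is empty")
  if (!word %in% model$vocabulary)
    return(list(word = word, standard = NA_character_,
                similarity = NA_real_, replaced = FALSE))
  if (word %in% model$standard_terms)
    return(list(word = word, standard = word, similarity = 1, replaced = FALSE))
  v <- model$vectors[word, ]
  sims <- vapply(model$standard_terms,
                 function(s) cosine_similarity(v, model$vectors[s, ]), 0)
  best <- which.max(sims)
  if (sims[best] >= threshold)
    list(word = model$standard_terms[best], standard = model$standard_terms[best],
         similarity = unname(sims[best]), replaced = TRUE)
  else
    list(word = word, standard = model$standard_terms[best],
         similarity = unname(sims[best]), replaced = FALSE)
}

#' Serialize / load a vector model as JSON
#' @param model a `vector_model`.
#' @param path file path.
#' @export
write_vector_model <- function(model, path) {
  obj <- list(vocabulary = model$vocabulary,
              vectors = apply(model$vectors, 1, as.numeric, simplify = FALSE),
              standard_terms = model$standard_terms)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_vector_model
#' @export
read_vector_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vec <- if (is.matrix(obj$vectors)) obj$vectors else do.call(rbind, obj$vectors)
  rownames(vec) <- obj$vocabulary
  structure(list(vocabulary = obj$vocabulary, vectors = vec,
                 standard_terms = as.character(obj$standard_terms)),
            class = "vector_model")
}
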