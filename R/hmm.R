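BMES <- c("B", "M", "E", "S")

# legal structure of BMES word tagging:
#   a word is S or B M* E; sentences start at a word start and end at a
#   word end.
legal_transitions <- function() {
  m <- matrix(FALSE, 4, 4, dimnames = list(BMES, BMES))
  m["B", c("M", "E")] <- TRUE
  m["M", c("M", "E")] <- TRUE
  m["E", c("B", "S")] <- TRUE
  m["S", c("B", "S")] <- TRUE
  m
}
LEGAL_INITIAL <- c(B = TRUE, M = FALSE, E = FALSE, S = TRUE)
LEGAL_FINAL   <- c(B = FALSE, M = FALSE, E = TRUE, S = TRUE)

new_hmm_model <- function(log_initial, log_transition, log_emission, log_unseen) {
  m <- structure(
    list(states = BMES,
         log_initial = log_initial,
         log_transition = log_transition,
         log_emission = log_emission,
         log_unseen = log_unseen),
    class = "hmm_model"
  )
  validate_hmm(m)
  m
}

validate_hmm <- function(m, tol = 1e-9) {
  stopifnot(identical(rownames(m$log_transition), BMES))
  if (abs(sum(exp(m$log_initial)) - 1) > tol) stop("initial distribution does not sum to 1")
  tr <- exp(m$log_transition)
  if (any(abs(rowSums(tr) - 1) > tol)) stop("transition rows do not sum to 1")
  if (any(tr[!legal_transitions()] > 0)) stop("illegal BMES transition has positive mass")
  em <- exp(m$log_emission)
  tot <- rowSums(em) + exp(m$log_unseen)
  if (any(abs(tot - 1) > tol)) stop("emission rows (plus unseen mass) do not sum to 1")
  invisible(m)
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> BMES character tagger, %d emission symbols\n",
              ncol(x$log_emission)))
  print(round(exp(x$log_transition), 3))
  invisible(x)
}

#' Train a BMES character HMM from a tagged corpus
#'
#' Maximum-likelihood counts with additive smoothing. Smoothing mass is
#' spread only over structurally legal transitions; illegal BMES moves keep
#' probability zero (-Inf in log space). Emissions reserve one smoothed
#' bucket for symbols never seen in training.
#'
#' @param corpus a `tagged_corpus`.
#' @param smoothing additive smoothing constant (> 0).
#' @return an `hmm_model` with log-space parameters.
#' @export
train_hmm <- function(corpus, smoothing = 0.5) {
  stopifnot(inherits(corpus, "tagged_corpus"))
  if (length(corpus$sentences) == 0L) stop("empty corpus")
  if (smoothing <= 0) stop("smoothing must be > 0")

  all_tags <- lapply(corpus$sentences, `[[`, "tags")
  all_syms <- lapply(corpus$sentences, `[[`, "symbols")
  symbols <- sort(unique(unlist(all_syms)))
  V <- length(symbols)

  init_counts <- stats::setNames(numeric(4), BMES)
  trans_counts <- matrix(0, 4, 4, dimnames = list(BMES, BMES))
  emit_counts <- matrix(0, 4, V, dimnames = list(BMES, symbols))

  for (i in seq_along(all_tags)) {
    tg <- all_tags[[i]]; sy <- all_syms[[i]]
    init_counts[tg[1L]] <- init_counts[tg[1L]] + 1
    if (length(tg) > 1L) {
      for (t in seq_len(length(tg) - 1L))
        trans_counts[tg[t], tg[t + 1L]] <- trans_counts[tg[t], tg[t + 1L]] + 1
    }
    for (t in seq_along(tg))
      emit_counts[tg[t], sy[t]] <- emit_counts[tg[t], sy[t]] + 1
  }

  ip <- ifelse(LEGAL_INITIAL, init_counts + smoothing, 0)
  log_initial <- log(ip / sum(ip))

  legal <- legal_transitions()
  tp <- ifelse(legal, trans_counts + smoothing, 0)
  log_transition <- log(sweep(tp, 1, rowSums(tp), "/"))

  denom <- rowSums(emit_counts) + smoothing * (V + 1)
  log_emission <- log(sweep(emit_counts + smoothing, 1, denom, "/"))
  log_unseen <- log(smoothing / denom)
  names(log_unseen) <- BMES

  new_hmm_model(log_initial, log_transition, log_emission, log_unseen)
}

emission_logp <- function(model, state, symbols) {
  known <- symbols %in% colnames(model$log_emission)
  out <- rep(model$log_unseen[[state]], length(symbols))
  out[known] <- model$log_emission[state, symbols[known]]
  out
}

#' Viterbi decoding of a symbol span into BMES tags
#'
#' Returns the maximum-probability structurally legal tag sequence (start in
#' B/S, legal word-internal transitions, end in E/S). Ties are broken by the
#' fixed state order B < M < E < S at every backpointer.
#'
#' @param symbols character vector of single symbols (or a single string,
#'   which is split).
#' @param model an `hmm_model`.
#' @return character vector of tags, one per symbol.
#' @export
viterbi_decode <- function(symbols, model) {
  if (length(symbols) == 1L && nchar(symbols) > 1L)
    symbols <- strsplit(symbols, "", fixed = TRUE)[[1]]
  n <- length(symbols)
  stopifnot(n >= 1L)
  delta <- matrix(-Inf, n, 4, dimnames = list(NULL, BMES))
  back <- matrix(NA_integer_, n, 4)
  for (s in seq_len(4))
    delta[1L, s] <- model$log_initial[[s]] + emission_logp(model, BMES[s], symbols[1L])[1L]
  if (n > 1L) {
    for (t in 2:n) {
      em <- vapply(BMES, function(st) emission_logp(model, st, symbols[t])[1L], 0)
      for (s in seq_len(4)) {
        cand <- delta[t - 1L, ] + model$log_transition[, s]
        k <- which.max(cand)           # first max = fixed B<M<E<S order
        delta[t, s] <- cand[k] + em[s]
        back[t, s] <- k
      }
    }
  }
  final <- delta[n, ]
  final[!LEGAL_FINAL] <- -Inf
  path <- integer(n)
  path[n] <- which.max(final)
  if (n > 1L) for (t in (n - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
  out <- BMES[path]
  attr(out, "logp") <- final[path[n]]
  out
}

#' Fixture: a known, identifiable BMES character HMM
#'
#' Produces a model whose four states each emit mostly from their own block
#' of the alphabet (`sharpness` of the mass), with seeded jitter on all
#' distributions. Used as ground truth for parameter-recovery experiments.
#'
#' @param alphabet_size number of symbols (>= 8 so each state owns a block).
#' @param sharpness in (0,1): within-block emission mass.
#' @param seed integer seed.
#' @return an `hmm_model` whose emission matrix covers the full alphabet.
#' @export
fixture_hmm_model <- function(alphabet_size = 20L, sharpness = 0.9, seed = 1L) {
  stopifnot(alphabet_size >= 8L, sharpness > 0, sharpness < 1)
  alph <- c(letters, LETTERS)[seq_len(alphabet_size)]
  blocks <- split(seq_len(alphabet_size),
                  cut(seq_len(alphabet_size), 4, labels = FALSE))
  withr::with_seed(seed, {
    emit <- matrix(0, 4, alphabet_size, dimnames = list(BMES, alph))
    for (s in seq_len(4)) {
      w_in <- stats::runif(length(blocks[[s]]), 0.5, 1)
      w_out <- stats::runif(alphabet_size - length(blocks[[s]]), 0.5, 1)
      emit[s, blocks[[s]]] <- sharpness * w_in / sum(w_in)
      emit[s, -blocks[[s]]] <- (1 - sharpness) * w_out / sum(w_out)
    }
    legal <- legal_transitions()
    trans <- matrix(0, 4, 4, dimnames = list(BMES, BMES))
    for (s in seq_len(4)) {
      w <- stats::runif(sum(legal[s, ]), 0.3, 1)
      trans[s, legal[s, ]] <- w / sum(w)
    }
    init <- c(B = 0, M = 0, E = 0, S = 0)
    w <- stats::runif(2, 0.3, 1)
    init[c("B", "S")] <- w / sum(w)
    new_hmm_model(log(init), log(trans), log(emit),
                  stats::setNames(rep(-Inf, 4), BMES))
  })
}

#' Sample a tagged corpus from a known HMM
#'
#' Draws tag paths from the initial/transition chain and symbols from the
#' per-state emissions; each sentence continues until it is at least
#' `min_length` symbols long and sits at a legal word end (E or S).
#'
#' @param model an `hmm_model` with full-alphabet emissions.
#' @param n_sentences number of sentences.
#' @param min_length minimum sentence length in symbols.
#' @param seed integer seed.
#' @return a `tagged_corpus`.
#' @export
simulate_hmm_corpus <- function(model, n_sentences, min_length = 15L, seed = 1L) {
  stopifnot(n_sentences >= 1L)
  alph <- colnames(model$log_emission)
  init_p <- exp(model$log_initial)
  trans_p <- exp(model$log_transition)
  emit_p <- exp(model$log_emission)
  withr::with_seed(seed, {
    sentences <- vector("list", n_sentences)
    for (i in seq_len(n_sentences)) {
      tags <- character(0)
      st <- sample(BMES, 1L, prob = init_p)
      repeat {
        tags <- c(tags, st)
        if (length(tags) >= min_length && st %in% c("E", "S")) break
        st <- sample(BMES, 1L, prob = trans_p[st, ])
      }
      syms <- vapply(tags, function(s) sample(alph, 1L, prob = emit_p[s, ]), "")
      sentences[[i]] <- list(symbols = unname(syms), tags = tags,
                             words = tags_to_words(unname(syms), tags),
                             is_oov = logical(0))
    }
    new_tagged_corpus(sentences)
  })
}

tags_to_words <- function(symbols, tags) {
  ends <- which(tags %in% c("E", "S"))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  vapply(seq_along(ends),
         function(k) paste(symbols[starts[k]:ends[k]], collapse = ""), "")
}

#' Word-boundary precision / recall / F1 of a predicted tagging
#'
#' Boundaries are the word end positions implied by the tags; the metric is
#' computed over all sentences jointly.
#'
#' @param predicted,truth lists of tag vectors (aligned).
#' @return named numeric: precision, recall, f1.
#' @export
boundary_metrics <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  tp <- fp <- fn <- 0
  for (i in seq_along(truth)) {
    pb <- which(predicted[[i]] %in% c("E", "S"))
    tb <- which(truth[[i]] %in% c("E", "S"))
    tp <- tp + length(intersect(pb, tb))
    fp <- fp + length(setdiff(pb, tb))
    fn <- fn + length(setdiff(tb, pb))
  }
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f)
}

#' Serialize / load an HMM model as JSON (log-space values)
#' @param model an `hmm_model`.
#' @param path file path.
#' @export
write_hmm <- function(model, path) {
  cap <- function(x) pmax(x, -1e308)  # JSON has no -Inf; restored on read
  obj <- list(states = model$states,
              log_initial = as.list(cap(model$log_initial)),
              log_transition = apply(cap(model$log_transition), 1, as.list, simplify = FALSE),
              emission_symbols = colnames(model$log_emission),
              log_emission = apply(cap(model$log_emission), 1, function(r) as.list(r), simplify = FALSE),
              log_unseen = as.list(cap(model$log_unseen)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- do.call(rbind, lapply(obj$log_transition, function(r) unlist(r)))
  em <- do.call(rbind, lapply(obj$log_emission, function(r) unlist(r)))
  dimnames(tr) <- list(BMES, BMES)
  dimnames(em) <- list(BMES, obj$emission_symbols)
  tr[tr < -1e300] <- -Inf
  li <- unlist(obj$log_initial)[BMES]; li[li < -1e300] <- -Inf
  lu <- unlist(obj$log_unseen)[BMES]; lu[lu < -1e300] <- -Inf
  new_hmm_model(li, tr, em, lu)
}
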