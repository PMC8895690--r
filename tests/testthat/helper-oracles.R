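# Brute-force oracles, independent of the package's DP / Viterbi code paths.

# all segmentations of a sentence admitted by lexicon words + single symbols
enumerate_segmentations <- function(sentence, lex) {
  syms <- strsplit(sentence, "", fixed = TRUE)[[1]]
  n <- length(syms)
  words <- names(lex$entries)
  maxlen <- max(nchar(words))
  recurse <- function(i) {
    if (i > n) return(list(character(0)))
    out <- list()
    for (j in i:min(n, i + maxlen - 1L)) {
      w <- paste(syms[i:j], collapse = "")
      if (j == i || w %in% words) {
        for (tail in recurse(j + 1L)) out[[length(out) + 1L]] <- c(w, tail)
      }
    }
    out
  }
  recurse(1L)
}

seg_score <- function(tokens, lex, oov_floor = 1e-3) {
  lp <- log(unname(lex$entries[tokens])) - log(lex$total_count)
  lp[is.na(lp)] <- -log(lex$total_count) + log(oov_floor)
  sum(lp)
}

brute_best_seg_score <- function(sentence, lex, oov_floor = 1e-3) {
  max(vapply(enumerate_segmentations(sentence, lex),
             seg_score, 0, lex = lex, oov_floor = oov_floor))
}

# all structurally legal BMES tag sequences of a given length
legal_tag_sequences <- function(n) {
  states <- c("B", "M", "E", "S")
  legal_next <- list(B = c("M", "E"), M = c("M", "E"),
                     E = c("B", "S"), S = c("B", "S"))
  recurse <- function(prefix) {
    if (length(prefix) == n) {
      if (prefix[n] %in% c("E", "S")) return(list(prefix))
      return(list())
    }
    out <- list()
    for (s in legal_next[[prefix[length(prefix)]]])
      out <- c(out, recurse(c(prefix, s)))
    out
  }
  out <- list()
  for (s in c("B", "S")) out <- c(out, recurse(s))
  out
}

tag_path_logp <- function(tags, symbols, model) {
  emi <- function(state, sym) {
    if (sym %in% colnames(model$log_emission)) model$log_emission[state, sym]
    else model$log_unseen[[state]]
  }
  lp <- model$log_initial[[tags[1L]]] + emi(tags[1L], symbols[1L])
  if (length(tags) > 1L) {
    for (t in 2:length(tags))
      lp <- lp + model$log_transition[tags[t - 1L], tags[t]] +
        emi(tags[t], symbols[t])
  }
  lp
}

brute_best_tag_logp <- function(symbols, model) {
  max(vapply(legal_tag_sequences(length(symbols)),
             tag_path_logp, 0, symbols = symbols, model = model))
}

# naive exponential-recursion Levenshtein over tokens
naive_edit <- function(a, b) {
  if (length(a) == 0L) return(length(b))
  if (length(b) == 0L) return(length(a))
  sub <- naive_edit(a[-1L], b[-1L]) + (a[1L] != b[1L])
  min(sub, naive_edit(a[-1L], b) + 1L, naive_edit(a, b[-1L]) + 1L)
}
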