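#' Word-graph (DAG) scan of a sentence
#'
#' Builds the directed acyclic word graph of all dictionary-admissible word
#' formations: an edge from position `i` to `j` (1-based, inclusive) exists
#' iff the covered span is a lexicon word, and every single symbol always
#' carries an edge so at least one full segmentation path exists.
#'
#' @param sentence character scalar (a symbol sequence).
#' @param trie a `lex_trie` from [build_trie()].
#' @return class `word_graph`: list with `sentence`, `symbols` and `edges`
#'   (per start index, the integer vector of admissible end indices).
#' @export
build_word_graph <- function(sentence, trie) {
  stopifnot(is.character(sentence), length(sentence) == 1L, nzchar(sentence))
  syms <- strsplit(sentence, "", fixed = TRUE)[[1]]
  n <- length(syms)
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    ends <- i  # single symbol always admissible
    jmax <- min(n, i + trie$max_len - 1L)
    frag <- ""
    for (j in i:jmax) {
      frag <- paste0(frag, syms[j])
      if (!trie_prefix(trie, frag)) break
      if (j > i && trie_member(trie, frag)) ends <- c(ends, j)
    }
    edges[[i]] <- ends
  }
  structure(list(sentence = sentence, symbols = syms, edges = edges),
            class = "word_graph")
}

#' Count the distinct full segmentation paths of a word graph
#' @param graph a `word_graph`.
#' @export
count_paths <- function(graph) {
  n <- length(graph$symbols)
  paths <- numeric(n + 1L)
  paths[n + 1L] <- 1
  for (i in n:1) paths[i] <- sum(paths[graph$edges[[i]] + 1L])
  paths[1L]
}

new_segmentation <- function(tokens, starts, ends, source) {
  structure(
    list(tokens = unname(tokens),
         spans = cbind(start = unname(as.integer(starts)),
                       end = unname(as.integer(ends))),
         source = unname(source)),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation> ", paste(x$tokens, collapse = " / "), "\n", sep = "")
  cat("  source:", paste(x$source, collapse = " "), "\n")
  invisible(x)
}

word_logp <- function(words, trie, oov_floor) {
  lp <- log(trie_freq(trie, words)) - log(trie$total_count)
  oov <- is.na(lp)
  lp[oov] <- -log(trie$total_count) + log(oov_floor)
  unname(lp)
}

#' Maximum-probability dictionary segmentation
#'
#' Dynamic programming over the word graph, right to left, maximising the sum
#' of unigram log probabilities `log(freq(word) / total_count)`. Single
#' symbols absent from the lexicon fall back to a floor probability
#' `oov_floor / total_count` so dictionary words are strictly preferred.
#' Ties are broken by fewer tokens, then the lexicographically earliest
#' boundary set.
#'
#' @param sentence character scalar.
#' @param lex a `lexicon` or a prebuilt `lex_trie`.
#' @param oov_floor multiplicative floor for out-of-vocabulary single
#'   symbols (default 1e-3).
#' @return a `segmentation`; `source` is `"DICT"` for lexicon words and
#'   `"OOV"` for single-symbol fallbacks.
#' @export
max_prob_segment <- function(sentence, lex, oov_floor = 1e-3) {
  trie <- if (inherits(lex, "lex_trie")) lex else build_trie(lex)
  graph <- build_word_graph(sentence, trie)
  n <- length(graph$symbols)
  best <- numeric(n + 1L)     # best[i] = best score of suffix starting at i
  ntok <- integer(n + 1L)
  nxt <- integer(n + 1L)      # chosen end index for suffix at i
  for (i in n:1) {
    ends <- graph$edges[[i]]
    words <- substring(graph$sentence, i, ends)
    cand <- word_logp(words, trie, oov_floor) + best[ends + 1L]
    cand_tok <- 1L + ntok[ends + 1L]
    # maximise score, then fewest tokens, then smallest end (earliest boundary)
    k <- order(-cand, cand_tok, ends)[1L]
    best[i] <- cand[k]
    ntok[i] <- cand_tok[k]
    nxt[i] <- ends[k]
  }
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- nxt[i]
    starts <- c(starts, i); ends <- c(ends, j)
    i <- j + 1L
  }
  tokens <- substring(sentence, starts, ends)
  src <- ifelse(trie_member(trie, tokens), "DICT", "OOV")
  seg <- new_segmentation(tokens, starts, ends, unname(src))
  attr(seg, "score") <- best[1L]
  seg
}

#' Default rule patterns for numeric / template spans
#'
#' Anchored regular patterns for dates, numeric ranges and number+unit
#' spans ("10 days" style measurements written without spaces in symbol
#' text), applied before word-graph construction so the matched span is
#' frozen as a single token.
#' @export
default_rules <- function() {
  c(date        = "[0-9]{4}-[0-9]{2}-[0-9]{2}",
    value_range = "[0-9]+(\\.[0-9]+)?-[0-9]+(\\.[0-9]+)?",
    number_unit = "[0-9]+(\\.[0-9]+)?[A-Za-z]{0,4}")  # unit suffix <= 4 symbols
}

#' Apply rule patterns to a sentence
#'
#' Returns the non-overlapping, leftmost-longest set of rule matches; on
#' equal start and length the earlier rule in `rules` wins, so overlapping
#' rule definitions resolve deterministically.
#'
#' @param sentence character scalar.
#' @param rules named character vector of regular expressions.
#' @return data.frame with columns `start`, `end` (1-based inclusive),
#'   `token`, `rule_id`; zero rows when nothing matches.
#' @export
apply_rule_patterns <- function(sentence, rules = default_rules()) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  hits <- list()
  for (r in seq_along(rules)) {
    m <- gregexpr(rules[[r]], sentence, perl = TRUE)[[1]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    hits[[length(hits) + 1L]] <- data.frame(
      start = as.integer(m), len = as.integer(len), rule = r)
  }
  empty <- data.frame(start = integer(0), end = integer(0),
                      token = character(0), rule_id = character(0))
  if (length(hits) == 0L) return(empty)
  h <- do.call(rbind, hits)
  h <- h[order(h$start, -h$len, h$rule), , drop = FALSE]
  keep <- integer(0); last_end <- 0L
  for (i in seq_len(nrow(h))) {
    if (h$start[i] > last_end) {
      keep <- c(keep, i)
      last_end <- h$start[i] + h$len[i] - 1L
    }
  }
  h <- h[keep, , drop = FALSE]
  data.frame(start = h$start,
             end = h$start + h$len - 1L,
             token = substring(sentence, h$start, h$start + h$len - 1L),
             rule_id = names(rules)[h$rule],
             row.names = NULL)
}

#' Full segmentation pipeline
#'
#' Rule spans are frozen first; the remaining chunks are segmented by
#' maximum-probability dictionary DP; maximal runs of two or more adjacent
#' single-symbol out-of-vocabulary fallbacks are then re-decoded with the
#' BMES character HMM (when supplied) and merged into OOV words.
#'
#' @param sentence character scalar.
#' @param lex `lexicon` or `lex_trie`.
#' @param hmm optional `hmm_model` for unknown-word formation.
#' @param rules named regex vector, or NULL to skip the rule stage.
#' @param oov_floor see [max_prob_segment()].
#' @return a `segmentation` with per-token `source` in DICT / RULE / OOV.
#' @export
segment <- function(sentence, lex, hmm = NULL, rules = default_rules(),
                    oov_floor = 1e-3) {
  stopifnot(is.character(sentence), length(sentence) == 1L, nzchar(sentence))
  trie <- if (inherits(lex, "lex_trie")) lex else build_trie(lex)
  frozen <- if (is.null(rules)) {
    data.frame(start = integer(0), end = integer(0),
               token = character(0), rule_id = character(0))
  } else {
    apply_rule_patterns(sentence, rules)
  }

  tokens <- character(0); starts <- integer(0); ends <- integer(0); src <- character(0)
  n <- nchar(sentence)
  bounds <- rbind(frozen[, c("start", "end")], data.frame(start = n + 1L, end = n))
  pos <- 1L
  for (b in seq_len(nrow(bounds))) {
    if (pos < bounds$start[b]) {
      chunk_start <- pos
      chunk <- substr(sentence, chunk_start, bounds$start[b] - 1L)
      seg <- max_prob_segment(chunk, trie, oov_floor)
      seg <- merge_oov_runs(seg, chunk, hmm)
      tokens <- c(tokens, seg$tokens)
      starts <- c(starts, seg$spans[, "start"] + chunk_start - 1L)
      ends <- c(ends, seg$spans[, "end"] + chunk_start - 1L)
      src <- c(src, seg$source)
    }
    if (b <= nrow(frozen)) {
      tokens <- c(tokens, frozen$token[b])
      starts <- c(starts, frozen$start[b])
      ends <- c(ends, frozen$end[b])
      src <- c(src, "RULE")
      pos <- frozen$end[b] + 1L
    }
  }
  new_segmentation(tokens, starts, ends, src)
}

# Re-decode maximal runs (length >= 2) of single-symbol OOV fallbacks with
# the character HMM and merge them into words along the BMES tags.
merge_oov_runs <- function(seg, chunk, hmm) {
  if (is.null(hmm)) return(seg)
  is_oov1 <- seg$source == "OOV" & nchar(seg$tokens) == 1L
  if (!any(is_oov1)) return(seg)
  r <- rle(is_oov1)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  out_tok <- character(0); out_s <- integer(0); out_e <- integer(0); out_src <- character(0)
  for (k in seq_along(r$lengths)) {
    idx <- run_start[k]:run_end[k]
    if (r$values[k] && r$lengths[k] >= 2L) {
      span_s <- seg$spans[idx[1L], "start"]
      span_e <- seg$spans[idx[length(idx)], "end"]
      syms <- strsplit(substr(chunk, span_s, span_e), "", fixed = TRUE)[[1]]
      tags <- viterbi_decode(syms, hmm)
      w_end <- which(tags %in% c("E", "S"))
      w_start <- c(1L, utils::head(w_end, -1L) + 1L)
      out_tok <- c(out_tok, substring(substr(chunk, span_s, span_e), w_start, w_end))
      out_s <- c(out_s, span_s + w_start - 1L)
      out_e <- c(out_e, span_s + w_end - 1L)
      out_src <- c(out_src, rep("OOV", length(w_end)))
    } else {
      out_tok <- c(out_tok, seg$tokens[idx])
      out_s <- c(out_s, seg$spans[idx, "start"])
      out_e <- c(out_e, seg$spans[idx, "end"])
      out_src <- c(out_src, seg$source[idx])
    }
  }
  new_segmentation(out_tok, out_s, out_e, out_src)
}
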