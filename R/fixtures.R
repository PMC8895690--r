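new_tagged_corpus <- function(sentences) {
  for (s in sentences) {
    if (length(s$symbols) != length(s$tags))
      stop("symbol and tag sequences must align")
  }
  structure(list(sentences = sentences, tagset = BMES), class = "tagged_corpus")
}

#' @export
print.tagged_corpus <- function(x, ...) {
  n <- length(x$sentences)
  lens <- vapply(x$sentences, function(s) length(s$symbols), 0L)
  cat(sprintf("<tagged_corpus> %d sentences, mean length %.1f symbols\n",
              n, mean(lens)))
  invisible(x)
}

word_tags <- function(word) {
  n <- nchar(word)
  if (n == 1L) "S" else c("B", rep("M", n - 2L), "E")
}

#' Generate a BMES-tagged corpus from a lexicon
#'
#' Sentences are concatenations of frequency-weighted lexicon words; with
#' probability `oov_rate` a token position instead receives an injected
#' out-of-vocabulary word (length 2-4 over the same alphabet, absent from
#' the lexicon). Tags record the true word boundaries; each sentence also
#' keeps the ground-truth word list and a per-word OOV flag.
#'
#' @param lex a `lexicon`.
#' @param n_sentences number of sentences.
#' @param oov_rate in [0,1): expected fraction of OOV word tokens.
#' @param seed integer seed.
#' @param words_per_sentence integer range (min, max) of words per sentence.
#' @return a `tagged_corpus`.
#' @export
generate_tagged_corpus <- function(lex, n_sentences, oov_rate = 0, seed = 1L,
                                   words_per_sentence = c(3L, 8L)) {
  stopifnot(inherits(lex, "lexicon"))
  if (oov_rate < 0 || oov_rate >= 1) stop("oov_rate must be in [0,1)")
  if (n_sentences < 1L) stop("n_sentences must be >= 1")
  alph <- lexicon_alphabet(lex)
  vocab <- names(lex$entries)
  wfreq <- lex$entries
  rand_oov <- function() {
    repeat {
      w <- paste(sample(alph, sample(2:4, 1L), replace = TRUE), collapse = "")
      if (!w %in% vocab) return(w)
    }
  }
  withr::with_seed(seed, {
    sentences <- vector("list", n_sentences)
    for (i in seq_len(n_sentences)) {
      k <- sample(words_per_sentence[1L]:words_per_sentence[2L], 1L)
      oov <- stats::runif(k) < oov_rate
      words <- character(k)
      words[!oov] <- sample(vocab, sum(!oov), replace = TRUE, prob = wfreq)
      if (any(oov)) words[oov] <- vapply(seq_len(sum(oov)), function(j) rand_oov(), "")
      tags <- unlist(lapply(words, word_tags))
      symbols <- strsplit(paste(words, collapse = ""), "", fixed = TRUE)[[1]]
      sentences[[i]] <- list(symbols = symbols, tags = tags,
                             words = words, is_oov = oov)
    }
    new_tagged_corpus(sentences)
  })
}

#' Read / write a tagged corpus as JSON lines
#'
#' One JSON object per line with `symbols` and `tags` arrays.
#' @param corpus a `tagged_corpus`.
#' @param path file path.
#' @export
write_tagged_corpus <- function(corpus, path) {
  lines <- vapply(corpus$sentences, function(s)
    jsonlite::toJSON(list(symbols = s$symbols, tags = s$tags)), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_tagged_corpus
#' @export
read_tagged_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  sentences <- lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l)
    list(symbols = obj$symbols, tags = obj$tags,
         words = tags_to_words(obj$symbols, obj$tags), is_oov = logical(0))
  })
  new_tagged_corpus(sentences)
}

#' Built-in disease templates for fixture records
#'
#' Two small templates (an inguinal-hernia surgery case and an upper
#' gastrointestinal hemorrhage case) carrying discipline, overview text,
#' ICD-coded correct diagnoses and typical wrong differentials.
#' @return data.frame, one row per template, with list columns
#'   `correct_dx` and `error_dx` of (label, icd) records.
#' @export
disease_templates <- function() {
  data.frame(
    template_id = c("inguinal_hernia", "upper_gi_hemorrhage"),
    disease = c("Inguinal hernia", "Upper gastrointestinal hemorrhage"),
    discipline = c("General surgery department", "Gastroenterology dept"),
    overview = c("A mass in the right groin area was found for 2 years and pain for half a year",
                 "Black stool for 10 days"),
    correct_dx = I(list(
      data.frame(label = "Right inguinal hernia", icd = "K40.9"),
      data.frame(label = c("Chronic gastritis", "Duodenal ulcer"),
                 icd = c("K29.5", "K26.9"))
    )),
    error_dx = I(list(
      data.frame(label = "Lipoma in the groin area", icd = "D17.2"),
      data.frame(label = "Gastric cancer", icd = "C16.9")
    )),
    stringsAsFactors = FALSE
  )
}

#' Generate a standard question library
#'
#' Questions are canonical token sequences (5-7 lexicon words) spread over
#' the consultation / physical-exam / auxiliary-exam scenes. Token sequences
#' are resampled until (a) re-segmenting their concatenation reproduces the
#' tokens and (b) all pairs of questions sit at token edit distance >= 5,
#' so matching outcomes are unambiguous.
#'
#' @param lex a `lexicon`.
#' @param n_questions number of questions.
#' @param seed integer seed.
#' @param p_correct probability a question is a correct (clinically
#'   indicated) item for the case.
#' @return a `question_library` data.frame with columns `question_id`,
#'   `scene`, `display_text`, `canonical_tokens` (list), `answer_text`,
#'   `is_correct_item`, `score_weight`.
#' @export
generate_question_library <- function(lex, n_questions = 20L, seed = 1L,
                                      p_correct = 0.75) {
  stopifnot(inherits(lex, "lexicon"), n_questions >= 1L)
  trie <- build_trie(lex)
  vocab <- names(lex$entries)
  scenes <- c("consultation", "physical_exam", "auxiliary_exam")
  withr::with_seed(seed, {
    toks <- vector("list", n_questions)
    for (i in seq_len(n_questions)) {
      for (try in seq_len(500L)) {
        cand <- sample(vocab, sample(5:7, 1L), replace = FALSE)
        if (!identical(segment(paste(cand, collapse = ""), trie, rules = NULL)$tokens,
                       cand)) next
        ok <- TRUE
        if (i > 1L) {
          for (j in seq_len(i - 1L)) {
            if (edit_distance(cand, toks[[j]]) < 5L) { ok <- FALSE; break }
          }
        }
        if (ok) { toks[[i]] <- cand; break }
      }
      if (is.null(toks[[i]]))
        stop("could not place question ", i, "; lexicon too small for a separable library")
    }
    lib <- data.frame(
      question_id = sprintf("q%03d", seq_len(n_questions)),
      scene = sample(scenes, n_questions, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2)),
      display_text = vapply(toks, paste, "", collapse = ""),
      stringsAsFactors = FALSE
    )
    lib$canonical_tokens <- toks
    lib$answer_text <- sprintf("Finding reported for %s", lib$question_id)
    lib$is_correct_item <- stats::runif(n_questions) < p_correct
    lib$score_weight <- sample(1:5, n_questions, replace = TRUE)
    class(lib) <- c("question_library", "data.frame")
    lib
  })
}

#' Read / write a question library as a JSON array
#' @param lib a `question_library`.
#' @param path file path.
#' @export
write_question_library <- function(lib, path) {
  jsonlite::write_json(as.data.frame(lib), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_question_library
#' @export
read_question_library <- function(path) {
  lib <- jsonlite::read_json(path, simplifyVector = TRUE)
  lib$canonical_tokens <- lapply(lib$canonical_tokens, as.character)
  lib$is_correct_item <- as.logical(lib$is_correct_item)
  class(lib) <- c("question_library", "data.frame")
  lib
}

rand_string <- function(chars, n) paste(sample(chars, n, replace = TRUE), collapse = "")

#' Generate a synthetic source medical record
#'
#' The narrative sections contain, as standalone clauses, extractable answer
#' content for `ceiling(answer_coverage * nrow(library))` standard questions
#' (the returned `answer_manifest` names them). Filler clauses are rejected
#' until they stay at edit distance >= 5 from every question, so recovery by
#' the matching pipeline is exact. PII fields (name, id number, admission
#' time) are populated and the patient name is additionally embedded in the
#' narrative, mirroring free-text identity leakage.
#'
#' @param disease_template a `template_id` from [disease_templates()].
#' @param library a `question_library`.
#' @param answer_coverage in [0,1]: fraction of questions answerable from
#'   the narrative.
#' @param lex the `lexicon` the library was generated from (for filler).
#' @param seed integer seed.
#' @return a `source_record`.
#' @export
generate_source_record <- function(disease_template, library, answer_coverage,
                                   lex, seed = 1L) {
  tpl <- disease_templates()
  if (!disease_template %in% tpl$template_id)
    stop("unknown disease template: ", disease_template)
  if (answer_coverage < 0 || answer_coverage > 1)
    stop("answer_coverage must be in [0,1]")
  tpl <- tpl[tpl$template_id == disease_template, ]
  n_ans <- as.integer(ceiling(answer_coverage * nrow(library)))
  vocab <- names(lex$entries)
  trie <- build_trie(lex)

  withr::with_seed(seed, {
    covered <- if (n_ans > 0) sort(sample(nrow(library), n_ans)) else integer(0)
    filler <- function() {
      for (try in seq_len(500L)) {
        cand <- sample(vocab, sample(6:8, 1L), replace = FALSE)
        seg <- segment(paste(cand, collapse = ""), trie, rules = NULL)$tokens
        ok <- all(vapply(library$canonical_tokens,
                         function(q) edit_distance(seg, q) >= 5L, NA))
        if (ok) return(paste(cand, collapse = ""))
      }
      stop("could not build a non-matching filler clause")
    }
    answer_clauses <- library$display_text[covered]
    sections <- c("chief_complaint", "present_illness", "past_history",
                  "personal_history", "family_history", "physical_exam")
    assign_to <- sample(sections, length(answer_clauses), replace = TRUE)
    name_val <- local({
      # the name lands in the narrative as a clause; keep it unmatchable
      for (try in seq_len(500L)) {
        nm <- rand_string(letters, 6L)
        seg <- segment(nm, trie, rules = NULL)$tokens
        if (all(vapply(library$canonical_tokens,
                       function(q) edit_distance(seg, q) >= 5L, NA))) return(nm)
      }
      stop("could not draw a non-matching patient name")
    })
    narrative <- stats::setNames(vector("list", length(sections)), sections)
    for (s in sections) {
      clauses <- c(filler(), answer_clauses[assign_to == s])
      narrative[[s]] <- paste0(paste(clauses, collapse = "."), ".")
    }
    # embedded free-text PII, as happens in real notes
    narrative$present_illness <- paste0(name_val, ".", narrative$present_illness)

    structured <- list(
      name = name_val,
      id_number = rand_string(as.character(0:9), 10L),
      admission_time = sprintf("2021-%02d-%02d", sample(12, 1L), sample(28, 1L)),
      gender = sample(c("F", "M"), 1L),
      report_table = list(hemoglobin = round(stats::runif(1, 90, 150), 1),
                          wbc = round(stats::runif(1, 4, 12), 1))
    )
    structure(
      list(record_id = sprintf("rec-%s-%05d", disease_template, sample(89999L, 1L) + 10000L),
           disease_template = disease_template,
           structured = structured,
           narrative = narrative,
           true_diagnoses = tpl$correct_dx[[1]],
           error_diagnosis_options = tpl$error_dx[[1]],
           pii_manifest = c(name = structured$name,
                            id_number = structured$id_number,
                            admission_time = structured$admission_time),
           answer_manifest = library$question_id[covered],
           deidentified = FALSE),
      class = "source_record"
    )
  })
}

#' @export
print.source_record <- function(x, ...) {
  cat(sprintf("<source_record> %s (%s), %d narrative sections, %d answerable questions%s\n",
              x$record_id, x$disease_template, length(x$narrative),
              length(x$answer_manifest),
              if (isTRUE(x$deidentified)) ", de-identified" else ""))
  invisible(x)
}

#' Simulate a student playing a case
#'
#' Each correct scoring item is attempted independently with probability
#' `competence`; incorrect/distractor items are picked with probability
#' `0.3 * (1 - competence)`. Completion time is the recommended time scaled
#' by `(2 - competence)` with small lognormal noise. The trace can be
#' replayed through the session engine with [run_trace()].
#'
#' @param playable a `playable_case`.
#' @param competence in [0,1].
#' @param seed integer seed.
#' @param time_noise_sd lognormal sd of the completion-time factor.
#' @return a `student_trace`.
#' @export
simulate_student <- function(playable, competence, seed = 1L, time_noise_sd = 0.05) {
  stopifnot(inherits(playable, "playable_case"))
  if (competence < 0 || competence > 1) stop("competence must be in [0,1]")
  case <- playable$base
  qs <- playable_questions(playable)
  withr::with_seed(seed, {
    pick <- function(correct) {
      p <- ifelse(correct, competence, 0.3 * (1 - competence))
      stats::runif(length(p)) < p
    }
    ask_rows <- qs[pick(qs$is_correct_item), , drop = FALSE]
    actions <- data.frame(kind = character(0), scene = character(0),
                          category = character(0), text = character(0),
                          id = character(0), stringsAsFactors = FALSE)
    add <- function(kind, scene = NA, category = NA, text = NA, id = NA) {
      rbind(actions, data.frame(kind = kind, scene = scene, category = category,
                                text = text, id = id, stringsAsFactors = FALSE))
    }
    for (i in seq_len(nrow(ask_rows)))
      actions <- add("ask", scene = ask_rows$scene[i], text = ask_rows$display_text[i])

    dx <- case$diagnoses
    sel_dx <- pick(dx$is_correct)
    for (i in which(sel_dx))
      actions <- add("diagnosis", text = dx$label[i])

    for (cat in c("bases", "treatments")) {
      items <- case[[cat]]
      sel <- pick(items$is_correct)
      for (i in which(sel)) {
        if (items$item_id[i] %in% playable$free_entry_items)
          actions <- add("enter", category = cat, text = items$text[i])
        else
          actions <- add("select", category = cat, id = items$item_id[i])
      }
    }
    t_act <- case$recommended_completion_time * (2 - competence) *
      exp(stats::rnorm(1, 0, time_noise_sd))
    structure(list(competence = competence, actions = actions,
                   t_act = t_act, seed = seed),
              class = "student_trace")
  })
}

#' @export
print.student_trace <- function(x, ...) {
  cat(sprintf("<student_trace> competence %.2f, %d actions, completion %.0f s\n",
              x$competence, nrow(x$actions), x$t_act))
  invisible(x)
}
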