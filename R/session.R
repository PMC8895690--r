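QUESTION_SCENES <- c("consultation", "physical_exam", "auxiliary_exam")
ALL_SCENES <- c(QUESTION_SCENES, "diagnosis", "treatment")

scene_category <- c(consultation = "inquiries",
                    physical_exam = "physical_exams",
                    auxiliary_exam = "auxiliary_exams")

log_event <- function(session, time, kind, payload) {
  if (length(session$log) && time < session$log[[length(session$log)]]$time)
    stop("timestamps must be monotone")
  session$log[[length(session$log) + 1L]] <-
    list(time = time, scene = session$current_scene, kind = kind,
         payload = payload)
  session
}

next_time <- function(session, at) {
  if (!is.null(at)) return(as.numeric(at))
  if (length(session$log)) session$log[[length(session$log)]]$time + 1 else 0
}

#' Start a learning session on a playable case
#'
#' Sessions are pure values: every operation returns the updated session,
#' appends to its action log, and the log alone replays to the identical
#' final state (see [replay_log()]).
#'
#' @param playable a `playable_case` (its base case must be released).
#' @param student_id identifier for the learner.
#' @param at start time (seconds); defaults to 0.
#' @return a `learning_session` in scene "consultation".
#' @export
start_session <- function(playable, student_id = "student", at = 0) {
  stopifnot(inherits(playable, "playable_case"))
  if (playable$base$review_status != "released")
    stop("sessions require a released case")
  session <- structure(
    list(session_id = sprintf("sess-%s-%s", playable$base$case_id, student_id),
         case = playable,
         student_id = student_id,
         current_scene = "consultation",
         asked = list(),
         selections = list(inquiries = character(0),
                           physical_exams = character(0),
                           auxiliary_exams = character(0),
                           diagnoses = character(0),
                           bases = character(0),
                           treatments = character(0)),
         error_diagnoses = character(0),
         free_entry_misses = character(0),
         pending_candidates = NULL,
         last_response = NULL,
         start_time = as.numeric(at),
         end_time = NULL,
         finished = FALSE,
         log = list()),
    class = "learning_session"
  )
  log_event(session, as.numeric(at), "start", list(student_id = student_id))
}

#' @export
print.learning_session <- function(x, ...) {
  sel <- vapply(x$selections, length, 0L)
  cat(sprintf("<learning_session> %s, scene %s%s\n", x$session_id,
              x$current_scene, if (x$finished) " (finished)" else ""))
  cat("  selections:", paste(sprintf("%s=%d", names(sel), sel), collapse = " "), "\n")
  invisible(x)
}

assert_active <- function(session) {
  if (session$finished) stop("session is finished")
  invisible(session)
}

#' Switch the active scene
#'
#' Learners may move between scenes at any time without losing selections.
#' @param session a `learning_session`.
#' @param scene one of consultation, physical_exam, auxiliary_exam,
#'   diagnosis, treatment.
#' @param at optional timestamp.
#' @export
switch_scene <- function(session, scene, at = NULL) {
  assert_active(session)
  if (!scene %in% ALL_SCENES) stop("unknown scene: ", scene)
  t <- next_time(session, at)
  session <- log_event(session, t, "switch_scene", list(scene = scene))
  session$current_scene <- scene
  session$pending_candidates <- NULL
  session
}

#' Ask a free-text question in the current scene
#'
#' Routes the text through [match_question()] against the questions of the
#' current scene (distractors included). An exact match returns the answer
#' and marks the item collected (idempotently); candidates are held pending
#' [confirm_candidate()]; a deviation logs the configured message.
#'
#' @param session a `learning_session` in a question scene.
#' @param text free-text question.
#' @param at optional timestamp.
#' @return the updated session; the response is in `$last_response`
#'   (fields `outcome` and `answer`/`candidates`/`message`).
#' @export
ask <- function(session, text, at = NULL) {
  assert_active(session)
  scene <- session$current_scene
  if (!scene %in% QUESTION_SCENES)
    stop("scene ", scene, " does not take free-text questions")
  qs <- playable_questions(session$case)
  qs_scene <- qs[qs$scene == scene, ]
  if (nrow(qs_scene) == 0L) stop("no questions configured for scene ", scene)
  res <- match_question(text, qs_scene, session$case$base$pipeline)
  t <- next_time(session, at)
  session <- log_event(session, t, "ask",
                       list(text = text, outcome = res$outcome,
                            distance = res$distance))
  session$asked[[length(session$asked) + 1L]] <-
    list(text = text, result = res, time = t)
  if (res$outcome == "EXACT") {
    cat_name <- scene_category[[scene]]
    session$selections[[cat_name]] <-
      union(session$selections[[cat_name]], res$matched$question_id)
    session$pending_candidates <- NULL
    session$last_response <- list(outcome = "EXACT",
                                  question_id = res$matched$question_id,
                                  answer = res$matched$answer_text)
  } else if (res$outcome == "CANDIDATES") {
    session$pending_candidates <- res$candidates
    session$last_response <- list(outcome = "CANDIDATES",
                                  candidates = res$candidates)
  } else {
    session$pending_candidates <- NULL
    session$last_response <- list(outcome = "DEVIATED", message = res$message)
  }
  session
}

#' Confirm one question from the pending candidate list
#'
#' @param session a `learning_session` with pending candidates.
#' @param question_id id chosen from the candidate list.
#' @param at optional timestamp.
#' @return updated session; answer in `$last_response$answer`.
#' @export
confirm_candidate <- function(session, question_id, at = NULL) {
  assert_active(session)
  if (is.null(session$pending_candidates) ||
      !question_id %in% session$pending_candidates$question_id)
    stop("question_id is not in the pending candidate list")
  qs <- playable_questions(session$case)
  row <- qs[qs$question_id == question_id, ]
  t <- next_time(session, at)
  session <- log_event(session, t, "confirm", list(question_id = question_id))
  cat_name <- scene_category[[row$scene]]
  session$selections[[cat_name]] <-
    union(session$selections[[cat_name]], question_id)
  session$pending_candidates <- NULL
  session$last_response <- list(outcome = "CONFIRMED",
                                question_id = question_id,
                                answer = row$answer_text)
  session
}

#' Submit a diagnosis in free text
#'
#' The text is matched (case-insensitively, after trimming) against the
#' case's ICD-coded diagnosis list. A correct diagnosis joins the learner's
#' differential; anything else is recorded as an error diagnosis for the
#' teacher's report.
#'
#' @param session a `learning_session` in scene "diagnosis".
#' @param text diagnosis label.
#' @param at optional timestamp.
#' @return updated session; `$last_response$correct` gives the verdict.
#' @export
submit_diagnosis <- function(session, text, at = NULL) {
  assert_active(session)
  if (session$current_scene != "diagnosis")
    stop("diagnoses are submitted in scene 'diagnosis'")
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("diagnosis text must be a non-empty string")
  dx <- session$case$base$diagnoses
  norm <- function(x) tolower(trimws(x))
  hit <- which(norm(dx$label) == norm(text))
  t <- next_time(session, at)
  correct <- length(hit) == 1L && dx$is_correct[hit]
  session <- log_event(session, t, "diagnosis",
                       list(text = text, correct = correct))
  if (correct) {
    session$selections$diagnoses <-
      union(session$selections$diagnoses, dx$dx_id[hit])
    session$last_response <- list(outcome = "CORRECT", correct = TRUE,
                                  dx_id = dx$dx_id[hit], icd = dx$icd[hit])
  } else {
    session$error_diagnoses <- union(session$error_diagnoses, text)
    session$last_response <- list(outcome = "ERROR", correct = FALSE)
  }
  session
}

#' Select basis / treatment items by id
#'
#' Selections are sets (re-selection is a no-op); correctness flags come
#' from the case ground truth at scoring time. Items marked free-entry at
#' the current difficulty level must be typed via [enter_item()] instead.
#'
#' @param session a `learning_session`.
#' @param category "bases" or "treatments".
#' @param ids item ids.
#' @param at optional timestamp.
#' @export
select_items <- function(session, category, ids, at = NULL) {
  assert_active(session)
  if (!category %in% c("bases", "treatments")) stop("unknown category: ", category)
  valid <- session$case$base[[category]]$item_id
  bad <- setdiff(ids, valid)
  if (length(bad)) stop("unknown item id(s): ", paste(bad, collapse = ", "))
  fe <- intersect(ids, session$case$free_entry_items)
  if (length(fe))
    stop("free-entry item(s) must be typed, not selected: ",
         paste(fe, collapse = ", "))
  t <- next_time(session, at)
  session <- log_event(session, t, "select",
                       list(category = category, ids = ids))
  session$selections[[category]] <- union(session$selections[[category]], ids)
  session
}

#' Type a free-entry basis / treatment item
#'
#' Free text is matched against the item texts (case-insensitive, trimmed);
#' an unmatched entry is logged as a free-entry miss.
#'
#' @inheritParams select_items
#' @param text typed item text.
#' @export
enter_item <- function(session, category, text, at = NULL) {
  assert_active(session)
  if (!category %in% c("bases", "treatments")) stop("unknown category: ", category)
  items <- session$case$base[[category]]
  norm <- function(x) tolower(trimws(x))
  hit <- which(norm(items$text) == norm(text))
  t <- next_time(session, at)
  session <- log_event(session, t, "enter",
                       list(category = category, text = text,
                            matched = length(hit) == 1L))
  if (length(hit) == 1L) {
    session$selections[[category]] <-
      union(session$selections[[category]], items$item_id[hit])
    session$last_response <- list(outcome = "ENTERED",
                                  item_id = items$item_id[hit])
  } else {
    session$free_entry_misses <- c(session$free_entry_misses, text)
    session$last_response <- list(outcome = "MISS")
  }
  session
}

#' Progress analysis: collected factors, hypotheses, important missing items
#'
#' Important items are correct scoring items whose weight reaches the
#' importance cutoff (default: the 75th percentile of the case's correct
#' item weights) and that have not been collected yet.
#'
#' @param session a `learning_session`.
#' @param importance_cutoff numeric weight cutoff, or NULL for the default.
#' @return class `progress_analysis`: `collected_factors`, `hypotheses`,
#'   `missing_important`.
#' @export
analyze_progress <- function(session, importance_cutoff = NULL) {
  stopifnot(inherits(session, "learning_session"))
  items <- scoring_items(session$case$base)
  correct <- items[items$is_correct, ]
  if (is.null(importance_cutoff))
    importance_cutoff <- stats::quantile(correct$score_weight, 0.75,
                                         names = FALSE, type = 7)
  collected <- unlist(session$selections, use.names = FALSE)
  important <- correct$item_id[correct$score_weight >= importance_cutoff]
  structure(
    list(collected_factors = collected,
         hypotheses = session$selections$diagnoses,
         missing_important = setdiff(important, collected),
         importance_cutoff = importance_cutoff),
    class = "progress_analysis"
  )
}

#' Finish a session
#'
#' Sets the end time and seals the log; a finished session rejects all
#' further actions, and double-finishing errors.
#'
#' @param session a `learning_session`.
#' @param at end time (seconds); defaults to one tick after the last event.
#' @return the finished session (its `$log` is the replayable action log).
#' @export
finish <- function(session, at = NULL) {
  assert_active(session)
  t <- next_time(session, at)
  session <- log_event(session, t, "finish", list())
  session$end_time <- t
  session$finished <- TRUE
  session
}

#' Replay an action log against a playable case
#'
#' Re-executes every logged event through the session operations; the
#' reconstructed state equals the original final state (replay
#' determinism).
#'
#' @param playable the `playable_case` the log was recorded on.
#' @param log a session `$log` (list of events).
#' @return the reconstructed `learning_session`.
#' @export
replay_log <- function(playable, log) {
  stopifnot(length(log) >= 1L, log[[1L]]$kind == "start")
  session <- start_session(playable, log[[1L]]$payload$student_id,
                           at = log[[1L]]$time)
  for (ev in log[-1L]) {
    session <- switch(ev$kind,
      switch_scene = switch_scene(session, ev$payload$scene, at = ev$time),
      ask = ask(session, ev$payload$text, at = ev$time),
      confirm = confirm_candidate(session, ev$payload$question_id, at = ev$time),
      diagnosis = submit_diagnosis(session, ev$payload$text, at = ev$time),
      select = select_items(session, ev$payload$category,
                            unlist(ev$payload$ids), at = ev$time),
      enter = enter_item(session, ev$payload$category, ev$payload$text,
                         at = ev$time),
      finish = finish(session, at = ev$time),
      stop("unknown event kind in log: ", ev$kind)
    )
  }
  session
}

#' Write / read an action log as JSON lines
#' @param log a session `$log`.
#' @param path file path.
#' @export
write_action_log <- function(log, path) {
  lines <- vapply(log, function(ev)
    as.character(jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA)), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_action_log
#' @export
read_action_log <- function(path) {
  lapply(readLines(path, encoding = "UTF-8"),
         function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' Drive a session from a simulated student trace
#'
#' Executes the trace's asks, diagnoses, selections and entries through the
#' session engine in scene order and finishes at the trace's completion
#' time.
#'
#' @param playable a `playable_case`.
#' @param trace a `student_trace` from [simulate_student()].
#' @param student_id learner identifier.
#' @return the finished `learning_session`.
#' @export
run_trace <- function(playable, trace, student_id = "sim") {
  stopifnot(inherits(trace, "student_trace"))
  session <- start_session(playable, student_id, at = 0)
  acts <- trace$actions
  for (scene in QUESTION_SCENES) {
    rows <- acts[acts$kind == "ask" & acts$scene == scene, , drop = FALSE]
    if (nrow(rows) == 0L) next
    session <- switch_scene(session, scene)
    for (i in seq_len(nrow(rows))) session <- ask(session, rows$text[i])
  }
  dx_rows <- acts[acts$kind == "diagnosis", , drop = FALSE]
  sel_rows <- acts[acts$kind %in% c("select", "enter"), , drop = FALSE]
  if (nrow(dx_rows) || nrow(sel_rows))
    session <- switch_scene(session, "diagnosis")
  for (i in seq_len(nrow(dx_rows)))
    session <- submit_diagnosis(session, dx_rows$text[i])
  for (i in seq_len(nrow(sel_rows))) {
    if (sel_rows$kind[i] == "select")
      session <- select_items(session, sel_rows$category[i], sel_rows$id[i])
    else
      session <- enter_item(session, sel_rows$category[i], sel_rows$text[i])
  }
  finish(session, at = trace$t_act)
}
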