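consult_q <- function(playable, correct = TRUE) {
  q <- playable$base$questions
  q <- q[q$scene == "consultation" & q$is_correct_item == correct, ]
  q[1L, ]
}

test_that("sessions start empty, require released cases, and are independent", {
  s <- start_session(tfx$playable, "stu1", at = 0)
  expect_identical(s$current_scene, "consultation")
  expect_true(all(vapply(s$selections, length, 0L) == 0L))
  expect_length(s$log, 1L)

  draft <- build_case(tfx$clean, tfx$lib, tfx$pipeline, seed = 131L)
  fake_playable <- structure(list(base = draft, level = 1L,
                                  visible_answers = TRUE,
                                  distractors = draft$questions[0, ],
                                  free_entry_items = character(0)),
                             class = "playable_case")
  expect_error(start_session(fake_playable), "released")

  s2 <- start_session(tfx$playable, "stu2", at = 0)
  s2 <- ask(s2, consult_q(tfx$playable)$display_text)
  expect_length(s2$selections$inquiries, 1L)
  expect_length(s$selections$inquiries, 0L)  # s untouched
})

test_that("ask routes to answer / candidates / deviation and is idempotent", {
  q <- consult_q(tfx$playable)
  s <- start_session(tfx$playable, "stu", at = 0)
  s <- ask(s, q$display_text)
  expect_identical(s$last_response$outcome, "EXACT")
  expect_identical(s$last_response$answer, q$answer_text)
  expect_identical(s$selections$inquiries, q$question_id)

  # asking again returns the same answer, selection set unchanged
  s <- ask(s, q$display_text)
  expect_identical(s$last_response$answer, q$answer_text)
  expect_identical(s$selections$inquiries, q$question_id)

  # off-library text deviates with the verbatim message
  off <- paste(rep("zq", 8L), collapse = "")
  s <- ask(s, off)
  expect_identical(s$last_response$outcome, "DEVIATED")
  expect_identical(s$last_response$message,
                   "You have deviated from the correct process")

  expect_error(ask(switch_scene(s, "diagnosis"), q$display_text),
               "does not take free-text")
})

test_that("near-miss questions go through candidate confirmation", {
  q <- consult_q(tfx$playable)
  toks <- q$canonical_tokens[[1L]]
  near <- paste(toks[-length(toks)], collapse = "")  # small nonzero distance
  s <- start_session(tfx$playable, "stu", at = 0)
  s <- ask(s, near)
  expect_identical(s$last_response$outcome, "CANDIDATES")
  expect_true(q$question_id %in% s$pending_candidates$question_id)
  expect_length(s$selections$inquiries, 0L)  # no state change before confirm

  expect_error(confirm_candidate(s, "not-a-candidate"), "candidate")
  s <- confirm_candidate(s, q$question_id)
  expect_identical(s$last_response$answer, q$answer_text)
  expect_identical(s$selections$inquiries, q$question_id)

  # confirm then re-ask exactly: selection unchanged
  s <- ask(s, q$display_text)
  expect_identical(s$selections$inquiries, q$question_id)
})

test_that("diagnosis submission checks the ICD-coded list and records errors", {
  s <- start_session(tfx$playable, "stu", at = 0)
  s <- switch_scene(s, "diagnosis")

  s <- submit_diagnosis(s, "Right inguinal hernia")
  expect_true(s$last_response$correct)
  expect_identical(s$last_response$icd, "K40.9")
  expect_length(s$selections$diagnoses, 1L)

  s <- submit_diagnosis(s, "Lipoma in the groin area")
  expect_false(s$last_response$correct)
  expect_identical(s$error_diagnoses, "Lipoma in the groin area")

  expect_error(submit_diagnosis(s, "  "), "non-empty")
  expect_error(submit_diagnosis(switch_scene(s, "consultation"), "x"),
               "scene 'diagnosis'")
})

test_that("item selection validates ids, is set-valued, flags free entry", {
  case <- tfx$playable$base
  s <- start_session(tfx$playable, "stu", at = 0)
  correct_bases <- case$bases$item_id[case$bases$is_correct]
  wrong_base <- case$bases$item_id[!case$bases$is_correct][1L]

  s <- select_items(s, "bases", correct_bases)
  expect_setequal(s$selections$bases, correct_bases)
  s <- select_items(s, "bases", c(correct_bases[1L], wrong_base))
  expect_setequal(s$selections$bases, c(correct_bases, wrong_base))
  expect_error(select_items(s, "bases", "nope"), "unknown item")

  # level-4 play: every scoring item is free entry; typed entry collects it
  l4 <- apply_difficulty(tfx$case, 4L, seed = 132L)
  s4 <- start_session(l4, "stu4", at = 0)
  expect_error(select_items(s4, "bases", correct_bases[1L]), "free-entry")
  s4 <- enter_item(s4, "bases", case$bases$text[case$bases$is_correct][1L])
  expect_identical(s4$last_response$outcome, "ENTERED")
  expect_length(s4$selections$bases, 1L)
  s4 <- enter_item(s4, "bases", "gibberish entry")
  expect_identical(s4$last_response$outcome, "MISS")
  expect_identical(s4$free_entry_misses, "gibberish entry")
})

test_that("progress analysis lists collected factors and important missing items", {
  s <- start_session(tfx$playable, "stu", at = 0)
  p0 <- analyze_progress(s)
  items <- scoring_items(tfx$playable$base)
  correct <- items[items$is_correct, ]
  important <- correct$item_id[correct$score_weight >= p0$importance_cutoff]
  expect_setequal(p0$missing_important, important)
  expect_length(p0$collected_factors, 0L)

  full <- perfect_session()
  pf <- analyze_progress(full)
  expect_length(pf$missing_important, 0L)
  expect_length(intersect(pf$missing_important, pf$collected_factors), 0L)

  # cutoff above the maximum weight: nothing is "important"
  high <- analyze_progress(s, importance_cutoff = max(correct$score_weight) + 1)
  expect_length(high$missing_important, 0L)
})

test_that("finishing seals the session and replaying the log reconstructs it", {
  q <- consult_q(tfx$playable)
  s <- start_session(tfx$playable, "stu", at = 0)
  s <- ask(s, q$display_text)
  s <- switch_scene(s, "diagnosis")
  s <- submit_diagnosis(s, "Right inguinal hernia")
  s <- select_items(s, "treatments",
                    tfx$playable$base$treatments$item_id[1L])
  s <- finish(s, at = 400)
  expect_identical(s$end_time, 400)
  expect_error(finish(s), "finished")
  expect_error(ask(s, q$display_text), "finished")

  replayed <- replay_log(tfx$playable, s$log)
  expect_equal(replayed, s)

  # replay equivalence for fuzzed simulated sessions
  for (k in 1:5) {
    trace <- simulate_student(tfx$playable, 0.7, seed = 140L + k)
    sess <- run_trace(tfx$playable, trace)
    expect_equal(replay_log(tfx$playable, sess$log), sess)
  }

  # logs round-trip through JSON lines and replay identically
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_action_log(s$log, path)
  back <- read_action_log(path)
  expect_equal(replay_log(tfx$playable, back), s)
})

test_that("scene switching at any time preserves selections", {
  q <- consult_q(tfx$playable)
  s <- start_session(tfx$playable, "stu", at = 0)
  s <- ask(s, q$display_text)
  for (scene in c("physical_exam", "auxiliary_exam", "diagnosis",
                  "consultation"))
    s <- switch_scene(s, scene)
  expect_identical(s$selections$inquiries, q$question_id)
  expect_error(switch_scene(s, "pharmacy"), "unknown scene")
})
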