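test_that("the five indicator formulas are exact on worked examples", {
  expect_equal(score_rigor(mkinputs(bases_sel = 3, bases_tot = 4)), 75)
  expect_equal(score_rigor(mkinputs(bases_sel = 4, bases_tot = 4)), 100)
  expect_equal(score_rigor(mkinputs(bases_sel = 0, bases_tot = 4)), 0)

  # everything selected: missed terms vanish
  expect_equal(score_logic(mkinputs()), 100)
  # half selected in both categories: selected - missed = 0
  expect_equal(score_logic(mkinputs(inq_sel = 2, inq_tot = 4,
                                    pe_sel = 2, pe_tot = 4)), 0)
  # nothing selected: numerator clamps at 0
  expect_equal(score_logic(mkinputs(inq_sel = 0, inq_tot = 4,
                                    pe_sel = 0, pe_tot = 4)), 0)

  expect_equal(score_systematic(mkinputs(all_sel = 10, all_tot = 20)), 50)
  expect_equal(score_systematic(mkinputs(all_sel = 20, all_tot = 20)), 100)

  # agility: equal times and full score -> 100 * 4/5 * 1 = 80
  expect_equal(score_agility(mkinputs(t_act = 600)), 80)
  # four times the recommended time, full score -> 4/(4+4)
  expect_equal(score_agility(mkinputs(t_act = 2400)), 50)
  # instant completion at half the score -> 50 in the limit
  expect_equal(score_agility(mkinputs(t_act = 0, sel_score = 5)), 50)

  # weights {3,2,5}, selected {3,5} -> 8/10
  expect_equal(score_expansion(mkinputs(dx_sel = 8, dx_tot = 10)), 80)
  expect_equal(score_expansion(mkinputs(dx_sel = 10, dx_tot = 10)), 100)
  expect_equal(score_expansion(mkinputs(dx_sel = 0, dx_tot = 10)), 0)
})

test_that("systematic score equals the weighted recombination of category fractions", {
  case <- tfx$playable$base
  trace <- simulate_student(tfx$playable, 0.7, seed = 150L)
  sess <- run_trace(tfx$playable, trace)
  x <- session_score_inputs(sess)
  items <- scoring_items(case)
  correct <- items[items$is_correct &
                     !(items$category == "question" &
                         items$scene == "auxiliary_exam"), ]
  sel <- unlist(sess$selections, use.names = FALSE)
  expect_equal(score_systematic(x),
               100 * sum(correct$item_id %in% sel) / nrow(correct))
})

test_that("vacuous denominators score 100 and invalid inputs are rejected", {
  expect_message(v <- score_rigor(mkinputs(bases_sel = 0, bases_tot = 0)),
                 "vacuous")
  expect_equal(v, 100)
  expect_message(expect_equal(
    score_logic(mkinputs(inq_sel = 0, inq_tot = 0, pe_sel = 0, pe_tot = 0)),
    100))
  expect_message(expect_equal(
    score_systematic(mkinputs(all_sel = 0, all_tot = 0)), 100))
  expect_message(expect_equal(
    score_expansion(mkinputs(dx_sel = 0, dx_tot = 0)), 100))
  expect_error(score_agility(mkinputs(sel_score = 0, tot_score = 0)),
               "positive total score")

  expect_error(mkinputs(bases_sel = -1), "non-negative")
  expect_error(mkinputs(t_rec = 0), "recommended time")
  expect_error(mkinputs(sel_score = 11, tot_score = 10), "exceed")
})

test_that("indicator monotonicity: more hits never hurt, more time never helps", {
  base <- mkinputs(bases_sel = 2, bases_tot = 4, all_sel = 8, all_tot = 20,
                   dx_sel = 5, dx_tot = 10, sel_score = 6)
  expect_gte(score_rigor(mkinputs(bases_sel = 3)), score_rigor(base))
  expect_gte(score_systematic(mkinputs(all_sel = 9, all_tot = 20)),
             score_systematic(base))
  expect_gte(score_expansion(mkinputs(dx_sel = 6)),
             score_expansion(base))
  expect_gt(score_agility(mkinputs(t_act = 500)),
            score_agility(mkinputs(t_act = 700)))
  expect_gt(score_agility(mkinputs(sel_score = 8)),
            score_agility(mkinputs(sel_score = 6)))
})

test_that("a perfect learner at the recommended time scores 100/100/100/80/100", {
  sess <- perfect_session()
  rep <- suppressMessages(build_report(sess))
  expect_equal(unname(rep$scores[c("rigor", "logic", "systematic", "expansion")]),
               c(100, 100, 100, 100))
  expect_equal(unname(rep$scores[["agility"]]), 80)
  expect_equal(rep$total, mean(rep$scores))
  expect_identical(names(rep$radar),
                   c("rigor", "logic", "systematic", "agility", "expansion"))
})

test_that("an empty session scores zero on every non-vacuous indicator", {
  s <- finish(start_session(tfx$playable, "idle", at = 0), at = 600)
  rep <- suppressMessages(build_report(s))
  expect_equal(unname(rep$scores[c("rigor", "logic", "systematic", "expansion")]),
               c(0, 0, 0, 0))
  expect_equal(unname(rep$scores[["agility"]]), 0)
})

test_that("all indicators stay within [0,100] over fuzzed sessions", {
  comps <- withr::with_seed(161L, round(stats::runif(60), 2))
  for (k in 1:60) {
    trace <- simulate_student(tfx$playable, comps[k], seed = 160L + k)
    sess <- run_trace(tfx$playable, trace)
    rep <- suppressMessages(build_report(sess))
    expect_true(all(rep$scores >= 0 & rep$scores <= 100))
    expect_true(rep$total >= 0 && rep$total <= 100)
  }
})

test_that("error diagnoses surface in the teacher report with the case context", {
  s <- start_session(tfx$playable, "stu", at = 0)
  s <- switch_scene(s, "diagnosis")
  s <- submit_diagnosis(s, "Right inguinal hernia")
  s <- submit_diagnosis(s, "Lipoma in the groin area")
  s <- finish(s, at = 500)
  rep <- suppressMessages(build_report(s))
  err <- rep$error_diagnoses
  expect_identical(err$error_selected, "Lipoma in the groin area")
  expect_identical(err$correct_selected, "Right inguinal hernia")
  expect_identical(err$disease, "Inguinal hernia")
  expect_identical(err$discipline, "General surgery department")
  expect_identical(err$overview,
                   "A mass in the right groin area was found for 2 years and pain for half a year")

  path <- withr::local_tempfile(fileext = ".csv")
  write_error_diagnoses(list(rep), path)
  tab <- utils::read.csv(path)
  expect_identical(tab$error_selected, "Lipoma in the groin area")
})
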