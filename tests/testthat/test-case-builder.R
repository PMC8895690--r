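test_that("matching rate equals the answerable-question fraction", {
  lib10 <- generate_question_library(tfx$lex, 10L, seed = 101L)
  pipe <- match_pipeline(tfx$lex, hmm = tfx$hmm)

  full <- generate_source_record("inguinal_hernia", lib10, 1.0, tfx$lex, seed = 102L)
  expect_equal(compute_matching_rate(full, lib10, pipe), 1.0)

  nine <- generate_source_record("inguinal_hernia", lib10, 0.9, tfx$lex, seed = 103L)
  expect_equal(compute_matching_rate(nine, lib10, pipe), 0.9)

  empty <- full
  empty$narrative <- lapply(empty$narrative, function(x) "")
  expect_equal(compute_matching_rate(empty, lib10, pipe), 0)
})

test_that("rank_and_gate orders by rate, gates at the threshold, and is stable", {
  lib <- generate_question_library(tfx$lex, 20L, seed = 104L)
  pipe <- match_pipeline(tfx$lex, hmm = tfx$hmm)
  recs <- list(
    generate_source_record("inguinal_hernia", lib, 0.95, tfx$lex, seed = 105L),
    generate_source_record("upper_gi_hemorrhage", lib, 0.85, tfx$lex, seed = 106L),
    generate_source_record("inguinal_hernia", lib, 0.5, tfx$lex, seed = 107L)
  )
  out <- rank_and_gate(recs, lib, pipe, threshold = 0.90)
  expect_equal(out$rate, c(0.95, 0.85, 0.5))
  expect_identical(out$gated, c(TRUE, FALSE, FALSE))
  # output rates equal recomputation per record (no caching drift)
  for (i in seq_len(nrow(out)))
    expect_equal(out$rate[i],
                 compute_matching_rate(out$record[[i]], lib, pipe))

  # permuting the input leaves the output ordering unchanged
  out2 <- rank_and_gate(recs[c(3, 1, 2)], lib, pipe, threshold = 0.90)
  expect_identical(out2$record_id, out$record_id)
  expect_equal(out2$rate, out$rate)

  # all-equal rates order by record id
  same <- list(
    generate_source_record("inguinal_hernia", lib, 1, tfx$lex, seed = 108L),
    generate_source_record("upper_gi_hemorrhage", lib, 1, tfx$lex, seed = 109L)
  )
  tied <- rank_and_gate(same, lib, pipe)
  expect_identical(tied$record_id, sort(tied$record_id))
})

test_that("de-identification masks configured fields everywhere, irreversibly", {
  rec <- generate_source_record("inguinal_hernia", tfx$lib, 0.5, tfx$lex, seed = 110L)
  name <- rec$pii_manifest[["name"]]
  idno <- rec$pii_manifest[["id_number"]]
  clean <- deidentify(rec)

  expect_identical(clean$structured$name, strrep("*", nchar(name)))
  expect_identical(clean$structured$id_number, strrep("*", nchar(idno)))
  # the name embedded mid-narrative is masked there too
  expect_false(grepl(name, clean$narrative$present_illness, fixed = TRUE))
  expect_true(grepl(strrep("*", nchar(name)), clean$narrative$present_illness,
                    fixed = TRUE))
  # leak scan over the whole record finds nothing
  expect_length(pii_leak_scan(clean, c(name, idno)), 0L)
  # no mapping back: the manifest now holds masks only
  expect_false(any(c(name, idno) %in% clean$pii_manifest))

  # record with empty PII fields passes through unchanged
  blank <- rec
  blank$structured$name <- ""
  blank$structured$id_number <- ""
  blank$structured$admission_time <- ""
  blank$pii_manifest[] <- ""
  blank2 <- deidentify(blank)
  expect_identical(blank2$narrative, blank$narrative)

  # unknown custom field warns but does not fail
  expect_warning(
    deidentify(rec, deid_config(custom_fields = "shoe_size")),
    "shoe_size")
})

test_that("released cases never contain a PII manifest value (fuzz)", {
  lib <- generate_question_library(tfx$lex, 8L, seed = 111L)
  pipe <- match_pipeline(tfx$lex, hmm = tfx$hmm)
  for (k in 1:25) {
    tplid <- disease_templates()$template_id[k %% 2L + 1L]
    rec <- generate_source_record(tplid, lib, 0.8, tfx$lex, seed = 3000L + k)
    pii <- unname(rec$pii_manifest)
    case <- build_case(deidentify(rec), lib, pipe, seed = k)
    case <- review_actions(case, "release", pii_values = pii)
    scan_case <- case; scan_case$pipeline <- NULL
    expect_length(pii_leak_scan(scan_case, pii), 0L)
  }
})

test_that("review actions implement the draft/review/release state machine", {
  case <- build_case(tfx$clean, tfx$lib, tfx$pipeline, seed = 112L)
  expect_identical(case$review_status, "draft")

  item <- tfx$lib[1L, ]
  item$question_id <- "q999"
  edited <- review_actions(case, "add_item", item = item)
  expect_true("q999" %in% edited$questions$question_id)
  back <- review_actions(edited, "delete_item", item_id = "q999")
  expect_identical(back$questions$question_id, case$questions$question_id)

  case <- review_actions(case, "set_difficulty", difficulty = "complex")
  expect_identical(case$difficulty_class, "complex")
  expect_error(review_actions(case, "set_difficulty", difficulty = "hard"),
               "invalid difficulty")

  case <- review_actions(case, "submit")
  expect_identical(case$review_status, "under_review")
  released <- review_actions(case, "release", pii_values = tfx$pii)
  expect_identical(released$review_status, "released")
  expect_error(review_actions(released, "add_item", item = item),
               "released cases cannot be edited")
  expect_error(review_actions(released, "release"), "already released")

  # a case built from a leaking (un-deidentified) record cannot be released
  leaky_rec <- generate_source_record("inguinal_hernia", tfx$lib, 0.5,
                                      tfx$lex, seed = 113L)
  leaky <- build_case(leaky_rec, tfx$lib, tfx$pipeline, seed = 114L)
  expect_error(review_actions(leaky, "release",
                              pii_values = unname(leaky_rec$pii_manifest)),
               "PII leak")
})

test_that("difficulty levels configure answers, distractors and free entry", {
  case <- tfx$case

  l1 <- apply_difficulty(case, 1L, seed = 120L)
  expect_true(l1$visible_answers)
  expect_identical(nrow(l1$distractors), 0L)
  expect_length(l1$free_entry_items, 0L)

  l2 <- apply_difficulty(case, 2L, seed = 121L)
  expect_identical(nrow(l2$distractors),
                   as.integer(ceiling(0.3 * nrow(case$questions))))
  expect_true(all(!l2$distractors$is_correct_item))
  # originals untouched
  expect_identical(l2$base$questions$is_correct_item,
                   case$questions$is_correct_item)
  # determinism per seed
  expect_identical(apply_difficulty(case, 2L, seed = 121L)$distractors,
                   l2$distractors)
  # cross-case pool distractors are forced incorrect
  pool <- generate_question_library(tfx$lex, 10L, seed = 122L)
  pool$question_id <- paste0("x", pool$question_id)
  l2p <- apply_difficulty(case, 2L, seed = 123L, distractor_pool = pool)
  expect_true(all(!l2p$distractors$is_correct_item))
  expect_true(all(l2p$distractors$question_id %in% pool$question_id))

  l3 <- apply_difficulty(case, 3L, seed = 124L)
  items <- scoring_items(case)
  correct <- items[items$is_correct, ]
  expect_length(l3$free_entry_items, as.integer(ceiling(0.3 * nrow(correct))))
  # free-entry items are the top-weighted ones
  fe_w <- correct$score_weight[correct$item_id %in% l3$free_entry_items]
  other_w <- correct$score_weight[!correct$item_id %in% l3$free_entry_items]
  expect_gte(min(fe_w), max(other_w))

  l4 <- apply_difficulty(case, 4L, seed = 125L)
  expect_setequal(l4$free_entry_items, items$item_id)
  expect_false(l4$visible_answers)

  expect_error(apply_difficulty(case, 5L), "level")
  draft <- build_case(tfx$clean, tfx$lib, tfx$pipeline, seed = 126L)
  expect_error(apply_difficulty(draft, 1L), "released")
})
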