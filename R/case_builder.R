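#' Fraction of standard questions answerable from a record
#'
#' The record narrative is split into clauses; each clause is normalised by
#' the matching pipeline and a question counts as answerable when some
#' clause reaches a token edit distance below the candidate bound (default
#' 5) to its canonical tokens.
#'
#' @param record a `source_record`.
#' @param library a `question_library`.
#' @param pipeline a `match_pipeline`.
#' @return real in [0,1]; 0 for an empty narrative.
#' @export
compute_matching_rate <- function(record, library, pipeline) {
  stopifnot(inherits(record, "source_record"), nrow(library) > 0L)
  text <- unlist(record$narrative, use.names = FALSE)
  clauses <- unlist(strsplit(text, ".", fixed = TRUE), use.names = FALSE)
  clauses <- clauses[nzchar(clauses)]
  if (length(clauses) == 0L) return(0)
  toks <- lapply(clauses, normalize_question, pipeline = pipeline)
  bound <- pipeline$max_candidate_distance
  matched <- vapply(library$canonical_tokens, function(q) {
    any(vapply(toks, function(tt) edit_distance(tt, q) < bound, NA))
  }, NA)
  mean(matched)
}

#' Rank records by matching rate and apply the review gate
#'
#' Records are ordered by descending matching rate, ties broken by record
#' id; records at or above the threshold (default 0.90) are flagged for
#' submission to the review teacher.
#'
#' @param records list of `source_record`.
#' @param library a `question_library`.
#' @param pipeline a `match_pipeline`.
#' @param threshold gate threshold in [0,1].
#' @return data.frame with `record_id`, `rate`, `gated` and a list column
#'   `record`, in gate order.
#' @export
rank_and_gate <- function(records, library, pipeline, threshold = 0.90) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0,1]")
  rates <- vapply(records, compute_matching_rate, 0,
                  library = library, pipeline = pipeline)
  ids <- vapply(records, `[[`, "", "record_id")
  ord <- order(-rates, ids)
  out <- data.frame(record_id = ids[ord], rate = rates[ord],
                    gated = rates[ord] >= threshold,
                    stringsAsFactors = FALSE)
  out$record <- records[ord]
  out
}

#' De-identification configuration
#'
#' @param default_fields PII field names masked by default (name, id
#'   number, admission time).
#' @param custom_fields additional field names to mask.
#' @param mask_symbol masking character (default "*").
#' @export
deid_config <- function(default_fields = c("name", "id_number", "admission_time"),
                        custom_fields = character(0),
                        mask_symbol = "*") {
  if (length(default_fields) == 0L) stop("default_fields must be non-empty")
  structure(list(default_fields = default_fields,
                 custom_fields = custom_fields,
                 mask_symbol = mask_symbol),
            class = "deid_config")
}

mask_of <- function(value, symbol) strrep(symbol, nchar(value))

#' Irreversibly de-identify a source record
#'
#' Every configured field value is replaced by a mask of equal length, and
#' every occurrence of the original value anywhere else in the record
#' (narrative text included) is masked too. No mapping back to the original
#' values is retained: the returned manifest holds masks only.
#'
#' @param record a `source_record`.
#' @param config a `deid_config`.
#' @return the masked `source_record`, with `deidentified = TRUE`.
#' @export
deidentify <- function(record, config = deid_config()) {
  stopifnot(inherits(record, "source_record"))
  fields <- unique(c(config$default_fields, config$custom_fields))
  values <- character(0)
  for (f in fields) {
    v <- record$structured[[f]]
    if (is.null(v)) {
      if (f %in% config$custom_fields)
        warning("configured de-identification field not present: ", f)
      next
    }
    v <- as.character(v)
    if (!nzchar(v)) next
    values <- c(values, v)
    record$structured[[f]] <- mask_of(v, config$mask_symbol)
  }
  if (length(values)) {
    scrub <- function(x) {
      if (is.character(x)) {
        for (v in values) x <- gsub(v, mask_of(v, config$mask_symbol), x, fixed = TRUE)
        x
      } else if (is.list(x)) {
        lapply(x, scrub)
      } else x
    }
    record$narrative <- scrub(record$narrative)
    record$structured <- scrub(record$structured)
  }
  record$pii_manifest[] <- mask_of(record$pii_manifest, config$mask_symbol)
  record$deidentified <- TRUE
  record
}

#' Scan an object for PII value leaks
#'
#' Serialises the object to JSON and reports which of the given values
#' still appear as substrings anywhere.
#'
#' @param x any serialisable object (record, case, ...).
#' @param values character vector of original PII values.
#' @return character vector of leaked values (empty when clean).
#' @export
pii_leak_scan <- function(x, values) {
  values <- values[nzchar(values)]
  if (length(values) == 0L) return(character(0))
  blob <- as.character(jsonlite::toJSON(unclass_deep(x), auto_unbox = TRUE,
                                        force = TRUE, null = "null"))
  values[vapply(values, function(v) grepl(v, blob, fixed = TRUE), NA)]
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}

#' Build a virtual case from a (de-identified) source record
#'
#' Questions come from the standard library; diagnoses combine the record's
#' ICD-coded true diagnoses with its wrong differential options; diagnosis
#' bases and treatments are seeded scored items linked to the correct
#' diagnoses. The matching pipeline is attached so free-text play needs no
#' extra state. Cases start in review status "draft".
#'
#' @param record a `source_record` (normally after [deidentify()]).
#' @param library a `question_library`.
#' @param pipeline a `match_pipeline`.
#' @param seed integer seed for the scored-item draw.
#' @param recommended_time recommended completion time, seconds.
#' @param n_bases,n_treatments number of basis / treatment items.
#' @return a `virtual_case` (review status "draft").
#' @export
build_case <- function(record, library, pipeline, seed = 1L,
                       recommended_time = 600, n_bases = 6L, n_treatments = 4L) {
  stopifnot(inherits(record, "source_record"), inherits(library, "question_library"))
  if (recommended_time <= 0) stop("recommended_time must be positive")
  tpl <- disease_templates()
  tpl <- tpl[tpl$template_id == record$disease_template, ]
  dx <- rbind(
    cbind(record$true_diagnoses, is_correct = TRUE),
    cbind(record$error_diagnosis_options, is_correct = FALSE)
  )
  dx$dx_id <- sprintf("dx%02d", seq_len(nrow(dx)))
  dx$score_weight <- ifelse(dx$is_correct, 5, 0)

  withr::with_seed(seed, {
    correct_ids <- dx$dx_id[dx$is_correct]
    bases <- data.frame(
      item_id = sprintf("bas%02d", seq_len(n_bases)),
      text = sprintf("basis finding %02d", seq_len(n_bases)),
      diagnosis_id = sample(correct_ids, n_bases, replace = TRUE),
      is_correct = c(rep(TRUE, ceiling(n_bases * 2 / 3)),
                     rep(FALSE, n_bases - ceiling(n_bases * 2 / 3))),
      score_weight = sample(2:5, n_bases, replace = TRUE),
      stringsAsFactors = FALSE
    )
    bases$score_weight[!bases$is_correct] <- 0
    treatments <- data.frame(
      item_id = sprintf("trt%02d", seq_len(n_treatments)),
      text = sprintf("treatment plan %02d", seq_len(n_treatments)),
      is_correct = c(rep(TRUE, ceiling(n_treatments * 3 / 4)),
                     rep(FALSE, n_treatments - ceiling(n_treatments * 3 / 4))),
      score_weight = sample(2:5, n_treatments, replace = TRUE),
      stringsAsFactors = FALSE
    )
    treatments$score_weight[!treatments$is_correct] <- 0
    case_id <- sprintf("case-%08x", sample.int(.Machine$integer.max, 1L))
  })

  structure(
    list(case_id = case_id,
         discipline = tpl$discipline,
         disease = tpl$disease,
         overview = tpl$overview,
         difficulty_class = "moderately_difficult",
         questions = library,
         narrative = record$narrative,  # answer source text shown to reviewers
         structured = record$structured,
         reports = record$structured$report_table,
         diagnoses = dx,
         bases = bases,
         treatments = treatments,
         recommended_completion_time = recommended_time,
         review_status = "draft",
         deidentified = isTRUE(record$deidentified),
         pipeline = pipeline,
         source_record_id = record$record_id),
    class = "virtual_case"
  )
}

#' @export
print.virtual_case <- function(x, ...) {
  cat(sprintf("<virtual_case> %s: %s (%s), status %s\n", x$case_id, x$disease,
              x$discipline, x$review_status))
  cat(sprintf("  %d questions, %d diagnoses, %d bases, %d treatments, recommended %g s\n",
              nrow(x$questions), nrow(x$diagnoses), nrow(x$bases),
              nrow(x$treatments), x$recommended_completion_time))
  invisible(x)
}

#' Teacher review actions and the release state machine
#'
#' Cases move draft -> under_review -> released. `add_item` / `delete_item`
#' edit the question list, `set_difficulty` sets the difficulty class;
#' all three require the case not to be released. `submit` moves a draft
#' under review. `release` runs the PII leak scan against the supplied
#' original values and hard-fails when any value still appears; released
#' cases reject further edits.
#'
#' @param case a `virtual_case`.
#' @param action one of "add_item", "delete_item", "set_difficulty",
#'   "submit", "release".
#' @param item for add_item: a one-row question data.frame (same columns as
#'   the library).
#' @param item_id for delete_item.
#' @param difficulty for set_difficulty: "simple", "moderately_difficult",
#'   "complex".
#' @param pii_values for release: original PII values to scan for (held by
#'   the build pipeline, never stored in the case).
#' @return the updated `virtual_case`.
#' @export
review_actions <- function(case, action, item = NULL, item_id = NULL,
                           difficulty = NULL, pii_values = character(0)) {
  stopifnot(inherits(case, "virtual_case"))
  editable <- case$review_status %in% c("draft", "under_review")
  switch(action,
    add_item = {
      if (!editable) stop("released cases cannot be edited")
      stopifnot(is.data.frame(item), nrow(item) == 1L)
      case$questions <- rbind(case$questions, item)
      class(case$questions) <- c("question_library", "data.frame")
    },
    delete_item = {
      if (!editable) stop("released cases cannot be edited")
      keep <- case$questions$question_id != item_id
      if (all(keep)) stop("no such question item: ", item_id)
      case$questions <- case$questions[keep, ]
      class(case$questions) <- c("question_library", "data.frame")
    },
    set_difficulty = {
      if (!editable) stop("released cases cannot be edited")
      if (!difficulty %in% c("simple", "moderately_difficult", "complex"))
        stop("invalid difficulty class")
      case$difficulty_class <- difficulty
    },
    submit = {
      if (case$review_status != "draft") stop("only draft cases can be submitted")
      case$review_status <- "under_review"
    },
    release = {
      if (!editable) stop("case already released")
      scan_case <- case; scan_case$pipeline <- NULL
      leaks <- pii_leak_scan(scan_case, pii_values)
      if (length(leaks))
        stop("release blocked: PII leak detected (", length(leaks), " value(s))")
      case$review_status <- "released"
    },
    stop("unknown review action: ", action)
  )
  case
}

#' Apply a learning difficulty level to a released case
#'
#' Level 1 shows the full case with an answer reference and no distractors.
#' Level 2 injects seeded distractor items (default 30% of the question
#' count) into the history / physical / auxiliary scenes; distractors are
#' always incorrect and the original items are untouched. Level 3 converts
#' the top-weighted scoring items to free entry. Level 4 is fully
#' independent self-study: every scoring item must be entered by the
#' learner.
#'
#' @param case a released `virtual_case`.
#' @param level integer 1-4.
#' @param seed integer seed for the distractor draw.
#' @param distractor_fraction fraction of questions added as distractors at
#'   level 2.
#' @param free_entry_fraction fraction of top-weighted items free-entered at
#'   level 3.
#' @param distractor_pool optional `question_library` from other cases to
#'   sample distractors from; a generic pool is synthesised when NULL.
#' @return a `playable_case`.
#' @export
apply_difficulty <- function(case, level, seed = 1L,
                             distractor_fraction = 0.3,
                             free_entry_fraction = 0.3,
                             distractor_pool = NULL) {
  stopifnot(inherits(case, "virtual_case"))
  if (case$review_status != "released") stop("case must be released before play")
  if (!level %in% 1:4) stop("level must be 1, 2, 3 or 4")

  empty_distractors <- case$questions[0, ]
  distractors <- empty_distractors
  free_entry <- character(0)
  scenes <- c("consultation", "physical_exam", "auxiliary_exam")

  if (level == 2L) {
    n_d <- as.integer(ceiling(distractor_fraction * nrow(case$questions)))
    withr::with_seed(seed, {
      if (is.null(distractor_pool)) {
        distractors <- data.frame(
          question_id = sprintf("dist%02d", seq_len(n_d)),
          scene = sample(scenes, n_d, replace = TRUE),
          display_text = sprintf("interference item %02d", seq_len(n_d)),
          stringsAsFactors = FALSE
        )
        distractors$canonical_tokens <- lapply(seq_len(n_d), function(i)
          c("interference", sprintf("%02d", i)))
        distractors$answer_text <- "No abnormality found"
        distractors$is_correct_item <- FALSE
        distractors$score_weight <- 0
      } else {
        pool <- distractor_pool[!distractor_pool$question_id %in%
                                  case$questions$question_id, ]
        take <- sample(nrow(pool), min(n_d, nrow(pool)))
        distractors <- pool[take, ]
        distractors$is_correct_item <- FALSE
        distractors$score_weight <- 0
      }
      class(distractors) <- c("question_library", "data.frame")
    })
  } else if (level == 3L) {
    items <- scoring_items(case)
    items <- items[items$is_correct, ]
    n_f <- as.integer(ceiling(free_entry_fraction * nrow(items)))
    ord <- order(-items$score_weight, items$item_id)
    free_entry <- items$item_id[ord][seq_len(n_f)]
  } else if (level == 4L) {
    free_entry <- scoring_items(case)$item_id
  }

  structure(
    list(base = case, level = as.integer(level),
         visible_answers = level == 1L,
         distractors = distractors,
         free_entry_items = free_entry),
    class = "playable_case"
  )
}

# every scoring item of a case, flattened: questions, diagnoses, bases,
# treatments (item_id, category, is_correct, score_weight)
scoring_items <- function(case) {
  rbind(
    data.frame(item_id = case$questions$question_id, category = "question",
               scene = case$questions$scene,
               is_correct = case$questions$is_correct_item,
               score_weight = case$questions$score_weight,
               stringsAsFactors = FALSE),
    data.frame(item_id = case$diagnoses$dx_id, category = "diagnosis",
               scene = "diagnosis", is_correct = case$diagnoses$is_correct,
               score_weight = case$diagnoses$score_weight,
               stringsAsFactors = FALSE),
    data.frame(item_id = case$bases$item_id, category = "bases",
               scene = "diagnosis", is_correct = case$bases$is_correct,
               score_weight = case$bases$score_weight,
               stringsAsFactors = FALSE),
    data.frame(item_id = case$treatments$item_id, category = "treatments",
               scene = "treatment", is_correct = case$treatments$is_correct,
               score_weight = case$treatments$score_weight,
               stringsAsFactors = FALSE)
  )
}

#' Questions visible in a playable case (library plus any distractors)
#' @param playable a `playable_case`.
#' @export
playable_questions <- function(playable) {
  stopifnot(inherits(playable, "playable_case"))
  q <- rbind(as.data.frame(playable$base$questions),
             as.data.frame(playable$distractors))
  class(q) <- c("question_library", "data.frame")
  q
}

#' @export
print.playable_case <- function(x, ...) {
  cat(sprintf("<playable_case> level %d of %s: %d questions (+%d distractors), %d free-entry items\n",
              x$level, x$base$case_id, nrow(x$base$questions),
              nrow(x$distractors), length(x$free_entry_items)))
  invisible(x)
}

#' Serialize / load a virtual case as JSON (schema version 1)
#' @param case a `virtual_case`.
#' @param path file path.
#' @export
write_case <- function(case, path) {
  obj <- unclass_deep(case)
  obj$pipeline <- NULL  # model state is serialised separately
  obj$schema_version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
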