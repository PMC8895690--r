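#' Score inputs for the five clinical-thinking indicators
#'
#' Collects every count and score the indicator formulas need. The
#' constructor checks internal consistency (missed = total - selected per
#' category, positive recommended time, selected score bounded by total).
#'
#' @param n_bases_selected_correct,n_bases_total_correct correct diagnosis
#'   bases selected / existing.
#' @param n_inq_selected_correct,n_inq_correct_total correct inquiries
#'   selected / existing.
#' @param n_pe_selected_correct,n_pe_correct_total correct physical exams
#'   selected / existing.
#' @param n_all_selected_correct,n_all_correct_total correct items selected
#'   / existing across inquiries, physical exams, diagnoses, bases and
#'   treatments.
#' @param t_rec,t_act recommended / actual completion time (same units).
#' @param selected_score,total_score weight sums over selected correct /
#'   all correct scoring items.
#' @param dx_selected_score,dx_total_score same, restricted to diagnoses
#'   and diagnosis bases.
#' @return class `score_inputs`.
#' @export
score_inputs <- function(n_bases_selected_correct, n_bases_total_correct,
                         n_inq_selected_correct, n_inq_correct_total,
                         n_pe_selected_correct, n_pe_correct_total,
                         n_all_selected_correct, n_all_correct_total,
                         t_rec, t_act,
                         selected_score, total_score,
                         dx_selected_score, dx_total_score) {
  x <- list(
    n_bases_selected_correct = n_bases_selected_correct,
    n_bases_total_correct = n_bases_total_correct,
    n_inq_selected_correct = n_inq_selected_correct,
    n_inq_correct_total = n_inq_correct_total,
    n_inq_correct_missed = n_inq_correct_total - n_inq_selected_correct,
    n_pe_selected_correct = n_pe_selected_correct,
    n_pe_correct_total = n_pe_correct_total,
    n_pe_correct_missed = n_pe_correct_total - n_pe_selected_correct,
    n_all_selected_correct = n_all_selected_correct,
    n_all_correct_total = n_all_correct_total,
    t_rec = t_rec, t_act = t_act,
    selected_score = selected_score, total_score = total_score,
    dx_selected_score = dx_selected_score, dx_total_score = dx_total_score
  )
  counts <- unlist(x[c("n_bases_selected_correct", "n_bases_total_correct",
                       "n_inq_selected_correct", "n_inq_correct_total",
                       "n_pe_selected_correct", "n_pe_correct_total",
                       "n_all_selected_correct", "n_all_correct_total")])
  if (any(counts < 0)) stop("counts must be non-negative")
  if (t_rec <= 0) stop("recommended time must be positive")
  if (t_act < 0) stop("actual time must be non-negative")
  if (selected_score > total_score)
    stop("selected score cannot exceed total score")
  structure(x, class = "score_inputs")
}

vacuous <- function(label) {
  message("vacuous denominator for ", label, ": scored 100 (no items in category)")
  100
}

#' Rigor of thinking
#'
#' 100 x (bases under the correct diagnosis actually selected / all bases
#' for the correct diagnosis). An empty basis category scores a vacuous
#' 100 with a log message.
#'
#' @param x a `score_inputs`.
#' @return real in [0, 100].
#' @export
score_rigor <- function(x) {
  if (x$n_bases_total_correct == 0) return(vacuous("rigor"))
  100 * x$n_bases_selected_correct / x$n_bases_total_correct
}

#' Logic of thinking
#'
#' 100 x (selected inquiries - missed correct inquiries + selected physical
#' exams - missed correct physical exams) / (correct inquiries + correct
#' physical exams), clamped to [0, 100]: as printed the numerator goes
#' negative once misses outnumber hits.
#'
#' @param x a `score_inputs`.
#' @return real in [0, 100].
#' @export
score_logic <- function(x) {
  denom <- x$n_inq_correct_total + x$n_pe_correct_total
  if (denom == 0) return(vacuous("logic"))
  num <- x$n_inq_selected_correct - x$n_inq_correct_missed +
    x$n_pe_selected_correct - x$n_pe_correct_missed
  min(100, 100 * max(0, num) / denom)
}

#' Systematic thinking
#'
#' 100 x (correct inquiries, physical exams, diagnoses, bases and
#' treatments selected / all correct items in those categories).
#'
#' @param x a `score_inputs`.
#' @return real in [0, 100].
#' @export
score_systematic <- function(x) {
  if (x$n_all_correct_total == 0) return(vacuous("systematic"))
  100 * x$n_all_selected_correct / x$n_all_correct_total
}

#' Agility of thinking
#'
#' 100 x (4 x recommended time / (4 x recommended time + actual time))
#' x (selected score / total score): strictly decreasing in the actual
#' time, strictly increasing in the selected score.
#'
#' @param x a `score_inputs`.
#' @return real in [0, 100].
#' @export
score_agility <- function(x) {
  if (x$total_score <= 0) stop("agility requires a positive total score")
  100 * (4 * x$t_rec / (4 * x$t_rec + x$t_act)) *
    (x$selected_score / x$total_score)
}

#' Expansion of knowledge
#'
#' 100 x (score of selected diagnoses and diagnosis bases / total score of
#' diagnoses and diagnosis bases).
#'
#' @param x a `score_inputs`.
#' @return real in [0, 100].
#' @export
score_expansion <- function(x) {
  if (x$dx_total_score == 0) return(vacuous("expansion"))
  100 * x$dx_selected_score / x$dx_total_score
}

#' Derive score inputs from a finished session
#'
#' Counts and weight sums come from the case ground truth crossed with the
#' session selections; times come from the session clock.
#'
#' @param session a finished `learning_session`.
#' @return a `score_inputs`.
#' @export
session_score_inputs <- function(session) {
  stopifnot(inherits(session, "learning_session"))
  if (!session$finished) stop("session must be finished before scoring")
  case <- session$case$base
  items <- scoring_items(case)
  correct <- items[items$is_correct, ]
  sel <- unlist(session$selections, use.names = FALSE)
  sel_correct <- correct[correct$item_id %in% sel, ]

  qsel <- function(scene) {
    q <- case$questions[case$questions$is_correct_item &
                          case$questions$scene == scene, ]
    c(total = nrow(q), selected = sum(q$question_id %in% sel))
  }
  inq <- qsel("consultation")
  pe <- qsel("physical_exam")

  dx_cat <- c("diagnosis", "bases")
  score_inputs(
    n_bases_selected_correct = sum(sel_correct$category == "bases"),
    n_bases_total_correct = sum(correct$category == "bases"),
    n_inq_selected_correct = inq[["selected"]],
    n_inq_correct_total = inq[["total"]],
    n_pe_selected_correct = pe[["selected"]],
    n_pe_correct_total = pe[["total"]],
    n_all_selected_correct = sum(sel_correct$category %in%
      c("question", "diagnosis", "bases", "treatments") &
      (sel_correct$category != "question" |
         sel_correct$scene %in% c("consultation", "physical_exam"))) ,
    n_all_correct_total = sum(correct$category %in%
      c("question", "diagnosis", "bases", "treatments") &
      (correct$category != "question" |
         correct$scene %in% c("consultation", "physical_exam"))),
    t_rec = case$recommended_completion_time,
    t_act = session$end_time - session$start_time,
    selected_score = sum(sel_correct$score_weight),
    total_score = sum(correct$score_weight),
    dx_selected_score = sum(sel_correct$score_weight[sel_correct$category %in% dx_cat]),
    dx_total_score = sum(correct$score_weight[correct$category %in% dx_cat])
  )
}

RADAR_ORDER <- c("rigor", "logic", "systematic", "agility", "expansion")

#' Build the multi-dimensional evaluation report for a finished session
#'
#' Computes the five indicators, their unweighted mean as the total score,
#' the radar payload in fixed order, the error-diagnosis records in the
#' teacher-report shape (case id, discipline, disease, overview, learning
#' times, correct selected, error selected) and the important missing
#' items.
#'
#' @param session a finished `learning_session`.
#' @param learning_times how many times the learner has studied this case.
#' @param importance_cutoff passed to [analyze_progress()].
#' @return class `evaluation_report`.
#' @export
build_report <- function(session, learning_times = 1L, importance_cutoff = NULL) {
  inputs <- session_score_inputs(session)
  scores <- c(rigor = score_rigor(inputs),
              logic = score_logic(inputs),
              systematic = score_systematic(inputs),
              agility = score_agility(inputs),
              expansion = score_expansion(inputs))
  case <- session$case$base
  dx <- case$diagnoses
  correct_selected <- dx$label[dx$dx_id %in% session$selections$diagnoses]
  err <- data.frame(
    case_id = case$case_id,
    discipline = case$discipline,
    disease = case$disease,
    overview = case$overview,
    learning_times = learning_times,
    correct_selected = paste(correct_selected, collapse = ", "),
    error_selected = if (length(session$error_diagnoses))
      paste(session$error_diagnoses, collapse = ", ") else "None",
    stringsAsFactors = FALSE
  )
  progress <- analyze_progress(session, importance_cutoff)
  structure(
    list(scores = scores,
         total = mean(scores),
         radar = scores[RADAR_ORDER],
         error_diagnoses = err,
         missing_items = progress$missing_important,
         inputs = inputs,
         student_id = session$student_id),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> clinical thinking indicators\n")
  for (k in RADAR_ORDER)
    cat(sprintf("  %-11s %6.2f\n", k, x$scores[[k]]))
  cat(sprintf("  %-11s %6.2f\n", "total", x$total))
  if (nrow(x$error_diagnoses) && x$error_diagnoses$error_selected != "None")
    cat("  error diagnoses:", x$error_diagnoses$error_selected, "\n")
  if (length(x$missing_items))
    cat("  important missing items:", paste(x$missing_items, collapse = ", "), "\n")
  invisible(x)
}

#' Radar plot of the five indicators
#'
#' Returns a ggplot object (polar bar chart) when ggplot2 is available.
#' @param report an `evaluation_report`.
#' @export
plot_radar <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for radar plots")
  df <- data.frame(indicator = factor(RADAR_ORDER, levels = RADAR_ORDER),
                   score = as.numeric(report$radar))
  ggplot2::ggplot(df, ggplot2::aes(x = indicator, y = score)) +
    ggplot2::geom_col(width = 1, alpha = 0.6, fill = "steelblue") +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(title = "Clinical thinking radar", x = NULL, y = NULL)
}

#' Export error-diagnosis records for teachers as CSV
#' @param reports list of `evaluation_report`.
#' @param path file path.
#' @export
write_error_diagnoses <- function(reports, path) {
  tab <- do.call(rbind, lapply(reports, `[[`, "error_diagnoses"))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
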