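#' Summarise one session into the task measures
#'
#' Metacognitive bias is the mean confidence rating across trials; task
#' difficulty is the mean dot difference (lower = harder); accuracy is the
#' mean proportion correct; RT is the mean response time in seconds;
#' `side_proportion` is the larger of the two choice-side proportions, used
#' by the side-bias exclusion. No exclusion is applied here.
#'
#' @param session Tibble of trials as produced by [run_session()] (columns
#'   `dot_difference`, `chosen_side`, `correct`, `confidence`, `rt_s`).
#' @return One-row tibble of session metrics.
#' @export
compute_session_metrics <- function(session) {
  if (!is.data.frame(session) || nrow(session) == 0L)
    stop("`session` must contain at least one trial", call. = FALSE)
  tibble::tibble(
    mean_confidence = mean(session$confidence),
    mean_dot_difference = mean(session$dot_difference),
    mean_accuracy = mean(session$correct),
    mean_rt = mean(session$rt_s),
    side_proportion = max(mean(session$chosen_side == "left"),
                          mean(session$chosen_side == "right")))
}

#' Session metrics for every participant and timepoint
#'
#' @param trials Long trial tibble with `participant_id` and `timepoint`
#'   columns in addition to the [run_session()] columns.
#' @return Tibble of metrics, one row per participant x timepoint.
#' @export
compute_cohort_metrics <- function(trials) {
  trials |>
    dplyr::group_by(.data$participant_id, .data$timepoint) |>
    dplyr::summarise(compute_session_metrics(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
}

#' Flag sessions that fail the task data-quality criteria
#'
#' A session is excluded for reason `"accuracy"` when mean accuracy is
#' strictly below `accuracy_bounds[1]` or strictly above
#' `accuracy_bounds[2]` (the staircase failed to converge in acceptable
#' bounds), and for reason `"side-bias"` when one side was chosen on
#' strictly more than `side_bias_cutoff` of trials. Inequalities are strict,
#' so sessions exactly on a boundary are retained; set `closed_bounds =
#' TRUE` for the closed-interval variant. Catch-item failures never exclude.
#'
#' @param metrics Metrics tibble from [compute_cohort_metrics()] or
#'   [compute_session_metrics()].
#' @param accuracy_bounds Length-2 retention interval for mean accuracy.
#' @param side_bias_cutoff Maximum tolerated choice-side proportion.
#' @param closed_bounds Treat the bounds as excluding their endpoints too.
#' @return `metrics` with logical `excluded` and a `reasons` string column
#'   (`";"`-separated, empty when retained).
#' @export
apply_task_exclusions <- function(metrics,
                                  accuracy_bounds = c(0.60, 0.85),
                                  side_bias_cutoff = 0.95,
                                  closed_bounds = FALSE) {
  acc_bad <- if (closed_bounds)
    metrics$mean_accuracy <= accuracy_bounds[1] |
      metrics$mean_accuracy >= accuracy_bounds[2]
  else
    metrics$mean_accuracy < accuracy_bounds[1] |
      metrics$mean_accuracy > accuracy_bounds[2]
  side_bad <- if (closed_bounds)
    metrics$side_proportion >= side_bias_cutoff
  else
    metrics$side_proportion > side_bias_cutoff
  reasons <- mapply(function(a, s)
    paste(c(if (a) "accuracy", if (s) "side-bias"), collapse = ";"),
    acc_bad, side_bad)
  metrics$excluded <- acc_bad | side_bad
  metrics$reasons <- as.character(reasons)
  metrics
}

#' Split-half reliability of mean confidence
#'
#' For each session, mean confidence is computed separately over
#' odd-indexed and even-indexed trials (1-based, so trial 1 is odd), and
#' the two half-scores are correlated across sessions (Pearson).
#'
#' @param trials Long trial tibble with `participant_id`, `timepoint`,
#'   `trial` and `confidence` columns; pass a single timepoint to mirror a
#'   per-assessment reliability estimate.
#' @return A list with `r`, `df` and two-tailed `p`.
#' @export
split_half_reliability <- function(trials) {
  halves <- trials |>
    dplyr::group_by(.data$participant_id, .data$timepoint) |>
    dplyr::summarise(odd = mean(.data$confidence[.data$trial %% 2L == 1L]),
                     even = mean(.data$confidence[.data$trial %% 2L == 0L]),
                     .groups = "drop")
  if (nrow(halves) < 3L)
    stop("need at least 3 sessions", call. = FALSE)
  if (anyNA(halves$odd) || anyNA(halves$even))
    stop("each session needs both odd- and even-indexed trials",
         call. = FALSE)
  if (stats::sd(halves$odd) == 0 || stats::sd(halves$even) == 0)
    stop("zero variance in a half-session vector; correlation undefined",
         call. = FALSE)
  ct <- stats::cor.test(halves$odd, halves$even)
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Restrict to completers
#'
#' Completers have a retained (non-excluded) session and, when dimension
#' scores are supplied, complete scores at both timepoints.
#'
#' @param metrics Exclusion-flagged metrics from [apply_task_exclusions()].
#' @param scores Optional dimension-score tibble from [score_dimensions()].
#' @return Character vector of completer participant ids.
#' @export
complete_case_filter <- function(metrics, scores = NULL) {
  if (!"excluded" %in% names(metrics))
    stop("run apply_task_exclusions() first", call. = FALSE)
  ok <- metrics |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      complete = sum(!.data$excluded & .data$timepoint %in% 0:1) >= 2L &&
        all(0:1 %in% .data$timepoint[!.data$excluded]),
      .groups = "drop")
  ids <- ok$participant_id[ok$complete]
  if (!is.null(scores)) {
    sok <- scores |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(
        complete = all(0:1 %in% .data$timepoint) &&
          !anyNA(c(.data$AD, .data$CIT, .data$SW)),
        .groups = "drop")
    ids <- intersect(ids, sok$participant_id[sok$complete])
  }
  ids
}
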