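# Shared fixtures, built in code. Heavy objects are memoised so several
# test files can reuse one generated cohort within a test run.

make_session <- function(confidence,
                         correct = rep(TRUE, length(confidence)),
                         chosen_side = rep(c("left", "right"),
                                           length.out = length(confidence)),
                         dot_difference = rep(30L, length(confidence)),
                         rt_s = rep(1, length(confidence))) {
  n <- length(confidence)
  tibble::tibble(
    trial = seq_len(n),
    dot_difference = as.integer(dot_difference),
    target_side = chosen_side,
    chosen_side = chosen_side,
    correct = correct,
    confidence = as.integer(confidence),
    rt_s = rt_s)
}

tiny_design <- function(...) {
  cohort_design(n_icbt = 30, n_antidepressant = 12, n_control = 12,
                staircase = staircase_config(n_trials = 30),
                seed = 101L, ...)
}

# fully null generative conditions: all couplings and arm effects zero and
# no person-level confidence-bias heterogeneity, so the observations satisfy
# the iid null assumptions of every test in the pipeline (the observation-
# level ANOVA convention is conservative for within-person terms whenever
# person-level variance is present; see the methods vignette)
null_design <- function(seed, n = 50L) {
  zero <- c(icbt = 0, antidepressant = 0, control = 0)
  cohort_design(n_icbt = n, n_antidepressant = n, n_control = n,
                treatment_effect_AD = zero, treatment_effect_other = zero,
                time_effect_bias = zero, coupling_bias_AD = 0,
                cross_sectional_beta_AD = 0, cross_sectional_beta_CIT = 0,
                bias_sd = 0, bias_change_sd = 0,
                practice_sigma_ratio = 1,
                staircase = staircase_config(n_trials = 30),
                seed = seed)
}

.fixture_env <- new.env()

get_tiny_cohort <- function() {
  if (is.null(.fixture_env$tiny))
    .fixture_env$tiny <- generate_cohort(tiny_design())
  .fixture_env$tiny
}

# default-design cohort at full arm sizes, shared by the recovery checks
get_default_cohort <- function() {
  if (is.null(.fixture_env$full))
    .fixture_env$full <- generate_cohort(cohort_design())
  .fixture_env$full
}

# long analysis table (metrics + scores + change scores) for a cohort
merge_analysis_table <- function(cohort) {
  metrics <- compute_cohort_metrics(cohort$trials)
  scores <- score_dimensions(cohort$items, cohort$weights)
  long <- dplyr::inner_join(metrics, scores,
                            by = c("participant_id", "timepoint"))
  long <- dplyr::inner_join(long, cohort$demographics, by = "participant_id")
  wide <- tidyr::pivot_wider(
    long[, c("participant_id", "timepoint", "mean_confidence", "AD")],
    names_from = "timepoint", values_from = c("mean_confidence", "AD"))
  wide$d_confidence <- wide$mean_confidence_1 - wide$mean_confidence_0
  wide$d_AD <- wide$AD_1 - wide$AD_0
  dplyr::inner_join(long, wide[, c("participant_id", "d_confidence", "d_AD")],
                    by = "participant_id")
}
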