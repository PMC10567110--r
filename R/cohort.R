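#' Design of a synthetic three-arm, two-timepoint cohort
#'
#' Captures the generative conditions the analysis pipeline assumes: arm
#' sizes, arm-specific symptom improvement, the cross-sectional coupling of
#' confidence bias to the transdiagnostic dimensions, the longitudinal
#' coupling of confidence-bias change to anxious-depression change, the
#' staircase operating point, demographics, and careless-responding rates.
#'
#' Scale conventions: latent dimensions are standardised (SD 1 at baseline)
#' with the stated correlation structure; confidence-bias quantities are in
#' criterion units of the observer model, where one unit moves mean
#' confidence by roughly 1.9 rating points near the centre of the scale.
#' Defaults are calibrated so a default cohort reproduces the magnitudes of
#' a large iCBT treatment cohort: mean confidence near 3.8 (SD ~0.85),
#' standardised baseline slopes of about -0.09 (anxious-depression) and
#' +0.11 (compulsivity), a standardised time effect on confidence of about
#' 0.17 in the iCBT arm (0.31 antidepressant, 0.11 control, the latter
#' non-significant at n = 88), a change-change correlation near -0.12, and
#' mean dot difference ~41.8 falling to ~39.8 with practice.
#'
#' @param n_icbt,n_antidepressant,n_control Arm sizes.
#' @param treatment_effect_AD Named mean reduction in anxious-depression per
#'   arm (latent SD units; positive = improvement).
#' @param treatment_effect_other Mean reduction of the other two dimensions
#'   per arm.
#' @param change_sd SD of person-level latent change around the arm mean.
#' @param time_effect_bias Named mean confidence-bias increase per arm.
#' @param coupling_bias_AD Slope linking (mean-centred) anxious-depression
#'   change to confidence-bias change; negative couples symptom improvement
#'   to rising confidence.
#' @param bias_change_sd SD of residual confidence-bias change.
#' @param cross_sectional_beta_AD,cross_sectional_beta_CIT Baseline slopes
#'   of confidence bias on the two dimensions (bias units per latent SD).
#' @param bias_intercept,bias_sd Baseline confidence-bias mean and SD.
#' @param dimension_correlations 3x3 positive semi-definite correlation
#'   matrix of the baseline dimensions (order AD, CIT, SW).
#' @param equilibrium_log_diff Staircase operating point at baseline (see
#'   [calibrated_observer()]).
#' @param practice_sigma_ratio Multiplier on perceptual noise at follow-up
#'   (< 1 encodes a practice effect: the staircase settles at a smaller dot
#'   difference while accuracy stays pinned).
#' @param demographics_model Category probabilities for gender, country and
#'   education plus a truncated-normal age model.
#' @param catch_fail_rate Per-assessment probability of failing at least one
#'   catch item.
#' @param item_noise_sd Item-level response noise (latent SD units).
#' @param staircase A [staircase_config()].
#' @param seed Integer master seed; expanded into per-participant substreams
#'   so changing one arm's size never reshuffles another arm.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_icbt = 649L, n_antidepressant = 82L,
                          n_control = 88L,
                          treatment_effect_AD = c(icbt = 0.43,
                                                  antidepressant = 0.82,
                                                  control = 0),
                          treatment_effect_other = c(icbt = 0.20,
                                                     antidepressant = 0.38,
                                                     control = 0),
                          change_sd = 0.5,
                          time_effect_bias = c(icbt = 0.086,
                                               antidepressant = 0.16,
                                               control = 0.056),
                          coupling_bias_AD = -0.07,
                          bias_change_sd = 0.22,
                          cross_sectional_beta_AD = -0.045,
                          cross_sectional_beta_CIT = 0.055,
                          bias_intercept = -0.05,
                          bias_sd = 0.45,
                          dimension_correlations =
                            matrix(c(1, 0.4, 0.5,
                                     0.4, 1, 0.3,
                                     0.5, 0.3, 1), 3L, 3L,
                                   dimnames = rep(list(c("AD", "CIT", "SW")),
                                                  2L)),
                          equilibrium_log_diff = 3.58,
                          practice_sigma_ratio = 0.952,
                          demographics_model = list(
                            gender = c(male = 0.218, female = 0.774,
                                       other = 0.008),
                            country = c(ireland = 0.138, uk = 0.844,
                                        other = 0.018),
                            education = c(below_undergraduate = 0.227,
                                          undergraduate = 0.529,
                                          above_undergraduate = 0.244),
                            age_mean = 32.2, age_sd = 11,
                            age_range = c(18, 75)),
                          catch_fail_rate = 0.083,
                          item_noise_sd = 1,
                          staircase = staircase_config(),
                          seed = 715L) {
  arms <- c("icbt", "antidepressant", "control")
  n_per_arm <- c(icbt = as.integer(n_icbt),
                 antidepressant = as.integer(n_antidepressant),
                 control = as.integer(n_control))
  if (any(n_per_arm < 1L))
    stop("arm sizes must be positive", call. = FALSE)
  for (nm in c("treatment_effect_AD", "treatment_effect_other",
               "time_effect_bias")) {
    v <- get(nm)
    if (!all(arms %in% names(v)))
      stop("`", nm, "` must be named for all of: ",
           paste(arms, collapse = ", "), call. = FALSE)
  }
  ev <- eigen(dimension_correlations, symmetric = TRUE, only.values = TRUE)
  if (any(ev$values < -1e-8))
    stop("`dimension_correlations` must be positive semi-definite",
         call. = FALSE)
  for (p in c(demographics_model$gender, demographics_model$country,
              demographics_model$education, catch_fail_rate))
    if (p < 0 || p > 1)
      stop("probability parameters must lie in [0, 1]", call. = FALSE)
  if (change_sd < 0 || bias_sd < 0 || bias_change_sd < 0 || item_noise_sd < 0)
    stop("SD parameters must be non-negative", call. = FALSE)
  structure(
    list(arms = arms, n_per_arm = n_per_arm,
         treatment_effect_AD = treatment_effect_AD,
         treatment_effect_other = treatment_effect_other,
         change_sd = change_sd, time_effect_bias = time_effect_bias,
         coupling_bias_AD = coupling_bias_AD,
         bias_change_sd = bias_change_sd,
         cross_sectional_beta_AD = cross_sectional_beta_AD,
         cross_sectional_beta_CIT = cross_sectional_beta_CIT,
         bias_intercept = bias_intercept, bias_sd = bias_sd,
         dimension_correlations = dimension_correlations,
         equilibrium_log_diff = equilibrium_log_diff,
         practice_sigma_ratio = practice_sigma_ratio,
         demographics_model = demographics_model,
         catch_fail_rate = catch_fail_rate,
         item_noise_sd = item_noise_sd,
         staircase = staircase, seed = as.integer(seed)),
    class = "cohort_design")
}

# Deterministic substream seeds: one draw sequence per (master seed, label),
# so the first k seeds of a stream are stable when n grows.
derive_seeds <- function(seed, label, n) {
  offset <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  withr::with_seed((seed * 1009L + offset * 31L) %% 2147483647L,
                   sample.int(2147483646L, n))
}

#' Generate one synthetic participant
#'
#' Draws demographics, correlated baseline latent dimensions, arm-specific
#' latent change, a baseline confidence bias coupled to anxious-depression
#' (negatively) and compulsivity (positively), a bias change coupled to the
#' mean-centred anxious-depression change, then runs one staircase session
#' and produces item-level questionnaire responses per timepoint.
#'
#' @param arm One of `"icbt"`, `"antidepressant"`, `"control"`.
#' @param design A [cohort_design()].
#' @param weights Item weights tibble (shared across the cohort).
#' @param id Participant identifier.
#' @param seed Integer substream seed.
#' @return A list of tibbles: `demographics`, `latent` (generative truth,
#'   incl. confidence bias), `trials`, `items`.
#' @export
generate_participant <- function(arm, design, weights,
                                 id = paste0(arm, "_1"),
                                 seed = 1L) {
  if (!arm %in% design$arms)
    stop("unknown arm: ", arm, call. = FALSE)
  withr::with_seed(seed, {
    dm <- design$demographics_model
    age <- 0
    while (age < dm$age_range[1] || age > dm$age_range[2])
      age <- stats::rnorm(1, dm$age_mean, dm$age_sd)
    demo <- tibble::new_tibble(list(
      participant_id = id, arm = arm, age = round(age, 1),
      gender = sample(names(dm$gender), 1L, prob = dm$gender),
      country = sample(names(dm$country), 1L, prob = dm$country),
      education = sample(names(dm$education), 1L, prob = dm$education)),
      nrow = 1L)

    R <- design$dimension_correlations
    base <- drop(chol(R) %*% stats::rnorm(3L))
    names(base) <- c("AD", "CIT", "SW")
    eff <- c(AD = design$treatment_effect_AD[[arm]],
             CIT = design$treatment_effect_other[[arm]],
             SW = design$treatment_effect_other[[arm]])
    change <- -eff + stats::rnorm(3L, 0, design$change_sd)
    names(change) <- names(base)
    follow <- base + change

    bias0 <- design$bias_intercept +
      design$cross_sectional_beta_AD * base[["AD"]] +
      design$cross_sectional_beta_CIT * base[["CIT"]] +
      stats::rnorm(1, 0, design$bias_sd)
    # coupling acts on the mean-centred AD change so the arm-level time
    # effect on bias stays at its stated value
    dbias <- design$time_effect_bias[[arm]] +
      design$coupling_bias_AD * (change[["AD"]] + eff[["AD"]]) +
      stats::rnorm(1, 0, design$bias_change_sd)
    bias1 <- bias0 + dbias

    sess_seeds <- sample.int(2147483646L, 2L)
    sigma0 <- design$equilibrium_log_diff / stats::qnorm(sqrt(0.5))
    obs0 <- observer_model(sigma0, confidence_bias = bias0)
    obs1 <- observer_model(sigma0 * design$practice_sigma_ratio,
                           confidence_bias = bias1)
    s0 <- run_session(obs0, design$staircase, sess_seeds[1])
    s1 <- run_session(obs1, design$staircase, sess_seeds[2])
    nt <- design$staircase$n_trials
    trials <- tibble::new_tibble(
      c(list(participant_id = rep(id, 2L * nt),
             timepoint = rep(0:1, each = nt)),
        lapply(stats::setNames(names(s0), names(s0)),
               function(cn) c(s0[[cn]], s1[[cn]]))),
      nrow = 2L * nt)

    wsas_base <- if (arm == "control") 1.0 else 2.8
    resp <- lapply(0:1, function(tp) {
      lat <- if (tp == 0L) base else follow
      generate_questionnaire_responses(
        lat, weights, noise_sd = design$item_noise_sd,
        wsas_base = wsas_base,
        catch_fail_rate = design$catch_fail_rate, timepoint = tp)
    })
    ni <- vapply(resp, nrow, integer(1))
    items <- tibble::new_tibble(
      list(participant_id = rep(id, sum(ni)),
           timepoint = rep(0:1, times = ni),
           item_id = c(resp[[1]]$item_id, resp[[2]]$item_id),
           response = c(resp[[1]]$response, resp[[2]]$response)),
      nrow = sum(ni))

    latent <- tibble::new_tibble(list(
      participant_id = rep(id, 2L), arm = rep(arm, 2L), timepoint = 0:1,
      AD = c(base[["AD"]], follow[["AD"]]),
      CIT = c(base[["CIT"]], follow[["CIT"]]),
      SW = c(base[["SW"]], follow[["SW"]]),
      confidence_bias = c(bias0, bias1)), nrow = 2L)

    list(demographics = demo, latent = latent, trials = trials,
         items = items)
  })
}

#' Generate a full synthetic cohort
#'
#' @param design A [cohort_design()].
#' @return An object of class `mc_cohort`: a list with tibbles `trials`,
#'   `items`, `demographics`, `latent` (generative truth, for validation
#'   only -- the analysis pipeline never reads it), `weights`, and the
#'   `design`.
#' @export
#' @examples
#' \donttest{
#' design <- cohort_design(n_icbt = 12, n_antidepressant = 6, n_control = 6,
#'                         staircase = staircase_config(n_trials = 30))
#' cohort <- generate_cohort(design)
#' table(cohort$demographics$arm)
#' }
generate_cohort <- function(design = cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  weights <- generate_item_weights(derive_seeds(design$seed, "weights", 1L))
  parts <- list()
  for (arm in design$arms) {
    n <- design$n_per_arm[[arm]]
    seeds <- derive_seeds(design$seed, arm, n)
    parts[[arm]] <- lapply(seq_len(n), function(i) {
      generate_participant(arm, design, weights,
                           id = sprintf("%s_%04d", arm, i),
                           seed = seeds[i])
    })
  }
  flat <- unlist(parts, recursive = FALSE)
  structure(
    list(trials = dplyr::bind_rows(lapply(flat, `[[`, "trials")),
         items = dplyr::bind_rows(lapply(flat, `[[`, "items")),
         demographics = dplyr::bind_rows(lapply(flat, `[[`, "demographics")),
         latent = dplyr::bind_rows(lapply(flat, `[[`, "latent")),
         weights = weights,
         design = design),
    class = "mc_cohort")
}

#' @export
print.mc_cohort <- function(x, ...) {
  cat("<mc_cohort> ", nrow(x$demographics), " participants (",
      paste(sprintf("%s=%d", names(x$design$n_per_arm), x$design$n_per_arm),
            collapse = ", "),
      "), ", nrow(x$trials), " trials, seed ", x$design$seed, "\n", sep = "")
  invisible(x)
}
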