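#' Signal-detection observer for the dot-difference task
#'
#' A type-1/type-2 signal-detection stand-in for a human participant. On a
#' trial with log dot difference `d`, the observer draws internal evidence
#' `e ~ Normal(d, sigma)` in favour of the target and chooses the target iff
#' `e > 0`, so accuracy is `pnorm(d / sigma)` and is strictly increasing in
#' `d / sigma`. Confidence is produced by comparing `|e| / sigma` against
#' five ordered criteria shifted down by `confidence_bias` (higher bias, more
#' confident) with optional Gaussian criterion jitter. Response times are
#' log-normal and enter analyses only as session means.
#'
#' @param sigma Perceptual noise SD in log-dot units (> 0).
#' @param confidence_bias Criterion shift; `+Inf` saturates ratings at the
#'   top of the scale, `-Inf` at the bottom.
#' @param confidence_noise SD of per-trial criterion jitter (>= 0).
#' @param criteria Five increasing type-2 criteria on the `|e|/sigma` scale.
#' @param rt_meanlog,rt_sdlog Log-normal RT parameters (seconds).
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(sigma,
                           confidence_bias = 0,
                           confidence_noise = 0,
                           criteria = c(-0.25, 0.20, 0.65, 1.15, 1.75),
                           rt_meanlog = 0,
                           rt_sdlog = 0.35) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  if (confidence_noise < 0)
    stop("`confidence_noise` must be >= 0", call. = FALSE)
  if (length(criteria) != 5L || is.unsorted(criteria, strictly = TRUE))
    stop("`criteria` must be five strictly increasing values", call. = FALSE)
  structure(
    list(sigma = sigma, confidence_bias = confidence_bias,
         confidence_noise = confidence_noise, criteria = criteria,
         rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog),
    class = "observer_model")
}

#' Observer calibrated to a staircase operating point
#'
#' Chooses `sigma` so that the psychometric function crosses the two-down
#' one-up equilibrium accuracy \eqn{\sqrt{0.5}} at `equilibrium_log_diff`,
#' i.e. `sigma = equilibrium_log_diff / qnorm(sqrt(0.5))`. With the default
#' the staircase settles around a dot difference of
#' `exp(3.58) ~ 36` dots and session-mean accuracy near 0.71.
#'
#' @param equilibrium_log_diff Log dot difference at which accuracy equals
#'   \eqn{\sqrt{0.5}}; must lie strictly inside `[log(6), log(81)]` for the
#'   staircase to converge.
#' @param ... Passed to [observer_model()].
#' @return An `observer_model`.
#' @export
calibrated_observer <- function(equilibrium_log_diff = 3.58, ...) {
  observer_model(sigma = equilibrium_log_diff / stats::qnorm(sqrt(0.5)), ...)
}

#' Simulate a single perceptual choice
#'
#' @param observer An [observer_model()].
#' @param log_diff Log dot difference of the current trial.
#' @return A list with `correct` (logical) and `evidence` (the internal
#'   evidence sample; its magnitude feeds [simulate_confidence()]).
#' @export
simulate_choice <- function(observer, log_diff) {
  stopifnot(inherits(observer, "observer_model"))
  if (!is.finite(log_diff))
    stop("`log_diff` must be finite", call. = FALSE)
  e <- stats::rnorm(1L, mean = log_diff, sd = observer$sigma)
  list(correct = e > 0, evidence = e)
}

#' Map evidence magnitude to an ordinal confidence rating
#'
#' The rating is one plus the number of (shifted, jittered) criteria that
#' `|evidence|/sigma` exceeds, giving values in 1..6. Expected ratings are
#' non-decreasing in both `confidence_bias` and `|evidence|`.
#'
#' @param observer An [observer_model()].
#' @param evidence Internal evidence from [simulate_choice()].
#' @return Integer rating in 1..6.
#' @export
simulate_confidence <- function(observer, evidence) {
  stopifnot(inherits(observer, "observer_model"))
  if (!is.finite(evidence))
    stop("`evidence` must be finite", call. = FALSE)
  z <- abs(evidence) / observer$sigma
  crit <- observer$criteria - observer$confidence_bias
  if (observer$confidence_noise > 0)
    crit <- crit + stats::rnorm(length(crit), 0, observer$confidence_noise)
  1L + sum(z > crit)
}

#' Draw response times for an observer
#'
#' @param observer An [observer_model()].
#' @param n Number of draws.
#' @return Positive numeric vector of RTs in seconds.
#' @export
simulate_rt <- function(observer, n = 1L) {
  stats::rlnorm(n, observer$rt_meanlog, observer$rt_sdlog)
}
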