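#' Configuration for the adaptive dot-difference staircase
#'
#' Defines a two-down one-up staircase on the log dot-difference scale:
#' the task becomes harder (smaller dot difference) after two consecutive
#' correct responses and easier after every error, which pins asymptotic
#' accuracy near \eqn{\sqrt{0.5} \approx 0.707}. Difficulty starts at
#' `start_log_diff` and moves by a trial-indexed step schedule, clamped to
#' `[log(min_dots), log(max_dots)]`.
#'
#' @param n_trials Total number of trials in a session.
#' @param n_blocks Number of equally sized blocks (`n_trials` must be
#'   divisible by `n_blocks`; the staircase itself runs continuously across
#'   blocks).
#' @param start_log_diff Starting dot difference in log space.
#' @param step_schedule A list of `c(first_trial, last_trial, step)` triples
#'   covering trials 1..`n_trials`; steps are log-space magnitudes. The
#'   default is 0.4 for trials 1-5, 0.2 for 6-10 and 0.1 thereafter.
#' @param min_dots,max_dots Integer bounds on the dot difference.
#' @param fixation_ms,stimulus_ms,feedback_ms Presentation timings in
#'   milliseconds (recorded for provenance; the simulator does not render
#'   stimuli).
#' @param confidence_levels Number of ordinal confidence levels
#'   (1 = guessing .. `confidence_levels` = certain).
#'
#' @return An object of class `staircase_config`.
#' @export
#' @examples
#' cfg <- staircase_config()
#' step_size_for_trial(1, cfg)   # 0.4
#' step_size_for_trial(11, cfg)  # 0.1
staircase_config <- function(n_trials = 210L,
                             n_blocks = 5L,
                             start_log_diff = 4.2,
                             step_schedule = list(c(1, 5, 0.4),
                                                  c(6, 10, 0.2),
                                                  c(11, Inf, 0.1)),
                             min_dots = 6L,
                             max_dots = 81L,
                             fixation_ms = 1000,
                             stimulus_ms = 300,
                             feedback_ms = 500,
                             confidence_levels = 6L) {
  n_trials <- as.integer(n_trials)
  n_blocks <- as.integer(n_blocks)
  if (n_trials < 1L || n_blocks < 1L || n_trials %% n_blocks != 0L)
    stop("`n_trials` must be a positive multiple of `n_blocks`", call. = FALSE)
  if (!is.finite(start_log_diff))
    stop("`start_log_diff` must be finite", call. = FALSE)
  if (min_dots < 1L || max_dots <= min_dots)
    stop("need 1 <= min_dots < max_dots", call. = FALSE)
  start_dots <- floor(exp(start_log_diff) + 0.5)
  if (start_dots <= min_dots || start_dots > max_dots)
    stop("`start_log_diff` must map inside (min_dots, max_dots]", call. = FALSE)
  steps <- vapply(step_schedule, `[`, numeric(1), 3L)
  if (any(!is.finite(steps)) || any(steps <= 0))
    stop("step sizes must be strictly positive", call. = FALSE)
  if (is.unsorted(rev(steps), strictly = FALSE))
    stop("step sizes must be non-increasing across the schedule", call. = FALSE)
  lo <- vapply(step_schedule, `[`, numeric(1), 1L)
  hi <- vapply(step_schedule, `[`, numeric(1), 2L)
  if (lo[1] != 1 || any(lo[-1] != hi[-length(hi)] + 1))
    stop("step schedule ranges must tile trials 1..n_trials without gaps",
         call. = FALSE)
  structure(
    list(n_trials = n_trials, n_blocks = n_blocks,
         start_log_diff = start_log_diff, step_schedule = step_schedule,
         min_dots = as.integer(min_dots), max_dots = as.integer(max_dots),
         fixation_ms = fixation_ms, stimulus_ms = stimulus_ms,
         feedback_ms = feedback_ms,
         confidence_levels = as.integer(confidence_levels)),
    class = "staircase_config")
}

#' Scheduled log-space step magnitude for a trial
#'
#' @param trial_index 1-based session trial number(s).
#' @param config A [staircase_config()].
#' @return Numeric vector of step magnitudes.
#' @export
step_size_for_trial <- function(trial_index, config = staircase_config()) {
  if (any(!is.finite(trial_index)) ||
      any(trial_index < 1 | trial_index > config$n_trials) ||
      any(trial_index != floor(trial_index)))
    stop("`trial_index` must be an integer in 1..n_trials", call. = FALSE)
  out <- rep(NA_real_, length(trial_index))
  for (rng in config$step_schedule) {
    sel <- trial_index >= rng[1] & trial_index <= rng[2]
    out[sel] <- rng[3]
  }
  out
}

#' Initial staircase state
#'
#' @param config A [staircase_config()].
#' @return A list with `trial_index` (trial about to run, 1-based),
#'   `log_diff` and `consecutive_correct` (0 or 1).
#' @export
staircase_state <- function(config = staircase_config()) {
  list(trial_index = 1L,
       log_diff = clamp_log_diff(config$start_log_diff, config),
       consecutive_correct = 0L)
}

clamp_log_diff <- function(log_diff, config) {
  pmin(log(config$max_dots), pmax(log(config$min_dots), log_diff))
}

#' Advance the two-down one-up staircase after a trial
#'
#' An incorrect response makes the next trial easier by the scheduled step;
#' a correct response after a previous unrewarded correct makes it harder by
#' the same amount; a single correct response leaves difficulty unchanged.
#' The consecutive-correct counter is reset after every step (in either
#' direction) and after every error, the standard Levitt convention.
#' `log_diff` is clamped to `[log(min_dots), log(max_dots)]` after every
#' update.
#'
#' @param state A staircase state as returned by [staircase_state()] or a
#'   previous call; `state$trial_index` is the trial just completed.
#' @param correct Logical outcome of the completed trial.
#' @param config A [staircase_config()].
#' @return The updated state, with `trial_index` advanced by one.
#' @export
update_staircase <- function(state, correct, config = staircase_config()) {
  stopifnot(is.logical(correct), length(correct) == 1L, !is.na(correct))
  step <- step_size_for_trial(state$trial_index, config)
  if (!correct) {
    state$log_diff <- state$log_diff + step
    state$consecutive_correct <- 0L
  } else if (state$consecutive_correct == 0L) {
    state$consecutive_correct <- 1L
  } else {
    state$log_diff <- state$log_diff - step
    state$consecutive_correct <- 0L
  }
  state$log_diff <- clamp_log_diff(state$log_diff, config)
  state$trial_index <- state$trial_index + 1L
  state
}

#' Integer dot difference shown for a log-space difficulty
#'
#' Rounds `exp(log_diff)` half-up and clamps to the configured dot range.
#'
#' @param log_diff Log-space dot difference (vectorised).
#' @param config A [staircase_config()] supplying the dot bounds.
#' @return Integer dot differences in `[min_dots, max_dots]`.
#' @export
#' @examples
#' dots_from_logdiff(log(6))   # 6, the hardest discrimination
#' dots_from_logdiff(log(81))  # 81, the easiest
dots_from_logdiff <- function(log_diff, config = staircase_config()) {
  if (any(!is.finite(log_diff)))
    stop("`log_diff` must be finite", call. = FALSE)
  as.integer(pmin(config$max_dots,
                  pmax(config$min_dots, floor(exp(log_diff) + 0.5))))
}

#' Simulate one full staircase session against an observer
#'
#' Alternates observer responses with staircase updates for
#' `config$n_trials` trials. The target side (which stimulus holds more
#' dots) is drawn uniformly each trial. Observers receive no accuracy
#' feedback, matching a task in which only the chosen side is echoed back.
#'
#' @param observer An [observer_model()].
#' @param config A [staircase_config()].
#' @param seed Optional integer; when supplied the run is bit-reproducible
#'   and the caller's RNG state is left untouched.
#' @return A tibble with one row per trial: `trial`, `dot_difference`,
#'   `target_side`, `chosen_side`, `correct`, `confidence`, `rt_s`.
#' @export
#' @examples
#' obs <- calibrated_observer()
#' sess <- run_session(obs, staircase_config(), seed = 1)
#' mean(sess$correct)
run_session <- function(observer, config = staircase_config(), seed = NULL) {
  stopifnot(inherits(observer, "observer_model"))
  if (!is.null(seed))
    return(withr::with_seed(seed, run_session(observer, config)))

  n <- config$n_trials
  steps <- step_size_for_trial(seq_len(n), config)
  lo <- log(config$min_dots)
  hi <- log(config$max_dots)
  mind <- config$min_dots
  maxd <- config$max_dots
  sigma <- observer$sigma
  crit0 <- observer$criteria - observer$confidence_bias
  n_crit <- length(crit0)
  max_conf <- config$confidence_levels

  dot_difference <- integer(n)
  target_idx <- sample.int(2L, n, replace = TRUE) # 1 = left, 2 = right
  correct <- logical(n)
  confidence <- integer(n)
  sides <- c("left", "right")
  # evidence noise and criterion jitter are independent of the difficulty
  # path, so they can be pre-drawn without changing the model
  eps <- stats::rnorm(n, 0, sigma)
  jitter <- if (observer$confidence_noise > 0)
    matrix(stats::rnorm(n * n_crit, 0, observer$confidence_noise), n, n_crit)

  ld <- min(hi, max(lo, config$start_log_diff))
  cc <- 0L
  for (t in seq_len(n)) {
    dot_difference[t] <- as.integer(min(maxd, max(mind, floor(exp(ld) + 0.5))))
    e <- ld + eps[t]
    ok <- e > 0
    correct[t] <- ok
    crit <- if (is.null(jitter)) crit0 else crit0 + jitter[t, ]
    conf <- 1L + sum(abs(e) / sigma > crit)
    if (conf > max_conf)
      stop("observer returned out-of-range confidence: ", conf, call. = FALSE)
    confidence[t] <- conf
    if (!ok) {
      ld <- ld + steps[t]
      cc <- 0L
    } else if (cc == 0L) {
      cc <- 1L
    } else {
      ld <- ld - steps[t]
      cc <- 0L
    }
    ld <- min(hi, max(lo, ld))
  }
  rt_s <- simulate_rt(observer, n)
  chosen_idx <- ifelse(correct, target_idx, 3L - target_idx)
  tibble::new_tibble(list(
    trial = seq_len(n),
    dot_difference = dot_difference,
    target_side = sides[target_idx],
    chosen_side = sides[chosen_idx],
    correct = correct,
    confidence = confidence,
    rt_s = rt_s), nrow = n)
}
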