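#' Item-level scoring key for the questionnaire battery
#'
#' Enumerates the 209 clinical items of the nine self-report instruments
#' (depression, trait anxiety, schizotypy, impulsivity, OCD, social anxiety,
#' eating disorder, apathy, alcohol misuse), the five WSAS functional
#' impairment items (0-8 each, total 0-40) and the two embedded catch items
#' with their mandated responses. Dimension scoring uses only the 209
#' clinical items; WSAS and catch items are carried alongside.
#'
#' @return A tibble with columns `item_id`, `instrument`, `scale_min`,
#'   `scale_max`, `in_dimensions` (one of the 209), `is_catch`,
#'   `catch_required` (mandated response, `NA` for non-catch items).
#' @export
scoring_key <- function() {
  if (!is.null(.metacog_cache$key)) return(.metacog_cache$key)
  .metacog_cache$key <- build_scoring_key()
  .metacog_cache$key
}

.metacog_cache <- new.env(parent = emptyenv())

build_scoring_key <- function() {
  inst <- tibble::tibble(
    instrument = c("zung", "stai", "ssms", "bis", "ocir",
                   "lsas", "eat", "aes", "audit"),
    n_items  = c(20L, 20L, 43L, 30L, 18L, 24L, 26L, 18L, 10L),
    scale_min = c(1L, 1L, 0L, 1L, 0L, 0L, 0L, 1L, 0L),
    scale_max = c(4L, 4L, 1L, 4L, 4L, 3L, 3L, 4L, 4L))
  clinical <- do.call(rbind, lapply(seq_len(nrow(inst)), function(i) {
    tibble::tibble(
      item_id = sprintf("%s_%02d", inst$instrument[i], seq_len(inst$n_items[i])),
      instrument = inst$instrument[i],
      scale_min = inst$scale_min[i], scale_max = inst$scale_max[i],
      in_dimensions = TRUE, is_catch = FALSE, catch_required = NA_integer_)
  }))
  stopifnot(nrow(clinical) == 209L)
  extra <- tibble::tibble(
    item_id = c(sprintf("wsas_%d", 1:5), "catch_ocir", "catch_wsas"),
    instrument = c(rep("wsas", 5L), "ocir", "wsas"),
    scale_min = c(rep(0L, 5L), 0L, 0L),
    scale_max = c(rep(8L, 5L), 4L, 8L),
    in_dimensions = FALSE,
    is_catch = c(rep(FALSE, 5L), TRUE, TRUE),
    # mandated answers: "A little" on the 0-4 OCD scale, "Not at all" on WSAS
    catch_required = c(rep(NA_integer_, 5L), 1L, 0L))
  rbind(clinical, extra)
}

#' Generate a synthetic 209 x 3 item-weights matrix
#'
#' A labelled stand-in for published factor-analytic item weights, which are
#' consumed from a user-supplied file when available. Each instrument loads
#' mainly on one transdiagnostic dimension (depression/anxiety on
#' anxious-depression; OCD, schizotypy, impulsivity and eating items on
#' compulsivity-and-intrusive-thought; social anxiety, apathy and alcohol
#' items on social withdrawal) with small cross-loadings, giving a sparse,
#' sign-structured matrix usable wherever a real weights file would be.
#'
#' @param seed Integer seed; the same seed always yields the same matrix.
#' @return A tibble with columns `item_id`, `w_AD`, `w_CIT`, `w_SW`.
#' @export
generate_item_weights <- function(seed = 1L) {
  key <- scoring_key()
  key <- key[key$in_dimensions, ]
  dominant <- c(zung = "AD", stai = "AD",
                ocir = "CIT", ssms = "CIT", bis = "CIT", eat = "CIT",
                lsas = "SW", aes = "SW", audit = "SW")
  withr::with_seed(seed, {
    n <- nrow(key)
    w <- matrix(stats::rnorm(n * 3L, 0, 0.06), n, 3L,
                dimnames = list(NULL, c("AD", "CIT", "SW")))
    dom <- dominant[key$instrument]
    for (d in c("AD", "CIT", "SW")) {
      sel <- dom == d
      w[sel, d] <- abs(stats::rnorm(sum(sel), 0.60, 0.15))
    }
    tibble::tibble(item_id = key$item_id,
                   w_AD = w[, "AD"], w_CIT = w[, "CIT"], w_SW = w[, "SW"])
  })
}

#' Generate item-level questionnaire responses from a latent state
#'
#' Inverts the weighted-sum scoring rule: each clinical item's response is
#' its scale midpoint plus half its span times the item's weighted latent
#' signal plus Gaussian noise, rounded and clipped to the item's ordinal
#' range. WSAS items scale with anxious-depression around an arm-dependent
#' base level; catch items fail independently with a per-item probability
#' chosen so the per-assessment "at least one failure" rate equals
#' `catch_fail_rate` when both catch items are present (baseline); follow-up
#' assessments carry only the WSAS catch item.
#'
#' @param latent Named numeric vector with elements `AD`, `CIT`, `SW`.
#' @param weights Weights tibble as from [generate_item_weights()] (or a
#'   real weights file read with the same columns).
#' @param noise_sd Item noise SD on the standardised latent scale.
#' @param key Scoring key, [scoring_key()] by default.
#' @param wsas_base Baseline mean per WSAS item (0-8 scale); around 2.8 for
#'   clinical-severity respondents, near 1 for non-clinical controls.
#' @param catch_fail_rate Probability of failing at least one catch item at
#'   an assessment with two catch items.
#' @param timepoint 0 (baseline: OCI-R + WSAS catch items) or 1 (follow-up:
#'   WSAS catch item only).
#' @param discretise Round and clip responses to each item's ordinal range.
#'   Disable to obtain the exact linear (unbounded) inverse of the scoring
#'   rule, useful for algebraic checks.
#' @return A tibble with columns `item_id`, `response`.
#' @export
generate_questionnaire_responses <- function(latent, weights,
                                             noise_sd = 1,
                                             key = scoring_key(),
                                             wsas_base = 2.8,
                                             catch_fail_rate = 0.083,
                                             timepoint = 0L,
                                             discretise = TRUE) {
  stopifnot(all(c("AD", "CIT", "SW") %in% names(latent)))
  validate_weights(weights)
  clin <- key[key$in_dimensions, ]
  w <- as.matrix(weights[match(clin$item_id, weights$item_id),
                         c("w_AD", "w_CIT", "w_SW")])
  if (anyNA(w))
    stop("weights do not cover all 209 clinical items", call. = FALSE)
  mid <- (clin$scale_min + clin$scale_max) / 2
  half <- (clin$scale_max - clin$scale_min) / 2
  signal <- drop(w %*% c(latent[["AD"]], latent[["CIT"]], latent[["SW"]]))
  resp <- mid + half * (signal + stats::rnorm(nrow(clin), 0, noise_sd))
  if (discretise)
    resp <- pmin(clin$scale_max, pmax(clin$scale_min, round(resp)))

  wsas <- wsas_base + 0.45 * latent[["AD"]] + stats::rnorm(5L, 0, 0.8)
  wsas <- pmin(8, pmax(0, round(wsas)))

  q_item <- 1 - sqrt(1 - catch_fail_rate)      # per-item failure probability
  catch <- key[key$is_catch, ]
  if (timepoint != 0L) catch <- catch[catch$item_id == "catch_wsas", ]
  catch_resp <- vapply(seq_len(nrow(catch)), function(i) {
    req <- catch$catch_required[i]
    if (stats::runif(1) < q_item) {
      wrong <- setdiff(catch$scale_min[i]:catch$scale_max[i], req)
      sample(wrong, 1L)
    } else req
  }, integer(1))

  ids <- c(clin$item_id, sprintf("wsas_%d", 1:5), catch$item_id)
  tibble::new_tibble(list(item_id = ids,
                          response = c(resp, wsas, catch_resp)),
                     nrow = length(ids))
}

validate_weights <- function(weights) {
  need <- c("item_id", "w_AD", "w_CIT", "w_SW")
  if (!all(need %in% names(weights)))
    stop("weights must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(weights) != 209L)
    stop("weights matrix must have exactly 209 rows, got ", nrow(weights),
         call. = FALSE)
  invisible(weights)
}
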