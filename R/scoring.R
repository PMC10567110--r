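#' Score the three transdiagnostic dimensions from item responses
#'
#' Each dimension score is the weighted sum of the 209 clinical item
#' responses (anxious-depression, compulsivity-and-intrusive-thought,
#' social withdrawal). When `centre = TRUE` the per-dimension sample mean at
#' baseline (timepoint 0) is subtracted from both timepoints, so scores are
#' centred on zero at baseline and within-person change scores are
#' unaffected by the offset.
#'
#' @param items Long tibble of responses with columns `participant_id`,
#'   `timepoint` (0/1), `item_id`, `response`. Extra items (WSAS, catch) are
#'   ignored; all 209 clinical items must be present exactly once per
#'   participant and timepoint.
#' @param weights Weights tibble (`item_id`, `w_AD`, `w_CIT`, `w_SW`).
#' @param centre Centre scores on the baseline sample means.
#' @param standardise_items Z-score each item across the scored sample
#'   before weighting (some published weight sets are defined on
#'   standardised items); default uses raw responses.
#' @return A tibble `participant_id`, `timepoint`, `AD`, `CIT`, `SW`; the
#'   baseline offsets used for centring are attached as attribute
#'   `"centring_offsets"`.
#' @export
score_dimensions <- function(items, weights, centre = TRUE,
                             standardise_items = FALSE) {
  validate_weights(weights)
  need <- c("participant_id", "timepoint", "item_id", "response")
  if (!all(need %in% names(items)))
    stop("`items` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  clin <- items[items$item_id %in% weights$item_id, ]
  if (anyDuplicated(clin[c("participant_id", "timepoint", "item_id")]))
    stop("duplicated item responses within a participant x timepoint",
         call. = FALSE)
  wide <- tidyr::pivot_wider(clin[need],
                             names_from = "item_id",
                             values_from = "response")
  missing <- setdiff(weights$item_id, names(wide))
  if (length(missing))
    stop("missing clinical items: ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(wide[, weights$item_id])
  if (anyNA(m)) {
    bad <- weights$item_id[colSums(is.na(m)) > 0]
    stop("missing responses for items: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (standardise_items) m <- scale(m)
  s <- m %*% as.matrix(weights[, c("w_AD", "w_CIT", "w_SW")])
  dimnames(s) <- NULL
  out <- tibble::tibble(participant_id = wide$participant_id,
                        timepoint = wide$timepoint,
                        AD = s[, 1], CIT = s[, 2], SW = s[, 3])
  offsets <- c(AD = 0, CIT = 0, SW = 0)
  if (centre) {
    base <- out[out$timepoint == 0, ]
    if (nrow(base) == 0L)
      stop("no baseline (timepoint 0) rows to centre on", call. = FALSE)
    offsets <- c(AD = mean(base$AD), CIT = mean(base$CIT),
                 SW = mean(base$SW))
    out$AD <- out$AD - offsets[["AD"]]
    out$CIT <- out$CIT - offsets[["CIT"]]
    out$SW <- out$SW - offsets[["SW"]]
  }
  attr(out, "centring_offsets") <- offsets
  out
}

#' Total WSAS functional-impairment score
#'
#' @param items Numeric vector of the five WSAS item responses, each 0-8.
#' @return Integer total in 0-40.
#' @export
#' @examples
#' score_wsas(c(3, 5, 2, 7, 1)) # 18
score_wsas <- function(items) {
  if (length(items) != 5L || anyNA(items) ||
      any(items < 0 | items > 8 | items != floor(items)))
    stop("WSAS requires five integer responses in 0..8", call. = FALSE)
  as.integer(sum(items))
}

#' Count catch-item failures per participant and timepoint
#'
#' A failure is any response other than the item's mandated answer. Catch
#' failures are reported, not used for exclusion.
#'
#' @param items Long response tibble (`participant_id`, `timepoint`,
#'   `item_id`, `response`).
#' @param key Scoring key with `is_catch` and `catch_required` columns.
#' @return Tibble `participant_id`, `timepoint`, `n_catch`, `n_failed`,
#'   `failed` (any failure).
#' @export
detect_catch_failures <- function(items, key = scoring_key()) {
  catch_key <- key[key$is_catch, ]
  if (any(is.na(catch_key$catch_required)))
    stop("catch items without a mandated response in the key", call. = FALSE)
  catch <- items[items$item_id %in% catch_key$item_id, ]
  if (nrow(catch) == 0L)
    stop("no catch items present in `items`", call. = FALSE)
  catch$required <- catch_key$catch_required[match(catch$item_id,
                                                   catch_key$item_id)]
  catch |>
    dplyr::group_by(.data$participant_id, .data$timepoint) |>
    dplyr::summarise(n_catch = dplyr::n(),
                     n_failed = sum(.data$response != .data$required),
                     failed = .data$n_failed > 0L,
                     .groups = "drop")
}

#' Per-instrument total scores
#'
#' Simple sums per instrument (the standard keying of each scale), used for
#' the per-scale exploratory change analyses; the WSAS total is included.
#' Catch items are never summed.
#'
#' @inheritParams detect_catch_failures
#' @return A wide tibble, one row per participant x timepoint, one column
#'   per instrument total.
#' @export
scale_totals <- function(items, key = scoring_key()) {
  scored <- key[!key$is_catch, ]
  dat <- items[items$item_id %in% scored$item_id, ]
  dat$instrument <- scored$instrument[match(dat$item_id, scored$item_id)]
  long <- dat |>
    dplyr::group_by(.data$participant_id, .data$timepoint,
                    .data$instrument) |>
    dplyr::summarise(total = sum(.data$response), .groups = "drop")
  tidyr::pivot_wider(long, names_from = "instrument", values_from = "total",
                     names_prefix = "total_")
}
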