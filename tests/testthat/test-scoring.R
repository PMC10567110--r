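make_items <- function(responses, ids = scoring_key()$item_id[1:209],
                       pid = "p1", tp = 0L) {
  tibble::tibble(participant_id = pid, timepoint = tp,
                 item_id = ids, response = responses)
}

test_that("dimension scores equal the weighted sums, to a brute-force oracle", {
  w <- generate_item_weights(3)
  withr::with_seed(10, {
    resp1 <- sample(0:4, 209, replace = TRUE)
    resp2 <- sample(0:4, 209, replace = TRUE)
  })
  items <- dplyr::bind_rows(make_items(resp1, pid = "p1"),
                            make_items(resp2, pid = "p2"))
  sc <- score_dimensions(items, w, centre = FALSE)
  # independent oracle: explicit loop over items
  for (pid in c("p1", "p2")) {
    r <- items$response[items$participant_id == pid]
    ids <- items$item_id[items$participant_id == pid]
    expected <- c(AD = 0, CIT = 0, SW = 0)
    for (i in seq_along(ids)) {
      k <- which(w$item_id == ids[i])
      expected <- expected + r[i] * c(w$w_AD[k], w$w_CIT[k], w$w_SW[k])
    }
    row <- sc[sc$participant_id == pid, ]
    expect_equal(c(AD = row$AD, CIT = row$CIT, SW = row$SW), expected,
                 tolerance = 1e-12)
  }
  # all-zero responses score zero
  z <- score_dimensions(make_items(rep(0, 209)), w, centre = FALSE)
  expect_equal(unlist(z[c("AD", "CIT", "SW")]), c(AD = 0, CIT = 0, SW = 0))
})

test_that("scoring is linear and additive over item partitions", {
  w <- generate_item_weights(3)
  withr::with_seed(11, resp <- sample(1:4, 209, replace = TRUE))
  s1 <- score_dimensions(make_items(resp), w, centre = FALSE)
  s3 <- score_dimensions(make_items(3 * resp), w, centre = FALSE)
  expect_equal(3 * s1$AD, s3$AD, tolerance = 1e-12)
  expect_equal(3 * s1$CIT, s3$CIT, tolerance = 1e-12)
  # additivity: zeroing complementary halves sums to the whole
  half <- rep(c(1, 0), length.out = 209)
  sa <- score_dimensions(make_items(resp * half), w, centre = FALSE)
  sb <- score_dimensions(make_items(resp * (1 - half)), w, centre = FALSE)
  expect_equal(sa$AD + sb$AD, s1$AD, tolerance = 1e-12)
})

test_that("centring zeroes baseline means but leaves change scores intact", {
  w <- generate_item_weights(3)
  withr::with_seed(12, {
    items <- dplyr::bind_rows(lapply(1:8, function(i) dplyr::bind_rows(
      make_items(sample(0:4, 209, TRUE), pid = paste0("p", i), tp = 0L),
      make_items(sample(0:4, 209, TRUE), pid = paste0("p", i), tp = 1L))))
  })
  raw <- score_dimensions(items, w, centre = FALSE)
  cen <- score_dimensions(items, w, centre = TRUE)
  expect_lt(abs(mean(cen$AD[cen$timepoint == 0])), 1e-10)
  expect_lt(abs(mean(cen$CIT[cen$timepoint == 0])), 1e-10)
  expect_lt(abs(mean(cen$SW[cen$timepoint == 0])), 1e-10)
  ch <- function(s) s$AD[s$timepoint == 1] - s$AD[s$timepoint == 0]
  expect_equal(ch(cen), ch(raw), tolerance = 1e-12)
  # the same baseline offsets are applied at follow-up
  off <- attr(cen, "centring_offsets")
  expect_equal(cen$AD[cen$timepoint == 1],
               raw$AD[raw$timepoint == 1] - off[["AD"]], tolerance = 1e-12)
})

test_that("schema violations name the offending items", {
  w <- generate_item_weights(3)
  items <- make_items(rep(1, 209))
  expect_error(score_dimensions(items[-5, ], w),
               items$item_id[5], fixed = TRUE)
  dup <- dplyr::bind_rows(items, items[1, ])
  expect_error(score_dimensions(dup, w), "duplicated")
  expect_error(score_dimensions(items, w[-1, ]), "209")
})

test_that("noise-free unbounded responses invert the scoring rule exactly", {
  # weights with a single unit-loading item per dimension make the score an
  # affine image of the latent state
  w <- generate_item_weights(3)
  w[, c("w_AD", "w_CIT", "w_SW")] <- 0
  w$w_AD[w$item_id == "zung_01"] <- 1
  w$w_CIT[w$item_id == "ocir_01"] <- 1
  w$w_SW[w$item_id == "lsas_01"] <- 1
  key <- scoring_key()
  lats <- list(c(AD = 0.7, CIT = -1.2, SW = 0.4),
               c(AD = -0.5, CIT = 0.3, SW = 2.0))
  for (lat in lats) {
    withr::with_seed(13,
      r <- generate_questionnaire_responses(lat, w, noise_sd = 0,
                                            discretise = FALSE))
    sc <- score_dimensions(make_items(r$response[1:209], ids = r$item_id[1:209]),
                           w, centre = FALSE)
    half <- function(id) {
      k <- key[key$item_id == id, ]
      (k$scale_max - k$scale_min) / 2
    }
    mid <- function(id) {
      k <- key[key$item_id == id, ]
      (k$scale_max + k$scale_min) / 2
    }
    expect_equal((sc$AD - mid("zung_01")) / half("zung_01"), lat[["AD"]],
                 tolerance = 1e-12)
    expect_equal((sc$CIT - mid("ocir_01")) / half("ocir_01"), lat[["CIT"]],
                 tolerance = 1e-12)
    expect_equal((sc$SW - mid("lsas_01")) / half("lsas_01"), lat[["SW"]],
                 tolerance = 1e-12)
  }
})

test_that("WSAS totals sum five 0-8 items", {
  expect_equal(score_wsas(c(0, 0, 0, 0, 0)), 0L)
  expect_equal(score_wsas(c(8, 8, 8, 8, 8)), 40L)
  expect_equal(score_wsas(c(3, 5, 2, 7, 1)), 18L)
  expect_error(score_wsas(c(3, 5, 2, 7)), "five")
  expect_error(score_wsas(c(3, 5, 2, 7, 9)), "0..8")
  expect_error(score_wsas(c(3, 5, 2, 7, 1.5)), "integer")
})

test_that("catch failures are counted per participant and timepoint", {
  key <- scoring_key()
  ok <- tibble::tibble(participant_id = "p1", timepoint = 0L,
                       item_id = c("catch_ocir", "catch_wsas"),
                       response = c(1, 0))
  res <- detect_catch_failures(ok, key)
  expect_equal(res$n_failed, 0L)
  expect_false(res$failed)
  # planted failures are found exactly
  planted <- tibble::tibble(
    participant_id = rep(c("p1", "p2"), each = 3),
    timepoint = c(0L, 0L, 1L, 0L, 0L, 1L),
    item_id = rep(c("catch_ocir", "catch_wsas", "catch_wsas"), 2),
    response = c(3, 0, 0,    # p1 fails the OCD catch at baseline only
                 1, 2, 5))   # p2 fails the WSAS catch at both timepoints
  res <- detect_catch_failures(planted, key)
  lookup <- function(p, t) res$n_failed[res$participant_id == p &
                                          res$timepoint == t]
  expect_equal(lookup("p1", 0), 1L)
  expect_equal(lookup("p1", 1), 0L)
  expect_equal(lookup("p2", 0), 1L)
  expect_equal(lookup("p2", 1), 1L)
  # unlabelled catch items are a schema error
  bad_key <- key
  bad_key$catch_required[bad_key$item_id == "catch_ocir"] <- NA_integer_
  expect_error(detect_catch_failures(planted, bad_key), "mandated")
  expect_error(detect_catch_failures(ok[0, ], key), "no catch items")
})

test_that("per-instrument totals sum the standard keys", {
  key <- scoring_key()
  items <- tibble::tibble(participant_id = "p1", timepoint = 0L,
                          item_id = key$item_id[!key$is_catch],
                          response = 1)
  tot <- scale_totals(items, key)
  expect_equal(tot$total_zung, 20)
  expect_equal(tot$total_ssms, 43)
  expect_equal(tot$total_wsas, 5)
  expect_false("total_catch" %in% names(tot))
})
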