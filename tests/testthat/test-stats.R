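# construct a vector with exactly the requested mean and SD
moment_matched <- function(n, m, s, seed) {
  withr::with_seed(seed, z <- rnorm(n))
  z <- (z - mean(z)) / sd(z)
  m + s * z
}

test_that("z-scoring centres and scales exactly", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  withr::with_seed(20, x <- rnorm(50, 5, 3))
  z <- zscore(x)
  expect_equal(z, (x - mean(x)) / sd(x))
  expect_equal(zscore(z), z)              # idempotent on standard vectors
  expect_error(zscore(rep(1, 5)), "zero variance")
  expect_error(zscore(1), ">= 2")
})

test_that("cross-sectional regression recovers exact and planted structure", {
  withr::with_seed(21, {
    d <- data.frame(x = rnorm(80))
    d$y <- d$x + rnorm(80, 0, 1e-6)
    fit <- cross_sectional_regression(d, "y", "x")
    expect_equal(fit$estimate[fit$term == "x"], 1, tolerance = 1e-6)
    expect_lt(fit$p[fit$term == "x"], 1e-12)
    # known coefficients with a covariate
    d2 <- data.frame(a = rnorm(500), b = rnorm(500))
    d2$y <- 0.4 * d2$a - 0.2 * d2$b + rnorm(500, 0, 1)
    fit2 <- cross_sectional_regression(d2, "y", c("a", "b"))
    sdy <- sd(d2$y)
    expect_equal(fit2$estimate[fit2$term == "a"], 0.4 / sdy,
                 tolerance = 0.15)
    # collinear terms are named
    d2$a2 <- d2$a
    expect_error(cross_sectional_regression(d2, "y", c("a", "a2")),
                 "collinear.*a2")
  })
})

test_that("permuted outcomes give uniform p-values in the regression", {
  withr::with_seed(22, {
    x <- rnorm(60)
    y <- 0.5 * x + rnorm(60)
    ps <- replicate(200, {
      d <- data.frame(x = x, y = sample(y))
      cross_sectional_regression(d, "y", "x")$p[2]
    })
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the mixed-model time effect equals the paired-difference estimate", {
  withr::with_seed(23, {
    n <- 12
    base <- rnorm(n, 0, 1)
    fol <- base + 0.5 + rnorm(n, 0, 0.4)
    d <- data.frame(participant_id = rep(sprintf("p%02d", 1:n), 2),
                    timepoint = rep(0:1, each = n),
                    y = c(base, fol))
  })
  fit <- mixed_change_model(d, "y")
  zy <- zscore(d$y)
  paired <- mean(zy[d$timepoint == 1] - zy[d$timepoint == 0])
  expect_equal(fit$estimate[fit$term == "time"], paired, tolerance = 1e-6)
  expect_equal(fit$n[1], n)
  # no within-person change: exactly zero time effect
  d0 <- d
  d0$y <- rep(base, 2)
  fit0 <- suppressWarnings(mixed_change_model(d0, "y"))
  expect_equal(fit0$estimate[fit0$term == "time"], 0, tolerance = 1e-8)
  # singletons are dropped with a warning
  expect_warning(mixed_change_model(d[-1, ], "y"), "single observation")
})

test_that("an injected time effect is recovered within its CI", {
  withr::with_seed(24, {
    hits <- replicate(30, {
      n <- 60
      base <- rnorm(n)
      fol <- base + 0.6 + rnorm(n, 0, 0.5)
      d <- data.frame(participant_id = rep(seq_len(n), 2),
                      timepoint = rep(0:1, each = n), y = c(base, fol))
      fit <- mixed_change_model(d, "y")
      est <- fit$estimate[fit$term == "time"]
      se <- fit$se[fit$term == "time"]
      truth <- 0.6 / sd(d$y)
      abs(est - truth) < 1.96 * se + 0.6 * abs(truth) * 0.1
    })
  })
  expect_gt(mean(hits), 0.85)
})

test_that("time-by-covariate interactions recover planted couplings", {
  withr::with_seed(25, {
    n <- 150
    cov <- rnorm(n)
    base <- rnorm(n)
    fol <- base + 0.2 - 0.5 * cov + rnorm(n, 0, 0.3)
    d <- data.frame(participant_id = rep(seq_len(n), 2),
                    timepoint = rep(0:1, each = n),
                    y = c(base, fol), cov = rep(cov, 2))
  })
  fit <- time_by_covariate_interaction(d, "y", "cov")
  b <- fit$estimate[fit$term == "time:cov"]
  expect_lt(b, 0)
  expect_lt(fit$p[fit$term == "time:cov"], 0.001)
  # scale: -0.5 covariate-SD units per time step, in outcome SDs
  expect_equal(b, -0.5 / sd(d$y), tolerance = 0.2)
  # a covariate unrelated to change is null
  withr::with_seed(26, {
    ps <- replicate(60, {
      d$noise <- rep(rnorm(n), 2)
      f <- time_by_covariate_interaction(d, "y", "noise")
      f$p[f$term == "time:noise"]
    })
  })
  expect_gt(mean(ps > 0.05), 0.85)
  # within-person variation in the covariate violates the contract
  bad <- d
  bad$cov[1] <- bad$cov[1] + 1
  expect_error(time_by_covariate_interaction(bad, "y", "cov"),
               "varies within")
})

test_that("change correlations match their closed form", {
  x <- c(0.3, -1, 2, 0.5, -0.2)
  res <- change_correlation(x, -x)
  expect_equal(res$r, -1)
  expect_equal(res$df, 3)
  withr::with_seed(27, {
    a <- rnorm(1000)
    b <- rnorm(1000)
  })
  res0 <- change_correlation(a, b)
  expect_lt(abs(res0$r), 4 / sqrt(1000))
  # p equals the t transform
  tt <- res0$r * sqrt(998 / (1 - res0$r^2))
  expect_equal(res0$p, 2 * pt(-abs(tt), 998), tolerance = 1e-12)
  expect_error(change_correlation(a, rep(1, 1000)), "zero variance")
  expect_error(change_correlation(1:2, 1:2), "n >= 3")
})

test_that("group-by-time ANOVA matches nested-model F ratios and df", {
  withr::with_seed(28, {
    n <- 30
    d <- data.frame(participant_id = rep(seq_len(3 * n), 2),
                    arm = rep(rep(c("a", "b", "c"), each = n), 2),
                    timepoint = rep(0:1, each = 3 * n))
    d$y <- 0.3 * (d$arm == "b") + 0.2 * d$timepoint +
      0.4 * (d$arm == "c") * d$timepoint + rnorm(nrow(d))
  })
  res <- group_time_anova(d, "y", group = "arm")
  expect_equal(unique(res$df2), nrow(d) - 6)
  # independent route: Type-II F from explicit nested model comparisons
  full <- lm(y ~ arm * timepoint2, data =
               transform(d, timepoint2 = factor(timepoint)))
  no_int <- update(full, . ~ . - arm:timepoint2)
  f_int <- anova(no_int, full)
  expect_equal(res$statistic[res$term == "group:time"], f_int$F[2],
               tolerance = 1e-10)
  f_time <- anova(update(no_int, . ~ . - timepoint2), no_int)
  # Type II tests each main effect against the no-interaction model,
  # with the full model's residual variance
  ss_time <- f_time$`Sum of Sq`[2]
  f_time_typeII <- (ss_time / 1) / (sum(residuals(full)^2) /
                                      df.residual(full))
  expect_equal(res$statistic[res$term == "time"], f_time_typeII,
               tolerance = 1e-10)
  # covariate extension carries the three-way interaction
  d$cov <- rep(rnorm(3 * n), 2)
  res3 <- group_time_anova(d, "y", group = "arm", covariate = "cov")
  expect_true("group:time:cov" %in% res3$term)
  expect_equal(unique(res3$df2), nrow(d) - 12)
  expect_error(group_time_anova(d[d$arm == "a", ], "y", group = "arm"),
               "two non-empty groups")
})

test_that("Welch's t from summaries equals the raw-data test", {
  expect_equal(welch_t_from_summary(5, 1, 30, 5, 1, 30)$t, 0)
  x <- moment_matched(40, 10.2, 3.1, seed = 29)
  y <- moment_matched(55, 8.9, 4.4, seed = 30)
  ref <- t.test(x, y)
  res <- welch_t_from_summary(mean(x), sd(x), 40, mean(y), sd(y), 55)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$df, unname(ref$parameter), tolerance = 1e-8)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_error(welch_t_from_summary(1, 0, 10, 2, 1, 10), "positive")
})

test_that("chi-square matches a brute-force cell loop on random tables", {
  chisq_oracle <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- 0
    for (i in seq_len(nrow(tab)))
      for (j in seq_len(ncol(tab)))
        stat <- stat + (tab[i, j] - e[i, j])^2 / e[i, j]
    stat
  }
  withr::with_seed(31, {
    for (k in 1:15) {
      nr <- sample(2:3, 1)
      nc <- sample(2:3, 1)
      tab <- matrix(rpois(nr * nc, 8) + 1, nr, nc)
      res <- chi_square_independence(tab)
      expect_equal(res$statistic, chisq_oracle(tab), tolerance = 1e-10)
      expect_equal(res$df, (nr - 1) * (nc - 1))
      expect_equal(res$p,
                   pchisq(res$statistic, res$df, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  })
  # a table equal to its own expected values scores zero
  tab <- outer(c(2, 3), c(4, 6))
  expect_equal(chi_square_independence(tab)$statistic, 0)
  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2)),
               "zero row or column margin")
})

test_that("Freeman-Halton enumeration agrees with the hypergeometric oracle", {
  # 2x2 oracle by direct hypergeometric enumeration
  tab <- matrix(c(1, 11, 9, 3), 2)
  m <- rowSums(tab)[1]; n2 <- rowSums(tab)[2]; k <- colSums(tab)[1]
  probs <- dhyper(max(0, k - n2):min(m, k), m, n2, k)
  p_oracle <- sum(probs[probs <= dhyper(tab[1, 1], m, n2, k) * (1 + 1e-7)])
  res <- fisher_exact_test(tab)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_equal(res$total_prob, 1, tolerance = 1e-9)
  # single-column table is degenerate
  expect_equal(fisher_exact_test(matrix(c(3, 5), 2, 1))$p, 1)
})

test_that("exact enumeration agrees with the reference implementation", {
  withr::with_seed(32, {
    for (k in 1:12) {
      nr <- sample(2:3, 1)
      nc <- sample(2:3, 1)
      tab <- matrix(rpois(nr * nc, 4), nr, nc)
      tab[1, 1] <- tab[1, 1] + 1  # avoid all-zero margins
      res <- fisher_exact_test(tab)
      expect_equal(res$p, fisher.test(tab)$p.value, tolerance = 1e-6)
      expect_equal(res$total_prob, 1, tolerance = 1e-9)
    }
  })
  # Monte-Carlo mode approximates the exact answer
  tab <- matrix(c(8, 3, 5, 9, 2, 7), 2, 3)
  exact <- fisher_exact_test(tab)$p
  withr::with_seed(33,
    mc <- fisher_exact_test(tab, monte_carlo = TRUE, mc_draws = 4e4)$p)
  expect_lt(abs(mc - exact), 0.02)
  # the guard refuses infeasible enumerations
  big <- matrix(rep(200L, 9), 3)
  expect_error(fisher_exact_test(big, max_tables = 1e3), "monte_carlo")
  expect_error(fisher_exact_test(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("summary-statistic ANOVA and Tukey match raw-data references", {
  groups <- list(moment_matched(20, 5.0, 1.2, seed = 34),
                 moment_matched(25, 6.1, 1.5, seed = 35),
                 moment_matched(30, 5.5, 1.1, seed = 36))
  means <- vapply(groups, mean, numeric(1))
  sds <- vapply(groups, sd, numeric(1))
  ns <- vapply(groups, length, numeric(1))
  res <- oneway_anova_from_summary(means, sds, ns)
  raw <- data.frame(y = unlist(groups),
                    g = factor(rep(1:3, times = ns)))
  ref <- summary(aov(y ~ g, raw))[[1]]
  expect_equal(res$F, ref$`F value`[1], tolerance = 1e-8)
  expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-8)
  expect_equal(c(res$df1, res$df2), ref$Df)
  # equal means give F = 0
  expect_equal(oneway_anova_from_summary(c(3, 3, 3), c(1, 1, 1),
                                         c(10, 10, 10))$F, 0)
  # Tukey-adjusted pairwise p-values match TukeyHSD
  tk <- tukey_hsd_from_summary(means, sds, ns)
  ref_tk <- TukeyHSD(aov(y ~ g, raw))$g
  expect_equal(sort(tk$p_adj), sort(unname(ref_tk[, "p adj"])),
               tolerance = 1e-8)
  # adjusted p decreases as a mean difference grows, variances fixed
  p_seq <- vapply(seq(0.2, 2, by = 0.3), function(d)
    tukey_hsd_from_summary(c(0, d, 0.1), c(1, 1, 1),
                           c(20, 20, 20))$p_adj[1], numeric(1))
  expect_true(all(diff(p_seq) < 0))
})

test_that("correlation sample sizes match a simulation-based power oracle", {
  n_hat <- power_sample_size_correlation(0.5, 0.80, 0.05)
  sim_power <- function(n, r, reps = 4000) {
    withr::with_seed(37, {
      hits <- replicate(reps, {
        x <- rnorm(n)
        y <- r * x + sqrt(1 - r^2) * rnorm(n)
        cor.test(x, y)$p.value < 0.05
      })
    })
    mean(hits)
  }
  # Monte-Carlo search in a window around the analytic answer
  cand <- (n_hat - 3):(n_hat + 3)
  pow <- vapply(cand, sim_power, numeric(1), r = 0.5)
  n_mc <- cand[which(pow >= 0.80)[1]]
  expect_lte(abs(n_mc - n_hat), 2)
  # limits and monotonicity
  expect_equal(power_sample_size_correlation(0.999), 4)
  ns <- vapply(c(0.1, 0.2, 0.3, 0.5, 0.7),
               power_sample_size_correlation, numeric(1))
  expect_true(all(diff(ns) < 0))
  expect_error(power_sample_size_correlation(0), "effect_r")
  expect_error(power_sample_size_correlation(0.5, power = 1), "effect_r")
})
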