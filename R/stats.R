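#' Z-score a numeric vector
#'
#' @param x Numeric vector with at least two values and nonzero variance.
#' @return `(x - mean(x)) / sd(x)` (sample SD, n - 1).
#' @export
zscore <- function(x) {
  if (length(x) < 2L || anyNA(x))
    stop("need >= 2 non-missing values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("zero variance; z-scores undefined", call. = FALSE)
  (x - mean(x)) / s
}

zscore_frame <- function(data, vars, z_score_dummies = FALSE) {
  for (v in vars) {
    if (is.numeric(data[[v]])) {
      data[[v]] <- zscore(data[[v]])
    } else {
      data[[v]] <- factor(data[[v]])
      if (z_score_dummies) {
        mm <- stats::model.matrix(~ d, data.frame(d = data[[v]]))[, -1,
                                                                  drop = FALSE]
        for (j in seq_len(ncol(mm)))
          data[[paste0(v, "_", colnames(mm)[j])]] <- zscore(mm[, j])
        data[[v]] <- NULL
      }
    }
  }
  data
}

tidy_lm <- function(fit, n) {
  sm <- summary(fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                 se = unname(sm[, 2]), statistic = unname(sm[, 3]),
                 p = unname(sm[, 4]), n = n)
}

#' Cross-sectional regression of a task measure on symptom dimensions
#'
#' Ordinary least squares of a (z-scored) outcome on z-scored numeric
#' predictors plus dummy-coded categorical covariates, the standard model
#' for baseline associations between task measures and the transdiagnostic
#' dimensions controlling for age, gender and education. Coefficients of
#' z-scored regressors are standardised betas.
#'
#' @param data A data frame of complete cases.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of focal predictor columns.
#' @param covariates Character vector of covariate columns (numeric ones
#'   are z-scored; categorical ones dummy-coded).
#' @param z_score_dummies Also z-score dummy columns (a strict reading of
#'   "all regressors standardised"); default keeps dummies 0/1 for
#'   interpretability.
#' @return Tidy tibble of terms: `estimate` (beta), `se`, `statistic`, `p`
#'   (two-tailed), `n`.
#' @export
cross_sectional_regression <- function(data, outcome, predictors,
                                       covariates = character(),
                                       z_score_dummies = FALSE) {
  vars <- c(outcome, predictors, covariates)
  stopifnot(all(vars %in% names(data)))
  data <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  data <- zscore_frame(data, vars, z_score_dummies)
  rhs <- setdiff(names(data), outcome)
  f <- stats::reformulate(rhs, response = outcome)
  fit <- stats::lm(f, data = data)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient model; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tidy_lm(fit, nrow(data))
}

#' Random-intercept model of change across two timepoints
#'
#' Fits `outcome ~ time + (1 | participant)` by maximum likelihood with the
#' outcome z-scored across all observations and time coded 0 (baseline) / 1
#' (follow-up), so the time coefficient is the standardised within-person
#' change. P-values are Wald, from the normal approximation. Participants
#' with a single observation are dropped with a warning (completer design).
#'
#' @param data Long data frame, one row per participant x timepoint.
#' @param outcome Name of the outcome column.
#' @param id,time Names of the participant and time (0/1) columns.
#' @return Tidy tibble of the fixed effects (`n` = participants analysed).
#' @export
mixed_change_model <- function(data, outcome, id = "participant_id",
                               time = "timepoint") {
  stopifnot(all(c(outcome, id, time) %in% names(data)))
  data <- data[stats::complete.cases(data[c(outcome, id, time)]), ]
  counts <- table(data[[id]])
  if (any(counts < 2L)) {
    warning(sum(counts < 2L),
            " participant(s) with a single observation dropped")
    data <- data[data[[id]] %in% names(counts)[counts >= 2L], ]
  }
  if (nrow(data) == 0L) stop("no complete pairs to analyse", call. = FALSE)
  df <- data.frame(y = zscore(data[[outcome]]),
                   time = as.numeric(data[[time]]),
                   pid = factor(data[[id]]))
  fit <- lme4::lmer(y ~ time + (1 | pid), data = df, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  sm <- summary(fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                 se = unname(sm[, 2]), statistic = unname(sm[, 3]),
                 p = unname(2 * stats::pnorm(-abs(sm[, 3]))),
                 n = nlevels(df$pid))
}

#' Time-by-covariate interaction on a repeated outcome
#'
#' Random-intercept model `outcome ~ time * covariate + (1 | participant)`
#' where the covariate is a single value per person (e.g. a symptom change
#' score, a baseline score, an engagement index, or a category). Numeric
#' covariates and the outcome are z-scored; main effects always accompany
#' the interaction; additional person-level covariates can be interacted
#' with time in the same model.
#'
#' @inheritParams mixed_change_model
#' @param covariate Name of the person-level covariate column.
#' @param extra_covariates Further person-level covariates, each entered
#'   with its own time interaction.
#' @return Tidy tibble of fixed effects; interaction rows are labelled
#'   `time:<covariate>`.
#' @export
time_by_covariate_interaction <- function(data, outcome, covariate,
                                          extra_covariates = character(),
                                          id = "participant_id",
                                          time = "timepoint") {
  covs <- c(covariate, extra_covariates)
  stopifnot(all(c(outcome, covs, id, time) %in% names(data)))
  for (v in covs) {
    within_var <- tapply(data[[v]], data[[id]],
                         function(x) length(unique(x)))
    if (any(within_var > 1L))
      stop("covariate `", v, "` varies within a participant", call. = FALSE)
  }
  df <- data.frame(y = zscore(data[[outcome]]),
                   time = as.numeric(data[[time]]),
                   pid = factor(data[[id]]))
  for (v in covs)
    df[[v]] <- if (is.numeric(data[[v]])) zscore(data[[v]])
               else factor(data[[v]])
  f <- stats::as.formula(paste(
    "y ~", paste(sprintf("time * %s", covs), collapse = " + "),
    "+ (1 | pid)"))
  fit <- lme4::lmer(f, data = df, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  sm <- summary(fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                 se = unname(sm[, 2]), statistic = unname(sm[, 3]),
                 p = unname(2 * stats::pnorm(-abs(sm[, 3]))),
                 n = nlevels(df$pid))
}

#' Pearson correlation of two change scores
#'
#' @param x_change,y_change Per-person change scores (follow-up minus
#'   baseline), same length, n >= 3.
#' @return A list with `r`, `df` (n - 2) and two-tailed `p` from the t
#'   transform.
#' @export
change_correlation <- function(x_change, y_change) {
  if (length(x_change) != length(y_change) || length(x_change) < 3L)
    stop("need two equal-length vectors with n >= 3", call. = FALSE)
  if (stats::sd(x_change) == 0 || stats::sd(y_change) == 0)
    stop("zero variance; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x_change, y_change)
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
}

#' Group-by-time ANOVA on a repeated outcome
#'
#' F table (Type-II sums of squares) for a long-format linear model with
#' group and time as crossed factors, optionally extended by a person-level
#' numeric covariate to give the three-way interaction. Denominator degrees
#' of freedom follow the observation-level convention (total observations
#' minus parameters), e.g. 1632 for 819 participants at two timepoints in
#' the two-factor model.
#'
#' @param data Long data frame.
#' @param outcome,group,time Column names; `time` coded 0/1.
#' @param covariate Optional person-level numeric covariate column
#'   (z-scored), interacted with group and time.
#' @param id Participant id column (used only to validate the covariate).
#' @return Tibble with `term`, `statistic` (F), `df1`, `df2`, `p`, `n`
#'   (observations).
#' @export
group_time_anova <- function(data, outcome, group = "arm",
                             time = "timepoint", covariate = NULL,
                             id = "participant_id") {
  stopifnot(all(c(outcome, group, time) %in% names(data)))
  df <- data.frame(y = data[[outcome]],
                   group = factor(data[[group]]),
                   time = factor(data[[time]]))
  if (nlevels(df$group) < 2L || any(table(df$group) == 0L))
    stop("need at least two non-empty groups", call. = FALSE)
  f <- y ~ group * time
  if (!is.null(covariate)) {
    stopifnot(covariate %in% names(data))
    df$cov <- zscore(data[[covariate]])
    f <- y ~ group * time * cov
  }
  fit <- stats::lm(f, data = df)
  at <- car::Anova(fit, type = 2)
  terms <- rownames(at)
  keep <- terms != "Residuals"
  tibble::tibble(term = terms[keep],
                 statistic = at$`F value`[keep],
                 df1 = at$Df[keep],
                 df2 = stats::df.residual(fit),
                 p = at$`Pr(>F)`[keep],
                 n = nrow(df))
}

#' Welch's two-sample t-test from summary statistics
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return A list with `t`, Welch-Satterthwaite `df` and two-tailed `p`.
#' @export
#' @examples
#' welch_t_from_summary(29.1, 12.0, 88, 30.5, 10.5, 82)
welch_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (s1 <= 0 || s2 <= 0 || n1 < 2 || n2 < 2)
    stop("need positive SDs and group sizes >= 2", call. = FALSE)
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test of independence
#'
#' Pearson's statistic without continuity correction, df = (r-1)(c-1).
#'
#' @param table Matrix of non-negative integer counts, at least 2x2, with
#'   positive margins.
#' @return A list with `statistic`, `df`, `p` and the `expected` table.
#' @export
chi_square_independence <- function(table) {
  table <- counts_matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L || any(table < 0))
    stop("need a table of non-negative counts, at least 2x2", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin; expected counts undefined",
         call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = ht$expected)
}

log_table_prob <- function(tab, lfact_margins) {
  lfact_margins - sum(lgamma(tab + 1))
}

# counts given inline as a matrix, or as a path to a headerless delimited
# file of counts
counts_matrix <- function(table) {
  if (is.character(table) && length(table) == 1L)
    table <- as.matrix(utils::read.csv(table, header = FALSE))
  as.matrix(table)
}

#' Freeman-Halton exact test for r x c tables
#'
#' Generalises Fisher's exact test: enumerates every table with the
#' observed margins, computes each table's hypergeometric probability
#' \eqn{\prod_i R_i! \prod_j C_j! / (N! \prod_{ij} n_{ij}!)}, and sums the
#' probabilities not exceeding that of the observed table (ties included
#' within a relative tolerance of 1e-7, the convention of standard
#' implementations). For tables whose enumeration would exceed
#' `max_tables`, a Monte-Carlo estimate over random margin-fixed tables is
#' available.
#'
#' @param table Matrix of non-negative integer counts.
#' @param max_tables Enumeration guard; exceeding it raises an error
#'   suggesting `monte_carlo = TRUE`.
#' @param monte_carlo Estimate the p-value from `mc_draws` random tables
#'   with the observed margins instead of enumerating.
#' @param mc_draws Number of Monte-Carlo tables.
#' @return A list with `p`, `method`, `tables` (number enumerated, `NA` for
#'   Monte-Carlo) and `total_prob` (enumerated probability mass, which must
#'   be 1 up to numerical error).
#' @export
#' @examples
#' gender <- matrix(c(20, 60, 2, 22, 66, 0), nrow = 3)
#' fisher_exact_test(gender)$p
fisher_exact_test <- function(table, max_tables = 2e6,
                              monte_carlo = FALSE, mc_draws = 1e5) {
  tab <- counts_matrix(table)
  if (any(tab < 0) || any(tab != floor(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  rm <- unname(rowSums(tab))
  cm <- unname(colSums(tab))
  keep_r <- rm > 0
  keep_c <- cm > 0
  tab <- tab[keep_r, keep_c, drop = FALSE]
  rm <- rm[keep_r]
  cm <- cm[keep_c]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(list(p = 1, method = "degenerate", tables = 1L, total_prob = 1))
  n <- sum(tab)
  lfact_margins <- sum(lgamma(rm + 1)) + sum(lgamma(cm + 1)) - lgamma(n + 1)
  lp_obs <- log_table_prob(tab, lfact_margins)
  tol <- log1p(1e-7)

  if (monte_carlo) {
    draws <- stats::r2dtable(mc_draws, rm, cm)
    lps <- vapply(draws, log_table_prob, numeric(1), lfact_margins)
    return(list(p = mean(lps <= lp_obs + tol), method = "monte-carlo",
                tables = NA_integer_, total_prob = NA_real_))
  }

  bound <- prod(outer(rm[-length(rm)], cm[-length(cm)], pmin) + 1)
  if (bound > max_tables)
    stop("enumeration guard exceeded (~", format(bound, digits = 3),
         " cell combinations); call with monte_carlo = TRUE", call. = FALSE)

  nr <- nrow(tab)
  nc <- ncol(tab)
  count <- 0L
  p_sum <- 0
  p_le <- 0
  # depth-first over rows; within a row, over its first nc-1 cells (the
  # last cell of a row, and the whole last row, are forced by the margins)
  row_rec <- function(i, colrem, lg_acc) {
    if (i == nr) {
      lp <- lfact_margins - lg_acc - sum(lgamma(colrem + 1))
      count <<- count + 1L
      pr <- exp(lp)
      p_sum <<- p_sum + pr
      if (lp <= lp_obs + tol) p_le <<- p_le + pr
      return(invisible())
    }
    cell_rec <- function(j, rem, colrem, lg_row) {
      if (j == nc) {
        if (rem <= colrem[nc]) {
          colrem[nc] <- colrem[nc] - rem
          row_rec(i + 1L, colrem, lg_acc + lg_row + lgamma(rem + 1))
        }
        return(invisible())
      }
      hi <- min(rem, colrem[j])
      lo <- max(0L, rem - sum(colrem[(j + 1L):nc]))
      for (x in lo:hi) {
        colrem2 <- colrem
        colrem2[j] <- colrem2[j] - x
        cell_rec(j + 1L, rem - x, colrem2, lg_row + lgamma(x + 1))
      }
    }
    cell_rec(1L, rm[i], colrem, 0)
  }
  row_rec(1L, unname(cm), 0)
  list(p = min(1, p_le), method = "enumeration", tables = count,
       total_prob = p_sum)
}

#' One-way ANOVA from group summary statistics
#'
#' @param means,sds,ns Equal-length vectors of group means, SDs and sizes
#'   (k >= 2 groups, each n >= 2).
#' @return A list with `F`, `df1`, `df2`, `p`, and the pooled `ms_within`.
#' @export
oneway_anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2L || length(sds) != k || length(ns) != k)
    stop("need >= 2 groups with matching means, sds, ns", call. = FALSE)
  if (any(sds <= 0) || any(ns < 2))
    stop("need positive SDs and group sizes >= 2", call. = FALSE)
  n_tot <- sum(ns)
  grand <- sum(ns * means) / n_tot
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- n_tot - k
  f <- (ss_between / df1) / (ss_within / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       ms_within = ss_within / df2)
}

#' Tukey HSD adjusted pairwise comparisons from summary statistics
#'
#' Studentised-range adjusted p-values for all pairwise mean differences,
#' using the Tukey-Kramer statistic for unequal group sizes.
#'
#' @inheritParams oneway_anova_from_summary
#' @param labels Optional group labels.
#' @return Tibble with one row per pair: `group1`, `group2`, `diff`, `q`,
#'   `p_adj`.
#' @export
tukey_hsd_from_summary <- function(means, sds, ns,
                                   labels = seq_along(means)) {
  aov_sum <- oneway_anova_from_summary(means, sds, ns)
  k <- length(means)
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- unname(means[i] - means[j])
    se <- sqrt(aov_sum$ms_within / 2 * unname(1 / ns[i] + 1 / ns[j]))
    q <- abs(d) / se
    c(diff = d, q = q,
      p_adj = stats::ptukey(q, k, aov_sum$df2, lower.tail = FALSE))
  })
  tibble::tibble(group1 = as.character(labels[pairs[1, ]]),
                 group2 = as.character(labels[pairs[2, ]]),
                 diff = out["diff", ], q = out["q", ],
                 p_adj = out["p_adj", ])
}

#' Sample size for detecting a Pearson correlation
#'
#' Smallest n for which the two-tailed test of r != 0 reaches the target
#' power under the Fisher-z approximation: with
#' \eqn{m = \sqrt{n-3}\,\mathrm{atanh}(|r|)}, power is
#' \eqn{\Phi(m - z_{1-\alpha/2}) + \Phi(-m - z_{1-\alpha/2})}.
#'
#' @param effect_r True correlation, 0 < |r| < 1.
#' @param power Target power in (0, 1).
#' @param alpha Two-tailed significance level in (0, 1).
#' @return Smallest required integer n (>= 4).
#' @export
power_sample_size_correlation <- function(effect_r, power = 0.80,
                                          alpha = 0.05) {
  if (abs(effect_r) <= 0 || abs(effect_r) >= 1 ||
      power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1)
    stop("need 0 < |effect_r| < 1 and power, alpha in (0, 1)", call. = FALSE)
  za <- stats::qnorm(1 - alpha / 2)
  pow <- function(n) {
    m <- sqrt(n - 3) * atanh(abs(effect_r))
    stats::pnorm(m - za) + stats::pnorm(-m - za)
  }
  n <- 4L
  while (pow(n) < power) n <- n + 1L
  n
}
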