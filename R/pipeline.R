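#' Run configuration for the simulate -> score -> analyze pipeline
#'
#' A serialisable bundle of seed, cohort-design overrides, staircase
#' overrides, paths and analysis toggles; a persisted config plus its seed
#' reproduces a run exactly.
#'
#' @param seed Master seed.
#' @param design_args Named list of overrides for [cohort_design()].
#' @param staircase_args Named list of overrides for [staircase_config()].
#' @param weights_file Optional path to a real item-weights file (CSV
#'   `item_id, w_AD, w_CIT, w_SW`); when `NULL` synthetic weights are
#'   generated.
#' @param out_dir Output directory for files and reports.
#' @param analyses Character subset of
#'   `c("baseline", "change", "interaction", "correlation", "anova",
#'   "table1")`.
#' @param z_score_dummies,closed_bounds Strictness flags passed through to
#'   [cross_sectional_regression()] and [apply_task_exclusions()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 715L,
                       design_args = list(),
                       staircase_args = list(),
                       weights_file = NULL,
                       out_dir = ".",
                       analyses = c("baseline", "change", "interaction",
                                    "correlation", "anova", "table1"),
                       z_score_dummies = FALSE,
                       closed_bounds = FALSE) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(list(seed = as.integer(seed), design_args = design_args,
                 staircase_args = staircase_args,
                 weights_file = weights_file, out_dir = out_dir,
                 analyses = analyses, z_score_dummies = z_score_dummies,
                 closed_bounds = closed_bounds),
            class = "run_config")
}

design_from_config <- function(config) {
  args <- config$design_args
  args$seed <- config$seed
  args$staircase <- do.call(staircase_config, config$staircase_args)
  do.call(cohort_design, args)
}

#' Write a cohort's tables as delimited text
#'
#' Emits `trials.csv`, `items.csv`, `weights.csv`, `demographics.csv` and
#' `latent_truth_synthetic.csv` (generative ground truth, kept apart from
#' the analysis inputs). All files are comma-delimited UTF-8 with headers,
#' `.` decimal and empty fields for missing values.
#'
#' @param cohort An `mc_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("trials.csv", "items.csv", "weights.csv",
                            "demographics.csv",
                            "latent_truth_synthetic.csv"))
  tabs <- list(cohort$trials, cohort$items, cohort$weights,
               cohort$demographics, cohort$latent)
  for (i in seq_along(paths))
    utils::write.csv(tabs[[i]], paths[i], row.names = FALSE, na = "")
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the CSV files.
#' @return An `mc_cohort`-like list (without the design object).
#' @export
read_cohort <- function(dir) {
  read1 <- function(f, required = TRUE) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      if (required) stop("missing file: ", p, call. = FALSE)
      return(NULL)
    }
    tibble::as_tibble(utils::read.csv(p, stringsAsFactors = FALSE))
  }
  structure(list(trials = read1("trials.csv"),
                 items = read1("items.csv"),
                 weights = read1("weights.csv"),
                 demographics = read1("demographics.csv"),
                 latent = read1("latent_truth_synthetic.csv",
                                required = FALSE)),
            class = "mc_cohort")
}

#' Demographic comparisons across study arms
#'
#' Reproduces the structure of a baseline characteristics table: gender by
#' Fisher's exact test (small cells), age by one-way ANOVA with Tukey
#' post-hoc comparisons, and country and education by Pearson chi-square.
#' With a single arm only descriptives are returned.
#'
#' @param demographics Tibble with `arm`, `age`, `gender`, `country`,
#'   `education` columns.
#' @return A list with `counts` (per characteristic), `tests` (tidy tibble)
#'   and `tukey_age` (pairwise tibble, `NULL` for < 3 arms).
#' @export
demographics_table <- function(demographics) {
  need <- c("arm", "age", "gender", "country", "education")
  if (!all(need %in% names(demographics)))
    stop("demographics must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  arms <- unique(demographics$arm)
  counts <- lapply(c(gender = "gender", country = "country",
                     education = "education"),
                   function(v) table(demographics[[v]], demographics$arm))
  if (length(arms) < 2L)
    return(list(counts = counts, tests = NULL, tukey_age = NULL,
                note = "single arm: descriptives only"))
  age_by <- split(demographics$age, demographics$arm)
  aov_age <- oneway_anova_from_summary(
    vapply(age_by, mean, numeric(1)),
    vapply(age_by, stats::sd, numeric(1)),
    vapply(age_by, length, numeric(1)))
  # exact enumeration when feasible; otherwise a seeded Monte-Carlo
  # estimate over margin-fixed tables (large three-arm tables)
  fisher_gender <- tryCatch(
    fisher_exact_test(counts$gender),
    error = function(e) withr::with_seed(
      1L, fisher_exact_test(counts$gender, monte_carlo = TRUE,
                            mc_draws = 2e5)))
  # characteristics collapsing to a single observed level (tiny cohorts)
  # yield NA statistics rather than failing the whole table
  safe_chi <- function(tab) tryCatch(
    chi_square_independence(tab),
    error = function(e) list(statistic = NA_real_, df = NA_real_,
                             p = NA_real_))
  chi_country <- safe_chi(counts$country)
  chi_education <- safe_chi(counts$education)
  tests <- tibble::tibble(
    characteristic = c("gender", "age", "country", "education"),
    test = c("fisher", "anova", "chi-square", "chi-square"),
    statistic = c(NA, aov_age$F, chi_country$statistic,
                  chi_education$statistic),
    df1 = c(NA, aov_age$df1, chi_country$df, chi_education$df),
    df2 = c(NA, aov_age$df2, NA, NA),
    p = c(fisher_gender$p, aov_age$p, chi_country$p, chi_education$p))
  tukey <- if (length(arms) >= 3L)
    tukey_hsd_from_summary(vapply(age_by, mean, numeric(1)),
                           vapply(age_by, stats::sd, numeric(1)),
                           vapply(age_by, length, numeric(1)),
                           labels = names(age_by))
  list(counts = counts, tests = tests, tukey_age = tukey)
}

#' Run the full analysis pipeline on a cohort
#'
#' Computes session metrics, applies the task exclusions, scores the
#' transdiagnostic dimensions (baseline-centred), restricts to completers,
#' and runs the enabled model families: baseline cross-sectional regression
#' of confidence on the three dimensions (age/gender/education controlled,
#' largest arm), per-arm random-intercept change models for confidence,
#' anxious-depression and task difficulty, the time-by-anxious-depression-
#' change interaction, per-arm change correlations, group-by-time ANOVAs
#' (with and without the change covariate), and the demographics table.
#'
#' @param cohort An `mc_cohort` (simulated or read from files).
#' @param config A [run_config()].
#' @return A list of class `mc_analysis` with elements `results` (one tidy
#'   tibble: model, term, estimate, se, statistic, df1, df2, p, n),
#'   `metrics`, `scores`, `catch`, `completers`, `funnel`, `table1`.
#' @export
analyze_cohort <- function(cohort, config = run_config()) {
  stopifnot(inherits(cohort, "mc_cohort"))
  if (nrow(cohort$trials) == 0L || nrow(cohort$items) == 0L)
    stop("empty cohort: no trials or no item responses", call. = FALSE)

  metrics <- apply_task_exclusions(compute_cohort_metrics(cohort$trials),
                                   closed_bounds = config$closed_bounds)
  weights <- if (!is.null(config$weights_file))
    tibble::as_tibble(utils::read.csv(config$weights_file))
  else cohort$weights
  scores <- score_dimensions(cohort$items, weights, centre = TRUE)
  catch <- detect_catch_failures(cohort$items)
  completers <- complete_case_filter(metrics, scores)
  funnel <- c(generated = length(unique(cohort$demographics$participant_id)),
              task_excluded_baseline =
                sum(metrics$excluded & metrics$timepoint == 0),
              task_excluded_followup =
                sum(metrics$excluded & metrics$timepoint == 1),
              completers = length(completers))
  if (length(completers) == 0L)
    stop("no completers after exclusions; nothing to analyse", call. = FALSE)

  demo <- cohort$demographics
  long <- metrics |>
    dplyr::filter(.data$participant_id %in% completers) |>
    dplyr::inner_join(scores, by = c("participant_id", "timepoint")) |>
    dplyr::inner_join(demo, by = "participant_id")
  wide <- long |>
    dplyr::select("participant_id", "arm", "timepoint",
                  "mean_confidence", "mean_dot_difference", "AD") |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = c("mean_confidence",
                                       "mean_dot_difference", "AD")) |>
    dplyr::mutate(
      d_confidence = .data$mean_confidence_1 - .data$mean_confidence_0,
      d_AD = .data$AD_1 - .data$AD_0)
  long <- dplyr::inner_join(
    long, wide[, c("participant_id", "d_confidence", "d_AD")],
    by = "participant_id")
  main_arm <- names(sort(table(long$arm), decreasing = TRUE))[1]

  res <- list()
  add <- function(model, tab) {
    for (col in c("estimate", "se", "statistic", "df1", "df2", "p", "n"))
      if (!col %in% names(tab)) tab[[col]] <- NA_real_
    res[[length(res) + 1L]] <<-
      dplyr::mutate(tab[c("term", "estimate", "se", "statistic",
                          "df1", "df2", "p", "n")],
                    model = model, .before = 1L)
  }

  base0 <- long[long$timepoint == 0 & long$arm == main_arm, ]
  if ("baseline" %in% config$analyses)
    add("baseline_confidence_dimensions",
        cross_sectional_regression(
          base0, "mean_confidence", c("AD", "CIT", "SW"),
          covariates = c("age", "gender", "education"),
          z_score_dummies = config$z_score_dummies))

  if ("change" %in% config$analyses)
    for (a in unique(long$arm))
      for (oc in c("mean_confidence", "AD", "mean_dot_difference")) {
        tab <- mixed_change_model(long[long$arm == a, ], oc)
        add(sprintf("change_%s_%s", oc, a), tab)
      }

  if ("interaction" %in% config$analyses) {
    arm_dat <- long[long$arm == main_arm, ]
    add("time_by_dAD_confidence",
        time_by_covariate_interaction(arm_dat, "mean_confidence", "d_AD"))
  }

  if ("correlation" %in% config$analyses)
    for (a in unique(long$arm)) {
      w <- wide[wide$participant_id %in%
                  long$participant_id[long$arm == a], ]
      ct <- change_correlation(w$d_AD, w$d_confidence)
      add(sprintf("corr_dAD_dconfidence_%s", a),
          tibble::tibble(term = "r", estimate = ct$r, df1 = ct$df,
                         p = ct$p, n = nrow(w)))
    }

  if ("anova" %in% config$analyses && length(unique(long$arm)) >= 2L) {
    for (oc in c("AD", "mean_confidence", "mean_dot_difference"))
      add(sprintf("anova_group_time_%s", oc),
          group_time_anova(long, oc))
    add("anova_group_time_dAD_confidence",
        group_time_anova(long, "mean_confidence", covariate = "d_AD"))
  }

  table1 <- if ("table1" %in% config$analyses)
    demographics_table(demo)

  structure(list(results = dplyr::bind_rows(res), metrics = metrics,
                 scores = scores, catch = catch, completers = completers,
                 funnel = funnel, table1 = table1, config = config),
            class = "mc_analysis")
}

#' Write a human-readable analysis report
#'
#' @param analysis An `mc_analysis` from [analyze_cohort()].
#' @param path Output file (markdown).
#' @return Invisibly, `path`.
#' @export
write_report <- function(analysis, path) {
  stopifnot(inherits(analysis, "mc_analysis"))
  fmt <- function(x, d = 3) ifelse(is.na(x), "", formatC(x, digits = d,
                                                         format = "f"))
  lines <- c("# Metacognitive bias treatment analysis", "",
             "## Participant funnel",
             sprintf("- %s: %d", names(analysis$funnel), analysis$funnel),
             "", "## Model results", "",
             "| model | term | estimate | se | stat | df1 | df2 | p | n |",
             "|---|---|---|---|---|---|---|---|---|")
  r <- analysis$results
  lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %s | %s | %s | %d |",
                            r$model, r$term, fmt(r$estimate), fmt(r$se),
                            fmt(r$statistic), fmt(r$df1, 1), fmt(r$df2, 1),
                            fmt(r$p, 4), as.integer(r$n)))
  if (!is.null(analysis$table1)) {
    t1 <- analysis$table1$tests
    lines <- c(lines, "", "## Demographics tests", "",
               "| characteristic | test | statistic | df | p |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %s | %s |", t1$characteristic,
                       t1$test, fmt(t1$statistic, 2), fmt(t1$df1, 0),
                       fmt(t1$p, 4)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a cohort and write its files
#'
#' The `simulate` pipeline stage: builds the design from a config,
#' generates the cohort and writes its delimited files.
#'
#' @param config A [run_config()].
#' @return The cohort, invisibly; files are written under
#'   `config$out_dir`.
#' @export
cli_simulate <- function(config = run_config()) {
  cohort <- generate_cohort(design_from_config(config))
  write_cohort(cohort, config$out_dir)
  invisible(cohort)
}

#' Analyze cohort files and write results
#'
#' The `analyze` pipeline stage: reads cohort files from
#' `config$out_dir`, runs [analyze_cohort()] and writes `results.csv` and
#' `report.md` beside the inputs.
#'
#' @param config A [run_config()].
#' @return The analysis, invisibly.
#' @export
cli_analyze <- function(config = run_config()) {
  cohort <- read_cohort(config$out_dir)
  analysis <- analyze_cohort(cohort, config)
  utils::write.csv(analysis$results,
                   file.path(config$out_dir, "results.csv"),
                   row.names = FALSE, na = "")
  write_report(analysis, file.path(config$out_dir, "report.md"))
  invisible(analysis)
}

#' Write and read a run configuration as key:value text
#'
#' Scalar fields are written one per line as `key: value`; design and
#' staircase overrides are namespaced as `design.<arg>` and
#' `staircase.<arg>`. A config written and read back reproduces the same
#' run.
#'
#' @param config A [run_config()].
#' @param path Text file path.
#' @return Invisibly, `path` (write) or the reconstructed `run_config`
#'   (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  kv <- c(seed = config$seed,
          out_dir = config$out_dir,
          weights_file = if (is.null(config$weights_file)) ""
                         else config$weights_file,
          analyses = paste(config$analyses, collapse = ","),
          z_score_dummies = config$z_score_dummies,
          closed_bounds = config$closed_bounds)
  for (nm in names(config$design_args))
    kv[paste0("design.", nm)] <- config$design_args[[nm]]
  for (nm in names(config$staircase_args))
    kv[paste0("staircase.", nm)] <- config$staircase_args[[nm]]
  writeLines(sprintf("%s: %s", names(kv), kv), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  kv <- stats::setNames(vals, keys)
  num <- function(x) if (grepl("^-?[0-9.]+$", x)) as.numeric(x) else x
  design_args <- lapply(kv[startsWith(keys, "design.")], num)
  names(design_args) <- sub("^design\\.", "", names(design_args))
  staircase_args <- lapply(kv[startsWith(keys, "staircase.")], num)
  names(staircase_args) <- sub("^staircase\\.", "", names(staircase_args))
  run_config(
    seed = as.integer(kv[["seed"]]),
    design_args = design_args,
    staircase_args = staircase_args,
    weights_file = if (nzchar(kv[["weights_file"]])) kv[["weights_file"]],
    out_dir = kv[["out_dir"]],
    analyses = strsplit(kv[["analyses"]], ",")[[1]],
    z_score_dummies = as.logical(kv[["z_score_dummies"]]),
    closed_bounds = as.logical(kv[["closed_bounds"]]))
}

#' Write or read the item scoring key as delimited text
#'
#' @param key A scoring key tibble ([scoring_key()] by default).
#' @param path CSV file path.
#' @return Invisibly `path`, or the key tibble when reading.
#' @export
write_scoring_key <- function(key = scoring_key(), path) {
  utils::write.csv(key, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_scoring_key
#' @export
read_scoring_key <- function(path) {
  key <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  key$catch_required <- as.integer(key$catch_required)
  key
}
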