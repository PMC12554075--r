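#' Paired two-tailed t-test on matched metric values
#'
#' For paired values `x`, `y` (one pair per independent experiment), forms
#' the differences `d = x - y` and computes `t = mean(d) / (sd(d) /
#' sqrt(n))` with `n - 1` degrees of freedom and a two-tailed p-value.
#' Identical pairs (`sd(d) = 0`) are a degenerate comparison: the statistic
#' is undefined and is returned as `NA` with a warning rather than an
#' infinity.
#'
#' @param x,y Numeric vectors of equal length `n >= 2`, same pairing order,
#'   all finite.
#' @return A one-row tibble: `n`, `mean_diff`, `sd_diff`, `t_stat`, `df`,
#'   `p_value`.
#' @examples
#' paired_t(c(2, 3, 4), c(1, 1, 1)) # diffs 1,2,3 -> t = 2*sqrt(3)
#' @export
paired_t <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2) {
    abort("`x` and `y` must be equal-length vectors with n >= 2.",
          class = "bretropy_validation_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("Paired values must all be finite (drop undefined metrics upstream).",
          class = "bretropy_validation_error")
  }
  d <- x - y
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    warn("Degenerate comparison: all paired differences are identical.",
         class = "bretropy_degenerate_comparison")
    return(tibble(n = n, mean_diff = m, sd_diff = 0, t_stat = NA_real_,
                  df = n - 1, p_value = NA_real_))
  }
  t_stat <- m / (s / sqrt(n))
  tibble(n = n, mean_diff = m, sd_diff = s, t_stat = t_stat, df = n - 1,
         p_value = 2 * pt(-abs(t_stat), df = n - 1))
}

#' Percentile bootstrap confidence interval for a mean difference
#'
#' Resamples the paired differences with replacement `n_boot` times,
#' takes the mean of each resample, and returns the percentile interval at
#' the requested level. Deterministic under a fixed seed.
#'
#' @param diffs Numeric vector of paired differences, length `>= 2`.
#' @param n_boot Number of resamples (default 1000), `>= 100`.
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Named numeric vector `c(ci_low = , ci_high = )`.
#' @examples
#' bootstrap_ci(c(0.1, 0.3, 0.2, 0.4), seed = 1)
#' @export
bootstrap_ci <- function(diffs, n_boot = 1000L, level = 0.95, seed = 1L) {
  diffs <- as.numeric(diffs)
  n <- length(diffs)
  if (n < 2 || !all(is.finite(diffs))) {
    abort("`diffs` must be >= 2 finite values.",
          class = "bretropy_validation_error")
  }
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  check_number(level, "level", lower = 0, upper = 1, strict_lower = TRUE)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  means <- colMeans(matrix(diffs[idx], nrow = n))
  qs <- quantile(means, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  c(ci_low = qs[1], ci_high = qs[2])
}

# Average replicate wells within each experiment, then return one value per
# (experiment, condition): wells on a plate are not independent, so the
# experiment is the pairing/error unit.
experiment_means <- function(values) {
  values |>
    dplyr::group_by(.data$experiment_id, .data$condition) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}

#' Compare entropy metrics between conditions
#'
#' For each configured condition pair and each selected metric, averages
#' wells within experiment (the independent unit), pairs the per-experiment
#' means across the two conditions, and reports the paired two-tailed
#' t-test ([paired_t()]) together with a percentile bootstrap confidence
#' interval ([bootstrap_ci()]) for the mean difference (condition 1 minus
#' condition 2). Undefined metric values (e.g. Sample Entropy with no
#' template matches) are dropped pairwise with a warning.
#'
#' @param metrics Metric tibble from [analyze_traces()].
#' @param config An [analysis_config()]; `comparisons`,
#'   `comparison_metrics`, `n_boot`, `p_adjust` and `seed` are used.
#' @param tau Coarse-graining scale to compare at (default 1).
#' @return A tibble with one row per (pair, metric): `metric`, `alpha`,
#'   `condition_1`, `condition_2`, `n`, `mean_diff`, `sd_diff`, `t_stat`,
#'   `df`, `p_value` (and `p_adj` if adjustment is on), `ci_low`,
#'   `ci_high`, `n_boot`, `seed`.
#' @export
compare_conditions <- function(metrics, config = analysis_config(),
                               tau = 1L) {
  config <- as_analysis_config(config)
  stopifnot(is.data.frame(metrics))
  metrics <- dplyr::filter(metrics, .data$tau == !!tau)
  present <- unique(metrics$condition)
  specs <- tidyr::expand_grid(
    pair = config$comparisons,
    config$comparison_metrics
  )
  rows <- purrr::pmap(specs, function(pair, metric, alpha) {
    if (!all(pair %in% present)) {
      abort(sprintf("Comparison (%s vs %s): condition not present in the metrics table.",
                    pair[1], pair[2]), class = "bretropy_config_error")
    }
    vals <- metric_values(metrics, metric, alpha) |>
      dplyr::filter(.data$condition %in% pair)
    dropped <- sum(!is.finite(vals$value))
    if (dropped > 0) {
      warn(sprintf("Comparison (%s vs %s, %s): dropped %d undefined value(s).",
                   pair[1], pair[2], metric, dropped))
      vals <- dplyr::filter(vals, is.finite(.data$value))
    }
    wide <- experiment_means(vals) |>
      tidyr::pivot_wider(names_from = "condition", values_from = "value") |>
      tidyr::drop_na()
    if (nrow(wide) < 2) {
      abort(sprintf("Comparison (%s vs %s, %s): fewer than 2 complete experiment pairs.",
                    pair[1], pair[2], metric),
            class = "bretropy_validation_error")
    }
    x <- wide[[pair[1]]]
    y <- wide[[pair[2]]]
    tt <- paired_t(x, y)
    ci <- bootstrap_ci(x - y, n_boot = config$n_boot, seed = config$seed)
    dplyr::bind_cols(
      tibble(metric = metric, alpha = alpha,
             condition_1 = pair[1], condition_2 = pair[2]),
      tt,
      tibble(ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
             n_boot = config$n_boot, seed = config$seed)
    )
  })
  out <- purrr::list_rbind(rows)
  if (config$p_adjust != "none") {
    out$p_adj <- stats::p.adjust(out$p_value, method = config$p_adjust)
    out <- dplyr::relocate(out, "p_adj", .after = "p_value")
  }
  out
}

# Pull one metric's per-well values out of the wide metric table.
metric_values <- function(metrics, metric, alpha = NA_real_) {
  id <- c("experiment_id", "well_id", "condition")
  if (metric %in% c("sampen", "H0")) {
    metrics |>
      dplyr::distinct(dplyr::pick(dplyr::all_of(c(id, metric)))) |>
      dplyr::rename(value = dplyr::all_of(metric))
  } else if (metric %in% c("H_raw", "H_norm")) {
    if (is.na(alpha)) {
      abort(sprintf("Metric '%s' needs an `alpha`.", metric),
            class = "bretropy_config_error")
    }
    sel <- dplyr::filter(metrics, .data$alpha == !!alpha)
    if (nrow(sel) == 0) {
      abort(sprintf("No rows at alpha = %s in the metrics table.",
                    format(alpha)), class = "bretropy_config_error")
    }
    dplyr::select(sel, dplyr::all_of(c(id, metric))) |>
      dplyr::rename(value = dplyr::all_of(metric))
  } else {
    abort(sprintf("Unknown metric '%s'.", metric),
          class = "bretropy_config_error")
  }
}

#' Per-condition mean and standard error of a metric
#'
#' Averages replicate wells within each experiment first, then reports the
#' cross-experiment mean and standard error of the mean (`s / sqrt(n)`) per
#' condition and metric — matching how replicate BRET kinetics are usually
#' summarized (means +/- SEM over independent experiments). Groups with a
#' single experiment get `NA` SEM; empty groups are dropped with a warning
#' upstream.
#'
#' @param metrics Metric tibble from [analyze_traces()].
#' @param metric_table Data frame with columns `metric`, `alpha` selecting
#'   the metrics to summarize (default [default_comparison_metrics()]).
#' @param tau Coarse-graining scale (default 1).
#' @return A tibble: `metric`, `alpha`, `condition`, `n_experiments`,
#'   `mean`, `sem`.
#' @export
summarize_metrics <- function(metrics,
                              metric_table = default_comparison_metrics(),
                              tau = 1L) {
  stopifnot(is.data.frame(metrics))
  metrics <- dplyr::filter(metrics, .data$tau == !!tau)
  purrr::pmap(metric_table, function(metric, alpha) {
    vals <- metric_values(metrics, metric, alpha)
    n_undef <- sum(!is.finite(vals$value))
    if (n_undef > 0) {
      warn(sprintf("Summary of %s: dropped %d undefined value(s).",
                   metric, n_undef))
      vals <- dplyr::filter(vals, is.finite(.data$value))
    }
    experiment_means(vals) |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(
        n_experiments = dplyr::n(),
        mean = mean(.data$value),
        sem = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n())
              else NA_real_,
        .groups = "drop") |>
      dplyr::mutate(metric = metric, alpha = alpha, .before = 1)
  }) |>
    purrr::list_rbind()
}
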