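#' Per-trace entropy metrics for a whole experiment set
#'
#' Runs the per-trace metric pass over every well: restricts each trace to
#' the configured segment (post-stimulation by default — the
#' ligand-response window), coarse-grains it at each scale in `tau_list`,
#' and computes the Sample Entropy plus the Hartley-normalized Renyi
#' spectrum ([renyi_spectrum()]). Traces that cannot be analyzed (zero
#' variance, too short after coarse-graining) are skipped, not dropped
#' silently: each skip is recorded with its reason in the `"skipped"`
#' attribute and raised as a warning. Output is deterministic given input
#' and configuration.
#'
#' @param traces A validated trace tibble ([validate_traces()] /
#'   [read_traces()] / [simulate_experiment_set()]).
#' @param config An [analysis_config()].
#' @return A tibble with one row per (trace, scale, order): columns
#'   `experiment_id`, `well_id`, `condition`, `tau`, `alpha`, `H_raw`,
#'   `H0`, `H_norm`, `sampen`. Attribute `"skipped"` holds a tibble of
#'   skipped (trace, scale) combinations with reasons.
#' @examples
#' traces <- simulate_experiment_set(simulation_config(seed = 3))
#' metrics <- analyze_traces(traces, analysis_config())
#' dplyr::n_distinct(metrics$experiment_id, metrics$well_id,
#'                   metrics$condition)
#' @export
analyze_traces <- function(traces, config = analysis_config()) {
  config <- as_analysis_config(config)
  traces <- validate_traces(traces)
  wells <- traces |>
    dplyr::group_by(.data$experiment_id, .data$well_id, .data$condition) |>
    dplyr::group_split()
  skipped <- list()
  rows <- list()
  for (w in wells) {
    seg <- segment_values(w$time_s, w$ratio, w$stim_time_s[1],
                          config$segment)
    key <- tibble(experiment_id = w$experiment_id[1],
                  well_id = w$well_id[1], condition = w$condition[1])
    for (tau in config$tau_list) {
      res <- tryCatch(
        {
          series <- coarse_grain(seg, tau)
          withCallingHandlers(
            renyi_spectrum(series, alphas = config$alphas,
                           n_support = config$n_support,
                           support_extent = config$support_extent,
                           p_threshold = config$p_threshold,
                           m = config$m, r_factor = config$r_factor,
                           correction = config$correction),
            bretropy_undefined_sampen = function(cnd) {
              # keep the spectrum; the NA sampen is logged below
              invokeRestart("muffleWarning")
            })
        },
        bretropy_degenerate_error = function(cnd) conditionMessage(cnd),
        bretropy_length_error = function(cnd) conditionMessage(cnd)
      )
      if (is.character(res)) {
        skipped[[length(skipped) + 1]] <-
          dplyr::mutate(key, tau = tau, reason = res)
      } else {
        if (is.na(res$sampen[1])) {
          skipped[[length(skipped) + 1]] <- dplyr::mutate(
            key, tau = tau,
            reason = "Sample Entropy undefined (no (m+1)-template matches); spectrum kept")
        }
        rows[[length(rows) + 1]] <-
          dplyr::bind_cols(key, dplyr::mutate(res, tau = tau))
      }
    }
  }
  if (length(rows) == 0) {
    abort("No analyzable traces (all wells skipped).",
          class = "bretropy_validation_error")
  }
  skipped <- if (length(skipped)) purrr::list_rbind(skipped) else
    tibble(experiment_id = character(0), well_id = character(0),
           condition = character(0), tau = integer(0), reason = character(0))
  if (nrow(skipped) > 0) {
    warn(sprintf("Skipped %d (trace, scale) combination(s); see attr(x, 'skipped').",
                 nrow(skipped)), class = "bretropy_skip_log")
  }
  out <- purrr::list_rbind(rows) |>
    dplyr::select(dplyr::all_of(c("experiment_id", "well_id", "condition",
                                  "tau", "alpha", "H_raw", "H0", "H_norm",
                                  "sampen")))
  attr(out, "skipped") <- skipped
  out
}

#' Run the whole entropy pipeline
#'
#' simulate (optional) -> analyze -> compare -> report, with every artifact
#' written under `out_dir`: the simulated traces (`traces.csv`), the metric
#' tables (`results_metrics.csv` / `.json`), the comparison table
#' (`results_comparisons.csv`), a human-readable `report.md`, and a
#' `manifest.json` echoing every parameter, seed and skip so a stochastic
#' run can be audited and reproduced. Identical configurations and seeds
#' produce byte-identical outputs.
#'
#' @param sim_config A [simulation_config()], or `NULL` when `traces` is
#'   given.
#' @param analysis A [analysis_config()].
#' @param traces Optional pre-loaded trace tibble (overrides simulation).
#' @param out_dir Output directory, created if needed; `NULL` writes
#'   nothing.
#' @return An object of class `"entropy_pipeline"`: a list with `traces`,
#'   `metrics`, `comparisons`, `summary`, `skipped`, `sim_config`,
#'   `analysis`, `files`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
run_pipeline <- function(sim_config = simulation_config(),
                         analysis = analysis_config(), traces = NULL,
                         out_dir = NULL) {
  analysis <- as_analysis_config(analysis)
  if (is.null(traces)) {
    sim_config <- as_simulation_config(sim_config)
    traces <- simulate_experiment_set(sim_config)
  } else {
    traces <- validate_traces(traces)
  }
  metrics <- suppressWarnings(analyze_traces(traces, analysis))
  skipped <- attr(metrics, "skipped")
  comparisons <- suppressWarnings(compare_conditions(metrics, analysis))
  summary_tbl <- suppressWarnings(
    summarize_metrics(metrics, analysis$comparison_metrics))

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    traces_path <- file.path(out_dir, "traces.csv")
    write_traces(traces, traces_path)
    files <- c(traces = traces_path,
               write_metrics(metrics, comparisons,
                             file.path(out_dir, "results")))
    report_path <- file.path(out_dir, "report.md")
    report(metrics, comparisons, report_path, summary_tbl = summary_tbl)
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(
      list(simulation = if (inherits(sim_config, "simulation_config"))
             unclass_config(sim_config) else NULL,
           analysis = unclass_config(analysis),
           skipped = skipped,
           n_traces = dplyr::n_distinct(
             traces[c("experiment_id", "well_id", "condition")])),
      manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
      na = "null")
    files <- c(files, report = report_path, manifest = manifest_path)
  }
  structure(
    list(traces = traces, metrics = metrics, comparisons = comparisons,
         summary = summary_tbl, skipped = skipped,
         sim_config = if (inherits(sim_config, "simulation_config"))
           sim_config else NULL,
         analysis = analysis, files = files),
    class = "entropy_pipeline")
}

# Configs -> plain nested lists for JSON (classes stripped, Inf-safe).
unclass_config <- function(x) {
  if (is.list(x)) {
    lapply(setNames(unclass(x), names(unclass(x))), unclass_config)
  } else if (is.numeric(x) && any(is.infinite(x))) {
    as.character(x)
  } else {
    x
  }
}

#' Write a plain-text analysis report
#'
#' Renders the per-condition metric summary (mean +/- SEM across
#' experiments) and the condition-comparison table as a Markdown document.
#' Regeneration from the same inputs is idempotent; plotting never touches
#' the metric files.
#'
#' @param metrics Metric tibble from [analyze_traces()].
#' @param comparisons Comparison tibble (may be empty / `NULL`).
#' @param path Output file.
#' @param summary_tbl Optional precomputed [summarize_metrics()] table.
#' @return `path`, invisibly.
#' @export
report <- function(metrics, comparisons = NULL, path,
                   summary_tbl = NULL) {
  if (is.null(summary_tbl)) {
    summary_tbl <- suppressWarnings(summarize_metrics(metrics))
  }
  fmt <- function(x) formatC(x, digits = 4, format = "g")
  lines <- c("# Entropy analysis report", "",
             "## Per-condition summary (mean +/- SEM over experiments)", "",
             "| metric | alpha | condition | n | mean | SEM |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(summary_tbl))) {
    r <- summary_tbl[i, ]
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %d | %s | %s |", r$metric,
      ifelse(is.na(r$alpha), "", format(r$alpha)), r$condition,
      r$n_experiments, fmt(r$mean),
      ifelse(is.na(r$sem), "NA", fmt(r$sem))))
  }
  if (!is.null(comparisons) && nrow(comparisons) > 0) {
    lines <- c(lines, "", "## Paired condition comparisons", "",
               "| metric | alpha | pair | n | mean diff | t | df | p | 95% CI |",
               "|---|---|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(comparisons))) {
      r <- comparisons[i, ]
      lines <- c(lines, sprintf(
        "| %s | %s | %s vs %s | %d | %s | %s | %d | %s | [%s, %s] |",
        r$metric, ifelse(is.na(r$alpha), "", format(r$alpha)),
        r$condition_1, r$condition_2, r$n, fmt(r$mean_diff),
        ifelse(is.na(r$t_stat), "NA", fmt(r$t_stat)), r$df,
        ifelse(is.na(r$p_value), "NA", fmt(r$p_value)),
        fmt(r$ci_low), fmt(r$ci_high)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.entropy_pipeline <- function(x, ...) {
  cat("<entropy_pipeline>\n")
  cat(sprintf("  traces:      %d wells, %d conditions\n",
              dplyr::n_distinct(x$traces[c("experiment_id", "well_id",
                                           "condition")]),
              dplyr::n_distinct(x$traces$condition)))
  cat(sprintf("  metrics:     %d rows (%d skipped)\n", nrow(x$metrics),
              nrow(x$skipped)))
  cat(sprintf("  comparisons: %d\n", nrow(x$comparisons)))
  invisible(x)
}

#' Tidy the fitted pipeline: the condition-comparison table
#'
#' @param x An `entropy_pipeline` object.
#' @param ... Unused.
#' @return The comparison tibble (one row per condition pair and metric).
#' @export
tidy.entropy_pipeline <- function(x, ...) x$comparisons

#' One-row pipeline overview
#'
#' @param x An `entropy_pipeline` object.
#' @param ... Unused.
#' @return A one-row tibble: trace/metric/comparison counts, skip count,
#'   smallest comparison p-value.
#' @export
glance.entropy_pipeline <- function(x, ...) {
  tibble(
    n_traces = dplyr::n_distinct(
      x$traces[c("experiment_id", "well_id", "condition")]),
    n_conditions = dplyr::n_distinct(x$traces$condition),
    n_metric_rows = nrow(x$metrics),
    n_skipped = nrow(x$skipped),
    n_comparisons = nrow(x$comparisons),
    min_p_value = if (nrow(x$comparisons) > 0)
      suppressWarnings(min(x$comparisons$p_value, na.rm = TRUE))
      else NA_real_
  )
}

#' @export
autoplot.entropy_pipeline <- function(object, ...) {
  plot_spectrum(object$metrics, ...)
}
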