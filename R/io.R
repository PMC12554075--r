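#' Validate a long table of kinetic traces
#'
#' Checks the trace-table contract used everywhere in the package: columns
#' `experiment_id`, `well_id`, `condition`, `time_s`, `ratio`,
#' `stim_time_s`; within each (experiment, well, condition) trace, strictly
#' increasing times, at least 10 samples, finite ratios, a single
#' stimulation time inside `[0, max(time_s)]`, and no duplicated time
#' points.
#'
#' @param traces A data frame of traces in long format.
#' @return The validated traces as a tibble (invisibly usable in pipes).
#' @export
validate_traces <- function(traces) {
  if (!is.data.frame(traces)) {
    abort("`traces` must be a data frame.",
          class = "bretropy_validation_error")
  }
  missing_cols <- setdiff(trace_cols, names(traces))
  if (length(missing_cols) > 0) {
    abort(paste0("Trace table is missing required column(s): ",
                 paste0("`", missing_cols, "`", collapse = ", "), "."),
          class = "bretropy_format_error")
  }
  traces <- as_tibble(traces)
  by_well <- dplyr::group_by(traces, .data$experiment_id, .data$well_id,
                             .data$condition)
  check <- dplyr::summarise(
    by_well,
    n = dplyr::n(),
    dup_time = anyDuplicated(.data$time_s) > 0,
    non_monotone = is.unsorted(.data$time_s, strictly = TRUE),
    bad_ratio = !all(is.finite(.data$ratio)),
    n_stim = dplyr::n_distinct(.data$stim_time_s),
    stim_out = any(.data$stim_time_s < 0 |
                     .data$stim_time_s > max(.data$time_s)),
    .groups = "drop"
  )
  fail <- function(mask, what) {
    if (any(mask)) {
      w <- check[mask, ][1, ]
      abort(sprintf("Well (%s, %s, %s): %s.", w$experiment_id, w$well_id,
                    w$condition, what),
            class = "bretropy_validation_error")
    }
  }
  fail(check$dup_time, "duplicated time points")
  fail(check$non_monotone, "times are not strictly increasing")
  fail(check$n < 10, "fewer than 10 samples")
  fail(check$bad_ratio, "non-finite BRET ratio values")
  fail(check$n_stim > 1, "multiple stimulation times in one well")
  fail(check$stim_out, "stimulation time outside the recorded time range")
  traces
}

#' Read kinetic traces from CSV
#'
#' Reads the package's long trace format (comma separator, `.` decimal,
#' UTF-8, mandatory header; columns `experiment_id`, `well_id`,
#' `condition`, `time_s`, `ratio`, `stim_time_s`), sorts each well by time
#' and validates the trace contract ([validate_traces()]). Ratios are
#' stored raw — no baseline subtraction happens at the I/O layer.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of traces.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path),
          class = "bretropy_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(trace_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("'", path, "' is missing required column(s): ",
                 paste0("`", missing_cols, "`", collapse = ", "), "."),
          class = "bretropy_format_error")
  }
  raw |>
    dplyr::mutate(dplyr::across(dplyr::all_of(c("experiment_id", "well_id",
                                                "condition")), as.character),
                  dplyr::across(dplyr::all_of(c("time_s", "ratio",
                                                "stim_time_s")), as.numeric)) |>
    dplyr::arrange(.data$experiment_id, .data$condition, .data$well_id,
                   .data$time_s) |>
    dplyr::select(dplyr::all_of(trace_cols)) |>
    validate_traces()
}

#' Write kinetic traces to CSV
#'
#' Inverse of [read_traces()]: fixed column order `experiment_id, well_id,
#' condition, time_s, ratio, stim_time_s`, full double precision. Refuses
#' non-finite ratios. An empty trace table yields a header-only file.
#'
#' @param traces A trace tibble (validated unless empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (!is.data.frame(traces)) {
    abort("`traces` must be a data frame.",
          class = "bretropy_validation_error")
  }
  if (nrow(traces) > 0) {
    traces <- validate_traces(traces)
  } else {
    traces <- as_tibble(traces)
    for (col in setdiff(trace_cols, names(traces))) {
      traces[[col]] <- if (col %in% c("experiment_id", "well_id", "condition"))
        character(0) else numeric(0)
    }
  }
  traces <- dplyr::arrange(traces, .data$experiment_id, .data$condition,
                           .data$well_id, .data$time_s)
  readr::write_csv(traces[, trace_cols], path, progress = FALSE)
  invisible(path)
}

#' Write entropy metrics and condition comparisons to disk
#'
#' Serializes the per-trace metric table and comparison rows in two
#' machine-readable forms: a long CSV (one row per trace, scale, metric and
#' order — schema below) and a JSON document carrying the full order grid
#' per trace plus the comparison records. All numbers round-trip at full
#' double precision (at least 15 significant digits).
#'
#' Long CSV schema: `experiment_id, well_id, condition, tau, metric, alpha,
#' value` where `metric` is one of `sampen` (`alpha` empty), `H0` (`alpha`
#' empty), `H_raw`, `H_norm` (one row per order; `alpha = Inf` written as
#' `Inf`). One trace at one scale therefore occupies
#' `2 * n_orders + 2` rows.
#'
#' @param metrics Metric tibble from [analyze_traces()].
#' @param comparisons Comparison tibble from [compare_conditions()], or
#'   `NULL`.
#' @param path_prefix Output path prefix; writes `<prefix>_metrics.csv`,
#'   `<prefix>_metrics.json` and, when comparisons are given,
#'   `<prefix>_comparisons.csv` / `.json`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_metrics <- function(metrics, comparisons = NULL, path_prefix) {
  stopifnot(is.data.frame(metrics))
  long <- metrics_long(metrics)
  files <- c(metrics_csv = paste0(path_prefix, "_metrics.csv"),
             metrics_json = paste0(path_prefix, "_metrics.json"))
  readr::write_csv(long, files[["metrics_csv"]], progress = FALSE)

  per_trace <- if (nrow(metrics) == 0) list() else {
    metrics |>
      dplyr::group_by(.data$experiment_id, .data$well_id, .data$condition,
                      .data$tau) |>
      dplyr::group_map(function(g, key) {
        list(experiment_id = key$experiment_id, well_id = key$well_id,
             condition = key$condition, tau = key$tau,
             sampen = g$sampen[1], H0 = g$H0[1],
             # alpha as strings: JSON has no Inf literal
             alpha = as.character(g$alpha), H_raw = g$H_raw,
             H_norm = g$H_norm)
      })
  }
  jsonlite::write_json(
    list(metrics = per_trace,
         comparisons = if (is.null(comparisons)) list() else comparisons),
    files[["metrics_json"]], auto_unbox = TRUE, digits = NA, pretty = TRUE,
    na = "null")

  if (!is.null(comparisons)) {
    files <- c(files,
               comparisons_csv = paste0(path_prefix, "_comparisons.csv"))
    readr::write_csv(comparisons, files[["comparisons_csv"]],
                     progress = FALSE)
  }
  invisible(files)
}

# Wide per-(trace, tau, alpha) metric rows -> documented long form.
metrics_long <- function(metrics) {
  id <- c("experiment_id", "well_id", "condition", "tau")
  if (nrow(metrics) == 0) {
    return(tibble(experiment_id = character(0), well_id = character(0),
                  condition = character(0), tau = integer(0),
                  metric = character(0), alpha = numeric(0),
                  value = numeric(0)))
  }
  per_alpha <- metrics |>
    tidyr::pivot_longer(dplyr::all_of(c("H_raw", "H_norm")),
                        names_to = "metric", values_to = "value") |>
    dplyr::select(dplyr::all_of(c(id, "metric", "alpha", "value")))
  scalars <- metrics |>
    dplyr::distinct(dplyr::pick(dplyr::all_of(c(id, "sampen", "H0")))) |>
    tidyr::pivot_longer(dplyr::all_of(c("sampen", "H0")),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(alpha = NA_real_) |>
    dplyr::select(dplyr::all_of(c(id, "metric", "alpha", "value")))
  dplyr::bind_rows(scalars, per_alpha) |>
    dplyr::arrange(.data$experiment_id, .data$condition, .data$well_id,
                   .data$tau, .data$metric, .data$alpha)
}

#' Read back a metrics JSON document
#'
#' Restores the tibbles written by [write_metrics()] from the JSON file.
#'
#' @param path Path to a `*_metrics.json` file.
#' @return A list with elements `metrics` and `comparisons` (tibbles).
#' @export
read_metrics_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  metrics <- if (length(doc$metrics) == 0) tibble() else {
    as_tibble(doc$metrics) |>
      tidyr::unnest(dplyr::all_of(c("alpha", "H_raw", "H_norm"))) |>
      dplyr::mutate(alpha = as.numeric(.data$alpha)) |>
      dplyr::select(dplyr::all_of(c("experiment_id", "well_id", "condition",
                                    "tau", "alpha", "H_raw", "H0", "H_norm",
                                    "sampen")))
  }
  comparisons <- if (length(doc$comparisons) == 0) tibble() else
    as_tibble(doc$comparisons)
  list(metrics = metrics, comparisons = comparisons)
}
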