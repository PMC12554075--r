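# Numerically stable log(sum(exp(x))); tolerates -Inf entries.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Required columns of the long trace table.
trace_cols <- c("experiment_id", "well_id", "condition", "time_s", "ratio",
                "stim_time_s")

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "bretropy_config_error")
  }
  bad <- if (strict_lower) x <= lower else x < lower
  if (bad || x > upper) {
    abort(sprintf("`%s` = %g is outside its valid range.", name, x),
          class = "bretropy_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "bretropy_config_error")
  }
  invisible(as.integer(x))
}

# Restrict one well's samples to the analysis segment.
segment_values <- function(time_s, ratio, stim_time_s, segment) {
  keep <- switch(segment,
    post_stim = time_s >= stim_time_s,
    full      = rep(TRUE, length(time_s)),
    baseline  = time_s < stim_time_s,
    abort(sprintf("Unknown segment '%s'.", segment),
          class = "bretropy_config_error")
  )
  ratio[keep]
}
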