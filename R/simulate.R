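# Deterministic per-trace seed: fold the indices into the master seed with
# a 31-bit linear congruential step (exact in doubles, stable across
# platforms and languages).
trace_seed <- function(seed, experiment_i, condition_i, well_i) {
  mod <- 2147483647 # 2^31 - 1
  h <- seed %% mod
  for (v in c(experiment_i, condition_i, well_i)) {
    h <- (h * 69069 + v) %% mod
  }
  as.integer(h)
}

# Pareto (type I) waiting times: minimum `scale`, tail exponent `tail`.
# Inversion of the CDF 1 - (scale/w)^tail.
rpareto <- function(n, scale, tail) {
  scale * runif(n)^(-1 / tail)
}

# Marginally-stationary AR(1) stream with sd `sigma`; phi = 0 reproduces the
# iid Gaussian stream draw-for-draw.
ar1_noise <- function(n, sigma, phi) {
  z <- rnorm(n)
  e <- numeric(n)
  e[1] <- sigma * z[1]
  if (n > 1) {
    s_inn <- sigma * sqrt(1 - phi^2)
    for (i in 2:n) e[i] <- phi * e[i - 1] + s_inn * z[i]
  }
  e
}

# Superpose exponentially-relaxing bursts at renewal event times drawn from
# a Pareto waiting-time distribution, starting at the stimulation time.
# Individual waiting times are truncated at the trace duration so the
# renewal loop terminates even for tail exponents <= 1 (diverging mean).
burst_component <- function(time_s, stim_time, total_duration, spec) {
  out <- numeric(length(time_s))
  t_event <- stim_time
  repeat {
    w <- min(rpareto(1L, spec$burst_rate_scale, spec$burst_tail),
             total_duration)
    t_event <- t_event + w
    if (t_event > total_duration) break
    on <- time_s >= t_event
    out[on] <- out[on] +
      spec$burst_amplitude * exp(-spec$burst_decay * (time_s[on] - t_event))
  }
  out
}

#' Simulate one BRET kinetic trace
#'
#' Generates one well's time series: a flat baseline up to the stimulation
#' time, then a mono-exponential association
#' `baseline + amplitude * (1 - exp(-rate * (t - stim_time)))`, with noise
#' drawn per the condition's [noise_spec()]. Identical seeds give identical
#' traces.
#'
#' @param kinetics A [condition_kinetics()].
#' @param dt Sampling interval, seconds.
#' @param baseline_duration Stimulation time, seconds.
#' @param total_duration Total recording time, seconds.
#' @param seed Integer seed for this trace's noise.
#' @param experiment_id,well_id Labels attached to the output rows.
#'
#' @return A tibble with columns `experiment_id`, `well_id`, `condition`,
#'   `time_s`, `ratio`, `stim_time_s` — one row per sample, times
#'   `0, dt, ..., floor(total/dt)*dt`.
#' @examples
#' tr <- simulate_trace(condition_kinetics("AngII", amplitude = 0.05),
#'                      seed = 7)
#' head(tr)
#' @export
simulate_trace <- function(kinetics, dt = 30, baseline_duration = 300,
                           total_duration = 2100, seed = 1L,
                           experiment_id = "E1", well_id = "W1") {
  if (!inherits(kinetics, "condition_kinetics")) {
    abort("`kinetics` must be a condition_kinetics().",
          class = "bretropy_config_error")
  }
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(baseline_duration, "baseline_duration", lower = 0,
               strict_lower = TRUE)
  check_number(total_duration, "total_duration", lower = baseline_duration,
               strict_lower = TRUE)

  time_s <- seq(0, by = dt, length.out = floor(total_duration / dt) + 1)
  stim <- baseline_duration
  mean_curve <- ifelse(
    time_s < stim,
    kinetics$baseline,
    kinetics$baseline +
      kinetics$amplitude * (1 - exp(-kinetics$rate * (time_s - stim)))
  )

  spec <- kinetics$noise
  n <- length(time_s)
  noise <- local({
    set.seed(seed)
    base <- switch(spec$family,
      gaussian_iid = if (spec$sigma > 0) spec$sigma * rnorm(n) else numeric(n),
      ar1          = ar1_noise(n, spec$sigma, spec$phi),
      burst_renewal = if (spec$sigma > 0) spec$sigma * rnorm(n) else numeric(n)
    )
    if (spec$family == "burst_renewal") {
      base <- base + burst_component(time_s, stim, total_duration, spec)
    }
    base
  })

  tibble(
    experiment_id = experiment_id, well_id = well_id,
    condition = kinetics$label, time_s = time_s,
    ratio = mean_curve + noise, stim_time_s = stim
  )
}

#' Simulate a full multi-condition, multi-experiment BRET dataset
#'
#' Produces `n_experiments * n_wells` traces per condition on a common time
#' grid. Each trace's RNG seed is derived from the master seed and the
#' (experiment, condition, well) indices by repeated 31-bit congruential
#' folding (`h <- (h * 69069 + index) mod 2^31-1`), so the same
#' configuration always yields byte-identical data and any single trace can
#' be regenerated in isolation.
#'
#' @param config A [simulation_config()].
#' @return A long tibble of traces (see [simulate_trace()] for columns),
#'   ordered by experiment, condition, well, time.
#' @examples
#' traces <- simulate_experiment_set(simulation_config(seed = 42))
#' dplyr::count(traces, condition)
#' @export
simulate_experiment_set <- function(config = simulation_config()) {
  config <- as_simulation_config(config)
  grid <- tidyr::expand_grid(
    experiment_i = seq_len(config$n_experiments),
    condition_i = seq_along(config$conditions),
    well_i = seq_len(config$n_wells)
  )
  purrr::pmap(grid, function(experiment_i, condition_i, well_i) {
    simulate_trace(
      config$conditions[[condition_i]],
      dt = config$dt,
      baseline_duration = config$baseline_duration,
      total_duration = config$total_duration,
      seed = trace_seed(config$seed, experiment_i, condition_i, well_i),
      experiment_id = sprintf("E%d", experiment_i),
      well_id = sprintf("W%d", well_i)
    )
  }) |>
    purrr::list_rbind()
}
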