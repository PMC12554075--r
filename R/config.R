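#' Noise model for a simulated BRET trace
#'
#' Describes the stochastic component added to the deterministic association
#' curve of one condition. Three families are available:
#'
#' * `"gaussian_iid"` — independent Gaussian noise of standard deviation
#'   `sigma` (BRET-ratio units) at every sample.
#' * `"ar1"` — stationary first-order autoregressive noise with lag-1
#'   coefficient `phi` and *marginal* standard deviation `sigma`. Innovations
#'   are scaled by `sqrt(1 - phi^2)` so that `phi = 0` reproduces the
#'   `gaussian_iid` stream draw-for-draw under the same seed.
#' * `"burst_renewal"` — a renewal process of signaling bursts with
#'   heavy-tailed (Pareto) waiting times, the statistical emulation of
#'   non-ergodic, intermittent receptor-state switching. Bursts start at the
#'   stimulation time; waiting times are drawn from a Pareto distribution
#'   with minimum `burst_rate_scale` (seconds) and tail exponent
#'   `burst_tail`, each burst adds a jump of height `burst_amplitude`
#'   relaxing exponentially at rate `burst_decay` (1/s). Independent
#'   Gaussian noise of sd `sigma` is added on top.
#'
#' @param family One of `"gaussian_iid"`, `"ar1"`, `"burst_renewal"`.
#' @param sigma Standard deviation of the additive Gaussian component
#'   (ratio units), `>= 0`.
#' @param phi AR(1) coefficient, `|phi| < 1`. Used only by `"ar1"`.
#' @param burst_rate_scale Pareto waiting-time scale (minimum waiting time),
#'   seconds.
#' @param burst_tail Pareto tail exponent, `> 0`. Values `<= 1` give a
#'   diverging theoretical mean waiting time; the generator still terminates
#'   because waiting times are truncated at the trace duration.
#' @param burst_amplitude Height of one burst (ratio units).
#' @param burst_decay Exponential relaxation rate of a burst, 1/seconds.
#'
#' @return A list of class `"noise_spec"`.
#' @examples
#' noise_spec("burst_renewal", sigma = 0.006, burst_rate_scale = 60,
#'            burst_tail = 1.5, burst_amplitude = 0.02, burst_decay = 0.02)
#' @export
noise_spec <- function(family = c("gaussian_iid", "ar1", "burst_renewal"),
                       sigma = 0, phi = 0, burst_rate_scale = 60,
                       burst_tail = 1.5, burst_amplitude = 0.02,
                       burst_decay = 0.02) {
  family <- match.arg(family)
  check_number(sigma, "sigma", lower = 0)
  check_number(phi, "phi", lower = -1, upper = 1, strict_lower = TRUE)
  if (abs(phi) >= 1) {
    abort("`phi` must satisfy |phi| < 1.", class = "bretropy_config_error")
  }
  check_number(burst_rate_scale, "burst_rate_scale", lower = 0,
               strict_lower = TRUE)
  check_number(burst_tail, "burst_tail", lower = 0, strict_lower = TRUE)
  check_number(burst_amplitude, "burst_amplitude")
  check_number(burst_decay, "burst_decay", lower = 0, strict_lower = TRUE)
  structure(
    list(family = family, sigma = sigma, phi = phi,
         burst_rate_scale = burst_rate_scale, burst_tail = burst_tail,
         burst_amplitude = burst_amplitude, burst_decay = burst_decay),
    class = "noise_spec"
  )
}

#' Kinetic model of one experimental condition
#'
#' The deterministic part of a simulated trace is a flat pre-stimulation
#' baseline followed by a mono-exponential association to plateau:
#' `B0` for `t < stim_time` and `B0 + A * (1 - exp(-k * (t - stim_time)))`
#' afterwards — the canonical shape of ligand-induced protein association
#' followed in real time by a BRET biosensor.
#'
#' @param label Condition name (e.g. `"AngII"`).
#' @param baseline Pre-stimulation BRET ratio `B0`, `> 0`.
#' @param amplitude Plateau increment `A` (ratio units), `>= 0`. Zero for
#'   conditions without an agonist response.
#' @param rate Association rate `k`, 1/seconds, `> 0`.
#' @param noise A [noise_spec()].
#'
#' @return A list of class `"condition_kinetics"`.
#' @export
condition_kinetics <- function(label, baseline = 0.8, amplitude = 0,
                               rate = 0.004, noise = noise_spec()) {
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      !nzchar(label)) {
    abort("`label` must be a non-empty string.",
          class = "bretropy_config_error")
  }
  check_number(baseline, "baseline", lower = 0, strict_lower = TRUE)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(rate, "rate", lower = 0, strict_lower = TRUE)
  if (!inherits(noise, "noise_spec")) {
    abort("`noise` must be a noise_spec().", class = "bretropy_config_error")
  }
  structure(
    list(label = label, baseline = baseline, amplitude = amplitude,
         rate = rate, noise = noise),
    class = "condition_kinetics"
  )
}

#' Default four-condition table for the synthetic BRET experiment
#'
#' Emulates a vehicle control, an orthosteric agonist (AngII 10 nM), an
#' allosteric modulator alone (LVV-H7 10 uM) and their combination. The
#' agonist gives a moderate mono-exponential rise; the modulator alone gives
#' no net rise but intermittent heavy-tailed signaling bursts; the
#' combination gives a larger, faster and less noisy rise (positive
#' allosteric potentiation). These parameters are calibration choices that
#' encode the qualitative phenomenology of the assay, not measured values;
#' they live in configuration so they can be replaced wholesale.
#'
#' @param baseline Shared pre-stimulation BRET ratio.
#' @return A named list of [condition_kinetics()].
#' @export
default_conditions <- function(baseline = 0.8) {
  conds <- list(
    condition_kinetics("vehicle", baseline = baseline, amplitude = 0,
                       noise = noise_spec("gaussian_iid", sigma = 0.004)),
    condition_kinetics("AngII", baseline = baseline, amplitude = 0.05,
                       rate = 0.004,
                       noise = noise_spec("gaussian_iid", sigma = 0.004)),
    condition_kinetics("LVV-H7", baseline = baseline, amplitude = 0,
                       noise = noise_spec("burst_renewal", sigma = 0.006,
                                          burst_rate_scale = 60,
                                          burst_tail = 1.5,
                                          burst_amplitude = 0.02,
                                          burst_decay = 0.02)),
    condition_kinetics("AngII+LVV-H7", baseline = baseline,
                       amplitude = 0.09, rate = 0.008,
                       noise = noise_spec("gaussian_iid", sigma = 0.002))
  )
  setNames(conds, vapply(conds, `[[`, character(1), "label"))
}

#' Two-condition table emulating a ligand-binding BRET experiment
#'
#' Emulates the agonist-binding readout (orthosteric agonist alone versus
#' agonist plus allosteric modulator) used to correlate signaling entropy
#' with binding kinetics: four independent experiments in duplicate wells,
#' lower noise than the signaling assay. The modulator's stabilizing action
#' is encoded in the noise structure — the agonist-alone condition carries
#' rare heavy-tailed burst excursions (spontaneous receptor fluctuations)
#' that the modulator suppresses — while the combined condition gains a
#' modest plateau increase at a matched association rate. This gives the
#' combined condition both a more regular series (lower Sample Entropy) and
#' a value distribution without extreme rare states (lower negative-order
#' Renyi entropy).
#'
#' @param baseline Shared pre-stimulation BRET ratio.
#' @return A named list of two [condition_kinetics()].
#' @export
binding_pair_conditions <- function(baseline = 0.8) {
  conds <- list(
    condition_kinetics("AngII", baseline = baseline, amplitude = 0.05,
                       rate = 0.004,
                       noise = noise_spec("burst_renewal", sigma = 0.002,
                                          burst_rate_scale = 120,
                                          burst_tail = 1.5,
                                          burst_amplitude = 0.03,
                                          burst_decay = 0.02)),
    condition_kinetics("AngII+LVV-H7", baseline = baseline,
                       amplitude = 0.07, rate = 0.004,
                       noise = noise_spec("gaussian_iid", sigma = 0.001))
  )
  setNames(conds, vapply(conds, `[[`, character(1), "label"))
}

#' Configuration of a simulated BRET experiment set
#'
#' Timing defaults mirror a standard real-time BRET protocol: a 5 min
#' luminescence baseline, ligand addition, then recording up to 30 min post
#' stimulation at 30 s intervals (71 samples per well), with three
#' independent experiments run in triplicate wells per condition.
#'
#' @param conditions List of [condition_kinetics()] (default
#'   [default_conditions()]).
#' @param n_experiments Number of independent experiments, `>= 1`.
#' @param n_wells Replicate wells per condition per experiment, `>= 1`.
#' @param dt Sampling interval, seconds.
#' @param baseline_duration Pre-stimulation recording time, seconds; the
#'   stimulation time of every trace.
#' @param total_duration Total recording time, seconds,
#'   `> baseline_duration`.
#' @param seed Integer master seed; per-trace seeds are derived from it
#'   deterministically (see [simulate_experiment_set()]).
#'
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(conditions = default_conditions(),
                              n_experiments = 3, n_wells = 3, dt = 30,
                              baseline_duration = 300, total_duration = 2100,
                              seed = 1L) {
  if (!is.list(conditions) || length(conditions) == 0L ||
      !all(vapply(conditions, inherits, logical(1), "condition_kinetics"))) {
    abort("`conditions` must be a non-empty list of condition_kinetics().",
          class = "bretropy_config_error")
  }
  labels <- vapply(conditions, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    abort("Condition labels must be unique.",
          class = "bretropy_config_error")
  }
  n_experiments <- check_count(n_experiments, "n_experiments")
  n_wells <- check_count(n_wells, "n_wells")
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(baseline_duration, "baseline_duration", lower = 0,
               strict_lower = TRUE)
  check_number(total_duration, "total_duration", lower = baseline_duration,
               strict_lower = TRUE)
  seed <- check_count(seed, "seed", min = 0L)
  if (floor(total_duration / dt) + 1 < 10) {
    abort("Trace would have fewer than 10 samples; decrease `dt` or extend `total_duration`.",
          class = "bretropy_config_error")
  }
  structure(
    list(conditions = setNames(conditions, labels),
         n_experiments = n_experiments, n_wells = n_wells, dt = dt,
         baseline_duration = baseline_duration,
         total_duration = total_duration, seed = seed),
    class = "simulation_config"
  )
}

#' Analysis configuration for the entropy pipeline
#'
#' Collects every tunable of the per-trace entropy pass and the
#' condition-level comparison pass.
#'
#' @param segment Which part of each trace to analyze: `"post_stim"`
#'   (default; samples with `t >= stim_time`, the ligand-response window),
#'   `"full"`, or `"baseline"`.
#' @param m Sample Entropy embedding dimension (default 1, appropriate for
#'   short kinetic reads).
#' @param r_factor Sample Entropy tolerance as a multiple of the segment's
#'   sample standard deviation (default 0.2).
#' @param correction Apply the small-sample factor `N/(N-2)` inside the
#'   Sample Entropy logarithm (default `TRUE`); turn off for the plain
#'   Richman–Moorman statistic.
#' @param n_support Number of KDE evaluation points; `NULL` (default) uses
#'   the segment length, keeping the Hartley normalizer `log(n)` comparable
#'   across equal-length traces.
#' @param support_extent `"data_range"` (default) evaluates the KDE on
#'   `[min, max]` of the data; `"extended"` pads by three bandwidths for
#'   sensitivity analysis.
#' @param p_threshold Minimum probability for a support point to count in
#'   the Hartley entropy (default 0; every Gaussian-KDE point has positive
#'   mass).
#' @param alphas Renyi orders reported (default integers -10..10 plus `Inf`).
#' @param tau_list Coarse-graining scales; each trace is analyzed once per
#'   scale (default 1, i.e. no temporal coarse-graining).
#' @param comparisons List of length-2 character vectors of condition labels
#'   to compare. Default: agonist vs combination, agonist vs modulator,
#'   modulator vs combination.
#' @param comparison_metrics Data frame with columns `metric`, `alpha`
#'   selecting which per-trace metrics are compared (default: Sample
#'   Entropy plus normalized Renyi entropy at alpha = -5, 1, Inf).
#' @param n_boot Bootstrap resamples for comparison confidence intervals.
#' @param p_adjust Multiple-testing adjustment across comparisons:
#'   `"none"` (default) or `"holm"`.
#' @param seed Integer seed for the bootstrap.
#'
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(segment = c("post_stim", "full", "baseline"),
                            m = 1L, r_factor = 0.2, correction = TRUE,
                            n_support = NULL,
                            support_extent = c("data_range", "extended"),
                            p_threshold = 0,
                            alphas = c(-10:10, Inf), tau_list = 1L,
                            comparisons = list(
                              c("AngII", "AngII+LVV-H7"),
                              c("AngII", "LVV-H7"),
                              c("LVV-H7", "AngII+LVV-H7")),
                            comparison_metrics = default_comparison_metrics(),
                            n_boot = 1000L, p_adjust = c("none", "holm"),
                            seed = 1L) {
  segment <- match.arg(segment)
  support_extent <- match.arg(support_extent)
  p_adjust <- match.arg(p_adjust)
  m <- check_count(m, "m")
  check_number(r_factor, "r_factor", lower = 0, strict_lower = TRUE)
  if (!is.null(n_support)) n_support <- check_count(n_support, "n_support", 2L)
  check_number(p_threshold, "p_threshold", lower = 0)
  if (!is.numeric(alphas) || length(alphas) == 0L || anyNA(alphas)) {
    abort("`alphas` must be a numeric vector.",
          class = "bretropy_config_error")
  }
  tau_list <- vapply(tau_list, check_count, integer(1), name = "tau_list")
  if (!is.list(comparisons) ||
      !all(vapply(comparisons, function(p)
        is.character(p) && length(p) == 2L, logical(1)))) {
    abort("`comparisons` must be a list of length-2 character vectors.",
          class = "bretropy_config_error")
  }
  stopifnot(is.data.frame(comparison_metrics),
            all(c("metric", "alpha") %in% names(comparison_metrics)))
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(segment = segment, m = m, r_factor = r_factor,
         correction = correction, n_support = n_support,
         support_extent = support_extent, p_threshold = p_threshold,
         alphas = sort(alphas), tau_list = tau_list,
         comparisons = comparisons, comparison_metrics =
           as_tibble(comparison_metrics),
         n_boot = n_boot, p_adjust = p_adjust, seed = seed),
    class = "analysis_config"
  )
}

#' @rdname analysis_config
#' @export
default_comparison_metrics <- function() {
  tibble(metric = c("sampen", "H_norm", "H_norm", "H_norm"),
         alpha = c(NA, -5, 1, Inf))
}

#' Build configurations from plain lists (e.g. parsed YAML)
#'
#' Converts nested lists — typically `yaml::read_yaml()` output — into
#' validated [simulation_config()] / [analysis_config()] objects, applying
#' the documented defaults for absent fields. `Inf` may be written as the
#' string `".inf"` or `"Inf"` in the alpha grid.
#'
#' @param x A named list.
#' @return The corresponding configuration object.
#' @export
as_simulation_config <- function(x) {
  if (inherits(x, "simulation_config")) return(x)
  stopifnot(is.list(x))
  # tolerate mixed simulation + analysis documents
  args <- x[intersect(names(x), names(formals(simulation_config)))]
  if (!is.null(args$conditions)) {
    args$conditions <- lapply(args$conditions, function(ck) {
      if (inherits(ck, "condition_kinetics")) return(ck)
      if (!is.null(ck$noise) && !inherits(ck$noise, "noise_spec")) {
        ck$noise <- do.call(noise_spec, ck$noise)
      }
      do.call(condition_kinetics, ck)
    })
  }
  do.call(simulation_config, args)
}

#' @rdname as_simulation_config
#' @export
as_analysis_config <- function(x) {
  if (inherits(x, "analysis_config")) return(x)
  stopifnot(is.list(x))
  x <- x[intersect(names(x), names(formals(analysis_config)))]
  if (!is.null(x$alphas)) {
    x$alphas <- as.numeric(vapply(x$alphas, function(a) {
      if (is.character(a)) a <- gsub("^\\.", "", a)
      as.numeric(a)
    }, numeric(1)))
  }
  if (!is.null(x$comparisons)) x$comparisons <- lapply(x$comparisons, unlist)
  if (!is.null(x$comparison_metrics) && !is.data.frame(x$comparison_metrics)) {
    cm <- x$comparison_metrics
    x$comparison_metrics <- tibble(
      metric = vapply(cm, function(m) as.character(m$metric), character(1)),
      alpha = vapply(cm, function(m) {
        if (is.null(m$alpha)) NA_real_ else as.numeric(m$alpha)
      }, numeric(1)))
  }
  do.call(analysis_config, x)
}
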