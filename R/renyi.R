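# Silverman's robust rule-of-thumb bandwidth.
silverman_bw <- function(x) {
  n <- length(x)
  s <- sd(x)
  iqr <- stats::IQR(x)
  spread <- if (iqr > 0) min(s, iqr / 1.34) else s
  0.9 * spread * n^(-1 / 5)
}

#' Discrete probability distribution of trace values by Gaussian KDE
#'
#' Estimates the distribution of a trace's values with a Gaussian kernel
#' density estimate, bandwidth from Silverman's robust rule
#' `h = 0.9 * min(sd, IQR/1.34) * N^(-1/5)`, evaluated on `n_support`
#' evenly spaced points and renormalized to sum to one. The default support
#' spans `[min(x), max(x)]` with `n_support = length(x)` points, which keeps
#' the Hartley normalizer `log(n)` identical across equal-length traces and
#' keeps every support point at strictly positive probability (the Gaussian
#' kernel never vanishes), so negative-order Renyi entropies stay finite.
#'
#' @param series Numeric vector, length `>= 10`, non-zero variance.
#' @param n_support Number of evaluation points (default `length(series)`),
#'   `>= 2`.
#' @param support_extent `"data_range"` (default) or `"extended"` (pads the
#'   range by three bandwidths on each side).
#'
#' @return A tibble with columns `support` (ratio units) and `p`
#'   (probabilities summing to 1); bandwidth in attribute `"bandwidth"`.
#' @examples
#' set.seed(1)
#' pd <- estimate_pdf(rnorm(50))
#' sum(pd$p)
#' @export
estimate_pdf <- function(series, n_support = NULL,
                         support_extent = c("data_range", "extended")) {
  support_extent <- match.arg(support_extent)
  series <- as.numeric(series)
  n <- length(series)
  if (n < 10) {
    abort("Need at least 10 samples to estimate a value distribution.",
          class = "bretropy_length_error")
  }
  if (!all(is.finite(series))) {
    abort("Series contains non-finite values.",
          class = "bretropy_validation_error")
  }
  s <- sd(series)
  if (!is.finite(s) || s == 0) {
    abort("Series has zero variance: KDE bandwidth would be 0.",
          class = "bretropy_degenerate_error")
  }
  if (is.null(n_support)) n_support <- n
  n_support <- check_count(n_support, "n_support", min = 2L)

  h <- silverman_bw(series)
  lim <- range(series)
  if (support_extent == "extended") lim <- lim + c(-3, 3) * h
  support <- seq(lim[1], lim[2], length.out = n_support)
  # direct Gaussian-kernel sum: n and n_support are both ~1e2 here, and the
  # exact tail mass matters for negative Renyi orders
  dens <- vapply(support, function(g) mean(stats::dnorm(g, series, h)),
                 numeric(1))
  p <- dens / sum(dens)
  structure(tibble(support = support, p = p), bandwidth = h)
}

#' Renyi entropy of a discrete distribution
#'
#' For probabilities `p` and order `alpha`, computes
#' `H_alpha = log(sum(p^alpha)) / (1 - alpha)` (in nats by default), with
#' the standard limits: `alpha = 1` gives Shannon entropy
#' `-sum(p * log p)`; `alpha = 0` gives Hartley entropy, the log of the
#' number of support points carrying mass above `p_threshold`;
#' `alpha = Inf` gives min-entropy `-log(max p)`. Negative orders weight
#' rare states: any zero probability makes them diverge, which is reported
#' as an error (cannot happen for [estimate_pdf()] output, whose
#' probabilities are all positive). Computation uses the log-sum-exp of
#' `alpha * log(p)`, so extreme orders on tiny probabilities do not
#' overflow.
#'
#' @param p Probability vector (or a data frame with a `p` column, e.g.
#'   [estimate_pdf()] output): non-negative, summing to 1 within `1e-9`.
#' @param alpha Order: any real number, or `Inf`.
#' @param p_threshold Mass threshold for counting support points at
#'   `alpha = 0` (default 0, i.e. `p > 0`).
#' @param base Logarithm base (default `exp(1)`, nats).
#'
#' @return A single entropy value.
#' @examples
#' renyi_entropy(rep(0.25, 4), 2)        # log(4): uniform is a fixed point
#' renyi_entropy(c(0.5, 0.25, 0.25), Inf) # -log(0.5)
#' @export
renyi_entropy <- function(p, alpha, p_threshold = 0, base = exp(1)) {
  if (is.data.frame(p)) p <- p$p
  p <- as.numeric(p)
  if (length(p) < 1 || anyNA(p) || any(p < 0)) {
    abort("`p` must be a vector of non-negative probabilities.",
          class = "bretropy_validation_error")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort("Probabilities must sum to 1 (within 1e-9).",
          class = "bretropy_validation_error")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha == -Inf) {
    abort("`alpha` must be a single real number or Inf.",
          class = "bretropy_config_error")
  }
  if (alpha < 0 && any(p == 0)) {
    abort("Negative-order Renyi entropy diverges when any probability is 0.",
          class = "bretropy_divergence_error")
  }
  h <- if (is.infinite(alpha)) {
    -log(max(p))
  } else if (alpha == 1) {
    pp <- p[p > 0]
    -sum(pp * log(pp))
  } else if (alpha == 0) {
    log(sum(p > p_threshold))
  } else {
    lp <- log(p[p > 0])
    logsumexp(alpha * lp) / (1 - alpha)
  }
  h / log(base)
}

#' Coarse-grain a series by non-overlapping averaging
#'
#' Standard multiscale-entropy preprocessing: replaces each block of `tau`
#' consecutive samples by its mean, shortening the series to
#' `floor(N / tau)`. `tau = 1` is the identity.
#'
#' @param series Numeric vector, length `>= 10 * tau`.
#' @param tau Integer scale factor, `>= 1`.
#' @return Numeric vector of length `floor(length(series) / tau)`.
#' @examples
#' coarse_grain(c(1, 3, 5, 7), 2)
#' @export
coarse_grain <- function(series, tau) {
  tau <- check_count(tau, "tau")
  series <- as.numeric(series)
  n <- length(series)
  if (n < 10 * tau) {
    abort(sprintf("Series of length %d too short for scale tau = %d (need >= %d).",
                  n, tau, 10 * tau), class = "bretropy_length_error")
  }
  if (tau == 1L) return(series)
  n_blocks <- n %/% tau
  colMeans(matrix(series[seq_len(n_blocks * tau)], nrow = tau))
}

#' Normalized Renyi entropy spectrum (plus Sample Entropy) of one series
#'
#' The per-trace metric set: estimates the value distribution by Gaussian
#' KDE ([estimate_pdf()]), computes the Renyi entropy at every requested
#' order (default integers -10..10 and `Inf`), normalizes by the Hartley
#' entropy `H0 = log(n_support)` so that `H_norm = H_alpha / H0` is
#' base-free and bounded by 1 for `alpha >= 0`, and attaches the series'
#' Sample Entropy computed with the same parameters used throughout the
#' pipeline. Negative orders magnify rare, low-probability values — the
#' transient states that motivate sweeping the order below zero.
#'
#' @inheritParams estimate_pdf
#' @param alphas Numeric vector of orders (default `c(-10:10, Inf)`).
#' @param m,r_factor,correction Sample Entropy parameters, see
#'   [sample_entropy()].
#' @param p_threshold Hartley-count threshold, see [renyi_entropy()].
#'
#' @return A tibble with one row per order: columns `alpha`, `H_raw`
#'   (nats), `H0` (nats), `H_norm` (`H_raw / H0`), `sampen` (constant
#'   across rows; `NA` if undefined for this series).
#' @examples
#' set.seed(1)
#' sp <- renyi_spectrum(cumsum(rnorm(71)))
#' sp[sp$alpha %in% c(-5, 1, Inf), ]
#' @export
renyi_spectrum <- function(series, alphas = c(-10:10, Inf), n_support = NULL,
                           support_extent = "data_range", p_threshold = 0,
                           m = 1L, r_factor = 0.2, correction = TRUE) {
  pd <- estimate_pdf(series, n_support = n_support,
                     support_extent = support_extent)
  h0 <- log(sum(pd$p > p_threshold))
  h_raw <- vapply(alphas, function(a)
    renyi_entropy(pd$p, a, p_threshold = p_threshold), numeric(1))
  se <- sample_entropy(series, m = m, r_factor = r_factor,
                       correction = correction)
  tibble(alpha = as.numeric(alphas), H_raw = h_raw, H0 = h0,
         H_norm = h_raw / h0, sampen = se)
}
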