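#' Template match counts for Sample Entropy
#'
#' Counts, over all unordered template pairs, how many length-`m` and
#' length-`m+1` templates of `series` lie within Chebyshev (maximum
#' coordinate) distance `r` of each other. Self-matches are excluded.
#' Length-`L` templates are the windows starting at `1 .. N - L`; the final
#' window is dropped, so a constant series of length `N` with `m = 1` gives
#' `B = choose(N - 1, 2)` and `A = choose(N - 2, 2)`.
#'
#' @param series Numeric vector, length `>= m + 2`.
#' @param m Embedding dimension, `>= 1`.
#' @param r Absolute match tolerance, `> 0`.
#'
#' @return Named integer-valued vector `c(B = , A = )`: `B` counts
#'   length-`m` matches, `A` length-`m+1` matches; `A <= B` always.
#' @examples
#' match_counts(rep(1, 10) + seq(0, 1e-4, length.out = 10), m = 1, r = 0.1)
#' @export
match_counts <- function(series, m, r) {
  series <- as.numeric(series)
  n <- length(series)
  m <- check_count(m, "m")
  check_number(r, "r", lower = 0, strict_lower = TRUE)
  if (n < m + 2) {
    abort(sprintf("Series of length %d is too short for m = %d (need >= m + 2).",
                  n, m), class = "bretropy_length_error")
  }
  count_len <- function(L) {
    n_tpl <- n - L
    if (n_tpl < 2) return(0)
    # templates as rows of an n_tpl x L matrix; running max of coordinate
    # distances, pair (i, j), i < j counted once
    tpl <- sapply(seq_len(L), function(k) series[(k):(k + n_tpl - 1)])
    tpl <- matrix(tpl, nrow = n_tpl)
    total <- 0L
    for (i in seq_len(n_tpl - 1)) {
      d <- abs(tpl[(i + 1):n_tpl, , drop = FALSE] -
                 matrix(tpl[i, ], nrow = n_tpl - i, ncol = L, byrow = TRUE))
      cheb <- if (L == 1L) d[, 1] else apply(d, 1, max)
      total <- total + sum(cheb <= r)
    }
    total
  }
  c(B = count_len(m), A = count_len(m + 1L))
}

#' Sample Entropy of a time series
#'
#' Sample Entropy (SampEn) is the negative logarithm of the conditional
#' probability that two templates matching for `m` points (within tolerance
#' `r`, Chebyshev distance, self-matches excluded) also match for `m + 1`
#' points. Lower values indicate a more regular, predictable series. The
#' tolerance is `r_factor` times the sample standard deviation of the
#' series, so the statistic is invariant to affine rescaling. An optional
#' small-sample factor `N/(N-2)` multiplies the match ratio inside the
#' logarithm (default on), giving
#' `SampEn = -log((A/B) * N/(N-2))` with `A`/`B` the `m+1`/`m` match counts
#' of [match_counts()].
#'
#' @param series Numeric vector, length `>= m + 2`, non-zero variance.
#' @param m Embedding dimension (default 1, suited to short kinetic reads).
#' @param r_factor Tolerance as a multiple of the series sd (default 0.2).
#' @param correction Apply the `N/(N-2)` factor (default `TRUE`).
#' @param r Absolute tolerance overriding `r_factor * sd(series)`; useful
#'   for near-constant series where the relative rule collapses.
#'
#' @return A single dimensionless number (non-negative when `correction =
#'   FALSE`; the correction can push an almost perfectly regular series
#'   marginally below zero), or `NA` with a
#'   warning when no `m+1`-template pair matches (`A = 0`: the entropy is
#'   undefined; downstream aggregation skips such traces).
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(200))
#' @export
sample_entropy <- function(series, m = 1L, r_factor = 0.2,
                           correction = TRUE, r = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  m <- check_count(m, "m")
  if (is.null(r)) {
    s <- sd(series)
    if (!is.finite(s) || s == 0) {
      abort("Series has zero variance: the relative tolerance r_factor * sd would be 0.",
            class = "bretropy_degenerate_error")
    }
    r <- r_factor * s
  }
  counts <- match_counts(series, m, r)
  if (counts[["B"]] == 0 || counts[["A"]] == 0) {
    warn(sprintf(
      "Sample Entropy undefined: no %s-template matches within r = %g.",
      if (counts[["B"]] == 0) "m" else "(m+1)", r),
      class = "bretropy_undefined_sampen")
    return(NA_real_)
  }
  ratio <- counts[["A"]] / counts[["B"]]
  if (correction) ratio <- ratio * n / (n - 2)
  -log(ratio)
}
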