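# Independent brute-force oracles, deliberately written as plain double
# loops / direct summations so they share no code with the implementation.

# O(N^2) template match counter: length-L templates start at 1..N-L,
# Chebyshev distance, unordered pairs, self-matches excluded.
brute_match_counts <- function(series, m, r) {
  count_len <- function(L) {
    n_tpl <- length(series) - L
    total <- 0L
    if (n_tpl >= 2) {
      for (i in 1:(n_tpl - 1)) {
        for (j in (i + 1):n_tpl) {
          d <- max(abs(series[i:(i + L - 1)] - series[j:(j + L - 1)]))
          if (d <= r) total <- total + 1L
        }
      }
    }
    total
  }
  c(B = count_len(m), A = count_len(m + 1))
}

# Direct-summation Renyi entropy (nats), no log-sum-exp tricks.
naive_renyi <- function(p, alpha) {
  if (is.infinite(alpha)) return(-log(max(p)))
  if (alpha == 1) return(-sum(p[p > 0] * log(p[p > 0])))
  if (alpha == 0) return(log(sum(p > 0)))
  log(sum(p[p > 0]^alpha)) / (1 - alpha)
}

# Symmetric Dirichlet sample via normalized gammas.
rdirichlet1 <- function(n, shape = 1) {
  g <- rgamma(n, shape = shape)
  g / sum(g)
}

# Small simulated dataset shared by several tests.
tiny_sim <- function(seed = 11, n_experiments = 2, n_wells = 2) {
  simulate_experiment_set(simulation_config(
    n_experiments = n_experiments, n_wells = n_wells, seed = seed))
}
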