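test_that("KDE probabilities are positive, normalized, and use Silverman's bandwidth", {
  set.seed(301)
  x <- rnorm(100)
  pd <- estimate_pdf(x)
  expect_equal(nrow(pd), 100)
  expect_lt(abs(sum(pd$p) - 1), 1e-12)
  expect_true(all(pd$p > 0))
  expect_equal(range(pd$support), range(x))
  h_expect <- 0.9 * min(sd(x), IQR(x) / 1.34) * 100^(-0.2)
  expect_equal(attr(pd, "bandwidth"), h_expect, tolerance = 1e-12)

  # extended support pads by three bandwidths
  pd_ext <- estimate_pdf(x, support_extent = "extended")
  expect_equal(range(pd_ext$support),
               range(x) + c(-3, 3) * h_expect, tolerance = 1e-12)
})

test_that("KDE resolves a bimodal value distribution", {
  set.seed(302)
  x <- c(rnorm(25, 0, 0.01), rnorm(25, 1, 0.01))
  pd <- estimate_pdf(x, n_support = 101)
  mid <- pd$p[which.min(abs(pd$support - 0.5))]
  p_lo <- max(pd$p[pd$support < 0.25])
  p_hi <- max(pd$p[pd$support > 0.75])
  expect_lt(mid, p_lo)
  expect_lt(mid, p_hi)
  # argmax sits inside one of the clusters
  expect_true(abs(pd$support[which.max(pd$p)]) < 0.25 ||
                abs(pd$support[which.max(pd$p)] - 1) < 0.25)
})

test_that("degenerate or invalid KDE inputs are rejected", {
  expect_error(estimate_pdf(rep(1, 50)),
               class = "bretropy_degenerate_error")
  expect_error(estimate_pdf(rnorm(5)), class = "bretropy_length_error")
  expect_error(estimate_pdf(rnorm(50), n_support = 1),
               class = "bretropy_config_error")
})

test_that("Renyi entropy hits its closed-form special cases", {
  u4 <- rep(0.25, 4)
  for (a in c(-10, -3, 0, 1, 2, 7, Inf)) {
    expect_equal(renyi_entropy(u4, a), log(4), tolerance = 1e-12)
  }
  point <- c(1, 0, 0)
  expect_equal(renyi_entropy(point, 2), 0)
  expect_equal(renyi_entropy(point, Inf), 0)
  p <- c(0.5, 0.25, 0.25)
  expect_equal(renyi_entropy(p, 2), -log(0.375), tolerance = 1e-12)
  expect_equal(renyi_entropy(p, Inf), -log(0.5), tolerance = 1e-12)
  expect_equal(renyi_entropy(p, 1), -sum(p * log(p)), tolerance = 1e-12)
  # zero mass is fatal for negative orders only
  expect_error(renyi_entropy(point, -1),
               class = "bretropy_divergence_error")
  expect_silent(renyi_entropy(point, 3))
})

test_that("Renyi entropy matches direct summation and is continuous through alpha = 1", {
  set.seed(303)
  for (i in 1:20) {
    p <- rdirichlet1(50, shape = runif(1, 0.2, 3))
    for (a in c(-10:10, Inf)) {
      expect_equal(renyi_entropy(p, a), naive_renyi(p, a),
                   tolerance = 1e-10)
    }
    h1 <- renyi_entropy(p, 1)
    expect_lt(abs(renyi_entropy(p, 1 + 1e-6) - h1), 1e-4)
    expect_lt(abs(renyi_entropy(p, 1 - 1e-6) - h1), 1e-4)
  }
})

test_that("the spectrum is non-increasing in the order on KDE and random distributions", {
  set.seed(304)
  grid <- c(-10:10, Inf)
  for (i in 1:10) {
    p <- rdirichlet1(50)
    h <- vapply(grid, function(a) renyi_entropy(p, a), numeric(1))
    expect_true(all(diff(h) <= 1e-9))
  }
  tr <- simulate_trace(condition_kinetics(
    "AngII", amplitude = 0.05, rate = 0.004,
    noise = noise_spec("gaussian_iid", sigma = 0.004)), seed = 8)
  sp <- renyi_spectrum(tr$ratio[tr$time_s >= 300])
  expect_true(all(diff(sp$H_raw) <= 1e-9))
  expect_true(all(sp$H_norm[sp$alpha >= 1] <= 1 + 1e-12))
  expect_true(all(sp$H_norm[sp$alpha >= 1] > 0))
  expect_lte(sp$H_norm[is.infinite(sp$alpha)], min(sp$H_norm[is.finite(sp$alpha)]))
})

test_that("normalized entropy is base-free and 1 for an equal-mass distribution", {
  n <- 64
  u <- rep(1 / n, n)
  for (a in c(-10:10, Inf)) {
    h_nats <- renyi_entropy(u, a)
    h_bits <- renyi_entropy(u, a, base = 2)
    expect_equal(h_nats / log(n), 1, tolerance = 1e-12)
    expect_equal(h_bits / log2(n), 1, tolerance = 1e-12)
  }
  set.seed(305)
  p <- rdirichlet1(30)
  for (a in c(-5, 2, Inf)) {
    expect_equal(renyi_entropy(p, a) / log(30),
                 renyi_entropy(p, a, base = 2) / log2(30),
                 tolerance = 1e-12)
  }
})

test_that("coarse graining averages non-overlapping blocks", {
  x <- seq_len(40)
  expect_identical(coarse_grain(x, 1), as.numeric(x))
  expect_equal(coarse_grain(c(1, 3, 5, 7, rep(0, 36)), 2)[1:2], c(2, 6))
  expect_length(coarse_grain(seq_len(35), 3), 11)
  expect_error(coarse_grain(seq_len(10), 2), class = "bretropy_length_error")
})

test_that("renyi_spectrum carries a consistent Hartley normalizer and SampEn", {
  set.seed(306)
  x <- cumsum(rnorm(71))
  sp <- renyi_spectrum(x, m = 1, r_factor = 0.2, correction = FALSE)
  expect_equal(unique(sp$H0), log(71))
  expect_equal(sp$H_norm, sp$H_raw / log(71))
  expect_equal(unique(sp$sampen),
               sample_entropy(x, m = 1, correction = FALSE))
  expect_equal(sp$alpha, c(-10:10, Inf))
})
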