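test_that("match counts on degenerate series hit the combinatorial values", {
  # constant series: every template matches every other
  const <- rep(1, 10) # any r > 0
  expect_equal(match_counts(const, m = 1, r = 0.1),
               c(B = choose(9, 2), A = choose(8, 2)))
  # strictly spaced series: gaps exceed r, so nothing matches
  spaced <- seq(0, 18, by = 2)
  expect_equal(match_counts(spaced, m = 1, r = 1), c(B = 0, A = 0))
  expect_error(match_counts(c(1, 2), m = 1, r = 0.5),
               class = "bretropy_length_error")
})

test_that("match counts equal the brute-force oracle on random series", {
  set.seed(201)
  for (i in 1:10) {
    x <- rnorm(200)
    for (m in c(1L, 2L)) {
      r <- 0.2 * sd(x)
      expect_identical(match_counts(x, m, r), brute_match_counts(x, m, r))
    }
  }
})

test_that("sample_entropy matches -log(A/B) from the counts, with and without correction", {
  set.seed(202)
  x <- rnorm(150)
  r <- 0.2 * sd(x)
  cnt <- brute_match_counts(x, 1, r)
  expect_equal(sample_entropy(x, m = 1, correction = FALSE),
               -log(cnt[["A"]] / cnt[["B"]]), tolerance = 1e-12)
  n <- length(x)
  expect_equal(sample_entropy(x, m = 1, correction = TRUE),
               -log(cnt[["A"]] / cnt[["B"]] * n / (n - 2)),
               tolerance = 1e-12)
})

test_that("all-matching series with a fixed absolute tolerance follows the closed form", {
  # constant-plus-tiny-jitter: every pair matches under a generous fixed r
  set.seed(203)
  n <- 100
  x <- 1 + 1e-8 * rnorm(n)
  got <- sample_entropy(x, m = 1, correction = FALSE, r = 0.5)
  # A/B = C(n-2,2)/C(n-1,2) = (n-3)/(n-1)
  expect_equal(got, -log((n - 3) / (n - 1)), tolerance = 1e-12)
  expect_equal(got, -log(brute_match_counts(x, 1, 0.5)[["A"]] /
                           brute_match_counts(x, 1, 0.5)[["B"]]),
               tolerance = 1e-12)
})

test_that("degenerate and undefined inputs are signaled, not silently returned", {
  expect_error(sample_entropy(rep(2, 50)),
               class = "bretropy_degenerate_error")
  # no (m+1)-matches: strictly spaced series under a small absolute r
  expect_warning(
    out <- sample_entropy(seq(0, 20), m = 1, r = 0.5),
    class = "bretropy_undefined_sampen")
  expect_true(is.na(out))
})

test_that("sample entropy is invariant to affine rescaling", {
  set.seed(204)
  for (i in 1:5) {
    x <- rnorm(120)
    base <- sample_entropy(x)
    for (ab in list(c(2, 0), c(-3, 1), c(0.01, -5))) {
      expect_equal(sample_entropy(ab[1] * x + ab[2]), base,
                   tolerance = 1e-12)
    }
  }
})

test_that("enlarging the tolerance never decreases the match counts", {
  set.seed(205)
  x <- rnorm(100)
  rs <- seq(0.05, 1, by = 0.05) * sd(x)
  counts <- vapply(rs, function(r) match_counts(x, 1, r), c(B = 0, A = 0))
  expect_true(all(diff(counts["B", ]) >= 0))
  expect_true(all(diff(counts["A", ]) >= 0))
  expect_true(all(counts["A", ] <= counts["B", ]))
})
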