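test_that("paired t statistic follows the closed form and is antisymmetric", {
  res <- paired_t(c(2, 3, 4), c(1, 1, 1)) # diffs 1, 2, 3
  expect_equal(res$mean_diff, 2)
  expect_equal(res$sd_diff, 1)
  expect_equal(res$t_stat, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$df, 2)

  swapped <- paired_t(c(1, 1, 1), c(2, 3, 4))
  expect_equal(swapped$t_stat, -res$t_stat, tolerance = 1e-12)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)

  expect_warning(deg <- paired_t(c(1, 2, 3), c(0, 1, 2)),
                 class = "bretropy_degenerate_comparison")
  expect_true(is.na(deg$t_stat))
  expect_error(paired_t(1, 1:2), class = "bretropy_validation_error")
})

test_that("paired t agrees with stats::t.test on random paired sets", {
  set.seed(401)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    x <- rnorm(n)
    y <- rnorm(n, mean = 0.3)
    res <- paired_t(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(res$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-8)
    expect_equal(res$df, unname(ref$parameter))
  }
})

test_that("bootstrap intervals are deterministic, ordered, and collapse on constants", {
  d <- c(0.11, 0.43, 0.27, 0.52, 0.31, 0.18, 0.66, 0.09)
  ci1 <- bootstrap_ci(d, seed = 9)
  ci2 <- bootstrap_ci(d, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["ci_low"]], mean(d))
  expect_gte(ci1[["ci_high"]], mean(d))
  expect_false(identical(ci1, bootstrap_ci(d, seed = 10)))

  const <- bootstrap_ci(rep(0.5, 6), seed = 1)
  expect_equal(unname(const), c(0.5, 0.5))
  expect_error(bootstrap_ci(0.5), class = "bretropy_validation_error")
  expect_error(bootstrap_ci(d, n_boot = 10), class = "bretropy_config_error")
})

test_that("bootstrap interval width shrinks roughly like 1/sqrt(n)", {
  set.seed(402)
  wins <- vapply(1:20, function(i) {
    small <- bootstrap_ci(rnorm(20, 0.5), seed = i)
    big <- bootstrap_ci(rnorm(80, 0.5), seed = i)
    diff(unname(big)) < diff(unname(small))
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("summaries report experiment-level mean and SEM", {
  metrics <- tibble::tibble(
    experiment_id = rep(c("E1", "E2", "E3"), each = 2),
    well_id = rep(c("W1", "W2"), 3),
    condition = "A", tau = 1L, alpha = 1,
    H_raw = 1, H0 = 1, H_norm = 1,
    sampen = c(0.5, 1.5, 1.5, 2.5, 2.5, 3.5))
  s <- summarize_metrics(metrics, tibble::tibble(metric = "sampen",
                                                 alpha = NA))
  # well means per experiment: 1, 2, 3
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$n_experiments, 3)

  # shuffling rows changes nothing
  shuf <- metrics[sample(nrow(metrics)), ]
  expect_equal(summarize_metrics(shuf, tibble::tibble(metric = "sampen",
                                                      alpha = NA)), s)

  # a single experiment has no SEM
  one <- dplyr::filter(metrics, experiment_id == "E1")
  s1 <- summarize_metrics(one, tibble::tibble(metric = "sampen", alpha = NA))
  expect_true(is.na(s1$sem))
})

test_that("condition comparisons pair experiments and respect configuration", {
  traces <- tiny_sim(seed = 12, n_experiments = 3, n_wells = 2)
  metrics <- suppressWarnings(analyze_traces(traces, analysis_config()))
  cfg <- analysis_config(seed = 5)
  cmp <- suppressWarnings(compare_conditions(metrics, cfg))
  expect_equal(nrow(cmp), 3 * 4) # 3 pairs x 4 default metrics
  expect_equal(unique(cmp$n), 3)
  expect_equal(unique(cmp$df), 2)
  expect_true(all(cmp$ci_low <= cmp$mean_diff + 1e-12))
  expect_true(all(cmp$ci_high >= cmp$mean_diff - 1e-12))
  # deterministic rerun
  expect_identical(cmp, suppressWarnings(compare_conditions(metrics, cfg)))

  # missing condition is a config error; self-comparison degenerates
  expect_error(
    suppressWarnings(compare_conditions(
      metrics, analysis_config(comparisons = list(c("AngII", "nope"))))),
    class = "bretropy_config_error")
  expect_warning(
    self <- compare_conditions(
      metrics, analysis_config(comparisons = list(c("AngII", "AngII")),
                               comparison_metrics =
                                 tibble::tibble(metric = "sampen",
                                                alpha = NA))),
    class = "bretropy_degenerate_comparison")
  expect_true(is.na(self$t_stat))

  # Holm adjustment only reorders significance bookkeeping
  holm <- suppressWarnings(compare_conditions(
    metrics, analysis_config(p_adjust = "holm", seed = 5)))
  expect_true("p_adj" %in% names(holm))
  expect_true(all(holm$p_adj >= holm$p_value - 1e-15, na.rm = TRUE))
})
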