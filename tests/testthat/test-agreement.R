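test_that("waveform correlation handles identity, negation and noise", {
  x <- time_series(sin((0:1499) / 20), 25)
  expect_equal(window_correlation(x, x)$r, 1)
  neg <- time_series(-x$samples, 25)
  expect_equal(window_correlation(neg, x)$r, -1)
  set.seed(4)
  a <- time_series(rnorm(1500), 25)
  b <- time_series(rnorm(1500), 25)
  expect_lt(abs(window_correlation(a, b)$r), 0.1)
  const <- time_series(rep(1, 1500), 25)
  expect_true(is.na(window_correlation(const, x)$r))
})

test_that("correlation is computed on the time overlap, not by index", {
  x <- sin((0:999) / 15)
  full <- time_series(x, 25, t0 = 0)
  late <- time_series(x[301:1000], 25, t0 = 12)   # same signal, 12 s in
  wc <- window_correlation(late, full)
  expect_equal(wc$r, 1)
  expect_equal(wc$n, 700)
})

test_that("exceedance fractions count thresholds correctly", {
  e <- exceedance_curve(c(0.2, 0.5, 0.8), c(0, 0.5, 0.9))
  expect_equal(e$fraction, c(1, 2 / 3, 0))
  expect_equal(exceedance_curve(rep(1, 5), c(0, 0.5, 1))$fraction,
               rep(1, 3))
  set.seed(9)
  for (i in 1:5) {
    e <- exceedance_curve(runif(50, -1, 1))
    expect_true(all(diff(e$fraction) <= 0))
    expect_true(all(e$fraction >= 0 & e$fraction <= 1))
  }
  expect_error(exceedance_curve(numeric(0)), "no correlation")
})

test_that("paired t-test matches the textbook formula on seeded data", {
  expect_equal(paired_ttest(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  set.seed(10)
  ref <- rnorm(10)
  shift <- paired_ttest(ref + 1, ref)
  expect_lt(shift$p, 0.001)
  expect_equal(shift$mean_diff, 1)

  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- paired_ttest(x, y)
    d <- x - y                                  # textbook formula
    t_ref <- mean(d) / (sd(d) / sqrt(n))
    p_ref <- 2 * pt(-abs(t_ref), n - 1)
    expect_equal(got$t, t_ref, tolerance = 1e-10)
    expect_equal(got$p, p_ref, tolerance = 1e-10)
  }
  expect_error(paired_ttest(1, c(1, 2)), "equal length")
})

test_that("Bland-Altman matches the mean +/- 1.96 SD construction", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$bias, same$loa_low, same$loa_high), c(0, 0, 0))

  const <- bland_altman(c(2, 3, 4), c(1, 2, 3))
  expect_equal(const$bias, 1)
  expect_equal(const$sd_diff, 0)
  expect_equal(c(const$loa_low, const$loa_high), c(1, 1))

  for (seed in 1:20) {
    set.seed(seed)
    x <- rlnorm(10); y <- rlnorm(10)
    for (rel in c(FALSE, TRUE)) {
      got <- bland_altman(x, y, relative = rel)
      d <- if (rel) 100 * (x - y) / ((x + y) / 2) else x - y
      expect_equal(got$bias, mean(d), tolerance = 1e-12)
      expect_equal(got$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
      expect_equal(got$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
      expect_equal(got$loa_high - got$loa_low, 2 * 1.96 * got$sd_diff,
                   tolerance = 1e-12)
    }
  }
})

test_that("Bland-Altman symmetry and scale invariances hold", {
  set.seed(11)
  x <- rlnorm(30, 1); y <- rlnorm(30, 1)
  ab <- bland_altman(x, y)
  ba <- bland_altman(y, x)
  expect_equal(ba$bias, -ab$bias)
  expect_equal(ba$loa_low, -ab$loa_high)
  expect_equal(ba$loa_high, -ab$loa_low)
  # percent mode ignores a common rescaling of both arms
  rel <- bland_altman(x, y, relative = TRUE)
  rel2 <- bland_altman(7 * x, 7 * y, relative = TRUE)
  expect_equal(rel2$bias, rel$bias, tolerance = 1e-12)
  expect_equal(rel2$loa_high, rel$loa_high, tolerance = 1e-12)
  expect_error(bland_altman(c(1, -1), c(1, 1), relative = TRUE), "zero")
})

test_that("the report covers every metric for every method", {
  cfg <- experiment_config(
    cohort = cohort_spec(n_subjects = 2, rates_bpm = c(10, 14),
                         serial_duration_s = 150, master_seed = 42),
    methods = "oracle", seed = 7)
  res <- run_experiment(cfg)
  rep <- res$report
  expect_equal(nrow(rep$agreement), 5)      # 5 metrics x 1 method
  expect_setequal(unique(rep$agreement$method), "oracle")
  expect_true(all(rep$agreement$n <= 2 * 2 * 5))
  expect_true(all(c("pair_mean", "pair_diff", "pair_diff_pct")
                  %in% names(rep$plot_data)))
  expect_error(build_report(res$windows[0, ]), "empty")
  expect_error(build_report(data.frame(a = 1)), "method")
  no_ref <- res$windows[res$windows$method != "reference", ]
  expect_error(build_report(no_ref), "no reference")
})
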