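test_that("Savitzky-Golay smoothing is exact on low-order polynomials", {
  tt <- (0:499) / 25
  cubic <- time_series(1 + 2 * tt - 0.5 * tt^2 + 0.1 * tt^3, 25)
  sm <- smooth_tvw(cubic, sg_window_s = 1, sg_order = 3)
  interior <- 26:474
  expect_lt(max(abs(sm$samples[interior] - cubic$samples[interior])), 1e-6)

  const <- time_series(rep(4, 200), 25)
  expect_equal(smooth_tvw(const)$samples, const$samples, tolerance = 1e-9)
  expect_error(smooth_tvw(cubic, sg_window_s = 0.04), "window")
  expect_error(smooth_tvw(cubic, sg_window_s = 0.2, sg_order = 7), "order")
})

test_that("smoothing removes at least half the noise variance at 10 dB SNR", {
  set.seed(8)
  tt <- (0:2999) / 25
  clean <- sin(2 * pi * tt / 6)
  noisy <- clean + rnorm(length(tt), sd = sqrt(var(clean) / 10))
  sm <- smooth_tvw(time_series(noisy, 25))
  expect_lt(var(sm$samples - clean), 0.5 * var(noisy - clean))
})

test_that("breath detection is exact on an analytic sinusoid", {
  ev <- detect_breaths(sine_breathing(10, 60))
  expect_equal(nrow(ev), 10)
  expect_true(all(abs(ev$tinsp - 3) <= 0.04 + 1e-9))
  expect_true(all(abs(ev$texp - 3) <= 0.04 + 1e-9))
})

test_that("detected breaths match the simulator ground truth at every rate", {
  for (r in c(6, 8, 10, 12, 14)) {
    b <- generate_breathing_trace(breathing_spec(r, 300, ie_ratio = 0.9))
    ev <- detect_breaths(b$trace)
    expect_equal(nrow(ev), nrow(b$events))
    expect_true(all(abs(diff(ev$peak_time) - 60 / r) <= 0.04 + 1e-9))
  }
})

test_that("degenerate traces yield an empty, flagged event list", {
  expect_warning(ev <- detect_breaths(time_series(rep(1, 300), 25)),
                 "no breaths|constant")
  expect_equal(nrow(ev), 0)
  expect_equal(attr(ev, "flag"), "no_breaths")
})

test_that("window metrics are forced by construction on a sinusoid", {
  ev <- detect_breaths(sine_breathing(10, 60))
  m <- compute_metrics(ev, 60)
  expect_equal(m$tinsp_s, 3, tolerance = 0.04 / 3)
  expect_equal(m$texp_s, 3, tolerance = 0.04 / 3)
  expect_equal(m$ie_ratio, 1, tolerance = 0.03)
  expect_equal(m$ibi_s, 6, tolerance = 0.04 / 6)
  expect_equal(m$br_bpm, 10)
})

test_that("I:E follows its definition and undefined windows are marked", {
  one <- data.frame(trough_time = 0, peak_time = 2, next_trough_time = 6,
                    next_peak_time = NA, tinsp = 2, texp = 4,
                    ie_ratio = 0.5)
  two <- one
  two[c("trough_time", "peak_time", "next_trough_time")] <-
    one[c("trough_time", "peak_time", "next_trough_time")] + 6
  m <- compute_metrics(rbind(one, two), 30)
  expect_equal(m$ie_ratio, 0.5)
  # definition identity on detector output
  ev <- detect_breaths(sine_breathing(12, 60))
  expect_equal(ev$ie_ratio * ev$texp, ev$tinsp, tolerance = 1e-12)

  und <- compute_metrics(one, 30)
  expect_equal(und$flag, "undefined")
  expect_true(is.na(und$br_bpm))
  expect_equal(und$n_breaths, 1L)
})

test_that("window summaries agree with the generator's stored events", {
  b <- generate_breathing_trace(
    breathing_spec(10, 120, ie_ratio = 0.9, ibi_jitter_cv = 0.05,
                   amplitude_jitter_cv = 0.1, seed = 12))
  m <- compute_metrics(detect_breaths(b$trace), 120)
  # independent per-breath averaging of the stored ground truth
  expect_equal(m$tinsp_s, mean(b$events$tinsp), tolerance = 0.04)
  expect_equal(m$texp_s, mean(b$events$texp), tolerance = 0.04)
  expect_equal(m$ibi_s, mean(diff(b$events$peak_time)), tolerance = 0.04)
  expect_equal(m$n_breaths, nrow(b$events))
  # counting BR and 60/IBI agree within 15% on windows with many breaths
  expect_lt(abs(m$br_bpm - 60 / m$ibi_s) / m$br_bpm, 0.15)
  # mean IBI x breath count approximates the covered duration
  expect_lt(abs(m$ibi_s * m$n_breaths - 120), 2 * m$ibi_s)
})

test_that("breath pairing matches nearest peaks and counts the rest", {
  ev <- function(pk) data.frame(peak_time = pk)
  same <- pair_breaths(ev(c(0, 6, 12)), ev(c(0, 6, 12)), 1)
  expect_equal(nrow(same$pairs), 3)
  expect_equal(same$pairs$offset_s, rep(0, 3))
  expect_equal(same$n_spurious, 0)
  expect_equal(same$n_missed, 0)

  extra <- pair_breaths(ev(c(0, 3, 6, 12)), ev(c(0, 6, 12)), 1)
  expect_equal(nrow(extra$pairs), 3)
  expect_equal(extra$n_spurious, 1)

  off <- pair_breaths(ev(c(0, 6, 12)), ev(c(0.4, 6.1, 12.2)), 1)
  expect_equal(off$pairs$offset_s, c(0.4, 0.1, 0.2))
})

test_that("breath detection reaches F1 = 1 in the noiseless regime", {
  for (r in c(6, 14)) {
    b <- generate_breathing_trace(breathing_spec(r, 300))
    pb <- pair_breaths(detect_breaths(b$trace), b$events,
                       max_offset_s = 30 / r)
    expect_equal(pb$n_spurious, 0)
    expect_equal(pb$n_missed, 0)
    expect_true(all(pb$pairs$offset_s <= 0.04 + 1e-9))
  }
})
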