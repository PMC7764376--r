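test_that("noiseless symmetric breathing forces exact timing", {
  b <- generate_breathing_trace(breathing_spec(10, 60, ie_ratio = 1))
  expect_equal(nrow(b$events), 10)
  expect_equal(b$events$tinsp, rep(3, 10))
  expect_equal(b$events$texp, rep(3, 10))
  expect_equal(diff(b$events$peak_time), rep(6, 9))

  b6 <- generate_breathing_trace(breathing_spec(6, 300))
  expect_equal(nrow(b6$events), 30)
  expect_equal(diff(b6$events$peak_time), rep(10, 29))
})

test_that("breath-interval jitter reproduces the requested moments", {
  b <- generate_breathing_trace(
    breathing_spec(12, 300, ibi_jitter_cv = 0.05, seed = 7))
  ibi <- diff(b$events$peak_time)
  expect_lt(abs(mean(ibi) - 5) / 5, 0.02)
  cv <- sd(ibi) / mean(ibi)
  expect_gte(cv, 0.02)
  expect_lte(cv, 0.10)
})

test_that("breathing trace rejects a duration shorter than one breath", {
  expect_error(generate_breathing_trace(breathing_spec(6, 5)),
               "shorter than one breath")
})

test_that("breath bookkeeping accounts for the covered duration", {
  for (seed in 1:3) {
    b <- generate_breathing_trace(
      breathing_spec(10, 120, ibi_jitter_cv = 0.06,
                     amplitude_jitter_cv = 0.1, seed = seed))
    covered <- max(b$events$next_trough_time)
    expect_equal(sum(b$events$tinsp + b$events$texp), covered,
                 tolerance = 1e-9)
    expect_lte(120 - covered, 60 / 10 * 1.5)  # within ~one breath of the end
  }
})

test_that("zero-jitter volume trace has its spectral peak at the coached rate", {
  for (r in c(6, 10, 14)) {
    b <- generate_breathing_trace(breathing_spec(r, 300))
    x <- b$trace$samples - mean(b$trace$samples)
    spec <- Mod(fft(x))[2:(length(x) %/% 2)]
    f <- (seq_along(spec)) * 25 / length(x)
    expect_lt(abs(f[which.max(spec)] - r / 60), 25 / length(x) + 1e-12)
  }
})

test_that("unmodulated PPG is a strictly periodic pulse train", {
  b <- generate_breathing_trace(breathing_spec(10, 60))
  mod <- ppg_modulation_spec(hr_bpm = 75, am_depth = 0, bw_amp = 0,
                             fm_depth = 0, noise_sd = 0)
  p <- generate_ppg(b$trace, b$events, mod)
  per <- round(25 * 60 / 75)          # one beat = 20 samples exactly
  a <- p$samples[101:(100 + 2 * per)]
  bb <- p$samples[(101 + 2 * per):(100 + 4 * per)]
  expect_equal(a, bb, tolerance = 1e-12)
})

test_that("baseline wander carries the volume trace into the PPG low band", {
  s <- strong_bw_serial(rate_bpm = 10, dur_s = 120, bw_amp = 0.5)
  # independent filter implementation: zero-phase Butterworth low-pass
  # below half the cardiac frequency
  bf <- signal::butter(4, (72 / 60 / 2) / (25 / 2), type = "low")
  low <- signal::filtfilt(bf, s$ppg$samples)
  expect_gt(cor(low, s$volume$samples), 0.95)
})

test_that("amplitude modulation imprints the volume on the beat peaks", {
  b <- generate_breathing_trace(breathing_spec(10, 120))
  mod <- ppg_modulation_spec(hr_bpm = 75, am_depth = 0.5, bw_amp = 0,
                             fm_depth = 0, noise_sd = 0)
  p <- generate_ppg(b$trace, b$events, mod)
  per <- round(25 * 60 / 75)
  nb <- length(p$samples) %/% per
  idx <- matrix(seq_len(nb * per), nrow = per)
  peaks <- apply(idx, 2, function(i) max(p$samples[i]))
  peak_t <- apply(idx, 2, function(i) (i[which.max(p$samples[i])] - 1) / 25)
  vol_at <- approx(ts_time(b$trace), b$trace$samples, xout = peak_t)$y
  expect_gt(cor(peaks, vol_at), 0.9)
})

test_that("beat-interval modulation depth is validated", {
  expect_error(ppg_modulation_spec(fm_depth = 1), "fm_depth")
  b <- generate_breathing_trace(breathing_spec(30, 10))
  mod <- ppg_modulation_spec(hr_bpm = 20)
  expect_error(generate_ppg(b$trace, b$events, mod),
               "must exceed the breathing rate")
})

test_that("stronger amplitude modulation increases beat-peak variance", {
  b <- generate_breathing_trace(breathing_spec(10, 120))
  per <- round(25 * 60 / 75)
  peak_var <- function(am) {
    mod <- ppg_modulation_spec(hr_bpm = 75, am_depth = am, bw_amp = 0,
                               fm_depth = 0, noise_sd = 0, seed = 9L)
    p <- generate_ppg(b$trace, b$events, mod)
    nb <- length(p$samples) %/% per
    var(apply(matrix(seq_len(nb * per), nrow = per), 2,
              function(i) max(p$samples[i])))
  }
  v <- vapply(c(0.1, 0.3, 0.5), peak_var, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("cohort generation matches the design arithmetic and is reproducible", {
  co <- generate_cohort(cohort_spec(n_subjects = 1, rates_bpm = 10,
                                    serial_duration_s = 60,
                                    master_seed = 3))
  expect_length(co$serials, 1)

  spec <- cohort_spec(n_subjects = 2, rates_bpm = c(6, 10),
                      serial_duration_s = 60, master_seed = 5)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1, co2)
  expect_length(co1$serials, 4)
  expect_equal(ts_duration(co1$serials[[1]]$ppg), 60)
  # stored peaks account one-to-one for generated breaths
  for (rec in co1$serials)
    expect_equal(sum(!is.na(rec$events$peak_time)), nrow(rec$events))
})

test_that("raw-rate mode emits native 75/100 Hz signals", {
  co <- generate_cohort(cohort_spec(n_subjects = 1, rates_bpm = 10,
                                    serial_duration_s = 60,
                                    raw_rates = TRUE, master_seed = 2))
  expect_equal(co$serials[[1]]$ppg$rate, 75)
  expect_equal(co$serials[[1]]$volume$rate, 100)
})
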