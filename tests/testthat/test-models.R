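test_that("both architectures emit one finite scalar per window", {
  for (kind in c("lstm", "unet")) {
    cfg <- extractor_config(kind, input_len = 32, hidden = 4, channels = 2,
                            kernel = 3, seed = 4)
    ex <- build_extractor(cfg)
    X <- matrix(rnorm(5 * 32), 5, 32)
    yhat <- ppgresp:::.nn_predict(kind, ex$params, X)
    expect_length(yhat, 5)
    expect_true(all(is.finite(yhat)))
    # same seed -> identical initial predictions
    ex2 <- build_extractor(cfg)
    expect_identical(ppgresp:::.nn_predict(kind, ex2$params, X), yhat)
  }
  expect_error(extractor_config("perceptron"))
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  X <- matrix(rnorm(2 * 6), 2, 6); y <- rnorm(2)
  p <- ppgresp:::.lstm_init(3, 5)
  g <- ppgresp:::.flatten_params(ppgresp:::.lstm_loss_grad(p, X, y)$grads)
  gn <- numerical_gradient(function(pp)
    ppgresp:::.lstm_loss_grad(pp, X, y)$loss, p)
  expect_lt(max_rel_err(g, gn), 1e-5)

  Xu <- matrix(rnorm(3 * 8), 3, 8); yu <- rnorm(3)
  pu <- ppgresp:::.unet_init(8, 2, 3, 7)
  gu <- ppgresp:::.flatten_params(ppgresp:::.unet_loss_grad(pu, Xu, yu)$grads)
  gnu <- numerical_gradient(function(pp)
    ppgresp:::.unet_loss_grad(pp, Xu, yu)$loss, pu)
  expect_lt(max_rel_err(gu, gnu), 1e-5)
})

test_that("early stopping follows the patience arithmetic", {
  # best epoch 2, patience 5: epochs 3..7 run without improvement and
  # epoch 8 is the first epoch not run
  expect_false(ppgresp:::.should_stop(7, 2, 5))
  expect_true(ppgresp:::.should_stop(8, 2, 5))

  # lr = 0: the validation loss improves only at epoch 1, so training
  # runs epochs 2..6 without improvement and stops at epoch 7
  set.seed(1)
  X <- matrix(rnorm(60 * 16), 60, 16); y <- rnorm(60)
  cfg <- extractor_config("lstm", input_len = 16, hidden = 3, lr = 0,
                          max_epochs = 50, early_stop_patience = 5,
                          batch_size = 32, seed = 2)
  tr <- train_extractor(build_extractor(cfg), X, y)
  expect_equal(tr$best_epoch, 1)
  expect_equal(nrow(tr$history), 6)
  expect_equal(tr$stopped_at_epoch, 7)
})

test_that("training converges on a degenerate zero target", {
  set.seed(3)
  X <- matrix(rnorm(300 * 16), 300, 16)
  y <- rep(0, 300)
  for (kind in c("lstm", "unet")) {
    cfg <- extractor_config(kind, input_len = 16, hidden = 4, channels = 2,
                            kernel = 3, max_epochs = 15, batch_size = 64,
                            seed = 5)
    tr <- train_extractor(build_extractor(cfg), X, y)
    expect_lt(abs(mean(ppgresp:::.nn_predict(kind, tr$params, X))), 0.05)
  }
})

test_that("seeded training is bit-reproducible", {
  set.seed(14)
  X <- matrix(rnorm(120 * 16), 120, 16)
  y <- rowMeans(X)
  for (kind in c("lstm", "unet")) {
    cfg <- extractor_config(kind, input_len = 16, hidden = 3, channels = 2,
                            kernel = 3, max_epochs = 4, batch_size = 32,
                            seed = 9)
    t1 <- train_extractor(build_extractor(cfg), X, y)
    t2 <- train_extractor(build_extractor(cfg), X, y)
    expect_identical(t1$params, t2$params)
    expect_identical(t1$history, t2$history)
  }
})

test_that("non-finite training loss aborts with a diagnostic", {
  X <- matrix(rnorm(40 * 16), 40, 16)
  y <- c(NA, rnorm(39))
  cfg <- extractor_config("lstm", input_len = 16, hidden = 3, seed = 1)
  expect_error(train_extractor(build_extractor(cfg), X, y), "non-finite")
})

test_that("predict_tvw obeys the sliding-window contract", {
  cfg <- extractor_config("lstm", input_len = 32, hidden = 4, seed = 6)
  ex <- build_extractor(cfg)
  ex$trained <- TRUE                     # inference contract needs no fit
  x <- rnorm(150)
  ppg <- time_series(x, 25)
  out <- predict_tvw(ex, ppg)
  expect_length(out$samples, 150 - 32 + 1)
  expect_equal(out$t0, 31 / 25)          # warm-up region precedes output
  expect_identical(predict_tvw(ex, ppg)$samples, out$samples)
  # translation consistency: shifting the input shifts the output
  shifted <- predict_tvw(ex, time_series(x[26:150], 25))
  expect_equal(shifted$samples, out$samples[26:119], tolerance = 1e-12)
  expect_error(predict_tvw(ex, time_series(rnorm(10), 25)), "shorter")
})

test_that("the band-pass baseline recovers wander and rejects the pulse", {
  s <- strong_bw_serial(rate_bpm = 10, dur_s = 120, bw_amp = 0.5)
  tvw <- bandpass_oracle_extract(s$ppg)
  expect_gt(cor(tvw$samples, s$volume$samples), 0.9)

  # pure cardiac train: everything lives above the breathing band
  b <- generate_breathing_trace(breathing_spec(10, 120))
  mod <- ppg_modulation_spec(hr_bpm = 75, am_depth = 0, bw_amp = 0,
                             fm_depth = 0, noise_sd = 0)
  pure <- generate_ppg(b$trace, b$events, mod)
  out <- bandpass_oracle_extract(pure)
  # compare on the original (un-normalized) scale
  x <- pure$samples - mean(pure$samples)
  n <- length(x)
  f <- seq(0, n - 1) * 25 / n; f <- pmin(f, 25 - f)
  X <- fft(x); X[f < 0.05 | f > 0.5] <- 0
  raw <- Re(fft(X, inverse = TRUE)) / n
  expect_lt(var(raw), 0.05 * var(pure$samples))

  expect_error(bandpass_oracle_extract(s$ppg, c(0.5, 0.05)), "band")
  expect_error(bandpass_oracle_extract(s$ppg, c(0.05, 20)), "band")
})

test_that("a trained network keeps pace with the band-pass baseline", {
  s <- strong_bw_serial(rate_bpm = 10, dur_s = 150, bw_amp = 0.5,
                        am_depth = 0.3, seed = 21)
  n <- length(s$ppg$samples)
  sp <- split_serial_folds(n, 5)
  b <- sp$blocks[sp$blocks$fold == 2, ]
  pairs <- make_training_pairs(s$ppg, s$volume)
  ok <- fold_training_starts(sp, 2, 320)
  ok <- ok[seq(1, length(ok), by = 8)]
  idx <- match(ok, pairs$start)
  cfg <- extractor_config("lstm", max_epochs = 8, seed = 31)
  tr <- train_extractor(build_extractor(cfg), pairs$X[idx, ], pairs$y[idx])

  block_ref <- ppgresp:::.block_ts(s$volume, b$start, b$end)
  pred <- predict_tvw(tr, ppgresp:::.block_ts(s$ppg, b$start - 319, b$end))
  r_net <- window_correlation(pred, block_ref)$r
  oracle <- bandpass_oracle_extract(s$ppg)
  r_oracle <- window_correlation(ppgresp:::.block_ts(oracle, b$start, b$end),
                                 block_ref)$r
  expect_gt(r_net, r_oracle - 0.1)
  expect_gt(r_net, 0.6)
})
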