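#' Configuration of a tidal-volume-waveform extractor
#'
#' Describes one of the three extractors: an LSTM sequence regressor, a
#' one-dimensional U-Net, or the model-free band-pass baseline. The two
#' networks map a `input_len`-sample PPG window to one volume sample and
#' are trained with mean-squared error, Adam, and early stopping that
#' halts when the validation loss has not improved for
#' `early_stop_patience` consecutive epochs (best-epoch weights are
#' retained).
#'
#' @param kind `"lstm"`, `"unet"` or `"bandpass_oracle"`.
#' @param input_len Input window length in samples.
#' @param hidden LSTM hidden-state width.
#' @param channels U-Net base channel count.
#' @param kernel U-Net convolution kernel length (odd).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param early_stop_patience Non-improving epochs tolerated (>= 1).
#' @param val_frac Fraction of training pairs held out (from the tail)
#'   as the validation set when none is supplied.
#' @param seed Seed for weight initialization and batch shuffling.
#'
#' @return An `extractor_config` object.
#' @export
extractor_config <- function(kind = c("lstm", "unet", "bandpass_oracle"),
                             input_len = 320, hidden = 16, channels = 4,
                             kernel = 7, lr = 0.01, batch_size = 64,
                             max_epochs = 30, early_stop_patience = 5,
                             val_frac = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  if (early_stop_patience < 1) stop("early_stop_patience must be >= 1")
  structure(list(kind = kind, input_len = as.integer(input_len),
                 hidden = as.integer(hidden),
                 channels = as.integer(channels),
                 kernel = as.integer(kernel), lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "extractor_config")
}

#' Build an untrained extractor
#'
#' Initializes the weights of the configured architecture; two builds with
#' the same config (including seed) produce identical initial predictions.
#'
#' @param config An [extractor_config()].
#' @return A `ppg_extractor` object.
#' @export
build_extractor <- function(config) {
  stopifnot(inherits(config, "extractor_config"))
  params <- switch(config$kind,
    lstm = .lstm_init(config$hidden, config$seed),
    unet = .unet_init(config$input_len, config$channels, config$kernel,
                      config$seed),
    bandpass_oracle = list())
  structure(list(config = config, params = params, trained = FALSE,
                 history = NULL),
            class = "ppg_extractor")
}

#' @export
print.ppg_extractor <- function(x, ...) {
  cat(sprintf("<ppg_extractor> %s, %d parameters, %s\n", x$config$kind,
              length(unlist(x$params)),
              if (x$trained) sprintf("trained (%d epochs)",
                                     nrow(x$history)) else "untrained"))
  invisible(x)
}

# ---- parameter flattening and Adam ----------------------------------------

.flatten_params <- function(p) unlist(p, use.names = FALSE)

.unflatten_params <- function(v, template) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  fill(template)
}

.adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

.adam_step <- function(theta, grad, st, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}

# Early-stopping rule: before running epoch `epoch`, stop when the best
# validation loss dates back more than `patience` epochs. With the best
# epoch at 2 and patience 5, epochs 3..7 run and epoch 8 does not.
.should_stop <- function(epoch, best_epoch, patience) {
  (epoch - best_epoch) > patience
}

.nn_loss_grad <- function(kind, params, X, y) {
  switch(kind, lstm = .lstm_loss_grad(params, X, y),
         unet = .unet_loss_grad(params, X, y),
         stop("unknown kind ", kind))
}

.nn_predict <- function(kind, params, X) {
  switch(kind, lstm = .lstm_predict(params, X),
         unet = .unet_predict(params, X),
         stop("unknown kind ", kind))
}

#' Train an extractor on sliding-window pairs
#'
#' Minimizes mean-squared error between the predicted and reference
#' volume sample with Adam. After every epoch the validation loss is
#' evaluated; training stops once it has failed to improve for
#' `early_stop_patience` consecutive epochs (or at `max_epochs`), and the
#' best-epoch weights are restored. When no validation set is supplied,
#' the tail `val_frac` of the training pairs is held out.
#'
#' @param extractor An untrained [build_extractor()] result of kind
#'   `"lstm"` or `"unet"`.
#' @param X Matrix of input windows (one per row).
#' @param y Target volume samples.
#' @param X_val,y_val Optional validation pairs.
#'
#' @return The trained `ppg_extractor`, with a `history` data frame of
#'   per-epoch training and validation loss and `stopped_at_epoch`, the
#'   first epoch not run.
#' @export
train_extractor <- function(extractor, X, y, X_val = NULL, y_val = NULL) {
  stopifnot(inherits(extractor, "ppg_extractor"))
  cfg <- extractor$config
  if (cfg$kind == "bandpass_oracle")
    stop("the band-pass oracle is deterministic and is not trained")
  if (!is.matrix(X) || nrow(X) == 0) stop("no training pairs supplied")
  if (ncol(X) != cfg$input_len)
    stop("window length ", ncol(X), " does not match config input_len ",
         cfg$input_len)
  if (is.null(X_val)) {
    n_val <- max(1L, floor(cfg$val_frac * nrow(X)))
    if (nrow(X) - n_val < 1) stop("too few pairs to hold out validation")
    vi <- (nrow(X) - n_val + 1L):nrow(X)
    X_val <- X[vi, , drop = FALSE]; y_val <- y[vi]
    X <- X[-vi, , drop = FALSE]; y <- y[-vi]
  }
  params <- extractor$params
  flat <- .flatten_params(params)
  st <- .adam_new(length(flat))
  set.seed(cfg$seed + 1L)
  best_loss <- Inf; best_flat <- flat; best_epoch <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  stopped_at <- cfg$max_epochs + 1L
  for (epoch in seq_len(cfg$max_epochs)) {
    if (.should_stop(epoch, best_epoch, cfg$early_stop_patience)) {
      stopped_at <- epoch
      break
    }
    ord <- sample.int(nrow(X))
    ep_loss <- 0
    for (s in seq(1L, length(ord), by = cfg$batch_size)) {
      bi <- ord[s:min(length(ord), s + cfg$batch_size - 1L)]
      lg <- .nn_loss_grad(cfg$kind, params, X[bi, , drop = FALSE], y[bi])
      if (!is.finite(lg$loss))
        stop(sprintf(
          "non-finite training loss (%s, epoch %d): try a lower lr",
          cfg$kind, epoch))
      ep_loss <- ep_loss + lg$loss * length(bi)
      up <- .adam_step(flat, .flatten_params(lg$grads), st, cfg$lr)
      flat <- up$theta; st <- up$state
      params <- .unflatten_params(flat, params)
    }
    val_loss <- mean((.nn_predict(cfg$kind, params, X_val) - y_val)^2)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = ep_loss / length(ord),
                                   val_loss = val_loss))
    if (val_loss < best_loss - 1e-12) {
      best_loss <- val_loss; best_flat <- flat; best_epoch <- epoch
    }
  }
  extractor$params <- .unflatten_params(best_flat, extractor$params)
  extractor$trained <- TRUE
  extractor$history <- hist
  extractor$best_epoch <- best_epoch
  extractor$stopped_at_epoch <- stopped_at
  extractor
}

#' Predict a tidal-volume waveform from a PPG trace
#'
#' Slides the extractor's input window over the PPG at stride 1 and emits
#' one volume sample per position. Under causal alignment the output
#' sample at time t is predicted from the window ending at t, so the
#' first `input_len - 1` samples of the trace form a warm-up region with
#' no prediction; the output `time_series` starts after it.
#'
#' @param extractor A trained `ppg_extractor` (or a `bandpass_oracle`
#'   one, which needs no training).
#' @param ppg A [time_series()] at the rate the extractor was trained on.
#' @param alignment Window-to-target alignment, as in
#'   [make_training_pairs()].
#' @return A [time_series()] of predicted relative volume.
#' @export
predict_tvw <- function(extractor, ppg,
                        alignment = c("causal", "center")) {
  alignment <- match.arg(alignment)
  stopifnot(inherits(extractor, "ppg_extractor"),
            inherits(ppg, "time_series"))
  cfg <- extractor$config
  if (cfg$kind == "bandpass_oracle")
    return(bandpass_oracle_extract(ppg))
  if (!extractor$trained) stop("extractor has not been trained")
  L <- cfg$input_len
  n <- length(ppg$samples)
  if (n < L) stop("input shorter than one window (", L, " samples)")
  starts <- seq_len(n - L + 1L)
  X <- matrix(0, length(starts), L)
  for (j in seq_len(L)) X[, j] <- ppg$samples[starts + j - 1L]
  yhat <- .nn_predict(cfg$kind, extractor$params, X)
  offset <- if (alignment == "causal") L - 1L else floor(L / 2)
  time_series(yhat, ppg$rate, t0 = ppg$t0 + offset / ppg$rate)
}

#' Model-free band-pass extraction of the breathing waveform
#'
#' Deterministic baseline extractor: zero-phase band-pass filtering of the
#' PPG over the breathing band (default 0.05-0.5 Hz, i.e. 3-30 breaths
#' per minute), implemented in the frequency domain, then z-scored. It
#' recovers the respiratory baseline-wander component directly and lets
#' every downstream stage run without any training.
#'
#' @param ppg A [time_series()].
#' @param band_hz Pass band `c(low, high)` in Hz; must satisfy
#'   `0 < low < high < rate/2`.
#' @return A [time_series()] on the same time base as the input.
#' @export
bandpass_oracle_extract <- function(ppg, band_hz = c(0.05, 0.5)) {
  stopifnot(inherits(ppg, "time_series"))
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[2] <= band_hz[1] ||
      band_hz[2] >= ppg$rate / 2)
    stop("band must satisfy 0 < low < high < rate/2")
  x <- ppg$samples - mean(ppg$samples)
  n <- length(x)
  f <- seq(0, n - 1) * ppg$rate / n
  f <- pmin(f, ppg$rate - f)            # two-sided frequency axis
  X <- stats::fft(x)
  X[f < band_hz[1] | f > band_hz[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(time_series(rep(0, n), ppg$rate, ppg$t0))
  time_series((y - mean(y)) / s, ppg$rate, ppg$t0)
}
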