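# LSTM sequence regressor: one gated recurrent layer unrolled over the
# input window, scalar regression head on the final hidden state.
# Implemented directly with batched matrix operations (forward + full
# backpropagation through time); correctness is pinned by the
# finite-difference gradient checks in the test suite.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform gate weights, forget-gate bias 1 (standard LSTM practice)
.lstm_init <- function(hidden, seed) {
  set.seed(seed)
  H <- hidden
  s <- sqrt(6 / (1 + H + 4 * H))
  W <- matrix(stats::runif((1 + H) * 4 * H, -s, s), 1 + H, 4 * H)
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1
  list(W = W, b = b,
       w_y = stats::rnorm(H, sd = 1 / sqrt(H)), b_y = 0)
}

# X: B x T matrix of input windows. Returns predictions and, optionally,
# the per-step cache needed for backpropagation.
.lstm_forward <- function(params, X, keep_cache = FALSE) {
  B <- nrow(X); Tn <- ncol(X); H <- length(params$w_y)
  Wx <- params$W[1, ]
  Wh <- params$W[-1, , drop = FALSE]
  bB <- rep(params$b, each = B)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  ii <- 1:H; fi <- (H + 1):(2 * H); gi <- (2 * H + 1):(3 * H)
  oi <- (3 * H + 1):(4 * H)
  cache <- if (keep_cache)
    list(I = vector("list", Tn), F = vector("list", Tn),
         G = vector("list", Tn), O = vector("list", Tn),
         TC = vector("list", Tn), Cprev = vector("list", Tn),
         Hprev = vector("list", Tn))
  for (t in seq_len(Tn)) {
    z <- outer(X[, t], Wx) + h %*% Wh + bB
    i <- .sigmoid(z[, ii, drop = FALSE])
    f <- .sigmoid(z[, fi, drop = FALSE])
    g <- tanh(z[, gi, drop = FALSE])
    o <- .sigmoid(z[, oi, drop = FALSE])
    if (keep_cache) {
      cache$I[[t]] <- i; cache$F[[t]] <- f; cache$G[[t]] <- g
      cache$O[[t]] <- o; cache$Cprev[[t]] <- cc; cache$Hprev[[t]] <- h
    }
    cc <- f * cc + i * g
    tc <- tanh(cc)
    if (keep_cache) cache$TC[[t]] <- tc
    h <- o * tc
  }
  yhat <- drop(h %*% params$w_y) + params$b_y
  list(yhat = yhat, h_final = h, cache = cache)
}

# Mean-squared-error loss and gradients for a batch.
.lstm_loss_grad <- function(params, X, y) {
  B <- nrow(X); Tn <- ncol(X); H <- length(params$w_y)
  fw <- .lstm_forward(params, X, keep_cache = TRUE)
  ca <- fw$cache
  res <- fw$yhat - y
  loss <- mean(res^2)
  dyhat <- 2 * res / B

  Wh <- params$W[-1, , drop = FALSE]
  dW <- matrix(0, 1 + H, 4 * H)
  db <- rep(0, 4 * H)
  dw_y <- drop(crossprod(fw$h_final, dyhat))
  db_y <- sum(dyhat)
  dh <- outer(dyhat, params$w_y)
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    i <- ca$I[[t]]; f <- ca$F[[t]]; g <- ca$G[[t]]; o <- ca$O[[t]]
    tc <- ca$TC[[t]]; cprev <- ca$Cprev[[t]]; hprev <- ca$Hprev[[t]]
    do_ <- dh * tc
    dc <- dc + dh * o * (1 - tc^2)
    di <- dc * g
    dg <- dc * i
    df <- dc * cprev
    dc <- dc * f
    dz <- cbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - g^2), do_ * o * (1 - o))
    dW[1, ] <- dW[1, ] + colSums(dz * X[, t])
    dW[-1, ] <- dW[-1, ] + crossprod(hprev, dz)
    db <- db + colSums(dz)
    dh <- dz %*% t(Wh)
  }
  list(loss = loss,
       grads = list(W = dW, b = db, w_y = dw_y, b_y = db_y))
}

.lstm_predict <- function(params, X, chunk = 2048L) {
  out <- numeric(nrow(X))
  for (s in seq(1L, nrow(X), by = chunk)) {
    e <- min(nrow(X), s + chunk - 1L)
    out[s:e] <- .lstm_forward(params, X[s:e, , drop = FALSE])$yhat
  }
  out
}
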