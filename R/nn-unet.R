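# One-dimensional U-Net regressor: a two-level convolutional
# encoder-decoder with skip connections over the input window, a 1x1
# output convolution and a dense readout to a single sample. All tensors
# are arrays of dim (batch, length, channels); convolutions use "same"
# zero padding and are evaluated in im2col form so each layer is a single
# BLAS matrix product. Backward passes are hand-derived and pinned by
# finite-difference gradient checks in the test suite.

# ---- convolution primitives ------------------------------------------------

# (B, L, Cin) -> (B*L) x (Cin*K), column blocks ordered by kernel offset
.im2col <- function(x, K) {
  d <- dim(x); B <- d[1]; L <- d[2]; Cin <- d[3]
  pad <- (K - 1L) %/% 2L
  xp <- array(0, c(B, L + K - 1L, Cin))
  xp[, pad + seq_len(L), ] <- x
  col <- matrix(0, B * L, Cin * K)
  for (k in seq_len(K)) {
    xs <- xp[, k:(k + L - 1L), , drop = FALSE]
    dim(xs) <- c(B * L, Cin)
    col[, ((k - 1L) * Cin + 1L):(k * Cin)] <- xs
  }
  col
}

# weight array (K, Cin, Cout) -> (Cin*K) x Cout matching .im2col layout
.wmat <- function(W) {
  d <- dim(W)
  m <- aperm(W, c(2L, 1L, 3L))
  dim(m) <- c(d[1] * d[2], d[3])
  m
}

.conv1d_fwd <- function(x, W, b) {
  d <- dim(x); B <- d[1]; L <- d[2]
  Cout <- dim(W)[3]
  col <- .im2col(x, dim(W)[1])
  out <- col %*% .wmat(W) + rep(b, each = B * L)
  dim(out) <- c(B, L, Cout)
  list(out = out, col = col)
}

# col: cached im2col of the layer input; x_dim: dim of that input
.conv1d_bwd <- function(col, x_dim, W, dout) {
  B <- x_dim[1]; L <- x_dim[2]; Cin <- x_dim[3]
  K <- dim(W)[1]; Cout <- dim(W)[3]
  pad <- (K - 1L) %/% 2L
  dmat <- dout; dim(dmat) <- c(B * L, Cout)
  db <- colSums(dmat)
  dWmat <- crossprod(col, dmat)
  dW <- array(dWmat, c(Cin, K, Cout))
  dW <- aperm(dW, c(2L, 1L, 3L))
  dcol <- dmat %*% t(.wmat(W))
  dxp <- array(0, c(B, L + K - 1L, Cin))
  for (k in seq_len(K)) {
    blk <- dcol[, ((k - 1L) * Cin + 1L):(k * Cin), drop = FALSE]
    dxp[, k:(k + L - 1L), ] <- dxp[, k:(k + L - 1L), , drop = FALSE] +
      array(blk, c(B, L, Cin))
  }
  list(dx = dxp[, pad + seq_len(L), , drop = FALSE], dW = dW, db = db)
}

# ---- pooling / upsampling / concatenation ---------------------------------

.pool2_fwd <- function(x) {
  L <- dim(x)[2]
  (x[, seq(1L, L, 2L), , drop = FALSE] +
     x[, seq(2L, L, 2L), , drop = FALSE]) / 2
}

.pool2_bwd <- function(dout, L) {
  d <- dim(dout)
  dx <- array(0, c(d[1], L, d[3]))
  dx[, seq(1L, L, 2L), ] <- dout / 2
  dx[, seq(2L, L, 2L), ] <- dout / 2
  dx
}

.up2_fwd <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1], 2L * d[2], d[3]))
  out[, seq(1L, 2L * d[2], 2L), ] <- x
  out[, seq(2L, 2L * d[2], 2L), ] <- x
  out
}

.up2_bwd <- function(dout) {
  L2 <- dim(dout)[2]
  dout[, seq(1L, L2, 2L), , drop = FALSE] +
    dout[, seq(2L, L2, 2L), , drop = FALSE]
}

.cat_ch <- function(a, b) {
  da <- dim(a); db_ <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db_[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db_[3])] <- b
  out
}

# ---- network ---------------------------------------------------------------

.unet_init <- function(input_len, channels, kernel, seed) {
  if (input_len %% 4L != 0L)
    stop("U-Net input length must be divisible by 4")
  if (kernel %% 2L == 0L) stop("kernel size must be odd")
  set.seed(seed)
  C <- channels
  he <- function(K, Cin, Cout)
    array(stats::rnorm(K * Cin * Cout, sd = sqrt(2 / (K * Cin))),
          c(K, Cin, Cout))
  list(enc1 = list(W = he(kernel, 1L, C), b = rep(0, C)),
       enc2 = list(W = he(kernel, C, 2L * C), b = rep(0, 2L * C)),
       bott = list(W = he(kernel, 2L * C, 2L * C), b = rep(0, 2L * C)),
       dec2 = list(W = he(kernel, 4L * C, 2L * C), b = rep(0, 2L * C)),
       dec1 = list(W = he(kernel, 3L * C, C), b = rep(0, C)),
       outc = list(W = he(1L, C, 1L), b = 0),
       head_w = stats::rnorm(input_len, sd = 1 / sqrt(input_len)),
       head_b = 0)
}

.unet_forward <- function(params, X, keep_cache = FALSE) {
  B <- nrow(X); L <- ncol(X)
  x <- array(X, c(B, L, 1L))
  f1 <- .conv1d_fwd(x, params$enc1$W, params$enc1$b)
  a1 <- pmax(f1$out, 0)
  p1 <- .pool2_fwd(a1)
  f2 <- .conv1d_fwd(p1, params$enc2$W, params$enc2$b)
  a2 <- pmax(f2$out, 0)
  p2 <- .pool2_fwd(a2)
  f3 <- .conv1d_fwd(p2, params$bott$W, params$bott$b)
  a3 <- pmax(f3$out, 0)
  c2 <- .cat_ch(.up2_fwd(a3), a2)
  f4 <- .conv1d_fwd(c2, params$dec2$W, params$dec2$b)
  a4 <- pmax(f4$out, 0)
  c1 <- .cat_ch(.up2_fwd(a4), a1)
  f5 <- .conv1d_fwd(c1, params$dec1$W, params$dec1$b)
  a5 <- pmax(f5$out, 0)
  f6 <- .conv1d_fwd(a5, params$outc$W, params$outc$b)
  zmat <- matrix(f6$out, B, L)
  yhat <- drop(zmat %*% params$head_w) + params$head_b
  cache <- if (keep_cache)
    list(z1 = f1$out, z2 = f2$out, z3 = f3$out, z4 = f4$out, z5 = f5$out,
         col1 = f1$col, col2 = f2$col, col3 = f3$col, col4 = f4$col,
         col5 = f5$col, col6 = f6$col,
         d_x = dim(x), d_p1 = dim(p1), d_p2 = dim(p2), d_c2 = dim(c2),
         d_c1 = dim(c1), zmat = zmat)
  list(yhat = yhat, cache = cache)
}

.unet_loss_grad <- function(params, X, y) {
  B <- nrow(X); L <- ncol(X)
  fw <- .unet_forward(params, X, keep_cache = TRUE)
  ca <- fw$cache
  res <- fw$yhat - y
  loss <- mean(res^2)
  dyhat <- 2 * res / B

  dhead_w <- drop(crossprod(ca$zmat, dyhat))
  dhead_b <- sum(dyhat)
  d_a5 <- dim(ca$z5)
  dz6 <- array(outer(dyhat, params$head_w), c(B, L, 1L))
  g6 <- .conv1d_bwd(ca$col6, d_a5, params$outc$W, dz6)
  dz5 <- g6$dx * (ca$z5 > 0)
  g5 <- .conv1d_bwd(ca$col5, ca$d_c1, params$dec1$W, dz5)
  C4 <- dim(ca$z4)[3]                   # channels carried up by the decoder
  du1 <- g5$dx[, , seq_len(C4), drop = FALSE]
  da1_skip <- g5$dx[, , -seq_len(C4), drop = FALSE]
  dz4 <- .up2_bwd(du1) * (ca$z4 > 0)
  g4 <- .conv1d_bwd(ca$col4, ca$d_c2, params$dec2$W, dz4)
  C3 <- dim(ca$z3)[3]
  du2 <- g4$dx[, , seq_len(C3), drop = FALSE]
  da2_skip <- g4$dx[, , -seq_len(C3), drop = FALSE]
  dz3 <- .up2_bwd(du2) * (ca$z3 > 0)
  g3 <- .conv1d_bwd(ca$col3, ca$d_p2, params$bott$W, dz3)
  da2 <- .pool2_bwd(g3$dx, dim(ca$z2)[2]) + da2_skip
  dz2 <- da2 * (ca$z2 > 0)
  g2 <- .conv1d_bwd(ca$col2, ca$d_p1, params$enc2$W, dz2)
  da1 <- .pool2_bwd(g2$dx, dim(ca$z1)[2]) + da1_skip
  dz1 <- da1 * (ca$z1 > 0)
  g1 <- .conv1d_bwd(ca$col1, ca$d_x, params$enc1$W, dz1)

  list(loss = loss,
       grads = list(enc1 = list(W = g1$dW, b = g1$db),
                    enc2 = list(W = g2$dW, b = g2$db),
                    bott = list(W = g3$dW, b = g3$db),
                    dec2 = list(W = g4$dW, b = g4$db),
                    dec1 = list(W = g5$dW, b = g5$db),
                    outc = list(W = g6$dW, b = g6$db),
                    head_w = dhead_w, head_b = dhead_b))
}

.unet_predict <- function(params, X, chunk = 1024L) {
  out <- numeric(nrow(X))
  for (s in seq(1L, nrow(X), by = chunk)) {
    e <- min(nrow(X), s + chunk - 1L)
    out[s:e] <- .unet_forward(params, X[s:e, , drop = FALSE])$yhat
  }
  out
}
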