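# Low-level differentiable operations for the network. Every *_fwd returns
# list(out, cache); every *_bwd takes the upstream gradient plus the cache
# and returns the input gradient and any parameter gradients. Shapes:
# signals are (N, L, C) arrays (batch, length, channels); token matrices
# are (M, l). All backward passes are verified against central finite
# differences in the test suite.

.nn_eps <- 1e-5

# ---- 1-D convolution (im2col) -----------------------------------------
# W is a (k*Cin, Cout) matrix; rows ordered so that column block j of the
# im2col matrix (kernel offset j, channels 1..Cin) matches rows
# ((j-1)*Cin + 1):(j*Cin).

conv1d_fwd <- function(X, W, b, stride = 1L, pad = 1L, k = 3L) {
  Y <- conv1d_fwd_cpp(X, W, as.numeric(b), stride, pad, k)
  list(out = Y, cache = list(X = X, stride = stride, pad = pad, k = k))
}

conv1d_bwd <- function(dY, W, cache) {
  r <- conv1d_bwd_cpp(cache$X, W, dY, cache$stride, cache$pad, cache$k)
  r$db <- as.numeric(r$db)
  r
}

# ---- instance normalization (per sample, per channel, over length) ----

inorm_fwd <- function(X) {
  r <- inorm_fwd_cpp(X, .nn_eps)
  list(out = r$xhat, cache = list(xhat = r$xhat, istd = r$istd))
}

inorm_bwd <- function(dY, cache) {
  inorm_bwd_cpp(dY, cache$xhat, cache$istd)
}

# ---- pointwise nonlinearities -----------------------------------------

relu_fwd <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}
relu_bwd <- function(dY, mask) dY * mask

gelu_fwd <- function(X) {
  ph <- stats::pnorm(X)
  list(out = X * ph, cache = list(X = X, ph = ph))
}
gelu_bwd <- function(dY, cache) {
  dY * (cache$ph + cache$X * stats::dnorm(cache$X))
}

# ---- x2 linear upsampling over length ---------------------------------
# out[2i-1] = x[i]; out[2i] = (x[i] + x[i+1])/2, clamped at the boundary.

upsample2_fwd <- function(X) {
  dm <- dim(X); N <- dm[1]; L <- dm[2]; C <- dm[3]
  Y <- array(0, c(N, 2L * L, C))
  odd <- seq.int(1L, 2L * L, by = 2L)
  Y[, odd, ] <- X
  nxt <- c(seq_len(L)[-1], L)
  Y[, odd + 1L, ] <- 0.5 * (X + X[, nxt, , drop = FALSE])
  list(out = Y, cache = L)
}

upsample2_bwd <- function(dY, L) {
  odd <- seq.int(1L, 2L * L, by = 2L)
  even <- odd + 1L
  dX <- dY[, odd, , drop = FALSE] + 0.5 * dY[, even, , drop = FALSE]
  if (L > 1) {
    dX[, 2:L, ] <- dX[, 2:L, , drop = FALSE] +
      0.5 * dY[, even[1:(L - 1)], , drop = FALSE]
  }
  dX[, L, ] <- dX[, L, , drop = FALSE] + 0.5 * dY[, even[L], , drop = FALSE]
  dX
}

# ---- dense layer -------------------------------------------------------

linear_fwd <- function(X, W, b) {
  Y <- X %*% W
  Y <- Y + rep(b, each = nrow(X))
  list(out = Y, cache = X)
}

linear_bwd <- function(dY, W, X) {
  list(dX = tcrossprod(dY, W), dW = crossprod(X, dY), db = colSums(dY))
}

# ---- layer normalization (per row, affine) ----------------------------

layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + .nn_eps)
  xhat <- xc * istd
  Y <- xhat * rep(g, each = nrow(X)) + rep(b, each = nrow(X))
  list(out = Y, cache = list(xhat = xhat, istd = istd))
}

layernorm_bwd <- function(dY, g, cache) {
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- dY * rep(g, each = nrow(dY))
  dX <- cache$istd * (dxhat - rowMeans(dxhat) -
                        xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

# ---- softmax over rows -------------------------------------------------

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

# dS from dA given A = softmax_rows(S)
softmax_rows_bwd <- function(dA, A) {
  A * (dA - rowSums(dA * A))
}

# ---- inverted dropout --------------------------------------------------

dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, cache = NULL))
  mask <- (stats::runif(length(X)) >= p) / (1 - p)
  dim(mask) <- dim(X)
  list(out = X * mask, cache = mask)
}

dropout_bwd <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}
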