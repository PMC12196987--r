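#' Architecture configuration
#'
#' Hyperparameters of the two-stage network: parallel residual U-shaped
#' 1-D convolutional encoders per cycle (stage 1) followed by Transformer
#' layers with a signed sinusoidal relative positional bias on the
#' attention scores (stage 2) and a per-token projection head.
#'
#' Cycle slices are stored at 125 samples and right zero-padded to
#' `l0 = 128` at the model input so the outer residual addition of stage 1
#' is shape-consistent with the feature length `l`.
#'
#' @param n Cycles per contextual sample (default 60).
#' @param l0 Model input length per cycle (128).
#' @param l Feature length per token (128; must equal `l0`).
#' @param d Depth of the U structure (number of 2x down-steps; default 2).
#' @param r Number of residual blocks at the bottleneck (default 8).
#' @param heads Attention heads (default 8; must divide `l`).
#' @param L Number of Transformer layers (default 3).
#' @param base_channels Convolution width at full resolution (default 16;
#'   doubles at each down-step).
#' @param mlp_expansion Hidden expansion ratio of the Transformer MLP.
#' @param dropout Dropout probability inside attention/MLP (training only).
#' @param pe_mode `"rpe"` (signed relative positional attention bias,
#'   the default), `"ape"` (absolute sinusoidal encodings added to the
#'   tokens once before layer 1), or `"none"`.
#' @param kernel_size Convolution kernel size (default 3).
#' @return A list of class `model_config`.
#' @export
model_config <- function(n = 60L, l0 = 128L, l = 128L, d = 2L, r = 8L,
                         heads = 8L, L = 3L, base_channels = 16L,
                         mlp_expansion = 4L, dropout = 0.1,
                         pe_mode = c("rpe", "ape", "none"),
                         kernel_size = 3L) {
  pe_mode <- match.arg(pe_mode)
  if (l %% heads != 0) stop("`l` must be divisible by `heads`", call. = FALSE)
  if (l0 != l) stop("`l0` must equal `l` (outer residual)", call. = FALSE)
  if (d < 1 || r < 1 || L < 1)
    stop("`d`, `r` and `L` must all be >= 1", call. = FALSE)
  if (l0 %% (2^d) != 0)
    stop("`l0` must be divisible by 2^d", call. = FALSE)
  structure(list(n = as.integer(n), l0 = as.integer(l0), l = as.integer(l),
                 d = as.integer(d), r = as.integer(r),
                 heads = as.integer(heads), L = as.integer(L),
                 base_channels = as.integer(base_channels),
                 mlp_expansion = as.integer(mlp_expansion),
                 dropout = dropout, pe_mode = pe_mode,
                 kernel_size = as.integer(kernel_size)),
            class = "model_config")
}

# ---- positional encodings ---------------------------------------------

# Sinusoidal encoding of a scalar offset j into D dimensions:
# dimension pair x (0-based): sin(j / 10000^(2x/D)), cos(j / 10000^(2x/D)).
pe_vector <- function(j, D) {
  x <- 0:(D %/% 2 - 1)
  freq <- 1 / 10000^(2 * x / D)
  out <- numeric(D)
  out[2 * x + 1] <- sin(j * freq)
  out[2 * x + 2] <- cos(j * freq)
  out
}

#' Signed relative positional encoding between two cycle positions
#'
#' Returns `sign(a - b) * PE(|a - b|)` where PE is the sinusoidal encoding
#' of the offset. Antisymmetric (`p(a,b) = -p(b,a)`) with a zero vector on
#' the diagonal, and a function of `a - b` only.
#'
#' @param a,b 1-based cycle positions.
#' @param D Encoding dimension (the feature length `l`).
#' @return Numeric vector of length `D`.
#' @export
signed_pe <- function(a, b, D) {
  sign(a - b) * pe_vector(abs(a - b), D)
}

# (n*n, D) matrix of signed relative encodings; row index a + n*(b-1).
rpe_matrix <- function(n, D) {
  lut <- t(vapply(0:(n - 1), pe_vector, numeric(D), D = D))  # offsets 0..n-1
  a <- rep(seq_len(n), n)
  b <- rep(seq_len(n), each = n)
  sign(a - b) * lut[abs(a - b) + 1L, , drop = FALSE]
}

# (n, D) absolute sinusoidal encodings for positions 1..n.
ape_matrix <- function(n, D) {
  t(vapply(seq_len(n), pe_vector, numeric(D), D = D))
}

#' Per-head relative positional attention bias
#'
#' Projects each signed relative encoding `p[a,b]` to a scalar with the
#' learnable head vector `w_p`, giving the `n x n` bias added to that
#' head's pre-softmax attention scores.
#'
#' @param wp `heads x l` matrix of head projection vectors.
#' @param n Sequence length.
#' @param Pmat Optional precomputed [rpe_matrix()].
#' @return `heads x n x n` array.
#' @export
rpe_bias <- function(wp, n, Pmat = NULL) {
  if (is.null(Pmat)) Pmat <- rpe_matrix(n, ncol(wp))
  H <- nrow(wp)
  out <- array(0, c(H, n, n))
  Bm <- Pmat %*% t(wp)                      # (n*n, H)
  for (h in seq_len(H)) out[h, , ] <- matrix(Bm[, h], n, n)
  out
}

# ---- parameter initialization -----------------------------------------

#' Initialize model parameters
#'
#' He-style normal initialization for convolutions (post-ReLU layers),
#' Xavier-style for dense maps, unit/zero layer norms, small-normal
#' positional projections. Deterministic given `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return Named list of parameter arrays.
#' @export
init_params <- function(config, seed = 1L) {
  cf <- config
  k <- cf$kernel_size
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  p <- list()
  cw <- function(cin, cout) matrix(stats::rnorm(k * cin * cout,
                                                sd = sqrt(2 / (k * cin))),
                                   k * cin, cout)
  lw <- function(din, dout) matrix(stats::rnorm(din * dout,
                                                sd = sqrt(1 / din)),
                                   din, dout)
  C <- cf$base_channels
  p[["resu.in.W"]] <- cw(1L, C); p[["resu.in.b"]] <- numeric(C)
  for (i in seq_len(cf$d)) {
    p[[sprintf("resu.down%d.W", i)]] <- cw(C * 2^(i - 1), C * 2^i)
    p[[sprintf("resu.down%d.b", i)]] <- numeric(C * 2^i)
  }
  Cd <- C * 2^cf$d
  for (j in seq_len(cf$r)) {
    p[[sprintf("resu.res%d.W1", j)]] <- cw(Cd, Cd)
    p[[sprintf("resu.res%d.b1", j)]] <- numeric(Cd)
    p[[sprintf("resu.res%d.W2", j)]] <- cw(Cd, Cd)
    p[[sprintf("resu.res%d.b2", j)]] <- numeric(Cd)
  }
  for (i in rev(seq_len(cf$d))) {
    p[[sprintf("resu.up%d.W", i)]] <- cw(C * 2^i, C * 2^(i - 1))
    p[[sprintf("resu.up%d.b", i)]] <- numeric(C * 2^(i - 1))
  }
  p[["resu.out.W"]] <- cw(C, 1L); p[["resu.out.b"]] <- numeric(1L)
  l <- cf$l
  for (t in seq_len(cf$L)) {
    pre <- sprintf("tr%d.", t)
    p[[paste0(pre, "ln1.g")]] <- rep(1, l)
    p[[paste0(pre, "ln1.b")]] <- numeric(l)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, nm)]] <- lw(l, l)
    for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(pre, nm)]] <- numeric(l)
    if (cf$pe_mode == "rpe")
      p[[paste0(pre, "wp")]] <- matrix(stats::rnorm(cf$heads * l, sd = 0.02),
                                       cf$heads, l)
    p[[paste0(pre, "ln2.g")]] <- rep(1, l)
    p[[paste0(pre, "ln2.b")]] <- numeric(l)
    e <- cf$mlp_expansion * l
    p[[paste0(pre, "mlp.W1")]] <- lw(l, e)
    p[[paste0(pre, "mlp.b1")]] <- numeric(e)
    p[[paste0(pre, "mlp.W2")]] <- lw(e, l)
    p[[paste0(pre, "mlp.b2")]] <- numeric(l)
  }
  p[["proj.W1"]] <- lw(l, l %/% 2); p[["proj.b1"]] <- numeric(l %/% 2)
  p[["proj.W2"]] <- lw(l %/% 2, 1L); p[["proj.b2"]] <- numeric(1L)
  p
}

#' Number of learnable parameters
#' @param params Parameter list from [init_params()].
#' @return Integer count.
#' @export
n_params <- function(params) sum(vapply(params, length, integer(1)))

# ---- stage 1: ResU -----------------------------------------------------

# conv + instance norm + ReLU
cir_fwd <- function(X, W, b, stride, k) {
  cv <- conv1d_fwd(X, W, b, stride = stride, pad = (k - 1L) %/% 2L, k = k)
  io <- inorm_fwd(cv$out)
  rl <- relu_fwd(io$out)
  list(out = rl$out, cache = list(cv = cv$cache, io = io$cache,
                                  mask = rl$cache))
}

cir_bwd <- function(dY, W, cache) {
  d1 <- relu_bwd(dY, cache$mask)
  d2 <- inorm_bwd(d1, cache$io)
  conv1d_bwd(d2, W, cache$cv)
}

#' Stage-1 forward: residual U-shaped encoder applied to each cycle
#'
#' Applies the shared-weight ResU block to every cycle in the batch:
#' an input conv-instancenorm-ReLU stem, `d` strided down-steps doubling
#' the channel width, `r` residual blocks at the bottleneck, `d`
#' interpolation+conv up-steps with additive encoder skips, an output stem
#' back to one channel, and finally addition of the raw input cycle (the
#' outer residual).
#'
#' @param params Parameter list.
#' @param config A [model_config()].
#' @param X `(N, l0)` matrix of cycles (any `N`; weights are shared).
#' @param want_cache Keep intermediates for the backward pass.
#' @return `list(out, cache)` with `out` an `(N, l)` feature matrix.
#' @export
resu_fwd <- function(params, config, X, want_cache = FALSE) {
  cf <- config; k <- cf$kernel_size
  N <- nrow(X)
  X3 <- array(X, c(N, cf$l0, 1L))
  ca <- list()
  st <- cir_fwd(X3, params[["resu.in.W"]], params[["resu.in.b"]], 1L, k)
  ca$stem <- st$cache
  h <- st$out
  skips <- list(h)
  for (i in seq_len(cf$d)) {
    dn <- cir_fwd(h, params[[sprintf("resu.down%d.W", i)]],
                  params[[sprintf("resu.down%d.b", i)]], 2L, k)
    ca[[sprintf("down%d", i)]] <- dn$cache
    h <- dn$out
    if (i < cf$d) skips[[i + 1L]] <- h
  }
  for (j in seq_len(cf$r)) {
    c1 <- cir_fwd(h, params[[sprintf("resu.res%d.W1", j)]],
                  params[[sprintf("resu.res%d.b1", j)]], 1L, k)
    cv2 <- conv1d_fwd(c1$out, params[[sprintf("resu.res%d.W2", j)]],
                      params[[sprintf("resu.res%d.b2", j)]],
                      stride = 1L, pad = (k - 1L) %/% 2L, k = k)
    io2 <- inorm_fwd(cv2$out)
    rl <- relu_fwd(io2$out + h)
    ca[[sprintf("res%d", j)]] <- list(c1 = c1$cache, cv2 = cv2$cache,
                                      io2 = io2$cache, mask = rl$cache)
    h <- rl$out
  }
  for (i in rev(seq_len(cf$d))) {
    up <- upsample2_fwd(h)
    uc <- cir_fwd(up$out, params[[sprintf("resu.up%d.W", i)]],
                  params[[sprintf("resu.up%d.b", i)]], 1L, k)
    ca[[sprintf("up%d", i)]] <- list(L = up$cache, cir = uc$cache)
    h <- uc$out + skips[[i]]
  }
  ot <- cir_fwd(h, params[["resu.out.W"]], params[["resu.out.b"]], 1L, k)
  ca$out <- ot$cache
  Y <- matrix(ot$out, N, cf$l) + X
  list(out = Y, cache = if (want_cache) ca else NULL)
}

resu_bwd <- function(params, config, dY, cache) {
  cf <- config
  N <- nrow(dY)
  g <- list()
  d3 <- array(dY, c(N, cf$l, 1L))
  bo <- cir_bwd(d3, params[["resu.out.W"]], cache$out)
  g[["resu.out.W"]] <- bo$dW; g[["resu.out.b"]] <- bo$db
  dh <- bo$dX
  dskips <- vector("list", cf$d)
  for (i in seq_len(cf$d)) {
    uc <- cache[[sprintf("up%d", i)]]
    dskips[[i]] <- dh                       # additive skip at level i
    bu <- cir_bwd(dh, params[[sprintf("resu.up%d.W", i)]], uc$cir)
    g[[sprintf("resu.up%d.W", i)]] <- bu$dW
    g[[sprintf("resu.up%d.b", i)]] <- bu$db
    dh <- upsample2_bwd(bu$dX, uc$L)
  }
  for (j in rev(seq_len(cf$r))) {
    rc <- cache[[sprintf("res%d", j)]]
    dsum <- relu_bwd(dh, rc$mask)
    d2 <- inorm_bwd(dsum, rc$io2)
    b2 <- conv1d_bwd(d2, params[[sprintf("resu.res%d.W2", j)]], rc$cv2)
    g[[sprintf("resu.res%d.W2", j)]] <- b2$dW
    g[[sprintf("resu.res%d.b2", j)]] <- b2$db
    b1 <- cir_bwd(b2$dX, params[[sprintf("resu.res%d.W1", j)]], rc$c1)
    g[[sprintf("resu.res%d.W1", j)]] <- b1$dW
    g[[sprintf("resu.res%d.b1", j)]] <- b1$db
    dh <- b1$dX + dsum                      # identity path
  }
  for (i in rev(seq_len(cf$d))) {
    bd <- cir_bwd(dh, params[[sprintf("resu.down%d.W", i)]],
                  cache[[sprintf("down%d", i)]])
    g[[sprintf("resu.down%d.W", i)]] <- bd$dW
    g[[sprintf("resu.down%d.b", i)]] <- bd$db
    # the input of down_i is skips[[i]] (stem output when i = 1), so the
    # additive decoder skip at level i joins the gradient here
    dh <- bd$dX + dskips[[i]]
  }
  bs <- cir_bwd(dh, params[["resu.in.W"]], cache$stem)
  g[["resu.in.W"]] <- bs$dW; g[["resu.in.b"]] <- bs$db
  g
}

# ---- stage 2: Transformer layer with relative positional bias ---------

# X: (B*n, l) token matrix, sample b occupying rows b + B*(0:(n-1)).
trans_layer_fwd <- function(params, cf, t, X, B, bias, training) {
  pre <- sprintf("tr%d.", t)
  n <- cf$n; l <- cf$l; H <- cf$heads; dk <- l %/% H
  ln1 <- layernorm_fwd(X, params[[paste0(pre, "ln1.g")]],
                       params[[paste0(pre, "ln1.b")]])
  Q <- linear_fwd(ln1$out, params[[paste0(pre, "Wq")]], params[[paste0(pre, "bq")]])
  K <- linear_fwd(ln1$out, params[[paste0(pre, "Wk")]], params[[paste0(pre, "bk")]])
  V <- linear_fwd(ln1$out, params[[paste0(pre, "Wv")]], params[[paste0(pre, "bv")]])
  O <- matrix(0, B * n, l)
  A_all <- array(0, c(B, H, n, n))
  for (b in seq_len(B)) {
    rb <- b + B * (0:(n - 1L))
    for (h in seq_len(H)) {
      ch <- ((h - 1L) * dk + 1L):(h * dk)
      S <- tcrossprod(Q$out[rb, ch, drop = FALSE],
                      K$out[rb, ch, drop = FALSE]) / sqrt(dk)
      if (!is.null(bias)) S <- S + bias[h, , ]
      if (any(!is.finite(S))) stop("non-finite attention scores", call. = FALSE)
      A <- softmax_rows(S)
      A_all[b, h, , ] <- A
      O[rb, ch] <- A %*% V$out[rb, ch, drop = FALSE]
    }
  }
  Wo <- linear_fwd(O, params[[paste0(pre, "Wo")]], params[[paste0(pre, "bo")]])
  dr1 <- dropout_fwd(Wo$out, cf$dropout, training)
  Xa <- X + dr1$out
  ln2 <- layernorm_fwd(Xa, params[[paste0(pre, "ln2.g")]],
                       params[[paste0(pre, "ln2.b")]])
  m1 <- linear_fwd(ln2$out, params[[paste0(pre, "mlp.W1")]],
                   params[[paste0(pre, "mlp.b1")]])
  ge <- gelu_fwd(m1$out)
  m2 <- linear_fwd(ge$out, params[[paste0(pre, "mlp.W2")]],
                   params[[paste0(pre, "mlp.b2")]])
  dr2 <- dropout_fwd(m2$out, cf$dropout, training)
  out <- Xa + dr2$out
  list(out = out,
       cache = list(ln1 = ln1$cache, ln1_out = ln1$out, Q = Q, K = K, V = V,
                    A = A_all, O = O, Wo_cache = Wo$cache, dr1 = dr1$cache,
                    Xa = Xa, ln2 = ln2$cache, ln2_out = ln2$out,
                    m1 = m1$cache, ge = ge$cache, m2 = m2$cache,
                    dr2 = dr2$cache))
}

trans_layer_bwd <- function(params, cf, t, dOut, B, cache) {
  pre <- sprintf("tr%d.", t)
  n <- cf$n; l <- cf$l; H <- cf$heads; dk <- l %/% H
  g <- list()
  dXa <- dOut
  dm2 <- dropout_bwd(dOut, cache$dr2)
  b2 <- linear_bwd(dm2, params[[paste0(pre, "mlp.W2")]], cache$m2)
  g[[paste0(pre, "mlp.W2")]] <- b2$dW; g[[paste0(pre, "mlp.b2")]] <- b2$db
  dge <- gelu_bwd(b2$dX, cache$ge)
  b1 <- linear_bwd(dge, params[[paste0(pre, "mlp.W1")]], cache$m1)
  g[[paste0(pre, "mlp.W1")]] <- b1$dW; g[[paste0(pre, "mlp.b1")]] <- b1$db
  l2 <- layernorm_bwd(b1$dX, params[[paste0(pre, "ln2.g")]], cache$ln2)
  g[[paste0(pre, "ln2.g")]] <- l2$dg; g[[paste0(pre, "ln2.b")]] <- l2$db
  dXa <- dXa + l2$dX
  dX <- dXa
  ddr1 <- dropout_bwd(dXa, cache$dr1)
  bo <- linear_bwd(ddr1, params[[paste0(pre, "Wo")]], cache$Wo_cache)
  g[[paste0(pre, "Wo")]] <- bo$dW; g[[paste0(pre, "bo")]] <- bo$db
  dO <- bo$dX
  dQ <- matrix(0, B * n, l); dK <- matrix(0, B * n, l); dV <- matrix(0, B * n, l)
  dbias <- if (cf$pe_mode == "rpe") array(0, c(H, n, n)) else NULL
  for (b in seq_len(B)) {
    rb <- b + B * (0:(n - 1L))
    for (h in seq_len(H)) {
      ch <- ((h - 1L) * dk + 1L):(h * dk)
      A <- cache$A[b, h, , ]
      dA <- tcrossprod(dO[rb, ch, drop = FALSE],
                       cache$V$out[rb, ch, drop = FALSE])
      dV[rb, ch] <- crossprod(A, dO[rb, ch, drop = FALSE])
      dS <- softmax_rows_bwd(dA, A)
      if (!is.null(dbias)) dbias[h, , ] <- dbias[h, , ] + dS
      dQ[rb, ch] <- dS %*% cache$K$out[rb, ch, drop = FALSE] / sqrt(dk)
      dK[rb, ch] <- crossprod(dS, cache$Q$out[rb, ch, drop = FALSE]) / sqrt(dk)
    }
  }
  bq <- linear_bwd(dQ, params[[paste0(pre, "Wq")]], cache$Q$cache)
  bk <- linear_bwd(dK, params[[paste0(pre, "Wk")]], cache$K$cache)
  bv <- linear_bwd(dV, params[[paste0(pre, "Wv")]], cache$V$cache)
  g[[paste0(pre, "Wq")]] <- bq$dW; g[[paste0(pre, "bq")]] <- bq$db
  g[[paste0(pre, "Wk")]] <- bk$dW; g[[paste0(pre, "bk")]] <- bk$db
  g[[paste0(pre, "Wv")]] <- bv$dW; g[[paste0(pre, "bv")]] <- bv$db
  dln1 <- bq$dX + bk$dX + bv$dX
  l1 <- layernorm_bwd(dln1, params[[paste0(pre, "ln1.g")]], cache$ln1)
  g[[paste0(pre, "ln1.g")]] <- l1$dg; g[[paste0(pre, "ln1.b")]] <- l1$db
  dX <- dX + l1$dX
  list(dX = dX, grads = g, dbias = dbias)
}

# ---- full model --------------------------------------------------------

#' Full forward pass
#'
#' Maps a batch of contextual cycles to predicted (standardized) SBP
#' sequences: stage-1 ResU features per cycle, optional absolute
#' positional encodings, `L` Transformer layers (with relative positional
#' bias in `"rpe"` mode), and the per-token projection head.
#'
#' @param params Parameter list.
#' @param config A [model_config()].
#' @param cycles `(B, n, l0)` array (pad 125-sample slices with
#'   [pad_cycles()] first).
#' @param training Enable dropout and keep caches for the backward pass.
#' @param Pmat Optional precomputed [rpe_matrix()].
#' @return `list(pred, cache)` with `pred` a `(B, n)` matrix.
#' @export
model_fwd <- function(params, config, cycles, training = FALSE,
                      Pmat = NULL) {
  cf <- config
  dmc <- dim(cycles)
  if (length(dmc) != 3 || dmc[2] != cf$n || dmc[3] != cf$l0)
    stop(sprintf("input must be (B, %d, %d)", cf$n, cf$l0), call. = FALSE)
  B <- dmc[1]
  X <- cycles
  dim(X) <- c(B * cf$n, cf$l0)
  rs <- resu_fwd(params, cf, X, want_cache = training)
  Tok <- rs$out
  if (cf$pe_mode == "ape") {
    APE <- ape_matrix(cf$n, cf$l)
    Tok <- Tok + APE[rep(seq_len(cf$n), each = B), , drop = FALSE]
  }
  if (cf$pe_mode == "rpe" && is.null(Pmat)) Pmat <- rpe_matrix(cf$n, cf$l)
  layers <- vector("list", cf$L)
  biases <- vector("list", cf$L)
  H <- Tok
  for (t in seq_len(cf$L)) {
    bias <- if (cf$pe_mode == "rpe")
      rpe_bias(params[[sprintf("tr%d.wp", t)]], cf$n, Pmat) else NULL
    biases[[t]] <- bias
    lt <- trans_layer_fwd(params, cf, t, H, B, bias, training)
    layers[[t]] <- if (training) lt$cache else NULL
    H <- lt$out
  }
  p1 <- linear_fwd(H, params[["proj.W1"]], params[["proj.b1"]])
  pr <- relu_fwd(p1$out)
  p2 <- linear_fwd(pr$out, params[["proj.W2"]], params[["proj.b2"]])
  pred <- matrix(p2$out, B, cf$n)
  cache <- if (training)
    list(resu = rs$cache, layers = layers, B = B, Pmat = Pmat,
         p1 = p1$cache, pmask = pr$cache, p2 = p2$cache) else NULL
  list(pred = pred, cache = cache)
}

# Gradient of all parameters given d(loss)/d(pred).
model_bwd <- function(params, config, dPred, cache) {
  cf <- config; B <- cache$B
  g <- list()
  dp <- matrix(dPred, B * cf$n, 1L)
  b2 <- linear_bwd(dp, params[["proj.W2"]], cache$p2)
  g[["proj.W2"]] <- b2$dW; g[["proj.b2"]] <- b2$db
  dh <- relu_bwd(b2$dX, cache$pmask)
  b1 <- linear_bwd(dh, params[["proj.W1"]], cache$p1)
  g[["proj.W1"]] <- b1$dW; g[["proj.b1"]] <- b1$db
  dH <- b1$dX
  for (t in rev(seq_len(cf$L))) {
    bt <- trans_layer_bwd(params, cf, t, dH, B, cache$layers[[t]])
    g <- c(g, bt$grads)
    if (!is.null(bt$dbias)) {
      H <- cf$heads
      dwp <- matrix(0, H, cf$l)
      for (h in seq_len(H))
        dwp[h, ] <- crossprod(cache$Pmat, as.vector(bt$dbias[h, , ]))
      g[[sprintf("tr%d.wp", t)]] <- dwp
    }
    dH <- bt$dX
  }
  gr <- resu_bwd(params, cf, dH, cache$resu)
  c(g, gr)
}

#' Right zero-pad cycle slices to the model input length
#'
#' @param cycles `(m, n, len)` array of slices (len typically 125).
#' @param l0 Target length (default 128).
#' @return `(m, n, l0)` array.
#' @export
pad_cycles <- function(cycles, l0 = 128L) {
  dm <- dim(cycles)
  if (dm[3] > l0) stop("slices longer than l0", call. = FALSE)
  if (dm[3] == l0) return(cycles)
  out <- array(0, c(dm[1], dm[2], l0))
  out[, , seq_len(dm[3])] <- cycles
  out
}
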