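#' Mean-absolute-error sequence loss
#'
#' Mean absolute deviation over all entries of a batch of predicted vs
#' ground-truth SBP sequences — both the training loss and the sequence
#' MAE metric.
#'
#' @param pred,gt Equal-shaped numeric matrices `(B, n)` (or vectors).
#' @return Scalar, in the units of the inputs (mmHg).
#' @export
loss_l1 <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt))
    stop("`pred` and `gt` must have identical shape", call. = FALSE)
  mean(abs(pred - gt))
}

#' Optimization settings
#'
#' @param lr Adam learning rate (full-scale default 1e-4; reduced desk-
#'   scale runs in this package use 1e-3).
#' @param batch_size Mini-batch size (default 16).
#' @param epochs Number of epochs (default 500).
#' @param seed Seed controlling initialization, shuffling and dropout; the
#'   whole fit is bit-reproducible given the seed.
#' @param early_stop_patience Stop after this many epochs without a new
#'   best validation MAE (`Inf` = never).
#' @param grad_clip Global-norm gradient clip (`Inf` = off).
#' @param standardize Z-score SBP labels with train-split statistics
#'   (inverted at prediction time).
#' @param verbose Print per-epoch progress.
#' @return A list of class `train_control`.
#' @export
train_control <- function(lr = 1e-4, batch_size = 16L, epochs = 500L,
                          seed = 1L, early_stop_patience = Inf,
                          grad_clip = Inf, standardize = TRUE,
                          verbose = FALSE) {
  if (lr <= 0) stop("`lr` must be positive", call. = FALSE)
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 early_stop_patience = early_stop_patience,
                 grad_clip = grad_clip, standardize = standardize,
                 verbose = verbose),
            class = "train_control")
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) array(0, dim(x) %||% length(x))),
       v = lapply(params, function(x) array(0, dim(x) %||% length(x))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

grad_global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
}

# extract (cycles, sbp) from a dataset_split part or a plain list
.as_xy <- function(data, what = "data") {
  if (is.null(data)) return(NULL)
  if (inherits(data, "dataset_split")) data <- data$train
  if (is.null(data$cycles) || is.null(data$sbp))
    stop(sprintf("`%s` must contain `cycles` and `sbp`", what), call. = FALSE)
  if (nrow(data$sbp) == 0) return(NULL)
  list(cycles = data$cycles, sbp = data$sbp)
}

#' Fit the contextual-cycle SBP trend model
#'
#' Trains the two-stage network (per-cycle residual U encoders followed by
#' Transformer layers with relative positional attention bias) to map
#' contextual PPG cycles to beat-to-beat SBP sequences, by mini-batch Adam
#' on the mean-absolute-error loss. Batches are reshuffled every epoch
#' (seeded); the incomplete final batch is kept. When a validation set is
#' supplied, the parameters with the lowest validation MAE are retained
#' alongside the final ones and used for prediction.
#'
#' @param data A `dataset_split` from [build_dataset()], or a list with
#'   `cycles` (`m x n x 125` or `m x n x 128` array) and `sbp` (`m x n`).
#' @param val Optional validation data in the same form (ignored when
#'   `data` is a `dataset_split`, whose own `val` part is used).
#' @param config A [model_config()]; its `n` must match the data.
#' @param control A [train_control()].
#' @return An object of class `resutrans` with components `params`,
#'   `best_params`, `config`, `control`, `history` (per-epoch train/val
#'   MAE in mmHg), `y_center`/`y_scale` (label standardization),
#'   `n_steps`, and the training data (for [residuals.resutrans()]).
#' @seealso [predict.resutrans()], [evaluation_report()]
#' @export
resutrans <- function(data, val = NULL, config = model_config(),
                      control = train_control()) {
  tr <- .as_xy(data, "data")
  if (is.null(tr)) stop("empty training split", call. = FALSE)
  if (inherits(data, "dataset_split")) val <- data$val
  va <- .as_xy(val, "val")
  cf <- config
  if (dim(tr$cycles)[2] != cf$n)
    stop(sprintf("data has n = %d cycles per sample but config n = %d",
                 dim(tr$cycles)[2], cf$n), call. = FALSE)

  X <- pad_cycles(tr$cycles, cf$l0)
  Y <- tr$sbp
  m <- nrow(Y)
  if (control$standardize) {
    y_center <- mean(Y); y_scale <- stats::sd(Y)
    if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  } else {
    y_center <- 0; y_scale <- 1
  }
  Yz <- (Y - y_center) / y_scale
  Xva <- if (!is.null(va)) pad_cycles(va$cycles, cf$l0) else NULL

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(control$seed)
  params <- init_params(cf, seed = control$seed)
  state <- adam_init(params)
  Pmat <- if (cf$pe_mode == "rpe") rpe_matrix(cf$n, cf$l) else NULL

  B <- control$batch_size
  hist_train <- numeric(control$epochs)
  hist_val <- rep(NA_real_, control$epochs)
  hist_sec <- numeric(control$epochs)
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  n_steps <- 0L
  since_best <- 0L

  for (epoch in seq_len(control$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- sample.int(m)
    starts <- seq(1L, m, by = B)
    epoch_abs <- 0
    for (s in starts) {
      idx <- ord[s:min(s + B - 1L, m)]
      xb <- X[idx, , , drop = FALSE]
      yb <- Yz[idx, , drop = FALSE]
      fw <- model_fwd(params, cf, xb, training = TRUE, Pmat = Pmat)
      err <- fw$pred - yb
      if (any(!is.finite(err)))
        stop("training diverged: non-finite loss", call. = FALSE)
      epoch_abs <- epoch_abs + sum(abs(err))
      dPred <- sign(err) / length(err)
      grads <- model_bwd(params, cf, dPred, fw$cache)
      if (is.finite(control$grad_clip)) {
        gn <- grad_global_norm(grads)
        if (gn > control$grad_clip)
          grads <- lapply(grads, function(g) g * control$grad_clip / gn)
      }
      up <- adam_step(params, grads, state, control$lr)
      params <- up$params; state <- up$state
      n_steps <- n_steps + 1L
    }
    hist_train[epoch] <- epoch_abs / length(Yz) * y_scale
    if (!is.null(va)) {
      pv <- .predict_params(params, cf, Xva, Pmat) * y_scale + y_center
      hist_val[epoch] <- loss_l1(pv, va$sbp)
      if (hist_val[epoch] < best_val) {
        best_val <- hist_val[epoch]
        best_params <- params
        best_epoch <- epoch
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
    }
    hist_sec[epoch] <- proc.time()[["elapsed"]] - t0
    if (control$verbose)
      message(sprintf("epoch %3d  train MAE %7.3f  val MAE %s mmHg",
                      epoch, hist_train[epoch],
                      ifelse(is.na(hist_val[epoch]), "   -",
                             sprintf("%7.3f", hist_val[epoch]))))
    if (!is.null(va) && since_best >= control$early_stop_patience) break
  }
  done <- if (exists("epoch")) epoch else 0L
  if (is.null(va)) { best_params <- params; best_epoch <- done }

  structure(list(
    params = params, best_params = best_params, best_epoch = best_epoch,
    config = cf, control = control,
    y_center = y_center, y_scale = y_scale,
    history = data.frame(epoch = seq_len(done),
                         train_mae = hist_train[seq_len(done)],
                         val_mae = hist_val[seq_len(done)],
                         seconds = hist_sec[seq_len(done)]),
    n_steps = n_steps,
    train_data = tr,
    call = match.call()
  ), class = "resutrans")
}

# forward in evaluation mode over mini-batches (bounded memory)
.predict_params <- function(params, cf, X, Pmat = NULL, chunk = 32L) {
  m <- dim(X)[1]
  out <- matrix(0, m, cf$n)
  for (s in seq(1L, m, by = chunk)) {
    idx <- s:min(s + chunk - 1L, m)
    out[idx, ] <- model_fwd(params, cf, X[idx, , , drop = FALSE],
                            training = FALSE, Pmat = Pmat)$pred
  }
  out
}

#' Save / load a fitted model
#'
#' Serializes the full fitted object (parameters, configuration, label
#' scaling, history) to a single file; the round trip reproduces
#' predictions bit-identically.
#'
#' @param object A `resutrans` fit.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the fit.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "resutrans"))
  obj <- object
  obj$train_data <- NULL                     # keep checkpoints lean
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "resutrans"))
  obj
}
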