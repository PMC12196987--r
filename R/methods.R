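#' @export
print.resutrans <- function(x, ...) {
  cf <- x$config
  cat("Beat-to-beat SBP trend model (ResU + Transformer-RPE)\n")
  cat(sprintf("  contextual cycles: n = %d, cycle length %d (input %d)\n",
              cf$n, 125L, cf$l0))
  cat(sprintf("  stage 1: ResU depth %d, %d residual blocks, %d channels\n",
              cf$d, cf$r, cf$base_channels))
  cat(sprintf("  stage 2: %d Transformer layer(s), %d heads, pe_mode = %s\n",
              cf$L, cf$heads, cf$pe_mode))
  cat(sprintf("  parameters: %s  (trained %d steps)\n",
              format(n_params(x$params), big.mark = ","), x$n_steps))
  h <- x$history
  if (nrow(h) > 0) {
    last <- h[nrow(h), ]
    cat(sprintf("  final train MAE: %.3f mmHg", last$train_mae))
    if (!is.na(last$val_mae))
      cat(sprintf("; best val MAE: %.3f mmHg (epoch %d)",
                  min(h$val_mae, na.rm = TRUE), x$best_epoch))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.resutrans <- function(object, ...) {
  out <- list(config = object$config,
              n_parameters = n_params(object$params),
              n_train = nrow(object$train_data$sbp %||% matrix(0, 0, 0)),
              history = object$history,
              best_epoch = object$best_epoch,
              y_center = object$y_center, y_scale = object$y_scale)
  class(out) <- "summary.resutrans"
  out
}

#' @export
print.summary.resutrans <- function(x, ...) {
  cat(sprintf("resutrans fit: %s parameters, %d training sequences\n",
              format(x$n_parameters, big.mark = ","), x$n_train))
  cat(sprintf("labels standardized: center %.2f, scale %.2f mmHg\n",
              x$y_center, x$y_scale))
  h <- x$history
  if (nrow(h) > 0) {
    cat(sprintf("epochs: %d (best validation at %d)\n", nrow(h), x$best_epoch))
    print(utils::tail(h, 5), row.names = FALSE)
  }
  invisible(x)
}

#' Predict SBP sequences from contextual cycles
#'
#' @param object A fitted `resutrans` model.
#' @param newdata A `dataset_split` part (or any list with a `cycles`
#'   array `m x n x 125`/`m x n x 128`), or the array itself. Defaults to
#'   the training data.
#' @param use_best Use the best-validation parameters (default) rather
#'   than the final ones.
#' @param ... Unused.
#' @return An `m x n` matrix of predicted SBP values, mmHg.
#' @export
predict.resutrans <- function(object, newdata = NULL, use_best = TRUE, ...) {
  cf <- object$config
  cycles <- if (is.null(newdata)) object$train_data$cycles
            else if (is.array(newdata)) newdata
            else newdata$cycles
  if (is.null(cycles)) stop("`newdata` contains no cycles", call. = FALSE)
  if (length(dim(cycles)) != 3 || dim(cycles)[2] != cf$n)
    stop(sprintf("model expects n = %d cycles per sample, got %d",
                 cf$n, dim(cycles)[2]), call. = FALSE)
  X <- pad_cycles(cycles, cf$l0)
  params <- if (use_best) object$best_params else object$params
  Pmat <- if (cf$pe_mode == "rpe") rpe_matrix(cf$n, cf$l) else NULL
  .predict_params(params, cf, X, Pmat) * object$y_scale + object$y_center
}

#' @export
residuals.resutrans <- function(object, ...) {
  if (is.null(object$train_data))
    stop("training data not stored with this object", call. = FALSE)
  predict(object) - object$train_data$sbp
}

#' @export
coef.resutrans <- function(object, use_best = TRUE, ...) {
  p <- if (use_best) object$best_params else object$params
  unlist(p)
}

#' Plot training history
#'
#' Train (and, when available, validation) MAE per epoch, mmHg.
#'
#' @param x A fitted `resutrans` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.resutrans <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) stop("no training history", call. = FALSE)
  ylim <- range(c(h$train_mae, h$val_mae), na.rm = TRUE)
  graphics::plot(h$epoch, h$train_mae, type = "l", lwd = 2,
                 xlab = "epoch", ylab = "MAE (mmHg)", ylim = ylim, ...)
  if (any(!is.na(h$val_mae))) {
    graphics::lines(h$epoch, h$val_mae, lty = 2, lwd = 2, col = 2)
    graphics::legend("topright", c("train", "validation"),
                     lty = c(1, 2), col = c(1, 2), lwd = 2, bty = "n")
  }
  invisible(x)
}
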