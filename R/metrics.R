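# Evaluation suite for sequence-valued SBP predictions. Sequence pairs are
# passed as equal-shaped (m, n) matrices: row i holds the i-th ground-truth
# or predicted SBP sequence. Error sign convention throughout: pred - gt.

.check_pairs <- function(gt, pred, min_len = 1L) {
  gt <- as.matrix(gt); pred <- as.matrix(pred)
  if (!all(dim(gt) == dim(pred)))
    stop("`gt` and `pred` must have identical dimensions", call. = FALSE)
  if (ncol(gt) < min_len)
    stop(sprintf("sequences need length >= %d", min_len), call. = FALSE)
  list(gt = gt, pred = pred)
}

#' Sequence mean absolute error
#'
#' Mean of `|gt - pred|` over all `m x n` beats.
#'
#' @param gt,pred `(m, n)` matrices of SBP sequences, mmHg.
#' @return Scalar MAE, mmHg.
#' @export
mae_seq <- function(gt, pred) {
  p <- .check_pairs(gt, pred)
  mean(abs(p$gt - p$pred))
}

#' Mean per-sequence Pearson correlation
#'
#' The Pearson correlation between each ground-truth sequence and its
#' prediction, averaged over sequences. Sequences in which either side has
#' zero variance have an undefined correlation and are excluded with a
#' warning.
#'
#' @inheritParams mae_seq
#' @return Scalar in `[-1, 1]`.
#' @export
rseq <- function(gt, pred) {
  p <- .check_pairs(gt, pred, min_len = 2L)
  rs <- vapply(seq_len(nrow(p$gt)), function(i) {
    x <- p$gt[i, ]; y <- p$pred[i, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  if (anyNA(rs)) {
    warning(sprintf("%d zero-variance sequence(s) excluded from Rseq",
                    sum(is.na(rs))))
    rs <- rs[!is.na(rs)]
  }
  if (length(rs) == 0) return(NA_real_)
  mean(rs)
}

#' First-order difference sequence
#'
#' Consecutive beat-to-beat changes of one SBP sequence; the building
#' block of average real variability.
#'
#' @param seq Numeric vector.
#' @return Vector of length `length(seq) - 1`.
#' @export
diff_seq <- function(seq) diff(seq)

#' Variability error
#'
#' Mean absolute difference between the ground-truth and predicted
#' beat-to-beat change sequences, normalized by `n - 1` per sequence and
#' averaged over sequences. Level-shift invariant: adding a constant to a
#' prediction leaves VE unchanged.
#'
#' @inheritParams mae_seq
#' @return Scalar VE, mmHg.
#' @export
ve <- function(gt, pred) {
  p <- .check_pairs(gt, pred, min_len = 2L)
  dg <- p$gt[, -1, drop = FALSE] - p$gt[, -ncol(p$gt), drop = FALSE]
  dp <- p$pred[, -1, drop = FALSE] - p$pred[, -ncol(p$pred), drop = FALSE]
  mean(rowMeans(abs(dg - dp)))
}

#' Steady vs unsteady classification of one SBP sequence
#'
#' A sequence is `"unsteady"` when its overall change — maximum minus
#' minimum — strictly exceeds the threshold, else `"steady"`.
#'
#' @param seq Numeric SBP sequence, mmHg.
#' @param thresh Threshold, mmHg (default 10; a span of exactly 10 is
#'   steady).
#' @return `"steady"` or `"unsteady"`.
#' @export
classify_state <- function(seq, thresh = 10) {
  if (max(seq) - min(seq) > thresh) "unsteady" else "steady"
}

#' Classification metrics for fluctuation detection
#'
#' Accuracy, precision, recall and F1 with `"unsteady"` (the clinically
#' alarming state) as the positive class, plus the confusion counts.
#'
#' @param gt_labels,pred_labels Character vectors of `"steady"` /
#'   `"unsteady"`.
#' @return List with `tp`, `fp`, `tn`, `fn`, `acc`, `precision`, `recall`,
#'   `f1`.
#' @export
classification_report <- function(gt_labels, pred_labels) {
  if (length(gt_labels) != length(pred_labels))
    stop("label vectors must have equal length", call. = FALSE)
  pos <- "unsteady"
  tp <- sum(gt_labels == pos & pred_labels == pos)
  fp <- sum(gt_labels != pos & pred_labels == pos)
  tn <- sum(gt_labels != pos & pred_labels != pos)
  fn <- sum(gt_labels == pos & pred_labels != pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       acc = (tp + tn) / length(gt_labels),
       precision = precision, recall = recall, f1 = f1)
}

#' Non-overlapping beat-averaged sequences
#'
#' Collapses each sequence to means over consecutive windows of `window`
#' beats (a length-60 sequence becomes 6 averages); any trailing remainder
#' is dropped. Downstream metrics apply unchanged to the result.
#'
#' @inheritParams mae_seq
#' @param window Beats per average (default 10).
#' @return List with matrices `gt` and `pred` of `floor(n/window)` columns.
#' @export
beat_averaged <- function(gt, pred, window = 10L) {
  p <- .check_pairs(gt, pred)
  n <- ncol(p$gt)
  k <- n %/% window
  if (k < 1) stop("sequences shorter than one window", call. = FALSE)
  avg <- function(M) {
    out <- matrix(0, nrow(M), k)
    for (w in seq_len(k))
      out[, w] <- rowMeans(M[, ((w - 1) * window + 1):(w * window),
                             drop = FALSE])
    out
  }
  list(gt = avg(p$gt), pred = avg(p$pred))
}

#' Mean error and standard deviation of errors
#'
#' Errors are `pred - gt` over all beats; SD uses the population
#' denominator (divide by N) for determinism of the reported value.
#'
#' @inheritParams mae_seq
#' @return List with `me` and `sd`, mmHg.
#' @export
me_sd <- function(gt, pred) {
  p <- .check_pairs(gt, pred)
  e <- as.vector(p$pred - p$gt)
  list(me = mean(e), sd = sqrt(mean((e - mean(e))^2)))
}

#' AAMI validation verdict
#'
#' Pass requires `|ME| <= 5` mmHg, `SD <= 8` mmHg, and at least 85
#' subjects.
#'
#' @param me,sd Mean error and SD of errors, mmHg.
#' @param n_subjects Number of subjects evaluated.
#' @return Logical pass/fail.
#' @export
aami_check <- function(me, sd, n_subjects) {
  abs(me) <= 5 && sd <= 8 && n_subjects >= 85
}

#' BHS cumulative-error grading
#'
#' Percentages of absolute errors within 5, 10 and 15 mmHg and the
#' resulting grade: A requires at least 60/85/95 %, B 50/75/90 %,
#' C 40/65/85 % (all three thresholds, boundaries inclusive); anything
#' less is ungraded ("D").
#'
#' @param abs_errors Vector of absolute errors, mmHg.
#' @return List with `pct5`, `pct10`, `pct15` (percent) and `grade`.
#' @export
bhs_grade <- function(abs_errors) {
  pct <- function(th) 100 * mean(abs_errors <= th)
  p5 <- pct(5); p10 <- pct(10); p15 <- pct(15)
  grade <- if (p5 >= 60 && p10 >= 85 && p15 >= 95) "A"
           else if (p5 >= 50 && p10 >= 75 && p15 >= 90) "B"
           else if (p5 >= 40 && p10 >= 65 && p15 >= 85) "C"
           else "D"
  list(pct5 = p5, pct10 = p10, pct15 = p15, grade = grade)
}

#' Bland-Altman agreement statistics
#'
#' Differences `pred - gt` per beat; limits of agreement are the mean
#' difference plus/minus 1.96 population SDs; also reports the percentage
#' of points inside the limits.
#'
#' @inheritParams mae_seq
#' @return List with `mean_diff`, `loa_low`, `loa_high`, `pct_within`.
#' @export
bland_altman <- function(gt, pred) {
  p <- .check_pairs(gt, pred)
  d <- as.vector(p$pred - p$gt)
  mu <- mean(d)
  s <- sqrt(mean((d - mu)^2))
  lo <- mu - 1.96 * s
  hi <- mu + 1.96 * s
  list(mean_diff = mu, loa_low = lo, loa_high = hi,
       pct_within = 100 * mean(d >= lo & d <= hi))
}

#' Full evaluation report
#'
#' Computes the complete evaluation suite for a set of ground-truth /
#' predicted SBP sequence pairs: sequence metrics (MAE, mean per-sequence
#' Pearson correlation, variability error), value metrics (ME, population
#' SD, Bland-Altman), 10-beat-averaged value metrics, steady/unsteady
#' fluctuation detection with accuracy/precision/recall/F1, and the
#' AAMI and BHS standard verdicts.
#'
#' @inheritParams mae_seq
#' @param subject Optional subject id per sequence (row); enables the
#'   AAMI subject count.
#' @param thresh Steady/unsteady threshold, mmHg.
#' @param window Beat-averaging window.
#' @return A list of class `sbp_eval_report`.
#' @export
evaluation_report <- function(gt, pred, subject = NULL, thresh = 10,
                              window = 10L) {
  p <- .check_pairs(gt, pred)
  gtl <- apply(p$gt, 1, classify_state, thresh = thresh)
  prl <- apply(p$pred, 1, classify_state, thresh = thresh)
  cls <- classification_report(gtl, prl)
  msd <- me_sd(p$gt, p$pred)
  ba_pairs <- beat_averaged(p$gt, p$pred, window = window)
  msd_avg <- me_sd(ba_pairs$gt, ba_pairs$pred)
  n_subj <- if (is.null(subject)) NA_integer_ else length(unique(subject))
  rep <- list(
    n_sequences = nrow(p$gt), seq_len = ncol(p$gt),
    n_subjects = n_subj,
    mae = mae_seq(p$gt, p$pred),
    rseq = suppressWarnings(rseq(p$gt, p$pred)),
    ve = ve(p$gt, p$pred),
    me = msd$me, sd = msd$sd,
    beat_avg = list(mae = mae_seq(ba_pairs$gt, ba_pairs$pred),
                    me = msd_avg$me, sd = msd_avg$sd),
    class_table = cls[c("tp", "fp", "tn", "fn")],
    acc = cls$acc, precision = cls$precision, recall = cls$recall,
    f1 = cls$f1,
    n_steady = sum(gtl == "steady"), n_unsteady = sum(gtl == "unsteady"),
    bhs = bhs_grade(abs(as.vector(p$pred - p$gt))),
    aami = list(pass = if (is.na(n_subj)) NA else
                  aami_check(msd$me, msd$sd, n_subj),
                me = msd$me, sd = msd$sd, n_subjects = n_subj),
    bland_altman = bland_altman(p$gt, p$pred)
  )
  class(rep) <- "sbp_eval_report"
  rep
}

#' @export
print.sbp_eval_report <- function(x, ...) {
  cat(sprintf("SBP trend evaluation on %d sequences x %d beats\n",
              x$n_sequences, x$seq_len))
  cat(sprintf("  MAE %.3f mmHg | Rseq %.3f | VE %.3f mmHg\n",
              x$mae, x$rseq, x$ve))
  cat(sprintf("  ME %+.3f mmHg | SD %.3f mmHg | 10-beat-avg MAE %.3f mmHg\n",
              x$me, x$sd, x$beat_avg$mae))
  cat(sprintf("  steady/unsteady: %d/%d | ACC %.1f%% | F1 %.1f%%\n",
              x$n_steady, x$n_unsteady, 100 * x$acc, 100 * x$f1))
  cat(sprintf("  BHS: %.2f%% / %.2f%% / %.2f%% within 5/10/15 mmHg -> grade %s\n",
              x$bhs$pct5, x$bhs$pct10, x$bhs$pct15, x$bhs$grade))
  if (!is.na(x$n_subjects))
    cat(sprintf("  AAMI (%d subjects): %s\n", x$n_subjects,
                ifelse(isTRUE(x$aami$pass), "PASS", "FAIL")))
  ba <- x$bland_altman
  cat(sprintf("  Bland-Altman: mean %+.3f, LoA [%.3f, %.3f], %.1f%% within\n",
              ba$mean_diff, ba$loa_low, ba$loa_high, ba$pct_within))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `sbp_eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
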