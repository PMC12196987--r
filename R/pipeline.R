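#' End-to-end pipeline: simulate, preprocess, fit, evaluate
#'
#' Runs the complete workflow on synthetic data: cohort simulation,
#' preprocessing into contextual cycles with the chronological split,
#' model fitting, and evaluation of the test split. Defaults are a
#' desk-scale study (reduced cohort, shorter records, compact model) that
#' completes on one CPU in minutes; all stages are deterministic given
#' `seed`.
#'
#' @param n_subjects Cohort size.
#' @param duration_s Record length per subject, seconds.
#' @param n Cycles per contextual sample.
#' @param config A [model_config()] (its `n` must match).
#' @param control A [train_control()].
#' @param sim Template [sim_config()] for the cohort (its seed is
#'   overridden by `seed`).
#' @param seed Master seed for simulation and training.
#' @param use_true_onsets Use simulator ground-truth onsets instead of the
#'   slope-sum detector.
#' @param min_len_s Record-screening minimum, seconds.
#' @return List with `dataset` (the split), `fit` (the `resutrans`
#'   object), `pred` (test predictions), and `report`
#'   (an [evaluation_report()] on the test split).
#' @export
run_pipeline <- function(n_subjects = 60,
                         duration_s = 240,
                         n = 15L,
                         config = model_config(n = n, base_channels = 8L,
                                               r = 2L, L = 1L),
                         control = train_control(lr = 1e-3, epochs = 30L),
                         sim = sim_config(duration_s = duration_s),
                         seed = 1L,
                         use_true_onsets = FALSE,
                         min_len_s = duration_s) {
  sim$duration_s <- duration_s
  sim$seed <- as.integer(seed)
  control$seed <- as.integer(seed)
  records <- simulate_cohort(n_subjects, sim)
  dataset <- build_dataset(records, n = n, min_len_s = min_len_s,
                           use_true_onsets = use_true_onsets)
  fit <- resutrans(dataset, config = config, control = control)
  pred <- predict(fit, dataset$test)
  report <- evaluation_report(dataset$test$sbp, pred,
                              subject = dataset$test$subject)
  list(dataset = dataset, fit = fit, pred = pred, report = report)
}

#' Mean-prediction baseline MAE
#'
#' MAE of always predicting the train-split mean SBP for every test beat:
#' the floor any informative model must beat.
#'
#' @param dataset A `dataset_split`.
#' @return Scalar MAE, mmHg.
#' @export
baseline_mean_mae <- function(dataset) {
  mu <- mean(dataset$train$sbp)
  mean(abs(dataset$test$sbp - mu))
}

#' Dataset bookkeeping from the construction rules
#'
#' Derived counts that follow from how contextual samples are built:
#' because windows never share a beat, a dataset of `m` samples of `n`
#' cycles contains exactly `m * n` distinct beats; per-beat analyses on
#' those samples (e.g. Bland-Altman points) therefore also contain
#' `m * n` points.
#'
#' @param n_samples Number of contextual samples.
#' @param n Cycles per sample.
#' @return Integer beat count.
#' @export
contextual_beat_count <- function(n_samples, n = 60L) {
  as.integer(n_samples) * as.integer(n)
}
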