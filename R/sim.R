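#' Simulation settings for paired PPG/ABP waveform records
#'
#' Builds the configuration object consumed by [generate_record()] and
#' [simulate_cohort()]. Defaults emulate an 8-minute bedside recording at
#' 125 Hz with moderate heart-rate variability, a slowly drifting systolic
#' pressure, and occasional hill-shaped SBP surges of 10-30 mmHg lasting
#' tens of seconds — the regime in which beat-to-beat trend estimation is
#' interesting.
#'
#' @param duration_s Record length in seconds (default 480, i.e. 8 min).
#' @param fs Sampling rate in Hz (default 125).
#' @param hr_mean_bpm Mean heart rate, beats/min.
#' @param hr_jitter Fractional standard deviation of cycle length.
#' @param sbp_base Baseline systolic pressure, mmHg.
#' @param dbp_base Baseline diastolic pressure, mmHg; must be below
#'   `sbp_base`.
#' @param steady_sigma Per-beat standard deviation of the bounded SBP
#'   random walk, mmHg.
#' @param surge_rate Expected surge events per minute.
#' @param surge_magnitude_range Two mmHg values; surge heights are drawn
#'   uniformly from this interval.
#' @param surge_duration_beats Surge width in beats (raised-cosine bump).
#' @param noise_sigma Additive white-noise level on the PPG (relative to a
#'   unit-amplitude pulse).
#' @param baseline_wander_amp Amplitude of the ~0.1 Hz respiratory baseline
#'   wander added to the PPG.
#' @param seed Integer seed; the same configuration (seed included) always
#'   produces a bit-identical record.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 480, fs = 125,
                       hr_mean_bpm = 75, hr_jitter = 0.03,
                       sbp_base = 120, dbp_base = 70,
                       steady_sigma = 0.6,
                       surge_rate = 0.5,
                       surge_magnitude_range = c(10, 30),
                       surge_duration_beats = 40,
                       noise_sigma = 0.02,
                       baseline_wander_amp = 0.05,
                       seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("`duration_s` must be positive", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0)
    stop("`fs` must be positive", call. = FALSE)
  if (dbp_base >= sbp_base)
    stop("`dbp_base` must be below `sbp_base`", call. = FALSE)
  if (length(surge_magnitude_range) != 2 || surge_magnitude_range[1] < 0)
    stop("`surge_magnitude_range` must be two values with lower bound >= 0",
         call. = FALSE)
  if (hr_mean_bpm <= 0) stop("`hr_mean_bpm` must be positive", call. = FALSE)
  structure(list(
    duration_s = duration_s, fs = fs,
    hr_mean_bpm = hr_mean_bpm, hr_jitter = hr_jitter,
    sbp_base = sbp_base, dbp_base = dbp_base,
    steady_sigma = steady_sigma,
    surge_rate = surge_rate,
    surge_magnitude_range = surge_magnitude_range,
    surge_duration_beats = surge_duration_beats,
    noise_sigma = noise_sigma,
    baseline_wander_amp = baseline_wander_amp,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Canonical intra-beat pressure shape on u in [0,1): fast systolic upstroke,
# decay with a small dicrotic shoulder. Rescaled so min = 0 (at the onset)
# and max = 1 (systolic peak), which makes the ABP beat peak equal the SBP
# label exactly.
.beat_pressure_shape <- function(len) {
  u <- (seq_len(len) - 1) / len
  up <- 0.30
  shape <- ifelse(u < up,
                  0.5 * (1 - cos(pi * u / up)),
                  cos(0.5 * pi * (u - up) / (1 - up))^2)
  shape <- shape + 0.12 * exp(-(u - 0.55)^2 / (2 * 0.05^2))
  (shape - min(shape)) / (max(shape) - min(shape))
}

# Two-Gaussian PPG pulse: systolic wave + dicrotic wave. Amplitude is linear
# in SBP and the systolic-peak latency shrinks linearly with SBP, giving the
# monotone morphology-SBP coupling the regression task needs.
.beat_ppg_shape <- function(len, sbp) {
  u <- (seq_len(len) - 1) / len
  amp <- 0.5 + 0.010 * (sbp - 80)
  mu1 <- 0.32 - 0.0010 * (sbp - 120)
  g1 <- amp * exp(-(u - mu1)^2 / (2 * 0.10^2))
  g2 <- 0.35 * amp * exp(-(u - 0.65)^2 / (2 * 0.14^2))
  g1 + g2
}

#' Generate one synthetic paired PPG/ABP record
#'
#' Simulates a subject's paired waveforms with known per-beat ground truth.
#' The beat-wise SBP trajectory is `sbp_base` plus a bounded random walk
#' (scale `steady_sigma`, clipped to 60-220 mmHg) plus superposed
#' raised-cosine surge bumps whose count is Poisson in `surge_rate` and
#' whose heights are drawn from `surge_magnitude_range`. Each ABP beat is a
#' pulse whose maximum equals that beat's SBP and whose minimum equals its
#' DBP; each PPG beat is a two-Gaussian pulse whose amplitude and
#' systolic-peak timing vary monotonically with the beat's SBP, plus
#' baseline wander and white noise.
#'
#' @param config A [sim_config()] object.
#' @param subject_id Identifier stored in the record.
#' @param forced_surges Optional data frame with columns `beat`, `magnitude`,
#'   `duration` overriding the random surge draw (used to place a surge of a
#'   known size deterministically).
#' @return A list of class `waveform_record` with elements `subject_id`,
#'   `fs`, `ppg`, `abp`, `beat_onsets_true` (1-based sample indices of beat
#'   starts), `sbp_true` and `dbp_true` (mmHg per beat).
#' @export
generate_record <- function(config, subject_id = "S1", forced_surges = NULL) {
  if (!inherits(config, "sim_config"))
    stop("`config` must be a sim_config object", call. = FALSE)
  cf <- config
  n_target <- round(cf$duration_s * cf$fs)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cf$seed)

  # --- beat grid ---------------------------------------------------------
  # beats are laid down until they overrun the target length; the record is
  # then cut at exactly duration_s * fs samples, and ground truth covers the
  # complete beats only
  mean_len <- 60 / cf$hr_mean_bpm * cf$fs
  n_beats_max <- ceiling(n_target / (mean_len * (1 - 3 * cf$hr_jitter))) + 4L
  jit <- pmin(pmax(stats::rnorm(n_beats_max), -3), 3)
  beat_len <- pmax(4L, as.integer(round(mean_len * (1 + cf$hr_jitter * jit))))
  onsets <- cumsum(c(1L, beat_len))
  started <- which(onsets[-length(onsets)] <= n_target)
  complete <- which(onsets[-1] <= n_target + 1L)
  if (length(complete) < 2L)
    stop("record too short to contain beats", call. = FALSE)
  n_beats <- length(started)
  onsets_beat <- onsets[started]
  beat_len <- beat_len[started]
  n_samples <- n_target

  # --- per-beat SBP trajectory ------------------------------------------
  walk <- cumsum(stats::rnorm(n_beats, 0, cf$steady_sigma))
  sbp <- pmin(pmax(cf$sbp_base + walk, 60), 220)
  if (is.null(forced_surges)) {
    n_surge <- stats::rpois(1, cf$surge_rate * cf$duration_s / 60)
    if (n_surge > 0) {
      forced_surges <- data.frame(
        beat = sample.int(n_beats, n_surge, replace = TRUE),
        magnitude = stats::runif(n_surge, cf$surge_magnitude_range[1],
                                 cf$surge_magnitude_range[2]),
        duration = rep(cf$surge_duration_beats, n_surge))
    }
  }
  if (!is.null(forced_surges) && nrow(forced_surges) > 0) {
    for (s in seq_len(nrow(forced_surges))) {
      b0 <- forced_surges$beat[s]
      dur <- forced_surges$duration[s]
      mag <- forced_surges$magnitude[s]
      idx <- b0:min(n_beats, b0 + dur - 1L)
      t_rel <- (idx - b0) / dur
      sbp[idx] <- sbp[idx] + mag * 0.5 * (1 - cos(2 * pi * t_rel))
    }
    sbp <- pmin(pmax(sbp, 60), 220)
  }
  # DBP tracks SBP weakly around its own base; pulse pressure stays wide.
  dbp <- pmin(cf$dbp_base + 0.25 * (sbp - cf$sbp_base), sbp - 20)

  # --- waveforms ---------------------------------------------------------
  n_buf <- onsets_beat[n_beats] + beat_len[n_beats] - 1L
  ppg <- numeric(n_buf)
  abp <- numeric(n_buf)
  for (b in seq_len(n_beats)) {
    len <- beat_len[b]
    i0 <- onsets_beat[b]
    idx <- i0:(i0 + len - 1L)
    abp[idx] <- dbp[b] + (sbp[b] - dbp[b]) * .beat_pressure_shape(len)
    ppg[idx] <- .beat_ppg_shape(len, sbp[b])
  }
  ppg <- ppg[seq_len(n_samples)]
  abp <- abp[seq_len(n_samples)]
  tt <- (seq_len(n_samples) - 1) / cf$fs
  wander_phase <- stats::runif(1, 0, 2 * pi)
  ppg <- ppg + cf$baseline_wander_amp * sin(2 * pi * 0.1 * tt + wander_phase)
  if (cf$noise_sigma > 0)
    ppg <- ppg + stats::rnorm(n_samples, 0, cf$noise_sigma)

  idx_c <- seq_along(complete)
  structure(list(
    subject_id = subject_id, fs = cf$fs,
    ppg = ppg, abp = abp,
    beat_onsets_true = onsets_beat[idx_c],
    sbp_true = sbp[idx_c], dbp_true = dbp[idx_c]
  ), class = "waveform_record")
}

#' Simulate a cohort of subjects
#'
#' Draws per-subject baseline pressures (normal with SD `sbp_base_sd` around
#' the configured base) and heart rates, then generates one record per
#' subject. Population-level baseline spread is what makes the PPG-to-SBP
#' mapping non-trivial for a pooled model.
#'
#' @param n_subjects Number of subjects.
#' @param config Template [sim_config()]; per-subject seeds are derived from
#'   its `seed`.
#' @param sbp_base_sd Between-subject SD of baseline SBP, mmHg.
#' @param hr_sd Between-subject SD of mean heart rate, bpm.
#' @return A list of `waveform_record` objects.
#' @export
simulate_cohort <- function(n_subjects, config = sim_config(),
                            sbp_base_sd = 15, hr_sd = 8) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  bases <- stats::rnorm(n_subjects, config$sbp_base, sbp_base_sd)
  hrs <- pmax(45, stats::rnorm(n_subjects, config$hr_mean_bpm, hr_sd))
  seeds <- sample.int(.Machine$integer.max, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    cfi <- config
    cfi$sbp_base <- max(80, min(180, bases[i]))
    cfi$dbp_base <- cfi$sbp_base - (config$sbp_base - config$dbp_base)
    cfi$hr_mean_bpm <- hrs[i]
    cfi$seed <- seeds[i]
    class(cfi) <- "sim_config"
    generate_record(cfi, subject_id = sprintf("S%03d", i))
  })
}

#' Per-beat SBP (or DBP) labels from the ABP waveform
#'
#' For each half-open inter-onset interval `[onset_j, onset_{j+1})` returns
#' the maximum of the ABP waveform (systolic pressure) or, in `"dbp"` mode,
#' the minimum (diastolic pressure).
#'
#' @param record A `waveform_record`.
#' @param onsets Strictly increasing 1-based sample indices of beat starts.
#' @param mode `"sbp"` (interval maximum) or `"dbp"` (interval minimum).
#' @return Numeric vector, one value per complete inter-onset interval
#'   (length `length(onsets) - 1`).
#' @export
sbp_from_abp_peaks <- function(record, onsets, mode = c("sbp", "dbp")) {
  mode <- match.arg(mode)
  if (length(onsets) < 2) {
    warning("fewer than 2 onsets: no complete beats")
    return(numeric(0))
  }
  if (any(diff(onsets) <= 0))
    stop("`onsets` must be strictly increasing", call. = FALSE)
  if (onsets[1] < 1 || onsets[length(onsets)] - 1L > length(record$abp))
    stop("`onsets` outside record bounds", call. = FALSE)
  f <- if (mode == "sbp") max else min
  vapply(seq_len(length(onsets) - 1L), function(j) {
    f(record$abp[onsets[j]:(onsets[j + 1L] - 1L)])
  }, numeric(1))
}

#' Write / read a waveform record as CSV plus JSON sidecar
#'
#' The CSV holds two columns (`ppg`, `abp`); the sidecar holds the sampling
#' rate, subject id and — for synthetic records — the ground-truth beat
#' onsets and per-beat pressures.
#'
#' @param record A `waveform_record`.
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @return `write_record_csv` returns `path` invisibly; `read_record_csv`
#'   returns the reconstructed `waveform_record`.
#' @export
write_record_csv <- function(record, path) {
  utils::write.csv(data.frame(ppg = record$ppg, abp = record$abp),
                   path, row.names = FALSE)
  meta <- list(subject_id = record$subject_id, fs = record$fs,
               beat_onsets_true = record$beat_onsets_true,
               sbp_true = record$sbp_true, dbp_true = record$dbp_true)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_record_csv
#' @export
read_record_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(
    subject_id = meta$subject_id, fs = meta$fs,
    ppg = df$ppg, abp = df$abp,
    beat_onsets_true = as.integer(meta$beat_onsets_true),
    sbp_true = meta$sbp_true, dbp_true = meta$dbp_true
  ), class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> subject %s: %.1f s at %g Hz, %d beats\n",
              x$subject_id, length(x$ppg) / x$fs, x$fs,
              length(x$sbp_true)))
  invisible(x)
}
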