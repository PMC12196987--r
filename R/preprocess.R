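#' Screen a waveform record for length and signal quality
#'
#' Rejects records shorter than `min_len_s` and builds a per-sample quality
#' mask flagging artifact spans: PPG flatlines (2-s windows whose standard
#' deviation falls below 1e-6 of the overall signal scale), ABP outside
#' 30-250 mmHg, 2-s ABP windows whose range is below 10 mmHg (a damped or
#' disconnected pressure line), and non-finite samples in either channel.
#'
#' @param record A `waveform_record`.
#' @param min_len_s Minimum record length in seconds (default 480 = 8 min).
#' @return A list: `accepted` (logical), `reason` (string when rejected),
#'   `record`, and `mask` (logical per sample, `TRUE` = usable).
#' @export
screen_record <- function(record, min_len_s = 480) {
  if (length(record$ppg) != length(record$abp))
    stop("ppg and abp must have equal length", call. = FALSE)
  n <- length(record$ppg)
  if (n < min_len_s * record$fs) {
    return(list(accepted = FALSE,
                reason = sprintf("record length %.1f s below minimum %g s",
                                 n / record$fs, min_len_s),
                record = record, mask = logical(0)))
  }
  mask <- rep(TRUE, n)
  w <- as.integer(2 * record$fs)
  scale <- stats::sd(record$ppg)
  if (!is.finite(scale) || scale == 0) scale <- 1
  starts <- seq(1L, n - w + 1L, by = w)
  for (s in starts) {
    idx <- s:(s + w - 1L)
    ppg_w <- record$ppg[idx]
    abp_w <- record$abp[idx]
    bad <- stats::sd(ppg_w) < 1e-6 * scale ||
      diff(range(abp_w)) < 10
    if (bad) mask[idx] <- FALSE
  }
  # trailing partial window inherits the verdict of its own checks
  if (n %% w != 0) {
    idx <- (starts[length(starts)] + w):n
    if (length(idx) > 1 &&
        (stats::sd(record$ppg[idx]) < 1e-6 * scale))
      mask[idx] <- FALSE
  }
  mask[record$abp < 30 | record$abp > 250] <- FALSE
  mask[!is.finite(record$ppg) | !is.finite(record$abp)] <- FALSE
  list(accepted = TRUE, reason = NULL, record = record, mask = mask)
}

#' Band-pass filter a PPG signal
#'
#' Zero-phase (forward-backward) 4th-order Chebyshev type-II band-pass,
#' stopband edges 0.5 and 10 Hz with 20 dB minimum stopband attenuation.
#' The band brackets cardiac content at rest while preserving the dicrotic
#' wave; forward-backward application removes phase distortion so onsets
#' are not displaced.
#'
#' @param ppg Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param band Stopband edges in Hz.
#' @param rs Minimum stopband attenuation, dB.
#' @return Filtered signal, same length as the input.
#' @export
filter_ppg <- function(ppg, fs, band = c(0.5, 10), rs = 20) {
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (length(ppg) < 8 * max(1, fs / band[1]))
    stop("signal shorter than filter warm-up", call. = FALSE)
  flt <- signal::cheby2(4, Rp = rs, W = band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(flt, ppg))
}

#' Detect PPG pulse onsets with a slope-sum-function detector
#'
#' Windowed sum of positive first differences (128 ms window), adaptive
#' threshold at 0.6 of an exponentially decaying running maximum (3 s time
#' constant), a 300 ms refractory period, and refinement of each threshold
#' crossing back to the local waveform minimum (the pulse foot).
#'
#' @param ppg Filtered PPG signal.
#' @param fs Sampling rate, Hz.
#' @param ssf_window_s Slope-sum window, seconds.
#' @param thresh_frac Threshold as a fraction of the running SSF maximum.
#' @param decay_s Time constant of the running-maximum decay, seconds.
#' @param refractory_s Minimum onset spacing, seconds.
#' @return Strictly increasing integer sample indices (1-based) of pulse
#'   feet; empty (with a warning) when no onsets are found.
#' @export
detect_onsets <- function(ppg, fs, ssf_window_s = 0.128,
                          thresh_frac = 0.6, decay_s = 3,
                          refractory_s = 0.3) {
  n <- length(ppg)
  d <- pmax(diff(ppg), 0)
  w <- max(1L, as.integer(round(ssf_window_s * fs)))
  ssf <- stats::filter(c(rep(0, w - 1), d), rep(1, w), sides = 1)
  ssf <- as.numeric(ssf[w:(w + n - 2L)])  # ssf[t] ~ slope sum ending at t+1
  if (all(ssf < .Machine$double.eps) || stats::sd(ppg) == 0) {
    warning("no onsets found")
    return(integer(0))
  }
  decay <- exp(-1 / (decay_s * fs))
  run_max <- numeric(length(ssf))
  m <- max(ssf[seq_len(min(length(ssf), as.integer(3 * fs)))])
  for (t in seq_along(ssf)) {
    m <- max(ssf[t], m * decay)
    run_max[t] <- m
  }
  thr <- thresh_frac * run_max
  above <- ssf > thr
  crossings <- which(above & !c(FALSE, above[-length(above)]))
  refr <- as.integer(refractory_s * fs)
  back <- as.integer(round(0.15 * fs))
  onsets <- integer(0)
  last <- -refr
  for (cr in crossings) {
    t0 <- cr + 1L  # ssf index -> signal index
    if (t0 - last < refr) next
    lo <- max(1L, t0 - back)
    foot <- lo + which.min(ppg[lo:t0]) - 1L
    if (length(onsets) == 0L || foot - onsets[length(onsets)] >= refr) {
      onsets <- c(onsets, foot)
      last <- foot
    }
  }
  if (length(onsets) == 0L) warning("no onsets found")
  onsets
}

#' Slice a record into length-normalized PPG cardiac cycles
#'
#' Cuts the PPG at consecutive onsets (half-open intervals), adjusts each
#' cycle to exactly 125 samples — right zero-padding when shorter, uniform
#' linear-interpolation resampling when longer — and labels it with the
#' maximum (or, in `"dbp"` mode, minimum) of the ABP over the same
#' interval. Cycles whose raw length falls outside the plausible beat range
#' (0.3-1.5 s, i.e. 40-200 bpm) or that touch masked samples are marked
#' unusable rather than silently dropped, so downstream windowing does not
#' bridge across them.
#'
#' @param ppg,abp Equal-length signals.
#' @param onsets Strictly increasing onset indices.
#' @param fs Sampling rate, Hz.
#' @param mask Optional logical quality mask per sample.
#' @param target_len Normalized slice length (125 samples).
#' @param label Either `"sbp"` or `"dbp"`.
#' @return A list: `slices` (k x 125 matrix), `label_val` (mmHg per slice),
#'   `onset_index`, `source_len`, `usable` (logical per slice).
#' @export
slice_cycles <- function(ppg, abp, onsets, fs, mask = NULL,
                         target_len = 125L, label = c("sbp", "dbp")) {
  label <- match.arg(label)
  if (length(onsets) < 2) stop("need at least 2 onsets", call. = FALSE)
  if (!is.null(mask) && length(mask) != length(ppg))
    stop("`mask` must match the signal length", call. = FALSE)
  k <- length(onsets) - 1L
  slices <- matrix(0, k, target_len)
  lab <- numeric(k)
  src_len <- integer(k)
  usable <- logical(k)
  lab_f <- if (label == "sbp") max else min
  lo_len <- 0.3 * fs
  hi_len <- 1.5 * fs
  for (j in seq_len(k)) {
    i0 <- onsets[j]
    i1 <- onsets[j + 1L] - 1L
    len <- i1 - i0 + 1L
    src_len[j] <- len
    seg <- ppg[i0:i1]
    if (len < target_len) {
      slices[j, seq_len(len)] <- seg           # right zero-padding
    } else if (len > target_len) {
      xout <- seq(1, len, length.out = target_len)
      slices[j, ] <- stats::approx(seq_len(len), seg, xout)$y
    } else {
      slices[j, ] <- seg
    }
    lab[j] <- lab_f(abp[i0:i1])
    usable[j] <- len >= lo_len && len <= hi_len &&
      all(is.finite(seg)) && is.finite(lab[j]) &&
      (is.null(mask) || all(mask[i0:i1]))
  }
  list(slices = slices, label_val = lab, onset_index = onsets[seq_len(k)],
       source_len = src_len, usable = usable)
}

#' Assemble contextual-cycle samples
#'
#' Groups consecutive usable cycle slices into non-overlapping windows of
#' `n` beats (no beat is reused across windows; the trailing remainder of
#' each run is discarded; runs broken by unusable beats are never bridged).
#'
#' @param sliced Output of [slice_cycles()].
#' @param n Cycles per contextual sample (default 60).
#' @return A list: `cycles` (m x n x 125 array), `sbp` (m x n matrix),
#'   `start_time` (onset index of each window's first beat). `m = 0` (with
#'   a warning) when fewer than `n` consecutive usable slices exist.
#' @export
assemble_contextual <- function(sliced, n = 60L) {
  usable <- sliced$usable
  usable[is.na(usable)] <- FALSE
  k <- length(usable)
  runs <- rle(usable)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  win_starts <- integer(0)
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r]) next
    m_r <- runs$lengths[r] %/% n
    if (m_r > 0)
      win_starts <- c(win_starts, starts[r] + (seq_len(m_r) - 1L) * n)
  }
  m <- length(win_starts)
  if (m == 0L) {
    warning("fewer than n consecutive usable slices: no contextual samples")
    return(list(cycles = array(0, c(0, n, ncol(sliced$slices))),
                sbp = matrix(0, 0, n), start_time = integer(0)))
  }
  cyc <- array(0, c(m, n, ncol(sliced$slices)))
  sbp <- matrix(0, m, n)
  for (i in seq_len(m)) {
    idx <- win_starts[i]:(win_starts[i] + n - 1L)
    cyc[i, , ] <- sliced$slices[idx, , drop = FALSE]
    sbp[i, ] <- sliced$label_val[idx]
  }
  list(cycles = cyc, sbp = sbp,
       start_time = sliced$onset_index[win_starts])
}

#' Subject-level inclusion by SBP dynamics
#'
#' Keeps a subject only if at least one of its SBP sequences spans strictly
#' more than `delta_thresh` mmHg (max minus min), ensuring the retained
#' cohort actually exhibits the fluctuations the model is meant to track.
#'
#' @param samples_by_subject Named list; each element has an `sbp` matrix.
#' @param delta_thresh mmHg threshold (default 10; strict inequality).
#' @return Character vector of retained subject names.
#' @export
apply_inclusion <- function(samples_by_subject, delta_thresh = 10) {
  keep <- vapply(samples_by_subject, function(s) {
    if (nrow(s$sbp) == 0) return(FALSE)
    any(apply(s$sbp, 1, function(x) max(x) - min(x)) > delta_thresh)
  }, logical(1))
  names(samples_by_subject)[keep]
}

#' Chronological per-subject train/validation/test split
#'
#' Per subject, samples sorted by start time are divided 7:1:2 — the first
#' `floor(0.7 k)` to train, the next `floor(0.1 k)` to validation, and the
#' remainder to test — so training data always precedes test data in time.
#' Subjects with fewer than 3 samples go entirely to train (with a
#' warning).
#'
#' @param samples_by_subject Named list with `cycles`, `sbp`, `start_time`.
#' @param ratios Length-3 positive weights (default `c(7, 1, 2)`).
#' @return A list of class `dataset_split` with elements `train`, `val`,
#'   `test`, each containing `cycles` (m x n x 125), `sbp` (m x n),
#'   `subject` and `start_time` vectors; plus a `counts` data frame.
#' @export
split_chronological <- function(samples_by_subject, ratios = c(7, 1, 2)) {
  ratios <- ratios / sum(ratios)
  parts <- list(train = list(), val = list(), test = list())
  counts <- data.frame(subject = character(0), k = integer(0),
                       train = integer(0), val = integer(0),
                       test = integer(0))
  for (sid in names(samples_by_subject)) {
    s <- samples_by_subject[[sid]]
    k <- nrow(s$sbp)
    if (k == 0) next
    ord <- order(s$start_time)
    if (k < 3) {
      warning(sprintf("subject %s has %d sample(s): all assigned to train",
                      sid, k))
      n_tr <- k; n_va <- 0L
    } else {
      n_tr <- floor(ratios[1] * k)
      n_va <- floor(ratios[2] * k)
    }
    n_te <- k - n_tr - n_va
    grp <- rep(c("train", "val", "test"), c(n_tr, n_va, n_te))
    for (g in c("train", "val", "test")) {
      idx <- ord[grp == g]
      if (length(idx) == 0) next
      parts[[g]][[sid]] <- list(
        cycles = s$cycles[idx, , , drop = FALSE],
        sbp = s$sbp[idx, , drop = FALSE],
        start_time = s$start_time[idx])
    }
    counts <- rbind(counts, data.frame(subject = sid, k = k, train = n_tr,
                                       val = n_va, test = n_te))
  }
  out <- lapply(parts, function(p) {
    if (length(p) == 0)
      return(list(cycles = NULL, sbp = NULL, subject = character(0),
                  start_time = integer(0)))
    cyc <- do.call(abind3, lapply(p, `[[`, "cycles"))
    sbp <- do.call(rbind, lapply(p, `[[`, "sbp"))
    subj <- rep(names(p), vapply(p, function(x) nrow(x$sbp), integer(1)))
    st <- unlist(lapply(p, `[[`, "start_time"), use.names = FALSE)
    list(cycles = cyc, sbp = sbp, subject = subj, start_time = st)
  })
  structure(c(out, list(counts = counts)), class = "dataset_split")
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  xs <- list(...)
  xs <- xs[!vapply(xs, is.null, logical(1))]
  if (length(xs) == 1) return(xs[[1]])
  d2 <- dim(xs[[1]])[2]; d3 <- dim(xs[[1]])[3]
  m <- sum(vapply(xs, function(x) dim(x)[1], integer(1)))
  out <- array(0, c(m, d2, d3))
  at <- 0L
  for (x in xs) {
    mi <- dim(x)[1]
    if (mi > 0) out[at + seq_len(mi), , ] <- x
    at <- at + mi
  }
  out
}

#' Build a contextual-cycle dataset from waveform records
#'
#' End-to-end preprocessing: screening, band-pass filtering, onset
#' detection (or the simulator's ground-truth onsets), cycle slicing and
#' normalization, contextual windowing, subject inclusion by SBP dynamics,
#' and the chronological 7:1:2 split.
#'
#' @param records List of `waveform_record` objects.
#' @param n Cycles per contextual sample.
#' @param min_len_s Minimum record length, seconds.
#' @param delta_thresh Subject-inclusion threshold, mmHg.
#' @param use_true_onsets Use the simulator's ground-truth onsets instead
#'   of the slope-sum detector (for end-to-end label-fidelity checks).
#' @param label `"sbp"` or `"dbp"` labeling.
#' @param ratios Split weights.
#' @return A `dataset_split` (see [split_chronological()]) with an added
#'   `manifest` summarizing attrition: records in/rejected, beats sliced
#'   and dropped, samples per subject, excluded subjects.
#' @export
build_dataset <- function(records, n = 60L, min_len_s = 480,
                          delta_thresh = 10, use_true_onsets = FALSE,
                          label = "sbp", ratios = c(7, 1, 2)) {
  by_subject <- list()
  manifest <- list(records_in = length(records), records_rejected = 0L,
                   beats_total = 0L, beats_dropped = 0L,
                   samples_by_subject = list(), excluded_subjects = character(0))
  for (rec in records) {
    scr <- screen_record(rec, min_len_s = min_len_s)
    if (!scr$accepted) {
      manifest$records_rejected <- manifest$records_rejected + 1L
      next
    }
    filtered <- filter_ppg(rec$ppg, rec$fs)
    onsets <- if (use_true_onsets) rec$beat_onsets_true
              else detect_onsets(filtered, rec$fs)
    if (length(onsets) < 2) next
    sliced <- slice_cycles(filtered, rec$abp, onsets, rec$fs,
                           mask = scr$mask, label = label)
    manifest$beats_total <- manifest$beats_total + length(sliced$usable)
    manifest$beats_dropped <- manifest$beats_dropped + sum(!sliced$usable)
    samp <- assemble_contextual(sliced, n = n)
    by_subject[[rec$subject_id]] <- samp
    manifest$samples_by_subject[[rec$subject_id]] <- nrow(samp$sbp)
  }
  kept <- apply_inclusion(by_subject, delta_thresh = delta_thresh)
  manifest$excluded_subjects <- setdiff(names(by_subject), kept)
  split <- split_chronological(by_subject[kept], ratios = ratios)
  split$manifest <- manifest
  split
}

#' @export
print.dataset_split <- function(x, ...) {
  sizes <- vapply(c("train", "val", "test"), function(g) {
    if (is.null(x[[g]]$sbp)) 0L else nrow(x[[g]]$sbp)
  }, integer(1))
  cat(sprintf(
    "<dataset_split> %d subjects; samples train/val/test = %d/%d/%d\n",
    length(unique(c(x$train$subject, x$val$subject, x$test$subject))),
    sizes[1], sizes[2], sizes[3]))
  invisible(x)
}
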