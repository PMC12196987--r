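test_that("short records are rejected and clean records fully accepted", {
  r7 <- quick_record(duration_s = 7 * 60, seed = 1)
  scr <- screen_record(r7, min_len_s = 480)
  expect_false(scr$accepted)
  expect_match(scr$reason, "below minimum")

  r8 <- quick_record(duration_s = 8 * 60, seed = 1)
  scr8 <- screen_record(r8, min_len_s = 480)
  expect_true(scr8$accepted)
  expect_true(all(scr8$mask))
})

test_that("flatline spans are masked out", {
  r <- quick_record(duration_s = 60, seed = 2)
  flat <- 2001:2625                      # 5 s flatline
  r$ppg[flat] <- r$ppg[2000]
  scr <- screen_record(r, min_len_s = 30)
  expect_true(scr$accepted)
  # the 2-s windows covering the flat span must be masked
  expect_true(all(!scr$mask[2251:2500]))
  # far-away samples stay usable
  expect_true(all(scr$mask[5000:6000]))
})

test_that("out-of-range ABP samples are masked", {
  r <- quick_record(duration_s = 60, seed = 2)
  r$abp[1000:1010] <- 300
  scr <- screen_record(r, min_len_s = 30)
  expect_true(all(!scr$mask[1000:1010]))
})

test_that("mismatched channel lengths are a structural error", {
  r <- quick_record(duration_s = 30, seed = 2)
  r$abp <- r$abp[-1]
  expect_error(screen_record(r, min_len_s = 10), "equal length")
})

test_that("band-pass filter attenuates drift and preserves cardiac band", {
  fs <- 125
  tt <- (0:(fs * 120 - 1)) / fs
  drift <- sin(2 * pi * 0.05 * tt)
  inband <- sin(2 * pi * 2 * tt)
  # 0.05 Hz lies deep in the stopband: >= 20 dB design attenuation,
  # doubled by the forward-backward pass
  expect_lt(sd(filter_ppg(drift, fs)) / sd(drift), 0.1)
  expect_gt(sd(filter_ppg(inband, fs)) / sd(inband), 0.85)
  expect_equal(filter_ppg(numeric(fs * 60), fs), numeric(fs * 60))
  expect_equal(length(filter_ppg(drift, fs)), length(drift))
  expect_error(filter_ppg(numeric(10), fs), "warm-up")
})

test_that("slope-sum onset detection matches simulator ground truth", {
  r <- quick_record(duration_s = 60, seed = 3, noise_sigma = 0.01)
  f <- filter_ppg(r$ppg, r$fs)
  on <- detect_onsets(f, r$fs)
  d <- sapply(on, function(a) min(abs(a - r$beat_onsets_true)))
  expect_gte(mean(d <= 3), 0.95)
  # count matches the constructed beat count to within one beat
  expect_lte(abs(length(on) - length(r$beat_onsets_true)), 1)
})

test_that("75 bpm clean PPG over 60 s yields 74-76 onsets", {
  r <- generate_record(sim_config(duration_s = 60, hr_mean_bpm = 75,
                                  hr_jitter = 0, noise_sigma = 0.005,
                                  baseline_wander_amp = 0, seed = 6))
  on <- detect_onsets(filter_ppg(r$ppg, r$fs), r$fs)
  expect_gte(length(on), 74)
  expect_lte(length(on), 76)
})

test_that("constant signal yields no onsets, with a warning", {
  expect_warning(on <- detect_onsets(rep(1, 1000), 125), "no onsets")
  expect_length(on, 0)
})

test_that("cycle slicing pads short cycles and resamples long ones", {
  set.seed(10)
  fs <- 125
  # construct three synthetic cycles of known lengths 100, 125, 150
  lens <- c(100, 125, 150)
  onsets <- cumsum(c(1, lens))
  total <- sum(lens)
  ppg <- unlist(lapply(lens, function(l) sin(pi * (0:(l - 1)) / l)))
  abp <- unlist(lapply(seq_along(lens), function(i) {
    70 + (40 + i) * ppgtrend:::.beat_pressure_shape(lens[i])
  }))
  sl <- slice_cycles(ppg, abp, onsets, fs)
  expect_equal(dim(sl$slices), c(3, 125))
  # padding: tail of the 100-sample cycle is exactly zero
  expect_true(all(sl$slices[1, 101:125] == 0))
  expect_equal(sl$slices[1, 1:100], ppg[1:100])
  # exact length passes through unchanged
  expect_equal(sl$slices[2, ], ppg[101:225])
  # resampling matches an independently coded linear-interpolation oracle
  seg <- ppg[226:375]
  xout <- seq(1, 150, length.out = 125)
  lo <- floor(xout); hi <- ceiling(xout); wfrac <- xout - lo
  oracle <- seg[lo] * (1 - wfrac) + seg[hi] * wfrac
  expect_equal(sl$slices[3, ], oracle, tolerance = 1e-12)
  # labels are the per-interval ABP maxima
  expect_equal(sl$label_val, c(111, 112, 113), tolerance = 1e-9)
  expect_equal(sl$source_len, lens)
})

test_that("implausible cycle lengths are flagged unusable", {
  fs <- 125
  lens <- c(30, 100, 200)                 # 0.24 s, 0.8 s, 1.6 s
  onsets <- cumsum(c(1, lens))
  ppg <- rnorm(sum(lens))
  abp <- rep(100, sum(lens)) + rnorm(sum(lens))
  sl <- slice_cycles(ppg, abp, onsets, fs)
  expect_equal(sl$usable, c(FALSE, TRUE, FALSE))
})

test_that("contextual windows are disjoint, complete, and chronological", {
  sl <- list(slices = matrix(rnorm(130 * 125), 130, 125),
             label_val = rnorm(130, 120, 5),
             onset_index = seq(1, by = 100, length.out = 130),
             source_len = rep(100L, 130), usable = rep(TRUE, 130))
  out <- assemble_contextual(sl, n = 60L)
  expect_equal(dim(out$cycles), c(2, 60, 125))   # floor(130/60), 10 discarded
  expect_equal(out$sbp[1, ], sl$label_val[1:60])
  expect_equal(out$sbp[2, ], sl$label_val[61:120])
  expect_equal(out$start_time, sl$onset_index[c(1, 61)])

  sl$usable <- rep(TRUE, 130)
  out1 <- assemble_contextual(list(slices = sl$slices[1:60, ],
                                   label_val = sl$label_val[1:60],
                                   onset_index = sl$onset_index[1:60],
                                   source_len = sl$source_len[1:60],
                                   usable = rep(TRUE, 60)), n = 60L)
  expect_equal(nrow(out1$sbp), 1)
  expect_warning(
    out0 <- assemble_contextual(list(slices = sl$slices[1:59, ],
                                     label_val = sl$label_val[1:59],
                                     onset_index = sl$onset_index[1:59],
                                     source_len = sl$source_len[1:59],
                                     usable = rep(TRUE, 59)), n = 60L),
    "no contextual samples")
  expect_equal(nrow(out0$sbp), 0)
})

test_that("windows never bridge across unusable beats", {
  usable <- rep(TRUE, 25)
  usable[11] <- FALSE                    # runs of 10 and 14 usable beats
  sl <- list(slices = matrix(rnorm(25 * 125), 25, 125),
             label_val = rnorm(25, 120, 5),
             onset_index = seq(1, by = 100, length.out = 25),
             source_len = rep(100L, 25), usable = usable)
  out <- assemble_contextual(sl, n = 10L)
  expect_equal(nrow(out$sbp), 2)
  expect_equal(out$sbp[1, ], sl$label_val[1:10])
  expect_equal(out$sbp[2, ], sl$label_val[12:21])   # restart after the gap
})

test_that("subject inclusion uses a strict 10 mmHg rule", {
  flat <- list(sbp = matrix(120 + 2 * sin(seq_len(120) / 5), 2, 60))
  spike <- list(sbp = rbind(rep(120, 60), c(rep(115, 30), rep(127.5, 30))))
  boundary <- list(sbp = rbind(seq(110, 120, length.out = 60)))
  subjects <- list(A = flat, B = spike, C = boundary)
  kept <- apply_inclusion(subjects, delta_thresh = 10)
  expect_identical(kept, "B")            # 4 mmHg out, 12.5 in, exactly 10 out
})

test_that("chronological split follows the 7:1:2 floor rules", {
  mk <- function(k) list(cycles = array(rnorm(k * 6 * 125), c(k, 6, 125)),
                         sbp = matrix(rnorm(k * 6, 120), k, 6),
                         start_time = seq_len(k) * 1000)
  sp10 <- split_chronological(list(S = mk(10)))
  expect_equal(sp10$counts[, c("train", "val", "test")],
               data.frame(train = 7L, val = 1L, test = 2L))
  sp20 <- split_chronological(list(S = mk(20)))
  expect_equal(unlist(sp20$counts[, c("train", "val", "test")],
                      use.names = FALSE), c(14L, 2L, 4L))
  sp3 <- split_chronological(list(S = mk(3)))
  expect_equal(unlist(sp3$counts[, c("train", "val", "test")],
                      use.names = FALSE), c(2L, 0L, 1L))
  expect_warning(split_chronological(list(S = mk(2))), "all assigned to train")
})

test_that("training data precedes test data in time for every subject", {
  mk <- function(k, seed) {
    set.seed(seed)
    list(cycles = array(rnorm(k * 6 * 125), c(k, 6, 125)),
         sbp = matrix(rnorm(k * 6, 120), k, 6),
         start_time = sample(seq_len(k) * 997))   # unsorted on purpose
  }
  sp <- split_chronological(list(A = mk(13, 1), B = mk(8, 2)))
  for (sid in c("A", "B")) {
    tr <- sp$train$start_time[sp$train$subject == sid]
    te <- sp$test$start_time[sp$test$subject == sid]
    expect_lt(max(tr), min(te))
  }
})

test_that("end-to-end dataset from true onsets has exact labels", {
  recs <- simulate_cohort(3, sim_config(duration_s = 90, seed = 17))
  ds <- build_dataset(recs, n = 15L, min_len_s = 60, use_true_onsets = TRUE)
  # every sequence label must equal the simulator truth for those beats
  for (part in c("train", "val", "test")) {
    p <- ds[[part]]
    if (is.null(p$sbp) || nrow(p$sbp) == 0) next
    for (i in seq_len(nrow(p$sbp))) {
      rec <- recs[[match(p$subject[i], sapply(recs, `[[`, "subject_id"))]]
      j0 <- match(p$start_time[i], rec$beat_onsets_true)
      expect_false(is.na(j0))
      expect_equal(p$sbp[i, ], rec$sbp_true[j0:(j0 + 14)], tolerance = 1e-12)
    }
  }
  # manifest bookkeeping is self-consistent
  m <- ds$manifest
  expect_equal(m$records_in, 3)
  expect_equal(m$records_rejected, 0)
  expect_true(m$beats_total > 0)
})

test_that("dbp labeling mode yields per-beat diastolic values", {
  recs <- simulate_cohort(2, sim_config(duration_s = 90, seed = 23))
  ds <- build_dataset(recs, n = 15L, min_len_s = 60, use_true_onsets = TRUE,
                      label = "dbp", delta_thresh = 0)
  p <- ds$train
  rec <- recs[[match(p$subject[1], sapply(recs, `[[`, "subject_id"))]]
  j0 <- match(p$start_time[1], rec$beat_onsets_true)
  expect_equal(p$sbp[1, ], rec$dbp_true[j0:(j0 + 14)], tolerance = 1e-12)
})
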