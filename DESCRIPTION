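Package: ppgtrend
Title: Beat-to-Beat Systolic Blood Pressure Trend Estimation from
    Photoplethysmography Contextual Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates beat-to-beat systolic blood pressure (SBP) trends from
    single-channel photoplethysmography (PPG) as a sequence regression task.
    Raw paired PPG/ABP waveforms are screened, band-pass filtered, segmented
    into cardiac cycles with a slope-sum-function onset detector, length
    normalized, and assembled into contextual cycles: windows of consecutive
    non-overlapping cycle slices paired with their per-beat SBP sequence.
    A two-stage network - parallel residual U-shaped 1-D convolutional
    encoders per cycle followed by Transformer layers whose attention scores
    carry a signed sinusoidal relative positional bias - maps each window to
    its SBP sequence, trained with mean-absolute-error loss and Adam.
    Includes a synthetic paired PPG/ABP waveform simulator with known
    per-beat ground truth, the full evaluation suite (sequence MAE, mean
    per-sequence Pearson correlation, variability error based on average
    real variability, steady/unsteady fluctuation detection, AAMI and BHS
    grading, Bland-Altman agreement), and deterministic training utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    graphics,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
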