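---
title: "Estimating beat-to-beat SBP trends from PPG contextual cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating beat-to-beat SBP trends from PPG contextual cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Beat-to-beat systolic blood pressure (SBP) carries information that
cuff measurements and window-averaged estimates wash out: short-lived
surges, the magnitude and pattern of blood-pressure variability, and the
transition between steady and unsteady states. Single-channel
photoplethysmography (PPG) is cheap and wearable, and its pulse
morphology co-varies with arterial pressure, so a natural goal is to
read an SBP *sequence* — one value per cardiac cycle — from a stretch of
PPG, rather than a single number per analysis window.

`ppgtrend` implements this as sequence regression on **contextual
cycles**: `n = 60` consecutive, non-overlapping, length-normalized PPG
cycle slices stacked in chronological order, mapped to the 60
corresponding per-beat SBP values. The sequence formulation is what
makes variability metrics (and surge detection) meaningful: errors in
the *shape* of the trajectory are scored, not only its level.

## Model

The network has two stages plus a head.

**Stage 1 — intra-cycle feature extraction.** Each 128-sample cycle
(125-sample slices are right zero-padded) passes through a shared-weight
residual U-shaped 1-D convolutional encoder ("ResU block"): a
conv–instance-norm–ReLU stem at `base_channels = 16`, `d = 2` strided
down-steps doubling the width, `r = 8` residual blocks at the
bottleneck, two linear-interpolation up-steps with additive encoder
skips, an output stem back to one channel, and an outer residual that
adds the raw cycle to the result. The output is one length-`l = 128`
feature token per cycle; `l = l0` is required precisely so that the
outer residual is well-typed. Whether the U interior carries skip
connections is a genuine design choice ("U-like" suggests it); additive
skips were chosen because they preserve the shape algebra of the outer
residual. Instance normalization (per cycle, per channel, population
variance, no affine) makes each branch insensitive to the DC level and
gain of its slice.

**Stage 2 — context-sensitive interaction.** The `n x l` token matrix
passes through `L = 3` pre-norm Transformer layers
(`F' = MSA(LN(F)) + F`; `F'' = MLP(LN(F')) + F'`) with 8 heads
(`d_k = 16`), GELU MLP at expansion 4, and dropout 0.1 during training.
Attention scores carry a **signed sinusoidal relative positional
bias**: for cycle positions `a, b` the encoding is
`p(a,b) = sign(a−b) · PE(|a−b|)` with the classic sinusoid
`PE_{2x}(j) = sin(j / 10000^{2x/D})`, `PE_{2x+1}(j) = cos(·)`,
`D = l`. Each head `h` in each layer owns a learnable vector `w_p`
projecting `p(a,b)` to a scalar added to the pre-softmax score:
`softmax(QK'/√d_k + w_p'p)V`. The bias is antisymmetric, zero on the
diagonal, and depends on `a − b` only — shifting all positions leaves it
unchanged, which is exactly the translation property that absolute
encodings lack. An `pe_mode = "ape"` toggle reproduces the
absolute-encoding ablation (sinusoids added to tokens once before layer
1, no score bias); `"none"` removes positional information entirely.

**Head.** A per-token projection (`l → l/2`, ReLU, `l/2 → 1`) emits one
SBP value per cycle.

Training is mini-batch Adam (`lr = 1e-4` at full scale, batch 16) on
the mean-absolute-error loss; batches are reshuffled each epoch from a
single seed, and the parameters with the best validation MAE are kept.
Everything — initialization, shuffling, dropout — is bit-reproducible
given the seed.

No deep-learning framework is involved: forward and backward passes are
written directly on matrix operations (with compiled im2col/GEMM
convolution and instance-norm kernels), and the full analytic gradient
is verified against central finite differences in the test suite.

### Numerical choices

* Label standardization: SBP targets are z-scored with train-split
  statistics inside `resutrans()` and inverted at prediction. With an
  L1 loss the per-step Adam displacement is roughly the learning rate,
  so targets on the raw mmHg scale would need tens of thousands of
  steps merely to reach the operating level; standardization removes
  that artifact of scale without touching the model.
* Instance/layer norm use `eps = 1e-5`; SD-type metrics use the
  population denominator so reported values are deterministic functions
  of the data.
* Gradient clipping (global norm) is available but off by default; the
  divergence path aborts with a diagnostic instead of silently
  producing NaNs.
* Ties and kinks: `|x|` uses `sign()` as its subgradient (zero at 0);
  ReLU uses the right derivative at 0.

## The waveform simulator

`sim_config()` / `generate_record()` produce paired PPG/ABP records
with known per-beat truth, emulating the regime the estimator is meant
for: 125 Hz sampling, records of at least 8 minutes (the screening
minimum), per-beat SBP formed as a baseline plus a bounded random walk
(`steady_sigma = 0.6` mmHg/beat, clipped to 60–220 mmHg) plus
raised-cosine surge bumps (rate 0.5/min, magnitude 10–30 mmHg, duration
40 beats — "hill-like" rises over tens of seconds, so the >10 mmHg
inclusion criterion is satisfiable but not trivially met by every
window). Each ABP beat is a pulse whose maximum equals the beat's SBP
and minimum its DBP *exactly*, so label extraction can be validated
end-to-end with zero tolerance. Each PPG beat is a two-Gaussian pulse
(systolic + dicrotic wave) whose amplitude grows linearly with SBP and
whose systolic peak arrives earlier at higher pressure, plus ~0.1 Hz
baseline wander (amplitude 0.05) and white noise (`noise_sigma = 0.02`
of a unit pulse). Cycle lengths vary around `60/hr` with 3% jitter;
`simulate_cohort()` additionally draws per-subject baselines
(SD 15 mmHg) and heart rates (SD 8 bpm), the population-level spread
that makes a pooled PPG→SBP mapping non-trivial.

What the simulator deliberately does **not** model: Windkessel-style
hemodynamics, reflected-wave physiology, motion artifacts,
device-specific transfer functions, or the noise statistics of any
real ICU archive. Passing tests on synthetic cohorts therefore
demonstrates that the pipeline and optimizer are correct and that the
architecture can learn a monotone morphology–pressure coupling under
realistic heart-rate and baseline variation — not that the headline
accuracy transfers to clinical recordings.

## Preprocessing rules

Screening rejects records under 8 minutes and masks artifact spans
(2-s PPG windows with SD below 1e-6 of signal scale; ABP outside
30–250 mmHg; 2-s ABP windows spanning under 10 mmHg, a damped or
disconnected line; non-finite samples). The pulse-pressure rule is
applied per 2-s window because beats are not yet delimited at screening
time; any such window contains at least one full beat, so its range
bounds the pulse pressure from above.

Filtering is a zero-phase 4th-order Chebyshev type-II band-pass. The
cutoffs are not dictated by the estimation problem itself, so they were
fixed once at 0.5–10 Hz (20 dB stopband), bracketing cardiac content at
rest while preserving the dicrotic notch; forward–backward application
avoids phase distortion that would displace onsets.

Onsets come from a slope-sum-function detector: 128 ms windowed sum of
positive first differences, threshold at 0.6 of a running maximum with
3 s exponential decay, 300 ms refractory period, and refinement of each
crossing back to the local waveform minimum (the pulse foot). On
low-noise synthetic records it recovers ≥95% of true onsets within ±3
samples.

Cycles are cut at consecutive onsets (half-open intervals, 1-based
indices), normalized to 125 samples — right zero-padding when shorter,
uniform linear-interpolation resampling when longer (the resampling
kernel is unspecified in the construction; linear was chosen and is
tested against an independent oracle) — and labeled with the ABP
maximum over the same interval (minimum for the DBP option). Cycles
outside 0.3–1.5 s (40–200 bpm) or touching masked samples are flagged
unusable. Contextual windows take `n` consecutive usable beats greedily
without reuse; runs broken by unusable beats are never bridged, and
remainders shorter than `n` are discarded. Subjects are retained only
if at least one sequence spans strictly more than 10 mmHg. The
chronological split assigns the first `floor(0.7k)` samples per subject
to train, the next `floor(0.1k)` to validation, and the remainder to
test — test takes the remainder so it is non-empty whenever `k ≥ 3`,
and training data always precedes test data in time.

## Evaluation suite

Sequence level: MAE over all beats; `Rseq`, the per-sequence Pearson
correlation averaged over sequences (zero-variance sequences are
excluded with a warning — their correlation is undefined); and the
variability error `VE`, the mean absolute difference between the
ground-truth and predicted first-difference sequences (normalized by
`n − 1` per sequence). VE is invariant to constant offsets in the
prediction; it scores trend shape, not level.

Value level: mean error and population SD of `pred − gt`, the same on
10-beat non-overlapping averages, Bland–Altman mean difference and
±1.96 SD limits of agreement, AAMI verdict (|ME| ≤ 5 mmHg, SD ≤ 8 mmHg,
≥85 subjects) and BHS grading by cumulative percentages of absolute
errors within 5/10/15 mmHg (A: 60/85/95; B: 50/75/90; C: 40/65/85;
boundaries inclusive).

Fluctuation detection: a sequence is *unsteady* when its span (max −
min) strictly exceeds 10 mmHg — a span of exactly 10 is steady,
matching the strict "over 10 mmHg" inclusion wording — and
accuracy/precision/recall/F1 are reported with unsteady as the positive
class (the clinically alarming state; the convention is recorded here
because either choice is defensible).

Every metric is checked against an independently coded brute-force
implementation on large random batches at 1e-10 tolerance.

## Desk-scale study sizes

The package's own experiments (tests and the acceptance script) run on
one CPU, so the default `run_pipeline()` study is deliberately compact:
60 subjects × 240 s records, `n = 15` cycles per sample, a reduced
model (`base_channels = 8`, `r = 2`, `L = 1`), 30 epochs at
`lr = 1e-3`. These sizes are the package's chosen demonstration
conditions: large enough that the cohort exhibits steady and unsteady
sequences and a meaningful train/val/test chronology, small enough to
iterate on. The higher learning rate for reduced runs compensates for
the far smaller step budget (hundreds rather than ~10^5 Adam steps);
the full-scale default `train_control()` retains `lr = 1e-4`,
batch 16, 500 epochs. A memorization check (5 training samples, 200
epochs) verifies optimizer capacity separately from generalization.

## Known limitations

* The simulator's morphology–SBP coupling is intentionally simple
  (amplitude and latency, monotone); real PPG–BP coupling is
  nonstationary and confounded by vasomotor tone.
* Records are assumed artifact-light after masking; no signal-quality
  index beyond the stated rules is computed.
* The chronological split is per subject; no leave-subject-out
  generalization claim is made or tested.
* The HDF5/MAT interchange formats of the original data pipeline are
  out of scope here; records travel as CSV + JSON sidecar, datasets and
  checkpoints as native R serialization at run time.
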