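---
title: "Models and methods behind nemaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nemaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`nemaquant` quantifies three linked kinds of evidence from *C. elegans*
mechanosensory experiments: ratiometric calcium responses of identified
neurons, operationally scored behaviors, and strain-level population
statistics. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
establish about real recordings.

## Ratiometric calcium quantification

FRET-based indicators such as cameleon report intracellular calcium as an
increase of the acceptor/donor (YFP/CFP) emission ratio. The analysis
chain is:

1. **ROI tracking.** A rectangular ROI around the cell body is re-centered
   once per frame at the intensity-weighted center of mass of the summed
   two-channel image inside the previous frame's ROI, after local
   background subtraction. One update per frame, no iteration; the ROI
   keeps its size and is clipped at image borders. A frame whose
   background-subtracted ROI total is non-positive raises a tracking-lost
   error naming the frame, rather than silently coasting.
2. **Fluorescence.** `F = Σ(ROI) − N · mean(faintest k pixels)`, with
   `k = max(1, floor(0.10 N))`. We read the faintest-decile rule as
   estimating a per-pixel background from the dimmest 10% of ROI pixels
   and removing it over the whole ROI area; the alternative reading —
   subtract only the decile's own sum — removes just a tenth of a uniform
   background and leaves `F` dominated by the pedestal, so it is offered
   only as `literal = TRUE` for comparability. `floor()` in `k` keeps the
   background sample away from median-brightness pixels; negative `F` in
   pathological frames is reported, never clipped.
3. **Ratio.** `R = (F_yellow − α·F_cyan) / F_cyan`. Donor bleed-through
   into the acceptor channel is modeled as one-directional linear mixing
   with a user-supplied coefficient α (default 0). Published descriptions
   of such corrections rarely state the coefficient; α is therefore
   explicit, recorded in every result, and validated against the
   generator's known mixing (matching α shrinks the recovered-peak bias —
   a tested property).
4. **Baseline and response.** `R0` is the mean `R` over the first
   `baseline_window` seconds (default 3 s; `round(window · rate)` frames,
   so exactly 30 frames at 10 Hz), `ΔR/R0 = 100·(R − R0)/R0`. Frames with
   `F_cyan ≤ 0` yield missing `R`, and a non-positive baseline is an
   error. A trial is a **responder** when the peak `ΔR/R0` inside
   `[onset, onset + stimulus duration + 10 s]` exceeds
   `max(3·σ_baseline, 5%)`. The stimulus durations follow the assay
   convention: 1 s firm nose press, 3.7 s food-mimicking buzz. The
   response criterion itself is not standardized in the literature this
   emulates; both constants are arguments and are recorded in each call.

**Smoothing.** Peak extraction and `σ_baseline` use a centered moving
average of 5 frames (0.5 s at 10 Hz, about one indicator rise time). Shot
noise makes the frame-wise maximum of a raw trace a biased peak estimator;
a window much shorter than the decay time (3 s) suppresses that bias
without clipping the true peak. `smooth_frames = 1` restores the raw
trace.

## Behavior scoring

- **Reversals.** `signed_speed < −0.05` body-lengths/s sustained for
  ≥ 0.2 s within 1 s after the tap. These constants are explicit
  stand-ins for the tracker-internal criterion of the emulated assay; all
  are arguments. A tracking gap overlapping the window gives an
  *untracked* outcome — the assay's denominators are worms tracked per
  tap, so untracked is never conflated with "did not reverse".
- **C-shaped bends.** |midbody bend angle| crossing 45° with 10°
  hysteresis, sides strictly alternating. Hysteresis suppresses noise
  chatter (tested: zero-mean noise with sd below a third of the
  hysteresis changes counts by < 2%). The state machine runs on
  run-length-compressed threshold codes, so scoring an 11-minute trace is
  linear in the number of threshold crossings rather than samples.
- **Paralysis.** No bend events within `[595, 600]` s for the standard
  10-min assay mark with a 5 s quiet window.
- **Thrash frequency.** One thrash = one full left-right cycle = two
  alternating bend events; frequency = events / (2 · interval). The
  convention is stated so counts can be doubled for comparison with
  half-cycle counting.
- **Body bends.** Event count in the 60–120 s persistence window of the
  basal slowing assay.

## Population statistics

Habituation curves report, per tap, worms reversing over worms tracked,
with Wilson score intervals by default — chosen for its behavior near the
0/1 boundaries reached at late taps; Clopper–Pearson is available and the
method is always recorded. The day-level QC gate passes a day only when
the reference strain's tap-1 reversal proportion is ≥ 0.80, inclusive at
the boundary.

The habituated level is reversal at tap 30 exactly (not an average of
late taps). Strain comparisons fit a binomial logistic model on strain
(treatment coding; worm-level observations, matching the
"worms reversing / worms tracked" unit) and test all pairwise log-odds
contrasts by Wald statistics. Familywise adjustment is the single-step
multivariate-normal method — the standard realization of Tukey-type
all-pairs contrasts for GLMs — using the joint normal law of the contrast
statistics; the all-pairs contrast correlation matrix is rank-deficient by
construction, which the multivariate-normal integration handles. A
Bonferroni fallback covers numerical failure, and adjusted p-values are
floored at the raw ones. Complete separation (a strain at 0% or 100%)
switches to a penalized fit that adds half a pseudo-success and
pseudo-failure to every strain's counts and flags the result; plates may
correlate worms, so a cluster-robust sandwich variance is available via
`cluster`. Calibration is validated by simulation at the assay's standard
design (3 strains × 100 worms, 30 taps): familywise type-I error within
[0.03, 0.07] at nominal 0.05 over 1,000 null replicates, and power > 0.8
for habituated levels 0.45 vs 0.25 over 500 replicates.

The basal slowing index, `1 − mean(bends on food)/mean(bends off food)`,
gets a seeded nonparametric bootstrap over worms (default 2,000
replicates) for strain intervals and pairwise differences.

## Synthetic data: what it emulates, and what it does not

The generators provide ground truth for every stage:

- **Tap experiments.** Per-tap reversal probability
  `p_t = p_inf + (p0 − p_inf)·e^{−λ(t−1)}`; reversals Bernoulli(`p_t`);
  tracking dropout independent Bernoulli per (worm, tap), reflecting that
  multi-worm trackers do not follow every animal at every tap. Defaults
  follow the standard protocol: 30 taps, 10 s ISI, 300 s acclimatization.
- **Image stacks.** A Gaussian spot (sd = `cell_radius`) on a uniform
  background; a single calcium transient with double-exponential time
  course (rise 0.5 s, decay 3 s — typical of genetically encoded
  indicators; response waveforms in the emulated experiments are shown
  but not parameterized, so these kinetics are placeholders, not fits),
  normalized to its analytic maximum so `transient_peak_dRR0` is exact;
  linear donor→acceptor bleed-through; per-pixel Poisson shot noise plus
  Gaussian read noise, rounded to integer camera counts. The default
  photon budget (1,000 signal photons/pixel at the spot center, 100
  background, read noise 3) matches EM-CCD imaging of a bright cell body
  at 10 Hz, where frame-wise ratio noise is a fraction of a percent —
  the regime in which responses of ten percent and larger are cleanly
  resolvable, as they are in the class of recordings emulated.
- **Swim traces.** `amplitude·sin(2πft)` plus Gaussian noise; at a
  paralysis onset the amplitude ramps to zero over 2 s (no real worm
  stops discontinuously) and stays there. Construction rejects sampling
  below the Nyquist rate of the thrash frequency.

All streams derive from one user seed: the master seed initializes R's
generator, and substream seeds are drawn uniformly from `1..2^31 − 2`
(`derive_seeds()`), so any stage can be reproduced in isolation from the
run manifest.

What passing the synthetic validation does **not** show: real worms are
not Gaussian spots (shape change and out-of-focus drift stress tracking
more than linear drift does); real bend-angle extraction from video has
correlated, non-Gaussian errors; real habituation outcomes are likely
correlated within plates and days, which the independent-Bernoulli model
ignores (hence the cluster-robust option); and real paralysis is not a
clean amplitude ramp. The generators validate the *computational* chain
against known truth; they are not evidence about biology.

## Numerical and design choices

- Baseline frame count uses `round()` to handle non-integer
  `window · rate` products; the 10 Hz/3 s standard gives exactly 30.
- Background estimation uses a partial sort (`O(N)` per frame).
- Ties in the faintest decile follow sort order; `F` is invariant to any
  constant pixel offset and `R` to common channel rescaling (both tested
  properties).
- Degenerate inputs error loudly: empty or too-small ROIs (< 10 px, so
  the decile is never empty), non-positive baselines, traces not covering
  a scoring window, paralysis onsets outside the recording.
- Centroid weights keep their sign after local background subtraction; a
  non-positive ROI total is an error rather than a clamped centroid.
- The paralysis ground-truth comparison draws onsets away from the 2 s
  ramp band just before the quiet window, where "last bend time" depends
  on the amplitude/threshold interplay and no exact truth exists; the
  boundary behavior is pinned instead by explicit traces whose bends
  cease at 590.3 s and 597.3 s.
- Validation problem sizes are the assay's standard designs: 50 stacks of
  300 frames at 64×64 px for recovery, 200 eleven-minute traces for
  paralysis, 1,000 + 500 replicates for calibration and power, 10,000
  draws for interval coverage.

## Known limitations

No motion correction beyond ROI re-centering; no spectral unmixing beyond
the linear α model; no automatic cell detection (the initial ROI is
supplied); no habituation-curve dynamics inference beyond the endpoint
comparison; no day/plate mixed-effects hierarchy beyond the cluster-robust
variance; no image-level worm segmentation (the package consumes per-worm
event and posture series).
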