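---
title: "Methods: the waveform fluctuation metric and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the waveform fluctuation metric and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcgfluct)
```

## The problem and the statistic

A ballistocardiogram (BCG) records the mechanical recoil of the body with
each heartbeat. Healthy adults at rest produce a nearly stationary beat
morphology; heart-failure patients often do not, and algorithms that read
single landmarks off the waveform inherit that instability as silent error.
`bcgfluct` quantifies the instability itself.

The unit of analysis is a 20-s epoch containing only the subject's dominant
beat type. Each heartbeat is the 700-sample (700 ms at 1000 Hz) segment
starting at its ECG R wave. A window of `T_EA` seconds slides through the
epoch in 1-s steps; window starts are `0, 1, …, 20 − T_EA − 1` s relative
to the epoch, i.e. the window whose right edge would coincide with the
epoch boundary is not generated. This start convention is what makes the
window count with dense beats equal `20 − T_EA` (12 windows at 8 s, 15 at
5 s), and it is asserted as an invariant in the test suite. A beat belongs
to a window iff its R time lies in the half-open interval
`[start, start + T_EA)`; its 700-sample crop may extend past the window
edge, which maximizes usable beats. Windows with no beats are dropped with
a warning; windows whose admitted-beat index set exactly repeats an earlier
window's are removed (equality of index sets, compared exactly).

Each retained window yields the sample-wise ensemble average of its beats.
With `N_Total` averages per epoch, every ordered pair contributes
`MSE_ij = Σ_t (f_i(t) − f_j(t))²` — deliberately the raw sum over the 700
samples, not divided by 700: the missing `1/n` adds the constant `ln 700`
on the log scale, which cancels in every within-study comparison. The
epoch's statistic is

```
WFMR = ln( max(ε, (1/(N_Total (N_Total − 1))) Σ_{i≠j} MSE_ij ) ),   ε = 1e−12.
```

The `ε` floor keeps a zero-fluctuation epoch finite (`ln ε ≈ −27.6`); the
same floor guards the log of any zero standard deviation elsewhere in the
package. By symmetry the ordered-pair mean equals the unordered-pair mean,
so the choice is immaterial; the implementation uses the squared Euclidean
distance matrix and is checked against a naive double loop for every
`N_Total ≤ 15`.

Useful algebraic facts, all property-tested: WFMR is invariant to
reordering the ensemble averages and to adding a constant to every
waveform, and scaling all waveforms by `a > 0` adds exactly `2 ln a`.

## Choosing the window size

For each `T_EA` in 2–15 s the per-subject epoch mean and then the grand
mean across subjects (subjects weighted equally, regardless of how many
epochs survived) give a monotone-decreasing sweep curve. The selected
window is the smallest `T_EA` whose marginal decrease falls below 10% of
the total decrease across the sweep. Two edge cases are fixed by
definition: a flat or non-decreasing curve returns the smallest window, and
a curve with no sufficiently small marginal drop returns the largest. Note
that for long curves a strictly linear decrease has marginal drops below
10% of the total from the first point on, so the "no elbow" outcome is
only attainable for short curves; the rule is deliberately applied as
stated. On the synthetic default cohort the elbow lands at 4 s — smaller
than the 8 s used as the package default — because the synthetic beat
jitter is temporally unstructured; `t_ea = 8` remains the default as the
field-standard choice, and both are reported.

## The synthetic testbed

No public recordings pair chair BCG with multichannel reference signals,
so validation runs against a generator whose every stage emits ground
truth.

**Beat schedule.** RR intervals are i.i.d. Gaussian around 60/HR, floored
at 0.35 s; there is deliberately no long-range heart-rate-variability
model. PVCs arrive 30% early with a compensatory pause.

**BCG.** Each beat is a sum of seven Gaussian bumps (H, I, J, K, L, M, N
waves; J dominant positive) over the 700 ms after R. Per beat the renderer
applies a lognormal amplitude scale (`amp_jitter_sd`), Gaussian
per-component timing shifts (`phase_jitter_sd_s`), an AR(1) log-width
"shape drift" (`shape_ar_coef`, `shape_innov_sd`), and sinusoidal
respiratory amplitude modulation; the record adds white noise and a
spline-smooth baseline drift. Beat-to-beat waveform variance is monotone in
each jitter dial (tested over a 3-point grid at fixed seed), and doubling
the amplitude jitter doubles the empirical SD of beat peak amplitudes.

**ECG.** Gaussian P-QRS-T components per beat type: paced beats carry a
1.5 ms-wide stimulus spike 55 ms before a widened QRS and no P wave; PVCs a
wide (≥120 ms by construction) P-less QRS with inverted T. Ground-truth
fiducials are analytic: QRS onset/offset at the 2σ edges of the Q and S
components, T end at the tangent-method intercept, which for a Gaussian T
is exactly `center + 2σ`.

**Blood pressure.** True beat-to-beat SBP/DBP is an AR(1) plus respiratory
oscillation around subject means; the continuous device adds a constant
offset plus noise; a cuff reads the true 60-s mean once per minute (five
readings in five minutes).

**Profiles.** The two populations differ only through the priors in
`inst/extdata/profiles.yaml` (uniform subject-level draws): amplitude
jitter 3–8% vs 10–25%, timing jitter 2–5 ms vs 6–15 ms, shape innovation
1–3% vs 3–8%, PVCs up to 8% and a 20% chance of a predominantly paced
rhythm only in the clinical profile. No quantitative description of
clinical BCG jitter exists to calibrate against, so these were fixed once
for qualitative separation and plausibility; consequently the cohort
comparison is validated as a property (the test detects the separation the
generator encodes) and the synthetic classification accuracies
(~97–99%) say nothing about accuracy on real recordings.

**What the generator does not emulate.** Hemodynamics (no physical model
links BCG shape to ejection), HRV spectra, motion artifacts, powerline
interference, electrode noise, or morphology classes beyond the Gaussian
template family. Passing tests demonstrate the pipeline's correctness and
sensitivity, not clinical performance.

**Fast path.** `simulate_cohort(render = FALSE)` materializes only the
beat schedule; the WFMR stage then renders just the 700-sample crops of
beats admitted to epochs, with the same per-beat latent states as the full
renderer (identical seeds give agreeing beats up to neighbouring-beat
overlap and sub-sample phase — verified in the tests) and white beat-level
noise, omitting baseline drift that the analysis high-pass removes anyway.
This is what makes the Monte-Carlo suite cheap: the power test runs 100
full 55-subject cohorts and the classification test 20, in a few minutes.

## Preprocessing choices

Filtering uses linear-phase window-design FIR filters (2 Hz high-pass,
order 1000, Hamming; 25 Hz low-pass for BCG; 40 Hz low-pass for
non-clinical ECG) applied in one pass with the constant group delay
removed — effectively zero-phase, so no fiducial shifts. Phase handling is
a package decision: crop alignment depends on it, and squared-magnitude
(forward-backward) filtering would have doubled the designed attenuation.

Clinical ECG is denoised with a stationary (undecimated) wavelet transform
instead of a low-pass, precisely so pacing spikes survive. The SWT is
implemented in the frequency domain (à-trous filters, circular
convolution, reflection padding so any signal length works); with the
orthogonal db5 pair the per-level identity `|H|² + |G|² = 2` makes
reconstruction exact to ~1e−14, which the tests assert. Denoising
soft-thresholds the detail coefficients per level. Thresholds are tuned by
a deterministic greedy grid search, finest level first, 20 candidates per
level spanning `[0, 3·MAD]` of that level's coefficients, maximizing an
SNR estimate — RMS within ±60 ms of the R peaks over RMS of mid-diastolic
(0.55–0.80 of the RR interval after R) segments — subject to the relative
RMS change within ±60 ms of R staying below 5%. A candidate is accepted
only on strict SNR improvement, and a signal whose level-1 detail MAD is
below `1e−8` of its RMS is treated as noise-free (there is no noise to
remove; any positive threshold only distorts), so clean inputs keep all
thresholds at zero. In the pipeline, tuning runs on the first 60 s and the
tuned spec denoises the full record.

Stream synchronization matches RR-interval sequences by maximizing their
cross-correlation over integer beat offsets (overlap at least half the
shorter sequence, so short coincidental matches cannot win) and converts
the best offset to a time lag. Constant-RR (fully paced) rhythms carry no
alignment information and raise a degenerate-input error by design.

## Beats and epochs

R-wave detection is a simplified Pan-Tompkins chain — 5–15 Hz band-pass,
five-point derivative, squaring, 150 ms integration, adaptive signal/noise
thresholds with a 250 ms refractory period, no search-back — with each
detection relocalized to the raw-ECG extremum within ±50 ms. Beat typing
is rule-based: a pacing spike is a <10 ms (half-height) deflection at
least 5× the local baseline scale in the 100–35 ms window before R; a PVC
has a QRS span ≥120 ms, measured as the distance between the first and
last smoothed-envelope excursion above 15% of the R amplitude within
−120…+150 ms (a span, not a contiguous run, because the Q–R and R–S zero
crossings dip through baseline inside a wide complex).

Epoch selection takes the majority beat type (ties toward intrinsic),
places non-overlapping pure 20-s windows greedily left-to-right on a 1-s
grid, then fills any shortfall with the least-contaminated non-overlapping
windows, excluding their non-dominant beats. Because greedy placement can
strand a short record, a final fallback re-selects on a regular 20-s
tiling. Every epoch must admit at least 8 beats — a package choice (no
minimum is standard) guaranteeing that every 8-s window holds at least one
beat. The 700-sample crop length is asserted at 1000 Hz rather than scaled
with the sampling rate.

## Reference features

Delineation is rule-based: Q and S are baseline returns (3% of local R
amplitude) walking outward from the Q/S troughs within 80 ms before and
120 ms after R; T end uses the tangent method on the steepest T downslope
within `[S + 80 ms, S + 400 ms]`, and a T wave flatter than 5× the
baseline threshold flags the beat, which is then excluded from interval
features (that beat only, not its epoch). Intervals: `RR`, `QRS = S − Q`,
`QT_BASE = T_end − Q`, `QT_QRS = QT_BASE − max(0, QRS − 120 ms)`
(emphasizing repolarization), and the linear rate correction
`QTc = QT + 0.154 (1 − RR)` with RR and QT in seconds — the constant is
the Framingham linear coefficient, defined for seconds. Continuous blood
pressure is shifted by the mean cuff-minus-device difference over the 60 s
preceding each cuff reading, SBP and DBP independently. Windowed epoch
statistics reuse the exact WFMR windowing (same starts, duplicate and
empty handling — the window counts are asserted equal), average the
feature per window, then log-transform window means, epoch mean and epoch
SD; an epoch with fewer than two retained windows has no SD and is
flagged. A window mean requires only one contributing beat.

## Cohort comparison

The one-sided Welch t-test (unequal variances, Satterthwaite degrees of
freedom, alternative: clinical mean higher) is `stats::t.test`; the test
suite checks it against a from-scratch formula evaluation. LOSO
classification holds out all epochs of one subject per fold and reports
epoch-level accuracy; a subject is misclassified when a majority of its
epochs are (a tie counts as misclassified — relevant only when epochs are
dropped). Naive Bayes uses per-class normal densities with the density
floor disabled (the default floor flips far-tail points of the majority
class); logistic regression is unpenalized `glm`; the decision tree is
`rpart` grown with `cp = 0` and pruned back to at most the requested
number of internal splits, with the cap swept over 5–30 and the argmax
reported. The fold construction makes leakage impossible by indexing on
subject id, and accuracy is invariant to row order (tested).

## Problem sizes and runtime choices

Unit tests run on 60–300 s single records; the Monte-Carlo checks use 100
seeded cohort replicates for Welch power, 20 for LOSO, 20 for the sweep
monotonicity and the 3-point jitter grids — sizes picked so the full suite
completes in a few minutes while the binomial margins on the ≥95%
assertions stay comfortable. Wavelet tuning in tests runs on 60 s
excerpts, matching the pipeline's tuning window.

## Known limitations

Rule-based typing and delineation are validated against the simulator's
analytic truth, not against expert labels; the generator's Gaussian
template family cannot produce the atypical morphologies seen in some
seated recordings; epoch placement is automatic where a practitioner might
curate; and the WFMR aggregates amplitude, phase and shape instability
into one number by design — decomposing the source of fluctuation is out
of scope.
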