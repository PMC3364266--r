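---
title: "Methods: quantifying arterial–CSF coupling from phase-contrast velocity imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying arterial–CSF coupling from phase-contrast velocity imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfpulse)
```

# The problem

Every heartbeat drives a bolus of arterial blood into the cranium. Because
the skull is rigid, the inflow must be buffered: cerebrospinal fluid (CSF)
is displaced caudally through the cervical spinal canal and, to a much
smaller extent, through the aqueduct between the third and fourth
ventricles. The timing and frequency content of this coupling carry
information about the mechanical state of the intracranial system (arterial
wall stiffness, parenchymal compliance), and reference values are needed to
interpret flow measurements in conditions such as normal pressure
hydrocephalus, where aqueductal stroke volume (reference threshold 42 µL)
and average aqueductal flow (18 mL/min) are used clinically.

`csfpulse` implements the full analysis chain for cardiac-gated 2D
phase-contrast MRI velocity data of three compartments — carotid/vertebral
arteries, cervical spinal canal at C3–C4, and aqueduct — from velocity
images to cohort-level statistics, together with a synthetic-data module
that generates coupled waveforms and phantom acquisitions with *known*
construction parameters. Because every synthetic quantity is known by
construction, each pipeline stage can be validated by parameter recovery.

# Image-domain processing

**Aliasing.** Phase-contrast velocities live on a circle: the encoding
velocity `venc` maps to ±π of phase, and a true velocity `venc + d` is
stored as `-venc + d`. `unwrap_velocity()` unwraps each pixel's velocity
time course with a jump tolerance of π (in phase units): consecutive
differences larger than `venc` are corrected by steps of `2*venc`. The
unwrap axis is time — in a gated cine series at fixed `venc`, aliasing is a
temporal event at the systolic peak. The operation is idempotent and leaves
non-aliased pixels untouched.

**Segmentation.** Artery and aqueduct cross-sections are segmented from
magnitude-image contrast with Otsu's histogram-shape threshold (256-bin
between-class variance maximization, implemented exactly so it can be
verified against a brute-force sweep), restricted to a user-drawn ROI
polygon, keeping the largest connected component. Arteries pulse visibly,
so they are segmented frame by frame; the aqueduct varies little and is
segmented on the frame with maximum velocities. The cervical spinal canal
has poor magnitude contrast, so `segment_spinal_frequency()` instead
thresholds the temporal-spectrum energy at non-zero frequencies of each
voxel: CSF pulsates at cardiac harmonics, static tissue does not. The
energy threshold is chosen automatically by Otsu on the log-energy map,
which makes the mask invariant to uniform amplitude scaling.

**Quality control.** Following the classic rim criterion, the velocity
content of two one-pixel rims adjacent to the outside and inside of the
mask is compared against the mask interior: outer-rim signal (above 3×
the background noise SD — the visual criterion made quantitative) means
the mask is too small; an inner rim far below the interior mean (below
20 % of it) means it is too large. `refine_segmentation()` iterates the
threshold by ±5 % steps, at most ten times, in the suggested direction.

**Background correction and flow.** The temporal-mean velocity of a static
reference region (a rectangle near the lumen, or the one-voxel contour
around the spinal canal, where no clean rectangle exists) is subtracted
from all frames. Volumetric flow is then the pixel-area-weighted velocity
sum over the mask, in mL/s.

# Waveform analysis

**Scalar metrics.** The average flow rate is the time-average of |Q(t)|
over one cycle (caudocranial plus craniocaudal transport; it is *not* net
flow, which is the signed average and reflects CSF production). Stroke
volume is the mean of the absolute areas under the positive and negative
lobes; a missing lobe contributes zero.

**Amplitude normalization.** CSF flows are divided by their cycle-average
|Q| (the normalized cycle has average flow exactly 1); arterial flow is
divided by the average of the *systolic* phase only, because systole has a
nearly heart-rate-invariant duration while diastole stretches with the RR
interval. Systole is demarcated from the R-wave to the minimum at aortic
valve closure (feature `ar5`), which the packaged templates place at 330 ms
(young) and 360 ms (elderly).

**Temporal normalization.** Cohort spectra require commensurable
frequencies, i.e. equal cycle lengths. Stretching the cycle would distort
systole, so the cycle is brought to a nominal 1 s by editing only the
diastolic tail: shorter cycles get a linear segment from the last data
point back to the first point's value, longer cycles are cut at 1 s; the
result is resampled at 10 ms (100 samples). Scalar metrics and amplitude
normalization are computed on the subject's true cycle *before* this step,
since physiological averages refer to real time.

**Feature points.** Extrema are sign changes of the first difference and
inflections of the second difference of a lightly smoothed copy (3-point
moving average — the minimal smoother that kills sampling jitter without
moving peaks), with amplitudes read from the unsmoothed curve. Labels
follow the conventional schemes (`ar1`–`ar6`, `sp1`–`sp6`, `aq1`–`aq5`).
Extremum labels are mandatory; inflection labels are reported when present
(a pure sinusoid has only two inflections per cycle, so requiring three
would reject valid smooth aqueductal cycles). Feature sets are fitted with
the monotonicity-preserving piecewise cubic Hermite interpolant.

# Spectral analysis and the noise floor

After temporal normalization, harmonics fall on integer frequencies;
`dft_components()` reports single-sided amplitudes `2|X_k|/N` (a unit sine
has magnitude 1), with the zero frequency excluded because amplitude
normalization decouples it from net flow. Windowing is deliberately not
offered: tapers redistribute energy between the very few harmonics that
matter here.

Which magnitudes are trustworthy is decided by a noise calibration: a sine
of decreasing amplitude is buried in unit-variance white noise, and an
amplitude counts as detectable when its bin carries the largest magnitude
of all bins in at least 90 % of trials. With a 2048-sample record the
maximal noise bin is about `sqrt(2/N) * sqrt(2 log N)` ≈ 0.12 SD, and the
simulation places the detection limit at one fifth of the noise SD
(`detectability_simulation()` reproduces this). Per compartment, the
threshold applied to subject spectra is the maximum over subjects of
(background noise SD)/5. The record length is a packaged calibration
constant: the dominance criterion and the one-fifth limit jointly pin it,
and 2048 is the standard FFT length in that range.

# Transfer functions

The arterial-to-CSF transmission is modelled as a discrete-time rational
transfer function of order 5 (5 poles, 5 zeros, 10 ms sampling) identified
from one normalized cycle by the prediction-error method: equation-error
least squares initializes the parameters, and a damped (Levenberg-style)
Gauss–Newton iteration minimizes the *simulation*-error sum of squares,
which never increases between accepted steps. Because the gated cycle is
one period of a periodic signal, simulation is circular (frequency-domain),
which avoids arbitrary initial conditions. Unstable poles are reflected
into the unit circle with a gain-preserving numerator compensation, so
every returned model is stable and causal.

Three conditioning choices matter and were genuinely open:

* **Static-gain constraint.** A 1 s record has 1 Hz frequency resolution:
  nothing between DC and the fundamental is observed. The DC ratio itself,
  however, *is* measured — it is the ratio of the signal means (net-flow
  transmission). Constraining the model's static gain to this ratio anchors
  the low-frequency limb of the gain curve in data instead of leaving it to
  the optimizer's whim. Without it, sub-fundamental gain (and with it any
  crossover below 1 Hz) is pure extrapolation.
* **Dead time.** Pulse transmission involves a genuine latency of up to
  ~160 ms (16 samples). A rational model without a delay term spends its
  poles approximating `z^-16` and has none left for the gain shape. The
  latency is therefore estimated first from the circular cross-correlation
  peak and split off; both the raw and the delay-compensated fits are
  computed and the one with the smaller prediction error is kept — for
  genuinely rational relations the raw fit wins and nothing changes.
* **Multi-start.** The equation-error initialization can land in a
  degenerate local minimum in which a pole-zero dipole at `z ≈ 1`
  satisfies the static-gain constraint as a spike while the rest of the
  curve collapses. A second start from the static-gain model costs one
  extra fit (~30 ms) and removes the failure mode; the lower-cost fit wins.

`bode()` evaluates gain and unwrapped phase (including the dead-time
contribution) on the unit circle up to the compartment's noise-limit
frequency (7 Hz spinal, 5 Hz aqueductal). `crossover_frequency()` returns
the smallest frequency at which the gain falls below one from above,
linearly interpolated between grid points, and flags curves that never
cross. Group curves in reports are pointwise medians across subjects,
robust to occasional ill-conditioned fits; group crossover values are the
mean of the per-subject crossings with undefined cases excluded.

# Cross-correlation latency

`transmission_delay()` estimates the delay of peak caudal CSF flow after
peak arterial inflow as the argmax of the circular normalized
cross-correlation of the arterial waveform with the negated CSF waveform
(CSF is cranial-positive). Circular, not zero-padded: a gated composite
cycle is one period of a periodic signal, and zero-padding would invent an
aperiodic edge. The grid peak is refined by a parabolic fit through its
two neighbours, giving sub-grid (sub-10 ms) resolution; for a circularly
shifted copy the estimate is exact at any on-grid lag because the
correlogram is symmetric about the true peak. A secondary peak-to-peak
estimate (time of maximum caudal flow minus time of systolic maximum,
modulo the cycle) is returned for comparison.

# Cohort statistics

Between-group comparisons of scalar quantities use the two-sided
Mann–Whitney test (exact by enumeration up to a combined n of 12 without
ties — the study scale of 11 vs 11 sits just above it — and the
tie-corrected normal approximation otherwise). Correlations use Spearman's
rho with the t approximation. Repeated-measure profiles (frequency
components, feature points, transfer-function samples, correlogram lags)
use a split-plot ANOVA with one between factor (group) and
Greenhouse–Geisser-corrected within-subject degrees of freedom; epsilon is
computed from the eigenvalues of the double-centred pooled within-group
covariance, `(Σλ)² / ((k−1) Σλ²)`, floored at `1/(k−1)` — the eigenvalue
form is numerically stabler than the direct covariance formula. Samples
failing a Shapiro–Wilk screen at 0.05 are log-transformed before
parametric analysis (the screen level is our choice; the convention of
transforming non-normal variables is standard).

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Cohorts.** Two groups (young, elderly) of 11 subjects; heart periods
  drawn from N(831, 169²) ms truncated to [500, 1200] ms; acquisition-like
  noise is additive white Gaussian on waveforms (arterial 0.36, spinal
  0.016, aqueductal 0.0014 mL/s — about 2–3 % of each signal's scale) and
  on phantom velocity images.
* **Arterial templates.** Anchor points joined by a shape-preserving cubic
  define the canonical cycles: the young template has a taller, narrower
  systolic peak with more high-harmonic energy; the elderly template a
  more pronounced late systolic peak (stiffer arterial walls, earlier wave
  reflections). Both carry a high diastolic baseline, as appropriate for
  the low-resistance cerebral vascular bed. Heart-rate variation is
  handled as in the analysis, in reverse: systole is invariant and the
  diastolic tail is truncated or linearly extended.
* **Coupling.** Spinal and aqueductal cycles are built from the subject's
  own arterial cycle: each harmonic is scaled by a stable second-order
  low-pass gain profile, phase-delayed by the packaged transmission lag
  (young 55/160 ms, elderly 34/132 ms for spinal/aqueductal), negated into
  the cranial-positive convention and placed on a unit baseline; the AC
  magnitude relative to the baseline is a calibrated shape constant. The
  zero-phase-plus-pure-delay construction makes the cross-correlation peak
  land *exactly* on the construction lag (the cross-spectrum has positive
  real coefficients times a pure delay), so delay recovery is an exact
  check at any on-grid lag.
* **Calibration.** The packaged lags and crossover frequencies *are* the
  published group values, so default end-to-end runs are
  construction-parameter recovery checks. The filter shape constants were
  solved offline so that the full pipeline, applied to reference ensembles
  of default cohorts, reproduces the target crossovers (young spinal
  0.5 Hz, elderly spinal 3 Hz, young aqueductal 0.8 Hz, elderly aqueductal
  0.5 Hz) in expectation. With 11 subjects per cohort the recovered group
  means scatter between seeds — delays by a few ms, crossovers by roughly
  ±0.05–0.25 Hz — which is the sampling noise of the estimator, not a bias.
* **Phantoms.** `synthesize_velocity_series()` renders a waveform into a
  phase-contrast-like acquisition: a circular lumen with a parabolic
  laminar profile scaled so the mask-integrated flow matches the waveform
  exactly per frame (parabolic, not Womersley, because only integrated
  flow matters downstream and the parabola integrates in closed form), a
  planar background phase offset, white velocity noise, and wrapping into
  `(-venc, venc]` exactly as a scanner stores aliased velocities.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: partial-volume and intra-voxel dephasing at
lumen edges, eddy-current background fields beyond a planar offset,
beat-to-beat variability (retrospective gating yields one composite
cycle), venous flow, Womersley/elastic-wall hemodynamics, and realistic
biphasic CSF waveform depth (the synthetic CSF carries a baseline chosen
for coupling calibration, so its flow-reversal is shallower than
physiological aqueductal flow; scalar CSF metrics from the generator are
internally consistent but not population-realistic).

# Numerical choices and degenerate inputs

Pixel coordinates are 0-based row-major; masks are half-open grid subsets.
Resampling interpolation is linear (only the 10 ms interval is
prescribed). The Gauss–Newton refinement runs at most 100 iterations with
relative cost tolerance 1e-9 and Levenberg damping adapted by factors of
10; reflected poles are placed at radius 0.995 to keep a numerical margin
from the unit circle. Constant images, constant inputs, empty masks, empty
samples, zero averages and out-of-range frequencies all raise informative
errors rather than propagating NaN. Problem sizes in the test-suite
simulations (cohorts of 11, 1000-replicate null calibration, 200-trial
detectability sweeps, 24–40-frame phantoms on 24–28 px grids) were chosen
so the whole suite exercises every stage at study scale in a few minutes.

# Known limitations

* Sub-fundamental crossover frequencies are anchored only by the static
  gain; their per-subject estimates are extrapolations of the rational
  model and correspondingly noisy at n = 11.
* The frequency-segmentation energy threshold uses Otsu on log-energy; for
  ROIs where pulsatile voxels are a very small minority the histogram may
  need the `frequency_threshold_scale` adjustment.
* The iterative rim-driven threshold refinement uses a fixed ±5 % schedule
  and at most ten iterations.
* `mann_whitney`'s exact branch requires tie-free data; tied small samples
  fall back to the corrected approximation.
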