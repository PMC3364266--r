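# csfpulse

Coupled analysis of cerebral arterial inflow and cerebrospinal fluid (CSF)
pulsation from cardiac-gated 2D phase-contrast MRI.

Every systole pushes arterial blood into the rigid cranium; the volume is
buffered by caudal displacement of CSF through the cervical spinal canal
and the aqueduct. `csfpulse` quantifies this coupling for three
compartments (carotid/vertebral arteries, cervical spinal canal at C3–C4,
aqueduct) and is aimed at researchers working on intracranial dynamics and
on reference values for conditions such as normal pressure hydrocephalus.

The package covers the full chain:

* **image domain** — temporal unwrapping of velocity aliasing at the
  encoding velocity (`venc`), Otsu-based lumen segmentation with rim-based
  quality control, a frequency-domain segmentation for the spinal canal,
  background phase correction, and flow integration
  `Q(t) = Σ_pixels A · v(t)`;
* **waveforms** — average flow rate (time-average of |Q| over the cycle),
  net flow rate, stroke volume (mean of the absolute lobe areas),
  amplitude normalization (CSF by cycle average, arterial by systolic
  average), temporal normalization to a nominal 1 s cycle by extending or
  cutting only the diastolic tail, resampled at 10 ms, feature-point
  detection (`ar1`–`ar6`, `sp1`–`sp6`, `aq1`–`aq5`) and monotone cubic
  Hermite fits;
* **spectra** — harmonic magnitudes `2|X_k|/N` at integer frequencies with
  a simulation-calibrated noise floor (minimal detectable sine amplitude
  ≈ one fifth of the background noise SD);
* **coupling** — fifth-order output-error transfer functions identified by
  the prediction-error method (equation-error initialization, damped
  Gauss–Newton on the simulation error, static-gain anchoring, dead-time
  estimation), Bode gain/phase curves, unity-gain crossover frequencies,
  and circular cross-correlation transmission delays;
* **statistics** — Mann–Whitney (exact for small tie-free samples),
  Spearman's rho, and split-plot repeated-measures ANOVA with
  Greenhouse–Geisser correction;
* **synthetic data** — group-specific waveform templates (young/elderly)
  and a coupling generator with packaged calibration (transmission lags
  55/160 ms young and 34/132 ms elderly for spinal/aqueductal flow;
  crossover frequencies 0.5/0.8 Hz young and 3/0.5 Hz elderly), plus a
  phase-contrast phantom renderer, so every stage is testable by
  construction-parameter recovery without patient data.

## Worked example

Simulate one elderly subject, normalize, and recover the packaged coupling
parameters:

```r
library(csfpulse)

subj <- generate_coupled_subject(coupling_spec("elderly"),
                                 heart_period_ms = 900, seed = 3)

art <- normalize_time(normalize_amplitude(subj$arterial, "systolic_average"))
spi <- normalize_time(normalize_amplitude(subj$spinal, "cc_average"))

transmission_delay(art, spi)
#> # A tibble: 1 × 2
#>   delay_ms peak_to_peak_ms
#>      <dbl>           <dbl>
#> 1     34.4              70

tf <- identify_tf(art, spi, order = 5)
glance(tf)
#> # A tibble: 1 × 7
#>   order delay_ms   vaf residual_variance iterations converged stable
#>   <dbl>    <dbl> <dbl>             <dbl>      <int> <lgl>     <lgl>
#> 1     5        0  99.5           0.00106         60 TRUE      TRUE

crossover_frequency(bode(tf, seq(0.05, 7, by = 0.05)))
#> [1] 2.589
```

The transmission delay recovers the packaged elderly spinal lag (34 ms)
to within a fraction of the sampling interval; the identified transfer function is stable with ~99.5 % variance
accounted for, and its unity-gain crossover lies near the packaged 3 Hz
calibration (single subjects scatter around it; group means converge).

A full cohort analysis, including group statistics:

```r
report <- run_pipeline(pipeline_config(seed = 1))
glance(report)       # group mean delays and crossover frequencies
tidy(report)         # per-subject metrics (stroke volume, average flows, flags)
autoplot(subj$aqueduct)
```

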