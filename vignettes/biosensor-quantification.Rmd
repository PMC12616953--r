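---
title: "Quantifying red-shifted FRET ERK biosensors: model, pipeline and characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying red-shifted FRET ERK biosensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rekar)
library(dplyr)
```

## The measurement model

A FRET-based kinase activity reporter carries a donor and an acceptor
fluorophore joined by a substrate/binding-domain linker. Phosphorylation by
ERK drives an intramolecular association that increases FRET. What ratio
imaging measures is the product **EfA**: the FRET efficiency *E* of the
associated configuration times the fraction *f~A~* of molecules in it. The
two factors are not separately identifiable from intensity data, so the
package treats EfA as the atomic readout and never represents *E* or *f~A~*
alone.

### Two-filter (CFP/YFP) configuration

When donor and acceptor can each be excited selectively, the readout is

$$EfA = 1 - \frac{I_{CFP}/I_{YFP}}{R_P},$$

where $R_P$ is the total donor-channel gain divided by the acceptor-channel
gain. Each gain is the product of relative excitation power, exposure time,
extinction coefficient, quantum yield and the integrals of the
source-filter-spectrum products (`compute_rp()`).

### Shared-excitation (near-infrared) configuration

The miRFP670nano3/miRFP720 pair overlaps too strongly for selective acceptor
excitation: both channels use one excitation band and differ only in their
emission filters. The donor channel (RFP670-type) and FRET channel
(FRET720-type) then each collect a mixture of donor emission, sensitized
acceptor emission, and directly excited acceptor emission. For channel $c$
and fluorophore $f$ we form the excitation product
$X_c^f(\lambda) = S(\lambda)\,T^{ex}_c(\lambda)\,\epsilon_f A_f(\lambda)$
and emission product
$M_c^f(\lambda) = QY_f\,E_f(\lambda)\,T^{em}_c(\lambda)$.

A modeling point worth making explicit: excitation and emission occur at
*different* wavelengths, so each channel signal term factorizes into the
integral of its excitation product times the integral of its emission
product; the package computes every calibration ratio in this factorized
form. This is also the only reading under which the donor-channel
acceptor-bleed term has its natural meaning — the fraction of
acceptor-emitted light collected relative to donor-emitted light — and
under which crosstalk genuinely lives in the spectral tails that make
computed ratios sensitive to tabulation error.

With the normalized intensity ratio
$NIR = (I_F/I_D) / (P_F t_F / P_D t_D)$ and the ratios $R_{XT}$ (donor
bleed-through), $R_{Chan}$ (direct acceptor excitation) and $R_{FRET}$
(sensitized emission), neglecting acceptor emission collected in the donor
channel gives the model

$$NIR = \frac{R_{XT}(1 - EfA) + R_{FRET}\,EfA + k\,R_{Chan}}{1 - EfA},
\qquad
EfA = \frac{NIR - R_{XT} - k\,R_{Chan}}{NIR - R_{XT} + R_{FRET}},$$

an exact algebraic inversion pair — the package's tests verify the round
trip to machine precision across the whole response range. The neglected
bleed term is on the order of 0.1 or less for this pair; `forward_nir()`
retains it behind `include_acceptor_bleed = TRUE` so its effect can be
audited (it biases the simplified inversion by a bounded, monotone amount
that vanishes with the term).

### Assumptions

- **k = C^A^/C^D^ = 1** by default: a single-chain sensor carries one donor
  and one acceptor per molecule. The parameter stays exposed for
  photobleaching or chromophore-maturation asymmetry studies.
- **Measured over computed crosstalk.** $R_{XT}$ is dominated by the overlap
  of the donor emission tail with the FRET emission filter; small vendor
  tabulation errors stack exactly there. A direct donor-only calibration
  (`calibrate_rxt()`) therefore overrides the spectra-computed value whenever
  available. `reference_calibration()` records the pair of values measured
  and computed on the instrument the sensors were originally characterized
  on (0.578 measured vs 0.551 computed, a 4.9% excess): a yardstick for how
  close a spectra-based prediction can come.
- **Arbitrary units.** All quantities are ratios; absolute spectral units
  cancel and are deliberately not enforced.
- **Out-of-range EfA values are flagged, never clipped.** Clipping would
  bias the downstream noise-variance estimate; `flag_efa_range()` marks
  excursions outside [0, 1].
- **Degenerate frames become missing values.** A nonpositive donor intensity
  or an inversion denominator within `1e-9 * (1 + |NIR|)` of zero yields
  `NA` for that frame rather than aborting the track.

### Numerical choices

Spectra are resampled to a common 1-nm grid (vendor curves are rarely finer)
by linear interpolation, zero outside each curve's tabulated support, and
integrated with the trapezoidal rule. On smooth synthetic spectra the 1-nm
ratios agree with a 0.01-nm fine-grid oracle to well within $10^{-4}$
relative; the shipped synthetic optics include realistic emission-tail
kinks, for which convergence is closer to $10^{-3}$ — still far below the
uncertainty of any tabulated spectrum.

## The synthetic-data generator

No public single-cell dataset accompanies the sensors this package models,
so the generator is a first-class module: it emulates the canonical
characterization experiment — MCF-10A cells sampled every 6 min, EGF
stimulation, then combined MEK/EGFR inhibition — and emits both the
observable track table and the generating ground truth, enabling exact
recovery tests.

### Kinetics

`activity_profile()` parameterizes a dimensionless activity fraction in
[0, 1]:

- baseline before EGF;
- a logistic rise reaching the peak exactly 30 min after EGF (the observed
  peak time), then exponential relaxation toward an elevated plateau
  (default halfway between baseline and peak, rate 0.03/min);
- after the inhibitor, a *compressed* exponential decay
  ($\tau$ = 4 min) that attains its floor exactly 12 min after treatment.
  A plain exponential only reaches its minimum asymptotically, i.e. at the
  last frame of the movie; the compressed form reproduces the observed
  "minimum within 20 min" on a noise-free trace;
- for the near-infrared sensors, an undershoot pulse
  $u(\Delta) = d\,(\Delta/t_{dip})^2 e^{2(1-\Delta/t_{dip})}$ dipping below
  baseline at $t_{dip}$ = 16 min and decayed to ~1% of its depth an hour
  later, matching the transient dip-and-recover behavior seen for this
  sensor class but not for CFP/YFP sensors;
- T/A phospho-null mutants are constant at baseline regardless of
  treatments.

The exact functional forms are a design choice — only the landmarks (peak
time, time-to-minimum, undershoot depth and recovery, flat T/A response) are
observationally constrained — and every rate is a parameter.

### Sensor presets

`sensor_preset()` bundles profile and response parameters so that the
noise-free dynamic range and the post-inhibition EfA noise variance equal
the values measured for each sensor on real cells:

| preset | EfA range | noise-free dynamic range | window noise variance |
|---|---|---|---|
| EKAREN4 | 0.30–0.65 | 0.203 | 0.0037 |
| REKAR67 | 0.15–0.40 | 0.130 | 0.009 |
| REKAR76 | 0.15–0.40 | 0.100 | 0.007 |
| REKAR67-TA / REKAR76-TA | 0.15–0.40 | 0 (flat) | as functional |

Noise in these presets is placed directly on EfA (the calibrated post-ratio
mode) so a generated population's window variance is exactly the stated
value; an intensity-noise mode (additive Gaussian per channel per frame,
reflecting the shared-excitation configuration that makes this sensor class
noisier) is available and is what the recovery tests exercise. Per-cell
heterogeneity enters as mean-one lognormal multipliers on expression
(brightness) and on activity amplitude; each cell draws from its own RNG
stream keyed by (seed, cell index), so any subset of cells is reproducible
and a fixed seed yields byte-identical tables.

### What the generator does not emulate

Segmentation and tracking artifacts, photobleaching, chromophore (biliverdin)
maturation kinetics, spatial context, cell division and death, and any
temporal correlation in the measurement noise. The last point matters most
for interpretation: see *Limitations*.

## The processing pipeline

`quantify_tracks()` converts channel intensities to EfA;
`filter_tracks()` then applies the two track-quality rules: a track must
cover **more than 85%** of the movie's frames, and its EfA values must stay
inside the sensor's operating range (EKAREN4 0.30–0.65, REKAR variants
0.15–0.40; both bounds inclusive). The strict reading — *any* out-of-range
frame rejects the track — is the default; a mean-based variant is
configurable. Every removal is logged with the rule that fired, and the
filter is idempotent.

For cross-sensor comparison: traces are smoothed with a centered 3-point
moving average (window shrinking at the edges, missing frames excluded),
floored by subtracting each trace's minimum, scaled by a sensor-to-reference
factor and multiplied by a per-sensor normalizing value (defaults: factors
1.5679 / 3.0042 for REKAR67 / REKAR76 with EKAREN4 at 1; normalizing values
5 / 3 / 4). `compute_scaling_factor()` estimates the factor from dual-sensor
cells as the cell-mean of the framewise reference-to-sensor ratio, taken
over frames where the sensor signal exceeds 5% of that cell's reference
maximum (avoiding 0/0 near the rebased baseline) and then averaged across
cells pooled over replicates. The orientation (reference over sensor) is
chosen so the factor up-scales the smaller-range sensor, consistent with the
published factors exceeding 1. When the two sensors share their kinetic
shape this estimator recovers the true amplitude ratio exactly; when shapes
differ (the undershoot), frames where one sensor is at zero and the other is
not pull the framewise mean down, so the fixed published constants remain
the default for normalization. Missing frames are never interpolated —
interpolation would fabricate noise structure.

## Characterization and statistics

Per cell, on the raw (unsmoothed) retained EfA trace:

- **Signal** — dynamic range, max minus min (`dynamic_range()`). Smoothing
  is part of the plotting/scaling path only, so it is deliberately not
  applied here.
- **Noise** — unbiased (n−1) sample variance over the closed window from 2 h
  to 5 h after inhibitor addition (31 frames at 6-min sampling), when true
  ERK activity is fully suppressed (`noise_variance()`). With ~31 frames the
  n vs n−1 choice shifts the estimate by ~3%, so it is fixed and documented;
  an alternative first-difference reading of "frame-to-frame variance" was
  considered and rejected in favor of the plain window variance, which is
  what the characterization procedure describes.
- **SNR** — the cell's Signal divided by its own Noise. The population SNR
  is the mean of per-cell ratios, *not* the ratio of mean Signal to mean
  Noise; with per-cell noise in the denominator these differ noticeably.

Cells are averaged within each technical replicate, and the technical-
replicate means pooled across experimental replicates form the statistical
sample — so inference is on replicates, not on (pseudo-replicated) cells.
`compare_groups()` runs a one-way ANOVA and all pairwise Tukey–Kramer
comparisons (the studentized-range procedure with unequal group sizes;
for balanced designs it reduces to Tukey's HSD). All pairs are computed;
reporting is filterable.

## Problem sizes

The shipped tests and the reproduction script use deliberately desk-scale
designs: inversion checks on a 100-point EfA grid times 50 random ratio
sets; 50 dual-sensor cells for exact zero-noise recovery; 1,000 cells for
noise-estimator calibration (mean recovered variance within 5%, and the
scaled estimates consistent with a $\chi^2_{30}$ law); and 8 technical × 3
experimental replicates of 25 cells per sensor for the comparative
statistics, repeated over 20 seeds where run-to-run reproducibility is the
question. These sizes were chosen to make every sampling-based check
well-powered while keeping a full run in minutes on one core.

## Limitations

- **Range statistics under i.i.d. noise.** The max-minus-min dynamic range
  is an extreme-value statistic: with i.i.d. Gaussian frame noise of
  standard deviation $\sigma$ over ~100 frames it inflates by roughly
  $5\sigma$ regardless of the underlying activity amplitude. At the noise
  level this sensor class exhibits post-inhibition (variance 0.009, i.e.
  $\sigma \approx 0.095$ on the EfA scale), the inflation term (~0.47)
  *dominates* the true amplitude (0.13). Two consequences follow. First,
  simulated Signal estimates sit far above the generating amplitude, and
  T/A null sensors — whose entire range is noise — are not separable from
  functional sensors by range alone. Second, reported per-cell variances of
  that magnitude cannot coexist with reported dynamic ranges of ~0.13 (or
  with a per-frame range filter at 0.15–0.40) under any i.i.d. noise model;
  real traces evidently carry their window variance in slow components
  rather than frame-to-frame jitter. The simulator's noise model is
  i.i.d. by construction (it is what makes the $\chi^2$ calibration of the
  noise estimator exact), so comparisons that are robust to the inflation
  (Noise itself, ordering of Signal between sensors) behave as on real
  data, while absolute Signal levels and SNR ratios do not. Analyses that
  need noise-robust amplitude estimates should use quantile ranges or
  smoothed extrema instead of the raw range.
- **The spectra shipped with the package are synthetic.** They are
  internally consistent and shaped like the real pair (small Stokes shifts,
  long red emission tails) but are stand-ins; computed ratios from them will
  not reproduce any particular instrument's calibration. Users should supply
  their own spectra CSVs or calibrate directly.
- No fluorescence-lifetime model, no pH-sensitivity model, no
  Förster-radius/dipole-orientation physics: the model operates at the EfA
  product level only.
- No image processing: the package starts from track tables; segmentation
  and tracking are upstream concerns.

## Session info

```{r}
sessionInfo()
```
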