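---
title: "Chronic FSCV dopamine analysis: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chronic FSCV dopamine analysis: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fscvr)
```

This vignette is the package's own account of the methods it implements:
the signal and image models, the tunable parameters and why their defaults
are what they are, the numerical choices, and what validation on synthetic
data does and does not demonstrate about real recordings.

## The voltammetric data model

One FSCV scan applies a triangular potential program and digitizes the
current on a fixed grid. `build_waveform()` represents the program by its
holding potential (−0.4 V default), apex (1.3 V), sweep rate (400 V/s),
repetition frequency (10 Hz) and samples per scan (214). The grid ascends
from hold to apex over the first half (the anodic sweep, 108 samples
including the shared apex sample) and descends over the second (cathodic).
Two conventions are worth stating:

- **The inter-scan hold is not digitized.** Sessions contain only in-scan
  samples, which is what a fixed "samples per scan" count implies; the
  electrode sits at the holding potential between scans but contributes no
  rows.
- **Potential offsets shift the applied program only.** In vivo an offset
  of 0.1–0.3 V compensates drift of the implanted Ag/AgCl reference. The
  offset is stored with the waveform, and every potential query (e.g.
  "current at +0.6 V") is interpreted on the offset-corrected chemistry
  axis, so analysis code never needs to know the offset.

`current_at_potential()` uses nearest-sample lookup rather than
interpolation: the grid step is 2·(v_peak − v_hold)/n ≈ 16 mV, an order of
magnitude narrower than the redox peaks (σ ≥ 150 mV), so the lookup error
is negligible and the result is deterministic.

Background subtraction (`subtract_background()`) removes the capacitive
current by subtracting the per-sample mean of a background scan window.
The default window is ten scans ending one second before the recorded
stimulation window — a pre-stimulus baseline, standard practice when no
window is supplied explicitly. Subtraction is idempotent, and the window's
column means vanish by construction; both are tested properties.

## Synthetic data: what is emulated

The generators exist so every stage can be validated against known ground
truth. They emulate the features that matter to the analysis and nothing
more:

- **Dopamine CV template** (`make_da_template()`): Gaussian oxidation bump
  at +0.6 V (σ = 0.15 V) on the anodic half, reduction bump at −0.2 V
  (σ = 0.2 V, amplitude ratio −0.4) on the cathodic half, exactly linear
  in concentration. Peak positions are the empirical dopamine redox
  potentials under this waveform; Gaussian shapes are the simplest choice
  honoring them while remaining resolvable on the 16 mV grid. The default
  sensitivity slope of 50 nA/µM is the scale reported for carbon-fiber
  microsensors of this class (in vitro fits around 52 nA/µM).
- **pH template** (`make_ph_template()`): a fixed difference of two wide
  Gaussians spanning the sweep, linear in ΔpH and restricted to
  |ΔpH| ≤ 0.4 (the physiological calibration range, pH 7.2–7.6 around
  7.4). Its correlation with the dopamine template is ≈ 0.31 in absolute
  value — interference is broad and *weakly* correlated, which is exactly
  what makes PCR separation possible and is asserted in a test.
- **Capacitive background**: a square-wave CV (+A on the anodic half, −A
  cathodic, A = 900 nA default) with optional linear drift. Real FSCV
  backgrounds have more structure, but only the magnitude (the
  functionality rules and sensitivity normalization use it) and the drift
  (which PCR must not confuse with dopamine) matter downstream.
- **Flow-cell sessions**: boluses at 0.25/0.5/1 µM (three replicates) over
  the background, plus white Gaussian current noise of 0.1 nA RMS — the
  in vitro noise scale of these sensors. Ground truth logs each bolus
  window.
- **Evoked sessions**: Δ[DA](t) rises linearly over the stimulus train
  (0.4 s default — 24 biphasic pulses at 60 Hz) to the configured peak,
  then decays as a single exponential (τ = 150 ms default), giving a
  closed-form decay to half-maximum of τ·ln 2. Current noise defaults to
  the chronic in vivo scale of 0.04 nA RMS. A pH transient with slower
  relaxation (τ = 2 s) can be superimposed. Sessions default to 10 s with
  stimulation at 5 s — a typical stimulation-evoked recording epoch.
- **Fault sessions**: perforated insulation (2.5 nA noise), broken fiber
  (50 nA background), and saturated input (background beyond the rails,
  clipped at ±2000 nA).
- **Histology images**: a zero-intensity displacement hole of configurable
  radius, a Gaussian halo of configurable peak (relative to background 1)
  and width, flat background plus Gaussian count noise; exactly
  rotationally symmetric before noise. Defaults (1300 µm square, 1 µm
  pixels, origin at the center) guarantee that rays at any angle reach the
  620 µm background annulus.

**What is not modeled** — and therefore what passing tests do *not* show:
adsorption kinetics and electrode history effects, diffusion-distorted in
vivo transient shapes, structured (non-white) noise and movement
artifacts, background drift nonlinearity, multi-marker image composition,
and anatomical asymmetry around implant tracks. Parameter-recovery results
on this synthetic data validate the *estimators*, not the biology.

## Principal-component regression

`fit_pcr()` mean-centers the standard CVs, computes a PCA, retains the
smallest number of components reaching a cumulative explained-variance
threshold (default 0.995), and regresses the known labels — dopamine in
nM, ΔpH in pH units, each zero for the other group — on the scores by
least squares with intercept. Choices worth recording:

- **Component floor.** Whenever pH standards are present, k is floored at
  2: the model must span both the dopamine and the pH subspaces or the
  regression cannot reject interference. With noiseless templates two
  components capture 100% of the variance.
- **Exactness.** Because labels are linear in the template coefficients
  and the standards span the template space, the noiseless calibration is
  exact: standards self-predict, a zero CV maps to zero concentration, and
  prediction is linear (α·CV ↦ α·Δ[DA]). These identities are tested, as
  is agreement with a direct minimum-norm least-squares oracle on tiny
  instances.
- **No residual filtering by default.** A Q-statistic screen on
  reconstruction residuals is a common addition but is not part of the
  described procedure; the package computes scores for any CV it is given.
- **Global calibration.** Standards are treated as one global set rather
  than per-probe; per-probe recalibration is a transfer problem outside
  scope.
- **Concentration noise** is the RMS of the projected Δ[DA] over the
  background window of the same recording, matching the definition of
  noise as RMS of background fluctuations; LOD = 3 × that value.

In principal-component score space, dopamine and pH standards form two
*lines* through the origin region (each group is elongated by its
concentration/ΔpH range), not compact blobs. `cluster_separation()`
reports centroid distance over pooled within-group RMS spread — the
conventional statistic — but for line-shaped groups that statistic is
bounded near 1 by the within-group spread itself. The sharper and tested
statement of separation is geometric: every CV lies nearer its own group's
principal line than the other group's, and evoked-recording CVs lie on the
dopamine line and off the pH line.

## Sensor metrics

Sensitivity is an OLS fit of oxidation current (at the +0.6 V anodic
sample) against concentration. Normalized sensitivity divides the per-nM
slope by the background current; as the proxy for "apparent capacitance"
the package uses the maximum |current| of the raw background CV, since the
capacitive plateau magnitude is what scales with exposed fiber area. The
functionality rules are applied in a fixed order — saturation, low
background, high noise — so a session violating several reports a single
deterministic reason; the order puts the coarsest hardware failure first.

For evoked kinetics, the decay from maximum to half-maximum is estimated
by **log-linear interpolation** between the two samples bracketing the
half-crossing. Plain linear interpolation of a convex exponential sampled
at 100 ms overestimates the crossing by up to ~10 ms at τ = 100 ms, which
is larger than the 5 ms accuracy the validation demands; log-linear
interpolation is exact for single-exponential decays and falls back to
linear when a bracketing sample is nonpositive (as noise can make it).
Peaks must exceed 3 × the concentration noise or a no-transient error is
raised; a trace that never falls to half-maximum yields `NA` with a
warning.

Geometry and mechanics are closed forms (πd²/4, E·πd⁴/64, E·A/L) with SI
conversion handled internally. Young's moduli are user inputs — material
properties, not measurement results; the documented defaults used in
examples are 72 GPa (fused silica) and 234 GPa (carbon fiber).

## Radial histology profiling

`radial_profile()` implements ray sampling: rays every 0.5° across the
requested arc (default 90°, chosen by the analyst to avoid anatomical
boundaries), bilinear interpolation at each 2 µm bin center from the
origin to 500 µm, averaging over rays per bin, and normalization by the
mean over the same rays at 600–620 µm. Ray semantics follow the
"radial lines at 0.5° intervals" procedure; a brute-force per-pixel
annulus average over the same arc serves as the independent oracle in the
tests, agreeing within 2% away from the innermost bins (where an annulus
holds only a handful of pixels). The profile includes the hole interior
(bins near zero intensity); `peak_relative_intensity()` takes an
`exclude_hole_um` argument for peak searches, and
`displacement_radius()` scans outward for the first bin within 10% of
background — the tolerance is a package choice, as "reached background"
needs an operational definition. A flat profile returns displacement 0.
Multi-channel registration is assumed done upstream: one origin is marked
per section and reused across channels.

## Longitudinal statistics

Trends are OLS slopes of a metric against days postimplant with Pearson R
and the two-sided t-test of R against zero (n − 2 df). Z-scores use the
sample (n − 1) standard deviation. Month bins use 30-day edges with ">3
months" meaning day > 90; bin summaries report 1.96 × SEM confidence
half-widths, undefined (and flagged) for single-record bins. Group
comparisons use the unpaired equal-variance two-tailed t-test and classic
one-way ANOVA; no multiple-testing correction is applied, and reports say
so. Null calibration (uniform p-values, type-I error ≈ α) is verified by
simulation in the test suite.

## Numerical and validation choices

- All generators accept a seed, restore the caller's RNG state, and are
  bit-reproducible; tests and the acceptance script derive every random
  input from explicit seeds.
- Validation problem sizes are chosen to keep the full suite fast at desk
  scale while leaving estimator error well below the asserted tolerances:
  100 evoked simulations for parameter recovery (median peak error < 10%),
  20 sessions for the CV-correlation floor, 30 random halo configurations
  for histology recovery (median peak error < 5%, displacement within one
  bin), 1000 null simulations for test calibration.
- Degenerate inputs fail loudly: empty or out-of-range background windows,
  rank-deficient calibrations, constant metrics in trend fits, zero
  standard deviations in Z-scores, arcs that exit the image before the
  background annulus.

## Known limitations

The PCR model carries no drift component unless drift appears in the
standards; strongly drifting sessions should be background-subtracted
against a window close to the event of interest. The pH rejection
guarantee is exact only for the template family the model was calibrated
on; real interferents (adenosine, oxygen, movement) are not modeled. The
histology profiler assumes a manually marked origin and a single channel;
it does not detect tracks or unmix stains. Longitudinal tools treat
sessions as independent observations — no mixed-effects structure across
probes or animals is fitted.
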