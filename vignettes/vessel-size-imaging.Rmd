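---
title: "Vessel size imaging from SAGE-EPI DSC-MRI: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel size imaging from SAGE-EPI DSC-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsimetry)
```

## The problem

Glioma neovasculature is abnormal in both density and caliber, and the two
carry different information: relative cerebral blood volume (rCBV) from
dynamic susceptibility contrast (DSC) MRI tracks how *much* vasculature a
voxel holds, while the ratio of gradient-echo to spin-echo relaxation-rate
changes tracks how *large* the vessels are, because spin-echo contrast is
weighted toward capillaries (radius below roughly 10 µm) and gradient-echo
contrast responds to vessels of all sizes. A vessel size index (VSI) built
from both, plus a diffusion correction, can be compared voxel-for-voxel
against vessel morphometry from stained biopsy tissue. This package
implements that whole comparison pipeline — MRI model inversion, map
computation, histology morphometry, and the agreement statistics — together
with a synthetic-data generator so every stage can be verified against a
known ground truth.

## The MRI signal model and its inversion

A spin-and-gradient-echo (SAGE) EPI readout acquires four echoes per shot:
two gradient echoes (TE₁, TE₂), an asymmetric spin echo (TE₃) and the spin
echo (TE₄); the default acquisition uses 14.0, 34.1, 58.0 and 92.4 ms. With
`S0` the unattenuated signal, `δ` the multiplicative residual between the
pre- and post-refocusing echo trains (imperfectly matched slice profiles),
and rates in ms⁻¹, the log-signals are linear in the parameter vector
`A = (ln S0, ln δ, R2*, R2)`:

```
ln S1 = ln S0 − TE1·R2*
ln S2 = ln S0 − TE2·R2*
ln S3 = ln S0 − ln δ + (TE3 − TE4)·R2* + (TE4 − 2·TE3)·R2
ln S4 = ln S0 − ln δ − TE4·R2
```

Four echoes, four unknowns: the system is exactly determined and the fit is
a single linear solve per voxel per timepoint (`sage_design_matrix()`,
`fit_sage_voxel()`, `fit_sage_series()`), not a least-squares problem. Two
consequences shape the test design: on noiseless data the inversion must be
exact to numerical precision, and scaling all four signals rescales only
`S0` — both are asserted as properties. The constraint `TE3 > TE4/2` keeps
the design matrix well-posed and matches the printed echo times. Voxels
with non-positive signals are masked rather than raising errors, because a
single bad voxel must not abort a volume fit; the fraction of invalid fits
is reported as a QC quantity, alongside the maximum percent variation of
the fitted `δ` over time (a slice-profile stability diagnostic — `δ` should
be time-constant when the model holds).

## From rate time courses to maps

`delta_curves()` subtracts the pre-bolus baseline mean from `R2*(t)` and
`R2(t)`. Bolus arrival is detected on the volume-mean `R2*(t)` curve as the
first timepoint exceeding the provisional baseline by five baseline
standard deviations, and the default window is timepoints 5 through
(arrival − 3) — standard DSC practice. Peak changes ΔR2\*max and ΔR2max are
independent curve maxima after a 3-point moving average (smoothing on by
default; configurable, since the smoothing of the source curves is a
genuinely open choice). Voxels whose peak is negative are marked invalid
rather than clipped to zero, so they cannot masquerade as zero-caliber
vessels downstream.

rCBV is the trapezoidal integral of the leakage-corrected ΔR2\*(t) curve
(`compute_cbv()`), normalized so the mean over a user-supplied
normal-appearing white matter (NAWM) mask is exactly 1
(`normalize_cbv()` — idempotent and scale-invariant by construction). The
integration window defaults to the full post-arrival series including
recirculation, consistent with the leakage model below.

Contrast leakage in enhancing tumor distorts ΔR2\*(t). `leakage_correct()`
regresses each voxel curve on a reference curve from non-leaky tissue plus
leakage terms and reconstructs the curve without them. The unidirectional
model uses the running integral of the reference (efflux); the
bidirectional default adds the double integral, a first-order term for
contrast flux back into the vasculature. This two-term linear form is this
package's own formulation of a bidirectional correction in the
Boxerman-style family; it is deliberately simple, linear per voxel, and is
validated against simulated leaky voxels rather than against any external
implementation.

ADC comes from an ordinary least-squares fit of `ln S` against b over the
acquired b-values (default 0/500/1000 s/mm²), negated and converted to
µm²/ms (1 µm²/ms = 10⁻³ mm²/s).

## The vessel size index

With rates in ms⁻¹ and ADC in µm²/ms, the map is

```
VSI = 0.867 · sqrt(rCBV · ADC) · ΔR2*max / ΔR2max^(3/2)   [µm]
```

The grouping matters: the gradient-echo peak divided by the 3/2 power of
the spin-echo peak. The alternative reading — the 3/2 power of the ratio —
is rejected here because it is dimensionally inconsistent with a result in
µm given these units ((µm²/ms)^½ · ms^½ = µm only with the adopted
grouping). The constant 0.867 is exposed as `constant_k` because its
absolute calibration between MRI and histology is not settled. Voxels with
non-positive spin-echo peaks or negative `rCBV·ADC` are invalid.

On the histology side, segmented vessels are summarised as randomly
oriented continuous cylinders:

```
VSI_histo = ( Σ n(rᵢ)·rᵢ^(4/3) / Σ n(rᵢ)·rᵢ² )^(−3/2)   [µm]
```

implemented literally with the −3/2 exponent on the ratio; this is
algebraically identical to `(Σn·r² / Σn·r^(4/3))^(3/2)`, the form more
often seen in the literature, and the identity is tested. Useful exact
properties: a monodisperse set returns its radius; the summary is
scale-equivariant; and it always lies within `[min(r), max(r)]`. (It is
*not* generally above the arithmetic mean radius, so no such bound is
asserted.)

## Histology segmentation and morphometry

`segment_vessels()` works in HSV space: pixels inside the vessel
hue/saturation/value gates are seeds, a relaxed gate defines the growable
region, and connected components containing at least one seed are kept.
`refine_objects()` then applies four refinement tasks in order: joining
fragments separated by at most `join_distance_um` (default 5 µm),
morphological closing (`closing_radius_px`, default 2 px) so lumens become
true holes, splitting objects with two or more interior lumens above
`min_lumen_area_px` (default 10 px²) by seeded propagation between the
lumens, and hole-filling so the lumen counts toward vessel area. These
three numeric defaults are this package's own, exposed in the
configuration; the per-object radius is the equivalent-circle radius
`sqrt(area/π)·µm_per_px` computed from the filled object (a minor-axis
alternative would suit strongly oblique sections, which the default
renderer does not produce). Density is object count divided by field area
(N/mm²). Per-target morphometry averages density and VSI over three
regions of interest; ROI placement within a slide is not standardised
anywhere, so the default is three random non-overlapping tiles under a
seed, with a stained-fraction "hotspot" mode as an option. Manual
correction of segmentations is replaced by an optional mask override — no
interactive editing.

## Biopsy targets and agreement statistics

`extract_target()` summarises a map over a 5-mm-radius sphere by the median
of all valid voxels whose centres fall inside (median because per-target
map summaries are conventionally reported as medians; mean available).
Sphere membership is by voxel-centre distance with no partial-volume
weighting — chosen so a brute-force enumeration can verify it exactly.

The agreement layer (`build_report()`) computes the four Pearson
correlations (rCBV and VSI_MRI against density and caliber), Bland–Altman
mean difference and limits of agreement `mean ± 1.96·SD` of the per-target
VSI differences (sample n−1 SD — the convention is not universal, so it is
stated), Mann–Whitney U comparisons between WHO grade III and IV targets
(exact for small untied samples), Shapiro–Wilk normality checks, and a
t-test of the VSI difference. The targets are intrinsically paired, so the
paired t-test is the default, with the unpaired variant available. The
standard tests are delegated to the stats routines every R user already
trusts (`cor.test`, `wilcox.test`, `shapiro.test`, `t.test`); the package's
own contribution is the pipeline that produces their inputs.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage has an oracle; its defaults are
the study conditions the pipeline is meant to emulate:

* **Phantom classes.** Tumor ADC 1.30 µm²/ms; tumor peak ΔR2\* 1.39× the
  NAWM peak, so the NAWM-normalized tumor rCBV is 1.39; tumor peak ΔR2
  chosen so the tumor-class ground-truth VSI is 13.67 µm. NAWM peaks use a
  ΔR2\*/ΔR2 ratio of 1.25 — a plausible white-matter value. The often-cited
  normal-tissue VSI near 4.5 µm is *not* reproduced by these defaults: with
  the physical constraint that the gradient-echo effect be at least the
  spin-echo effect, and plausible white-matter ADC, such a value would
  require ΔR2\* < ΔR2, so it is treated as a plausibility reference only.
* **Bolus.** A peak-normalised gamma-variate (mode at `t0 + α·β`) with an
  optional delayed, dispersed recirculation pass. The acquisition protocol
  does not pin down bolus timing or width, so the defaults are a
  physiologically plausible choice made once: α = 3, β = 3.5 s gives a
  first pass roughly 10–15 s wide, properly sampled at TR = 2 s. ΔR2\*(t)
  and ΔR2(t) are the class peaks times this one curve, so each class's
  ΔR2\*/ΔR2 ratio is constant over the bolus and its ground-truth VSI is
  well defined.
* **Leakage.** A leaky class adds `leakage_rate` times the
  back-flux-decayed running bolus integral to its observed ΔR2\*(t). The
  leaky test condition uses `leakage_rate = 2e-4`, which distorts the
  uncorrected integral by roughly 45 % — representative of strong
  extravasation in enhancing tumor.
* **Noise** is additive Gaussian per echo sample, not Rician. At the
  simulated signal levels the log-domain fit stays far from the Rician
  floor, and the inversion is linear in log-signal; this is a documented
  simplification, and one reason passing tests do not certify behaviour at
  very low SNR.
* **Slides** are rendered as stained endothelial rings around paler
  lumens, counterstained nuclei, and a pale background — the three-hue
  structure the segmenter exploits. Vessels are perpendicular circular
  sections by default (an oblique-ellipse flag exists); the
  cylinder-orientation correction is exercised analytically through the
  VSI formula, not pictorially. Default radii are lognormal
  (sdlog 0.3) with the meanlog set so the *expected* cylinder-model VSI is
  12.6 µm, and the default field carries 41 vessels in 1 mm². Real slides
  differ in ways the renderer does not attempt: stain variability,
  overlapping and collapsed vessels, tissue folds, out-of-focus blur.
* **Cohorts.** `make_paired_cohort()` draws paired (rCBV, density) and
  (VSI_MRI, VSI_histo) values from bivariate-normal latents at requested
  correlations (defaults 0.42 and 0.49), with marginal means at the
  emulated cohort's medians (1.39, 40.6 /mm², 13.67 µm, 12.60 µm) and
  spreads consistent with its interquartile ranges; 17 of 26 targets are
  labelled grade III. Truncation of negative draws slightly attenuates the
  realised correlations for high-variance variables — visible in recovery
  experiments as a small downward bias, and accepted as the price of
  positivity.

Because no raw patient data accompany the emulated study, its
patient-level numbers are not reproduction targets; the validation is
property-based (exact inversion, exact identities, ground-truth recovery,
statistical calibration).

## Numerical choices and degenerate inputs

* Baseline windows must hold at least 3 timepoints and must not contain
  the bolus peak (refused with an error); a series with no detectable
  bolus uses the whole series as baseline, making Δ-curves exactly zero.
* The design-matrix solve asserts non-singularity even though valid echo
  times cannot produce a singular matrix.
* Empty vessel sets yield density 0 and an NA (flagged) VSI — never a
  fabricated zero radius.
* Sphere extraction errors when no valid voxel falls inside, rather than
  returning a silent NA.
* Packing failures in the renderer are explicit errors, never silent
  truncation of the vessel count.

## Problem sizes

The test suite and the acceptance script run: exact-inversion checks on
1000 random parameter draws; end-to-end recovery on a noiseless
32 × 32 × 8 phantom with 40 timepoints; a 1000 × 1000 px slide with 50
vessels; 500 simulated 26-target cohorts for statistical calibration; and
a leaky 16 × 16 × 4 phantom at SNR 100. These sizes were chosen so the
whole suite completes in about a minute while every assertion still has
the resolution it needs (e.g. the bolus-peak discretization error at
TR = 2 s is ~2 %, well inside the 5 % end-to-end band).

## Known limitations

* No arterial input function deconvolution: rCBV is a normalized integral,
  not absolute blood volume, and the VSI inherits that approximation.
* No image registration: maps and targets must share one coordinate frame.
* The bidirectional leakage model is a first-order linear variant, not a
  pharmacokinetic fit; `k_back` is a regression coefficient, not a rate
  constant with units.
* Gaussian (not Rician) noise in the simulator; very low SNR behaviour is
  untested.
* The renderer's idealised slides mean segmentation accuracy on real
  stained tissue will be worse than the synthetic oracle suggests; the
  hue gates and morphology radii will need tuning per staining protocol.

## A short worked example

```{r example, eval = FALSE}
library(vsimetry)

run <- run_pipeline(default_run_config(seed = 1))
run$targets          # per-target paired MRI and histology values
glance(run$report)   # Bland-Altman + headline correlations
autoplot(run$report) # Bland-Altman plot
```
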