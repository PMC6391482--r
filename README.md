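# vsimetry

Vessel size imaging (VSI) from spin-and-gradient-echo (SAGE) EPI DSC-MRI,
validated against quantitative histology — as a reusable, fully testable R
pipeline.

In high-grade glioma, relative cerebral blood volume (rCBV) from dynamic
susceptibility contrast (DSC) perfusion MRI reflects how *much* vasculature
a voxel contains, while the ratio of gradient-echo to spin-echo
relaxation-rate changes reflects how *large* its vessels are (spin-echo
contrast is capillary-weighted; gradient-echo contrast sees all calibers).
`vsimetry` implements the complete chain needed to compute a vessel size
index map from a four-echo SAGE acquisition and compare it, target by
biopsy target, against vessel morphometry from endothelium-stained tissue
sections. It is written for imaging scientists building or validating
perfusion-based microvascular biomarkers.

## The models

**SAGE inversion.** Each repetition acquires four echoes (two gradient
echoes, an asymmetric spin echo, the spin echo; default TEs 14.0 / 34.1 /
58.0 / 92.4 ms). The log-signals are linear in
`A = (ln S0, ln δ, R2*, R2)`, where δ absorbs the residual between the
pre- and post-refocusing echo trains:

    Y A = (ln S1, ln S2, ln S3, ln S4)ᵀ

with the 4×4 coefficient matrix `Y` built from the echo times. Four
equations, four unknowns: the per-voxel, per-timepoint fit is an exact
linear solve. Baseline-referenced ΔR2\*(t) and ΔR2(t) curves and their
peaks follow.

**Maps.** rCBV = trapezoidal integral of the leakage-corrected ΔR2\*(t),
normalized to a mean of 1 over normal-appearing white matter; ADC from the
log-linear fit over b = 0/500/1000 s/mm²; and the vessel size index

    VSI [µm] = 0.867 · √(rCBV · ADC) · ΔR2*max / ΔR2max^(3/2)

with ADC in µm²/ms and rates in ms⁻¹ (the unit combination that makes the
result micrometres).

**Histology.** Stained vessels are segmented by HSV seed-and-grow,
refined (join / close / split multi-lumen / hole-fill), and summarised as
vessel density (N/mm²) and the randomly-oriented-cylinder radius summary

    VSI_histo [µm] = ( Σ n(rᵢ)·rᵢ^{4/3} / Σ n(rᵢ)·rᵢ² )^{−3/2}

**Agreement.** Per-target medians over 5-mm spherical targets, Pearson
correlations, Bland–Altman limits of agreement, Mann–Whitney grade
comparisons, Shapiro–Wilk and paired t tests.

A synthetic-data module generates SAGE time series, DWI stacks, rendered
stained slides and paired cohorts with known ground truth, so every stage
is tested against an oracle. See the methods vignette
(`vignettes/vessel-size-imaging.Rmd`) for the full model account, all
tunable parameters, and design decisions.

## Worked example

```r
library(vsimetry)

run <- run_pipeline(default_run_config(seed = 1))
run$targets[, c("target", "grade", "rcbv", "adc", "vsi_mri", "density", "vsi_histo")]
#> # A tibble: 4 × 7
#>   target grade  rcbv   adc vsi_mri density vsi_histo
#>    <int> <chr> <dbl> <dbl>   <dbl>   <dbl>     <dbl>
#> 1      1 III    1.34  1.30    13.5    51.4      8.05
#> 2      2 IV     1.41  1.30    14.2    51.4     10.8
#> 3      3 III    1.37  1.29    13.0    66.1      8.92
#> 4      4 IV     1.39  1.30    13.8    66.1     11.2

run$report
#> MRI-histology agreement report (4 targets)
#>   Bland-Altman VSI (MRI - histology): mean 3.91 um, LoA [1.54, 6.27]
#>   rcbv_vs_density        r =  0.12, p = 0.882
#>   rcbv_vs_caliber        r =  0.92, p = 0.080
#>   vsi_mri_vs_density     r = -0.52, p = 0.483
#>   vsi_mri_vs_caliber     r =  0.70, p = 0.296
#>   VSI difference t-test (paired): p = 0.008
```

The demo run simulates a noisy 32×32×8 phantom whose tumor class has
ground-truth rCBV 1.39, ADC 1.30 µm²/ms and VSI 13.67 µm: the per-target
MRI medians above recover those values through the full fit → correct →
normalize → combine chain. The histology columns come from rendered
stained slides pushed through segmentation and morphometry; at four
targets the correlations are illustrative only (the statistics module is
calibrated on 500 simulated 26-target cohorts in the test suite).
`autoplot(run$report)` draws the Bland–Altman plot and
`plot_correlations(run$report)` the four scatter panels.

A thin command-line wrapper is installed at `inst/exec/vsimetry`
(`vsimetry run --config cfg.yaml --out DIR`); the bundled demo
configuration lives at `inst/extdata/demo_config.yaml`.

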