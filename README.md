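# bhdsc — breath-hold dynamic susceptibility contrast perfusion MRI

`bhdsc` estimates relative cerebral perfusion — blood volume (CBV), blood
flow (CBF), mean transit time (MTT) and bolus delay — from breath-hold
gradient-echo (T2\*-weighted) MRI time series, without gadolinium and
without a gas control system. It is aimed at perfusion-MRI researchers who
want a contrast-free DSC analysis, and at methods developers who need a
fully synthetic test bed: the package ships a multi-compartment GRE signal
simulator that generates breath-hold datasets with known ground truth and
quantifies the perfusion bias that dynamic vasodilation introduces.

## The model

A paced breath-hold (10 s preparation, 16 s hold, 34 s recovery, nine
blocks) raises arterial CO₂; cerebrovascular reactivity raises flow, and
the transient washout of deoxyhemoglobin acts as an endogenous
paramagnetic bolus. Signal is converted to the apparent relaxation-rate
change

  ΔR₂\*(t) = −(1/TE) · ln( S(t) / S₀ ),

and analysed with indicator dilution theory. Because arterial blood is
near-saturation, the arterial input function (AIF) cannot be a dOHb bolus;
instead, voxels in which *vasodilation* (high-R₂\* blood displacing CSF and
tissue) produces a **negative** signal change — magnitude above the 99th
percentile, short delay — are averaged into a vasodilation-based AIF. The
AIF is scaled by the integral of a venous output function (VOF; 99.9th
percentile, long delay, low S₀):

  AIF_scaled(t) = ( ∫VOF dt / ∫AIF dt ) · AIF(t),

which also flips it into the tissue sign convention. Perfusion then
follows the standard truncated-SVD deconvolution with hematocrit
correction k_H = 1.45, brain density ρ = 1.05, and a 20 % singular-value
threshold:

  CBV = (k_H/ρ) · ∫c_tissue / ∫AIF_scaled,  c_tissue = A k,
  CBF = (k_H/ρ) · max k(t),  MTT = CBV / CBF,

with A the lower-triangular convolution matrix of the scaled AIF. Delay
maps come from shifting the AIF forward in 0.5 s steps (up to 8 s) and
maximising the correlation per voxel.

The simulator represents a voxel as tissue + CSF + arterial/capillary/
venous blood, S(t) = S₀ Σᵢ fᵢ(t) exp(−TE·R₂ᵢ\*(t)), with a quadratic
intravascular oxygenation dependence, a linear extravascular
(static-dephasing) term, and vasodilation that displaces CSF first, then
tissue. See the methods vignette (`vignettes/bhdsc-methods.Rmd`) for the
calibration anchors and every numerical choice.

## Worked example

Simulate a 7 T breath-hold phantom (8×8×2 voxels: 18 artery, 18 vein,
46 gray-matter at CBV 4 %, 46 white-matter at CBV 2 %, mid-typical 6.5 %
tissue vasodilation, calibrated noise) and run the full fit:

```r
library(bhdsc)
ph  <- generate_phantom(seed = 42)
reg <- ph$truth$region
fit <- bhdsc(ph$ts,
             artery_mask = reg == 1, vein_mask = reg == 4,
             gm_mask = reg == 2, wm_mask = reg == 3)
fit
#> Breath-hold DSC fit (7 T, TR 2 s, TE 20 ms)
#> AIF: 15 voxels, integral +11.4 | VOF: 15 voxels, integral -629
#> scaling ratio -55.3; deconvolution window 14.0-52.0 s
#> GM-to-WM CNR contrast: 5.40
summary(fit)
#> Perfusion (valid voxels):
#>  region parameter  n     mean       sd     cv
#>      gm       CBV 46  0.02896 0.003186 0.1100
#>      gm       CBF 46  0.00301 0.000379 0.1260
#>      gm       MTT 46  9.68901 0.938937 0.0969
#>      wm       CBV 46  0.01356 0.002917 0.2151
#>      wm       CBF 46  0.00101 0.000195 0.1921
#>      wm       MTT 46 13.45398 1.970493 0.1465
```

Reading the numbers: the AIF integral is positive (apparent relaxation
*increase* from vasodilation) and the VOF integral negative, so the
scaling ratio is negative. Gray-matter CBV comes out near 0.029 against a
ground truth of 0.040 — the ~30 % underestimation caused by the 6.5 %
tissue vasodilation the phantom contains — while the GM/WM ratio stays at
~2.1, matching the constructed 2:1 contrast: vasodilation rescales the
maps globally but preserves relative values. MTT is inflated by the long
(35 s) bolus, as expected for regularised SVD.

The bias experiment makes that explicit:

```r
vasodilation_bias_experiment(cbv_grid = 0.04,
                             dcbv_grid = c(0, 0.04, 0.065, 0.09))
#>   dcbv_rel cbv_recovered pct_error
#> 1    0.000          4.04     0.943
#> 2    0.040          3.24   -19.057
#> 3    0.065          2.74   -31.562
#> 4    0.090          2.24   -44.069
```

With no vasodilation the pipeline is unbiased to ~1 %; across the typical
4–9 % vasodilation range of a 16 s hold, CBV is underestimated by roughly
20–40 %, and a 4 % voxel reads ~2.7 %.

A thin command-line driver over the same functions lives at
`inst/cli/bhdsc.R` (`simulate`, `bias`, `run` subcommands).

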