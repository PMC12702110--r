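# cdtiopt

Protocol optimization for in vivo cardiac diffusion tensor imaging (cDTI).

Clinical cDTI must split a fixed scan-time budget between the number of
unique diffusion-encoding directions (ND), the number of repetitions per
direction (NR), and low-b-value sampling. `cdtiopt` provides the complete
computational pipeline for comparing candidate acquisition schemes on those
axes: direction-scheme design and condition-number scoring, a digital
left-ventricle phantom with known microstructure, Rician-noise DWI
simulation with physiological corruption, robust diffusion-tensor fitting,
cardiac metric maps (MD, FA, helix angle, sheetlet angle) in cylindrical
ventricular coordinates, and a stratified *bootknife* bootstrap that scores
each scheme's accuracy (RMSD against a fully sampled reference) and
precision (SD across bootstrap samples, precision = SD⁻²).

It is aimed at MR physicists and image-analysis researchers designing or
harmonizing cDTI protocols, and at anyone who needs a tested, seedable
reference implementation of repetition-stratified bootstrap uncertainty for
diffusion MRI.

## The core quantities

* **Encoding condition number.** For unit directions *g*, the direction-set
  transformation matrix has rows
  (*g*ₓ², *g*ᵧ², *g*_z², 2*g*ₓ*g*ᵧ, 2*g*ₓ*g*_z, 2*g*ᵧ*g*_z); its condition
  number κ (evaluated in the orthonormal tensor basis, making it exactly
  rotation-invariant) predicts noise amplification in tensor estimation.
  The classic 6-direction dual-gradient set has κ = 2.00, the icosahedral
  set κ = √(5/2) ≈ 1.581, an electrostatically optimized 30-direction set
  κ ≈ 1.59.
* **Scheme generation.** Directions minimize the antipodally symmetrized
  electrostatic energy Σ 1/‖gᵢ−gⱼ‖ + 1/‖gᵢ+gⱼ‖. The 61-direction
  *incremental* scheme is grown in stages (optimal 6 ⊂ optimal 30 ⊂ 61) and
  ordered so every prefix is well conditioned; `best_circular_subsample()`
  finds the consecutive run of ND directions minimizing κ.
* **Tensor fit.** log-linear model ln *S* = ln *S*₀ − *b g*ᵀ*D g*, estimated
  by LLS, WLS (squared-predicted-signal weights), or robust IRLS
  (Geman–McClure weights on MAD-standardized residuals; volumes with final
  weight < 0.1 are outliers).
* **Bootknife.** Each direction × shell is a stratum; a bootstrap sample
  removes one random volume per stratum, then draws the plan's repetition
  count with replacement — correcting the small-sample variance
  underestimation of the plain stratified bootstrap.

## Worked example

```r
library(cdtiopt)

inc61 <- generate_incremental_scheme(61, seed = 1)
best_circular_subsample(inc61, 30)$cn
#> [1] 1.589
condition_number(dual_gradient_scheme())
#> [1] 2
condition_number(icosahedral_scheme())
#> [1] 1.5811

plan <- build_plan(best_circular_subsample(inc61, 30)$scheme,
                   na_b500 = 120, b50_divisor = 3)
plan
#> <acquisition_plan> incr61_sub30_120_40: NA_b50 = 40, NA_b500 = 120,
#>   NA_all = 160, time = 8:00 min

ph <- make_lv_phantom()            # 64x64 short-axis annulus, 460 voxels
stk <- simulate_dwi(ph, plan, noise = noise_model(snr_b500 = 9.6), seed = 1)
fit <- dti_fit(stk, method = "robust")
summary(fit)
#> Diffusion tensor fit (robust), 460 voxels, 160 volumes
#>   MD: median 0.001409 mm^2/s (IQR 0.001391-0.00143)
#>   FA: median 0.364 (IQR 0.344-0.381)
#>   outlier volume fraction: 0.011
```

The phantom's ground truth is MD = 1.46 × 10⁻³ mm²/s and FA = 0.35; at an
SNR of 9.6 with the default corruption model (5% outlier volumes, 3%
per-direction bias) the robust fit recovers MD within ~4% and FA within
~4%, and flags ~1% of volume fits as outliers. A 50-sample bootknife of the
shortest 30-direction plan then quantifies accuracy and precision per
metric:

```r
run <- run_bootstrap(stk, build_plan(best_circular_subsample(inc61, 30)$scheme, 30, 3),
                     ph$frames, n_samples = 50, seed = 1)
ref <- metric_maps(fit, ph$frames)
summarize_bootstrap(run, ref, ph$voxels, center_of_mass(ph$mask))
#>                scheme  metric statistic     value
#> 1  incr61_sub30_30_10      md      mean  1.41e-03
#> 2  incr61_sub30_30_10      md      rmsd  5.98e-05
#> 3  incr61_sub30_30_10      md        sd  5.97e-05
#> 4  incr61_sub30_30_10      fa      mean  3.75e-01
#> 5  incr61_sub30_30_10      fa      rmsd  4.63e-02
#> ...
#> 13 incr61_sub30_30_10 abs_e2a      mean  3.20e+01
```

Read: with only 40 volumes (2:00 min nominal), the ROI-mean RMSD of MD is
6.0 × 10⁻⁵ mm²/s (~4% of the reference MD) and the bootstrap SD of FA is
0.044 — the numbers that shrink as NA_all, ND, or low-b sampling grow.
`run_experiment()` scales this comparison over the full 96-plan grid with
replicates and Holm-corrected paired tests; see the vignette
(`vignettes/protocol-optimization.Rmd`) for the model details and design
choices.

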