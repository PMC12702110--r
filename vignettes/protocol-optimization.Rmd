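---
title: "Optimizing cardiac DTI protocols: directions, repetitions, and the bootknife"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing cardiac DTI protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdtiopt)
```

## The problem

In vivo cardiac diffusion tensor imaging (cDTI) estimates a symmetric
positive-definite tensor $D$ per myocardial voxel from magnitude
diffusion-weighted images. Scan time is spent on two competing axes: the
number of unique diffusion-encoding directions (ND) and the number of
repetitions per direction (NR). Because each volume costs roughly one
nominal TR (3 s at a heart rate of 60 bpm, one slice triplet per 3 RR
intervals), a clinical protocol must choose how to divide a fixed budget of
acquisitions between ND, NR, and low-b-value sampling. `cdtiopt` implements
the full computational machinery for making that choice quantitatively:
scheme design and scoring, a digital left-ventricle phantom with known
microstructure, robust tensor estimation, cardiac metric maps, and a
stratified bootknife bootstrap that measures the accuracy and precision of
every candidate protocol.

All experiments in the package run on synthetic data. The phantom replaces
volunteer scans: it supplies the ground truth that in vivo data lack, at
the cost of simplifying the physics (see *Limitations*).

## Diffusion-encoding schemes and the condition number

A scheme is an ordered set of unit directions $g_i$ at one b-value. The
noise performance of tensor estimation is governed by the conditioning of
the second-moment *encoding matrix* with rows

$$(g_x^2,\; g_y^2,\; g_z^2,\; 2g_xg_y,\; 2g_xg_z,\; 2g_yg_z),$$

and we score schemes by its condition number (ratio of extreme singular
values). This form deliberately excludes a b0/intercept column, so the
score is a property of the direction set alone; the b-value enters only at
fitting time through the design matrix. One numerical subtlety matters: in
the doubled-cross-term coordinates above, the singular values are *not*
invariant under rotation of the direction set (a rotated dual-gradient set
can score 1.93 instead of 2.00), because that basis of symmetric matrices
is not orthonormal. The condition number is therefore evaluated in the
isometric basis — cross terms scaled by $\sqrt{2}$ — where rotations act
orthogonally on the rows: the score is then exactly rotation-invariant and
still reproduces the classic values, 2.00 for the 6-direction dual-gradient
set and $\sqrt{5/2} \approx 1.581$ for the icosahedral set, the latter
being the empirical lower bound we assert for all generated schemes.

```{r schemes, eval = FALSE}
condition_number(dual_gradient_scheme())  # 2.00
condition_number(icosahedral_scheme())    # 1.5811
```

Scheme generation minimizes the antipodally symmetrized electrostatic
energy $\sum_{i<j} 1/\lVert g_i - g_j\rVert + 1/\lVert g_i + g_j\rVert$
(diffusion encoding is symmetric under $g \mapsto -g$, so charges live on
axes, not points) by projected gradient descent with backtracking from a
seeded random start. A 30-direction optimized scheme lands at a condition
number near 1.59.

The 61-direction *incremental* scheme is ordered so that early prefixes are
themselves usable schemes — insurance against premature scan termination —
and so that consecutive runs are good subsampling targets. Ordering a
single globally optimized 61-set is not enough: the best 30-subset of an
optimal 61-point arrangement is geometrically constrained and plateaus near
a condition number of 1.65, well above the 1.59 optimum of a free 30-set.
The generator therefore grows the scheme in stages: an unconstrained
optimal 6-set first, then 24 directions optimized around the fixed 6, then
31 more around the fixed 30, with positions within each stage ordered
greedily by prefix condition number (energy as tie-break) — the same
criterion by which subsampled runs are later selected. Prefixes at the
stage sizes are then fully optimized sets (the 6-prefix scores 1.581, the
30-prefix ~1.589), and all prefixes of length 6–61 stay below 2.2.
`best_circular_subsample()` scans every wrapping window of consecutive
directions and returns the start index minimizing the condition number,
with ties broken toward the smallest start. Windows wrap past the end of
the scheme: every start index then indexes a genuine window, which is the
only reading under which all 61 starts are comparable. The published
coordinates of the original 61-direction scheme are not available, so the
package generates its own stand-in; downstream condition numbers match the
published ones to within a few hundredths rather than exactly.

For the study panel (`study_direction_schemes()`), the 18-, 10- and
6-direction windows are, by default, chosen among windows contained in the
best 30-direction window. This nesting guarantees that every subsampled
plan can be drawn from one simulated reference session — the 6-direction
plan at NR = 20 pools its own shell's 8 repetitions with the 30-direction
shell's 12 — mirroring how the repetition counts of the reference
acquisition are chosen to add up. Set `nested = FALSE` to minimize each
window independently.

## Acquisition plans

`build_plan()` pairs a high-b scheme (b = 500 s/mm²) with a low-b shell
(b = 50 s/mm², three orthogonal axes) whose volume count is
`na_b500 / divisor` for divisors 10, 5, 3, 2. Indivisible combinations are
an error — no silent rounding. Within a shell, volumes are spread as evenly
as possible over directions; any remainder goes to distinct directions
chosen uniformly at random, so per-direction counts differ by at most one.
`enumerate_study_plans()` crosses six schemes × four high-b counts
(30–120) × four divisors into 96 plans plus the 720-volume reference
session (24 × 3 low-b + 12 × 30 + 8 × 6 + 20 × 6 + 4 × 30 high-b; 36 min
at TR 3 s). The nominal TR is a plan field, so other heart rates are a
parameter change, not a code change.

## The digital left-ventricle phantom

The phantom is a single mid-ventricular short-axis slice: an annulus at
2.3 mm in-plane resolution (slice thickness is carried as metadata only).
Its microstructure is controlled by `lv_phantom_spec()`:

* **MD = 1.46e-3 mm²/s, FA = 0.35** — healthy-myocardium values; the
  eigenvalue triple is solved numerically under the shape constraint
  $\lambda_2 = \rho\,\lambda_3$ (default $\rho = 1.55$) to match MD and FA
  to $10^{-8}$.
* **Helix angle** varies linearly with transmural depth
  $d = (r_{epi} - r)/(r_{epi} - r_{endo})$ from −60° (epicardium) to +60°
  (endocardium). The endpoints follow the standard cardiac literature
  convention — the study itself never states volunteer ground truth — and
  are configurable.
* **Sheetlet angle** has constant magnitude 33° with sign alternating over
  six angular sectors. The alternation is deliberate: slice averages of
  signed E2A then cancel toward zero while |E2A| stays near 33°,
  reproducing the cancellation seen in vivo. Six sectors keep each sector
  several voxels wide at a 32²–64² grid.
* **Local frames**: radial points outward from the slice centroid,
  longitudinal is the slice normal, circumferential = longitudinal ×
  radial (counter-clockwise viewed from base). This handedness fixes the
  helix-angle sign and is pinned by tests.

The tensor field is assembled by rotating the eigenvalue triple into each
voxel's frame; recomputing MD/FA/HA/E2A from the stored tensors reproduces
the ground-truth maps to numerical precision, which is the round-trip
invariant the test suite enforces.

## Signal simulation and the noise model

Noiseless signals follow the monoexponential tensor representation
$S = S_0 \exp(-b\, g^\top D g)$. Corruption is applied in three layers,
each seeded and recorded in the volume metadata:

1. **Per-direction bias** — one multiplicative lognormal factor per
   stratum (σ = 0.03). This emulates direction-specific image-quality
   variation (e.g. eddy-current effects), the reason redundancy in ND has
   value beyond averaging.
2. **Outlier volumes** — each volume is, with probability 0.05, attenuated
   by a uniform factor in [0.3, 0.7], emulating residual-motion signal
   loss. The in vivo literature characterizes this "physiological noise"
   only qualitatively; these magnitudes are free parameters with stated
   defaults, chosen so that outliers are clearly separable from Rician
   noise at the study SNR yet rare enough not to dominate.
3. **Rician magnitude noise** — $\sqrt{(S+\varepsilon_1)^2 +
   \varepsilon_2^2}$ with Gaussian $\varepsilon$ scaled so that the mean
   noiseless b500 myocardial signal divided by σ equals the target SNR
   (default 9.6). Noise is independent across voxels; no spatial
   correlation is modeled.

`measure_snr()` implements the repetition-based estimator (per-voxel,
per-direction mean over SD, averaged over directions then voxels). On pure
Rician data it recovers the target within ~8% at 12 repetitions; on real
data this estimator conflates thermal noise with registration residuals,
which is why the simulator exposes the corruption components separately
instead of guessing their mix.

## Tensor fitting

`dti_fit()` is the modelling core and returns a classed object with the
usual `coef`/`predict`/`residuals`/`summary` methods. The design matrix is
$N \times 7$: a column of ones for $\ln S_0$ and the negated b-weighted
second-moment terms; the b = 50 shell enters as ordinary diffusion-weighted
rows (the protocol has no b = 0). Three estimators:

* **LLS** — ordinary least squares on log-signals.
* **WLS** — weights equal to squared predicted signals from the previous
  iterate, two passes from an LLS start; the standard correction for the
  heteroscedasticity of log-magnitude data.
* **robust** — iteratively reweighted least squares multiplying the WLS
  weight by a Geman–McClure weight $1/(1+u^2)^2$ with $u = r/(3\hat\sigma)$,
  residuals standardized by the MAD scale ($\hat\sigma$ = 1.4826 × median
  absolute deviation) and a tuning constant of 3 — clean volumes within
  ~3$\hat\sigma$ keep weight above 0.5 while the 0.1 outlier cutoff
  corresponds to residuals beyond 4.4$\hat\sigma$. Iteration stops
  when the largest tensor-element change falls below 1e-8 mm²/s or after
  50 iterations; non-convergence is reported, not hidden. Volumes with
  final robust weight below 0.1 are flagged as outliers. The published
  pipeline names robust weighted least squares without formulas, so this
  is a faithful, testable choice rather than a bit-compatible port; the
  weight function and cutoff are documented constants of this package.

Numerical edge cases: non-positive magnitudes are clamped to
$10^{-6}\times$ the voxel maximum before the log (flagged per voxel, never
silently dropped); fitted tensors are kept as raw elements, with negative
eigenvalues clipped to zero only when computing FA and other metrics, so
FA cannot exceed 1. Zero-frequency volumes (bootstrap) are removed from
the fit algebraically, which the permutation- and scale-equivariance tests
pin down. The per-voxel engine is compiled (RcppArmadillo); a plain-R
normal-equations path serves as the oracle in the tests.

At the study conditions (SNR 9.6, 160 volumes) the estimators are
essentially unbiased for MD: the Rician mean inflation and the concavity
of the log cancel to first order at these signal levels, so the WLS-vs-LLS
MD-bias comparison is a near-tie resolved only by large Monte-Carlo
ensembles; the clearer WLS benefit is in FA. This is stated here because a
reader may otherwise expect a dramatic bias difference that the study's
own operating point does not produce.

## Cardiac metrics

MD is trace/3; FA the normalized eigenvalue dispersion. The helix angle is
the signed angle of the primary eigenvector's projection in the
circumferential–longitudinal plane, measured from circumferential toward
longitudinal in (−90°, 90°]; the sheetlet angle (E2A) is the signed angle
of the secondary eigenvector's projection in the cross-myocyte–radial
plane, measured from the cross-myocyte direction (the wall-tangent vector
orthogonal to the primary eigenvector) toward radial. Both are invariant
to eigenvector sign flips; degenerate projections (primary eigenvector
along radial) return `NA` rather than an arbitrary angle. Whether the
original study's sign convention for mean HA matches ours cannot be
verified from its text; the convention here is explicit and test-pinned.

## Bootknife bootstrap

Each direction × shell is a stratum. One bootstrap sample removes one
uniformly chosen volume per stratum, then draws the stratum's requested
count *with replacement* from the remainder — the jackknife-style removal
corrects the small-sample variance underestimation of the plain stratified
bootstrap, so the SD of a resampled stratum mean estimates $\sigma/\sqrt{k}$
without the $(k-1)/k$ deflation. The removal is drawn per stratum per
sample (the literal reading of the procedure). Each stratum consumes its
own seeded substream, so adding strata never perturbs another stratum's
draws. Resampled multiplicities enter the tensor fit as frequency weights,
which is algebraically identical to duplicating volumes.

Strata for the low-b shell are handled identically to high-b strata, with
requested counts split across the three orthogonal directions by the same
max-difference-1 rule — the source procedure is silent on the low-b split,
so the high-b rule is extended by analogy. A plan that requests more
repetitions than a session acquired raises an error naming the stratum.

Accuracy is RMSD against the metric maps of the fully sampled reference
fit; precision is the SD across bootstrap samples (precision = SD⁻²).
Angular metrics use wrapped (modulo-180°) differences, and their SD is
taken about the axial mean — the original report does not state its
handling, and wrapping materially changes HA statistics near ±90°, so both
the choice and its motivation are documented here. ROI aggregation uses
12 equal azimuth wedges around the LV centroid; excluding wedges stands in
for artifact masking, and a contiguous pair of wedges stands in for the
septal AHA segments, which require anatomical landmarks the phantom lacks.
Paired comparisons between plans use paired t-tests across replicates with
Holm adjustment; replicates are independent noise realizations standing in
for subjects, and confidence intervals of pooled means use the normal
approximation.

## Experiment orchestration

`run_experiment()` ties the chain together: per replicate, one reference
session is simulated and fitted, and every plan is bootknife-resampled
*from that session* — plans share data within a replicate on purpose,
preserving the non-independence inherent to single-session subsampling
designs. The manifest records seeds and sizes sufficient to reproduce any
number in the output; identical configurations reproduce identical tables.
The package deliberately ships no shell executable: the exported functions
and `scripts/acceptance.R` are the entry points, and every stage reads and
writes standard formats (NIfTI, FSL bval/bvec, JSON, data frames) for use
in scripted pipelines.

## Problem sizes used by the tests

The shipped tests run the full logic at reduced size, chosen as the
smallest scales at which each effect is statistically resolvable: the
noiseless round-trip uses the 64² phantom (460 masked voxels); Rician
recovery uses 100 phantom realizations at SNR 9.6 with 160 volumes;
bootknife theory uses 50 toy datasets × 500 samples; and the
scheme-ordering experiment uses a 32² phantom (108 voxels), 100 bootstrap
samples and 5 replicates, which reproduces the direction of the published
ND-vs-NR and low-b findings (lower RMSD and SD of MD and FA for ND = 30
than ND = 6 at matched scan time, and with more low-b volumes at fixed
high-b count). Magnitudes on synthetic data are not expected to match
volunteer values.

## Limitations

The phantom omits EPI distortion, susceptibility and B0 effects, cardiac
and respiratory motion warps, partial-volume beyond a binary mask, and
spatially correlated noise; its corruption model is a two-component
caricature (per-direction bias + attenuation outliers) of physiological
noise. Consequently, passing tests demonstrate that the estimation and
resampling machinery behaves correctly and that the protocol-ordering
conclusions are reproducible under a plausible noise model — not that the
specific volunteer-study numbers are recovered. Real-data mode
(`read_dwi()`) accepts 4D NIfTI with bval/bvec and a mask, but image
registration and segmentation are out of scope and must happen upstream;
`predict()` on a fitted model supplies the model-predicted series such
registration pipelines need.
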