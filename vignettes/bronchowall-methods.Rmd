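---
title: "Quantifying bronchial wall T2w signal: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bronchial wall T2w signal: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bronchowall)
```

## The measurement problem

Bronchial inflammation thickens and alters the signal of the airway wall.
CT resolves airway geometry well but cannot separate inflammation from
remodeling; T2-weighted MRI is sensitive to inflammatory edema but has too
little resolution to segment the wall directly. `bronchowall` implements the
multimodal strategy that combines both: segment the wall where geometry is
sharp (a CT-like volume), bring everything into a common frame (a UTE-like
MRI reference acquired at the same lung volume), and read out the wall's
mean normalized T2w intensity — the per-patient biomarker `BrWall_T2-MIS` —
together with the CT-derived normalized wall area `WA% = 100 * WA/(WA+LA)`.

Every stage is developed and validated against a synthetic airway phantom
with analytic ground truth, because the corresponding patient data are not
publicly deposited. The phantom generator is first-class, tested code: it
defines the study conditions under which all quantitative claims of this
package are demonstrated.

## The synthetic phantom

`generate_phantom()` rasterizes a symmetric dichotomous airway tree —
trachea = generation 0, branch half-angle 35 degrees, child/parent length
ratio 0.8, defaults: trachea 22 mm, lumen radii (4, 3, 2.5, 2) mm and wall
thickness 2 mm per generation — into three co-registered volumes:

* **CT-like** (HU-analog: lumen -1000, wall 0, parenchyma -850),
* **UTE-like** (arbitrary units: 10 / 120 / 40), the fixed reference,
* **T2w-like** (lumen 5, parenchyma 30, wall = `wall_t2_signal`).

Geometry is anti-aliased over one voxel in the CT/UTE volumes so that
boundary positions are defined at sub-voxel precision; the T2w volume uses
sharp classification instead, so interior wall voxels carry exactly the
ground-truth signal that the pipeline must recover. Parenchyma is textured
with vessel-like blobs (default 150, kept at least 2 mm clear of any outer
wall): lung parenchyma is threaded with vasculature in every modality, and
those landmarks are what drives deformable registration of the lung
interior; a featureless background would make that problem artificially
ill-posed. Noise is additive Gaussian on the CT-like volume and Rician on
the MR-like volumes, with defaults giving wall SNR of about 10.

The inter-modality misalignment is a smooth sinusoidal displacement field
(one lateral-frequency sinusoid per component, period 48 mm, total
magnitude bounded by the 3 mm amplitude, fold-free by construction). The
CT-like and T2w-like volumes are resampled through it; the stored ground
truth contains both the forward field and its numerical inverse — the field
a registration back onto the UTE-like frame should recover. A single seed
determines all stochastic content bit-for-bit.

`generate_cohort()` draws the tabular side of the study: two groups of
asthma patients (severe / non-severe), biomarker means 74 +/- 12 vs
49 +/- 14 Au, spirometry, FeNO and blood eosinophils on log-normal scales,
WA%, a frequent-exacerbator outcome following a logistic model with odds
ratio 1.11 per Au, and reader-replicate readings with 0.7 Au measurement
error (which implies inter-reader ICC near 0.99 and Bland-Altman limits of
agreement near +/- 1.9 Au). Correlation targets (for example -0.54 between
the biomarker and FEV1 % predicted) are *pooled* whole-cohort correlations:
the generator solves analytically for the within-group covariance that,
combined with the group mean separation, produces the requested pooled
value. FEV1/FVC group means (0.75 +/- 0.08 and 0.65 +/- 0.10) are a chosen
plausible parameterization, as only correlations involving that ratio are
reported externally.

## T2w normalization

MRI intensities are not calibrated across subjects, so each T2w volume is
standardized with its whole-image statistics:

$$f(x) = \frac{x - \mu_x}{\sigma_x} + 3\sigma_x$$

with the mean and *population* SD taken over **all** voxels, background
included — the literal whole-image reading. The output has SD exactly 1 and
mean $3\sigma_x$; a constant volume is a degenerate input and raises an
error rather than dividing by zero. Note the deliberate quirk of this
transform: the $+3\sigma_x$ offset re-introduces the original global scale
into the normalized mean, so normalized wall values are comparable across
subjects only to the extent that whole-image statistics are. The formula is
implemented exactly as specified; `normalize_value()` exposes the same map
for scalars so the phantom's ground-truth wall signal can be transformed
analytically and compared to the measured biomarker. Normalization is
applied to the native T2w volume before registration resampling.

## Registration

`register_volumes()` aligns the CT-like and T2w-like volumes onto the
UTE-like reference with a demons-style variational scheme on *normalized
edge maps*, $|\nabla I| / \sqrt{|\nabla I|^2 + \epsilon^2}$ with
$\epsilon$ tied to the mean gradient magnitude. Edge maps are invariant to
global intensity scaling and nearly so to contrast conventions, which is
what makes the scheme multimodal. The update is the classical demons force
(symmetrized over fixed and warped-moving gradients), smoothed with a
fluid-type Gaussian (4 mm) before composition and a light diffusion-type
smoothing of the accumulated field (0.8 mm) after it; both scales are
physical and converted to voxels per pyramid level. Four pyramid levels
with schedules weighted toward the cheap coarse levels
(100/150/80/40 iterations by default) carry most of the optimisation;
similarity is checked every five iterations and a level stops when a check
window gains less than `tol`.

Numerical choices that matter:

* the displacement field lives on the fixed grid in mm, pull-back
  convention `warped(x) = moving(x + u(x))`; trilinear interpolation for
  intensities, nearest-neighbour for label masks;
* fluid-dominant regularization was chosen over strong field smoothing
  because the accumulated field would otherwise be re-damped every
  iteration, which systematically under-recovers smooth displacement
  amplitudes;
* `field_jacobian_det()` verifies the recovered field is fold-free.

On the standard phantom, the default configuration recovers the 3 mm
sinusoidal field with mean endpoint error below one voxel over the airway
mask (typically 0.6–0.9 mm at 1 mm spacing, with or without SNR-10 noise),
and a pure 4 mm translation to within 0.3 mm. The pipeline default
(`default_config()$register`) trades a little accuracy for a roughly
ten-fold speedup by truncating the finest level — appropriate for cohort
throughput where the biomarker read-out tolerates ~1 mm residual
misalignment; the diffusion scale is raised to 1.6 mm there to keep the
truncated field gentle. The visual misalignment check of a human reader is
replaced by `check_alignment()`, the cosine overlap of edge maps inside the
dilated airway mask, flagged below 0.8.

## Airway tree extraction

`segment_lumen()` thresholds the CT-like volume at -500 HU-analog (after a
0.5-voxel presmooth, escalated deterministically if noise or resampling
pinholes through the wall flood the growing) and
keeps the 26-connected component containing the tracheal seed. The -500
cutoff lands exactly on the lumen/wall partial-volume midpoint, so lumen
volume is recovered to a few percent; region growing, not the threshold,
prevents leakage into background air.

`extract_centerline()` traces medial paths on the voxel graph of the lumen:
edge weights are step length divided by the squared depth-to-wall (an
erosion-count distance transform), so geodesics hug the tube centre.
Terminals are discovered iteratively — each iteration runs a Dijkstra from
the *current* tree via a zero-weight virtual source, picks the farthest
uncovered voxel, and backtraces to the attach point — which guarantees that
paths through shared trunks share their prefix exactly and bifurcations
fall at the true carinae. Spurious skeleton spurs scale with the local tube
radius (they live in fat junction zones), so a terminal twig is pruned
unless it exceeds both `prune_mm` (default 4 mm) and 1.2 local diameters.
Branch polylines are smoothed with a 5-point moving average, and tangents
are centred finite differences.

Generations are labeled from the trachea (0) with +1 at every bifurcation.
`select_paths()` matches each requested lobe to its nearest
generation-3 branch (falling back to deeper-labelled branches near the
lobe point, since spurious proximal bifurcations inflate nominal
generations while the anatomical segmental branch remains the nearest
candidate); in the phantom's ground truth each lobe is one
generation-2 subtree, as real lobar bronchi are. The mucus-plug criterion —
visual in clinical practice — is automated as: mean CT intensity along the
proximal third of the path's centerline above -300 HU-analog, or no
generation-3 branch found near the lobe at all (a fully plugged bronchus
disconnects its distal lumen). Excluded lobes are recorded, not fatal; a
tree with no generation-3 branches at all is a selection error.

Measurement sites sit at fixed arc-length fractions (1/3 and 2/3 for the
standard two sites per path; 1/2 for one), which keeps them away from both
bifurcation zones; a branch shorter than two local lumen diameters is
refused. Where along each path clinical readers placed their two
measurements is not specified externally; the fixed fractions are this
package's declared convention.

## Wall measurement

`reformat_cross_section()` samples an oblique plane perpendicular to the
local bronchial tangent by trilinear interpolation at half-voxel spacing.
`detect_wall()` then locates the wall on radial rays from the lumen
centroid at Laplacian-of-Gaussian scale sigma: the boundary criterion is
the zero-crossing of the *second radial derivative* of the
Gaussian-smoothed section along each ray (the 1D LoG of the radial
profile), with sub-sample positions by linear interpolation. The full 2D
LoG was evaluated and rejected for this purpose: on a curved boundary it
carries a $(1/r)\,\partial S/\partial r$ term that displaces zero-crossings
outward, inflating the outer boundary. Similarly, the scale sweep
{0.3, 0.5, 0.8} mm keeps the *smallest* scale that yields a valid
measurement rather than the response-maximizing one: the ridge response
grows with sigma while the boundary bias grows like $\sigma^2/2r$, so
maximizing response systematically overestimates wall area (by over 30% on
the standard annulus). Larger scales still serve noisy sections where the
small scales fail. When several negative ridges exist along a ray the
innermost significant one is kept (nearest the lumen). A ray without a
bracketing zero-crossing pair fails; more than 25% failed rays fails the
section (recorded, not fatal). Areas come from the shoelace formula on the
64 boundary vertices; `WA% = 100*WA/(WA+LA)` exactly.

On analytic annuli sampled at 0.3 mm (lumen radius 2 mm, wall 2 mm), LA and
WA are recovered within 5% and WA% within 3 points, clean and at wall
SNR 10. Measurements on sections resampled from a 1 mm voxel grid carry an
extra partial-volume blur and are biased a few percent — visible in the
phantom's WA% of about 76 against the analytic 75.

`wall_mask_3d()` rasterizes each measured section's annulus into a 2 mm
slab on the reference grid, labeled per site, with any voxel of the lumen
segmentation cleared so wall and lumen masks are disjoint by construction.
`brwall_t2_mis()` applies the masks to the normalized T2w volume and
averages site, then path, then patient — each an unweighted mean, the
aggregation order declared here since only the final averaging is specified
externally. The same site set feeds the per-patient WA%.

## The statistical battery

All tests follow the clinical-paper conventions: two-sided, alpha 0.05, no
multiplicity correction.

* `shapiro_gate_transform()`: natural-log transform iff Shapiro-Wilk
  p < 0.05; geometric mean/SD on back-transform.
* `compare_groups_continuous()`: pooled-variance Student's t (not Welch),
  accepting raw vectors or printed summary statistics; zero pooled variance
  with unequal means is reported as the p -> 0 limit with a flag.
* `compare_groups_categorical()`: Fisher's exact test when any expected
  cell is below 5, chi-square without continuity correction otherwise.
* `roc_youden()`: empirical ROC, trapezoidal AUC (equal to the normalized
  Mann-Whitney U, verified against a brute-force pairwise oracle), cutoff
  maximizing Youden's J with ties broken toward the *lowest* cutoff
  (favouring sensitivity), exact Clopper-Pearson CIs for sensitivity and
  specificity at the cutoff, DeLong-variance CI for the AUC.
* `clopper_pearson()`: beta-quantile form with closed-form boundary cases.
* `stepwise_logistic()`: forward selection by likelihood-ratio p < 0.05,
  backward elimination at p > 0.10; odds ratios with Wald CIs; complete
  separation is flagged and a weakly ridge-penalized refit reported.
  Note the implied type-I behaviour: with four noise candidates screened at
  p-enter 0.05, the model stays empty with probability $0.95^4 = 0.815$,
  and the tests assert that closed form, not a higher figure.
* `icc_absolute()`: ICC(A,1) — two-way, absolute agreement, single measure —
  from the mean-squares decomposition with F-based confidence bounds and
  the standard category bands ("almost perfect" at 0.95 and above).
* `bland_altman()`: mean difference (a - b), t-based CI, limits of
  agreement at +/- 1.96 SD of the differences.
* `quartile_anova()`: quartile groups by inclusive linear interpolation
  (boundary values to the lower group), one-way ANOVA with Tukey HSD.

`cohort_stats_report()` assembles the full battery for a cohort table —
group comparisons (log-gated for FeNO and eosinophils), ROC of the
biomarker, whole-cohort and per-group correlations, stepwise regression of
the frequent-exacerbator outcome, reproducibility when replicate readings
are present, and the two quartile cross-classifications when WA% is
present. `run_cohort()` drives either a table-only cohort or the full
imaging pipeline over per-patient phantoms (measurement order
seed-shuffled, emulating blinded random-order reading; the order is
recorded in the manifest).

## Problem sizes and determinism

The validation suite runs phantoms at 96^3 voxels of 1 mm (study-like
airway dimensions at manageable cost), annulus sections at 0.3 mm sampling,
cohort round-trips at n = 10000 per group, type-I simulations at 2000
replicates, and one full 15 + 15 imaging cohort; these sizes are the
package's declared validation conditions. Every stochastic stage is a pure
function of its seed: the same configuration and seed reproduce volumes,
measurements and reports bit-for-bit. Config hashes, per-stage status,
checksums and exclusion records are collected in each run's manifest.

## What the phantom does and does not show

Passing phantom tests demonstrates the internal correctness of the
machinery — geometry recovery, field recovery, unbiased boundary detection
at known scales, correct statistics — under idealized conditions: circular
cross-sections, piecewise-constant tissue classes, stationary noise, a
smooth low-frequency misalignment, and vessels that keep clear of the
airway wall. Real data add tapering and elliptical lumina, wall texture,
mucosal secretions, cardiac and respiratory motion artifacts, receiver-coil
bias fields, and vessels abutting the wall; none of these are modeled, and
the package's accuracy figures do not transfer to them. The lobe labels of
real airway trees are supplied by the user, not inferred.

## Known limitations

* The demons-style registration recovers displacement best where edges
  constrain it; along featureless tube segments the tangential component is
  interpolated by the regularizer. The phantom's vascular texture mirrors
  the information density of real lungs, but pathologically featureless
  regions would degrade accuracy.
* The +3 sigma_x normalization offset ties the normalized scale to
  whole-image statistics; cross-subject comparability inherits any
  systematic differences in field of view or background composition.
* Wall measurements assume a single closed wall per section; touching
  structures (plugs, vessels on the wall) are only handled by the
  innermost-ridge rule and the exclusion mechanisms.
* At 1 mm voxels a 2 mm wall spans two voxels; absolute LA/WA from such
  grids carry percent-level partial-volume bias (WA% is much more stable,
  as the biases largely cancel in the ratio).
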