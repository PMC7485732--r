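---
title: "Simulating multiparametric quantitative MRI of cortical aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multiparametric quantitative MRI of cortical aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexage)
```

## The question the package addresses

Cross-sectional quantitative-MRI (qMRI) studies of cortical aging report
linear associations between age and global cortical relaxometry parameters —
T1, proton density (PD), the irreversible, effective and reversible
transverse relaxation times T2, T2\* and T2′ — together with cortical
thickness. Such studies rest on a long measurement chain: multi-contrast
acquisitions, voxelwise model fits, cortical segmentation, surface sampling
and correlation statistics. `cortexage` rebuilds that chain on digital brain
phantoms whose cortical parameters carry *known* linear age effects, so one
can ask: if the population truth is a given set of correlations and
between-subject spreads, does the full measurement chain recover them, with
what bias, and at what sample size?

## The aging model and its calibration

For each parameter the subject-level cortical mean is linear in age,

$$ v_i = v_0 + b\,(a_i - a_\mathrm{ref}) + \varepsilon_i, \qquad
   \varepsilon_i \sim N(0, \sigma_\mathrm{res}^2), $$

and the pair $(b, \sigma_\mathrm{res})$ is calibrated from a target Pearson
correlation $r$ with age and a target between-subject SD $s$:

$$ b = r\,s / s_\mathrm{age}, \qquad
   \sigma_\mathrm{res} = s\sqrt{1 - r^2}. $$

In the infinite-cohort limit the simulated value then has exactly the
requested correlation and marginal SD (the package checks this closure with
a 10,000-subject scalar simulation). The default calibration targets are
published global cortical statistics of healthy adults at 3 T: baselines
1528.75 ms (T1), 79.48 p.u. (PD), 86.99 ms (T2), 201.50 ms (T2′), 2.45 mm
(thickness); between-subject SDs 40.58, 1.85, 4.17, 22.47 and 0.08; global
age correlations −0.421, 0.287, 0.445, −0.724 and −0.444, with an age SD of
14.97 years.

Two calibration choices deserve a note:

* **Reference age.** Ages are drawn uniformly on 19–71 years (population SD
  15.01, matching the target 14.97). The baseline is anchored at the
  midpoint, 45 years, i.e. at the *expected cohort mean age*, so the
  expected cohort mean of each parameter equals its calibrated baseline.
  Anchoring anywhere else would shift every cohort mean by
  $b\,(45 - a_\mathrm{ref})$.

* **T2\* is derived, not injected.** T2′ — the reversible component and the
  iron-sensitive quantity of interest — carries its own calibrated trend,
  and ground-truth T2\* follows voxelwise from
  $1/T2^* = 1/T2 + 1/T2'$. This keeps the headline T2′ effect exact but
  means T2\* inherits a *composite* trend; see "Known limitations".

## The phantom

Each subject is a nested-ellipsoid head on an isotropic grid (default
64³ voxels at 2 mm): an outer CSF layer (3 mm), a cortical gray-matter
shell whose thickness is the subject's age-dependent value, a white-matter
core, and one ventricle. The shell is delimited by an approximate Euclidean
distance to the pial surface, so its thickness is uniform; at the default
scale the phantom is roughly a half-size head (TIV ≈ 500 mL), which is
irrelevant for the statistics because TIV enters only as a covariate and is
internally consistent. Per-subject randomness comprises a log-normal global
scale (2 % SD, plus ~2.5 % for male subjects so that TIV correlates with
sex as in real cohorts) and a sub-voxel center jitter that decorrelates
grid-quantization errors across subjects.

Within the cortex, each qMRI parameter additionally varies around the
subject mean along a fixed smooth spatial profile scaled to the published
within-cortex SDs (146.73, 5.45, 27.69 and 90.83 for T1, PD, T2, T2′).
The profile is identical across subjects and age-independent, so it widens
the per-subject cortical distribution without touching the cohort
statistics. Thickness is spatially uniform: a 0.62 mm spatial SD cannot be
represented on a 2 mm grid without the shell locally dropping below one
voxel. White matter and CSF use fixed literature-style values (e.g. WM
T1 850 ms, T2 75 ms, T2′ 150 ms; CSF PD ≡ 100 p.u.) and carry no age
effect.

## The acquisitions and their inversion

The synthesized session mirrors a 3 T relaxometry protocol:

| stack | forward model | fitted by |
|---|---|---|
| VFA FLASH pair (TR 16.4 ms, TE 6.7 ms, α 4°/24°) | spoiled-GE steady state $S = R\,PD\,\sin(\kappa\alpha)\frac{1-E_1}{1-\cos(\kappa\alpha)E_1}e^{-TE/T2^*}$ | two-point linearization: $S/\sin$ vs $S/\tan$ has slope $e^{-TR/T1}$ |
| 4-echo FSE (TE 17/86/103/120 ms) | $S = R\,PD\,e^{-TE/T2}$ | weighted log-linear fit |
| 8-echo GE (TE 10–52 ms, TR 2.4 s, α 30°) | spoiled-GE with echo train | weighted log-linear fit → T2\* |
| B1 pair (β 60°) | prepared/reference ratio $=\cos(\kappa\beta)$ | $\kappa = \arccos(\mathrm{ratio})/\beta$ |
| TE-difference pair (ΔTE 6.7 ms) | two GE echoes | pairwise T2\* for the PD correction |

$\kappa$ (transmit) and $R$ (receive) are smooth random second-order
polynomial fields with ±10 % amplitude by default. Noise is additive
Gaussian on the magnitude (clamped at zero) with SD equal to the mean
noiseless cortical-GM signal of the high-angle VFA volume divided by the
SNR (default 50); a Rician option exists for low-SNR realism. At SNR 50 the
Gaussian model keeps the fitters effectively unbiased, which is the regime
the closed-loop checks are run in.

PD is recovered from the VFA intercept by removing the saturation factor
$(1-e^{-TR/T1})$, the residual $e^{-TE/T2^*}$ weighting (using the
TE-difference pair), and the receive field, then scaling the ventricle-CSF
median to 100 p.u. In simulation mode the known synthetic receive field is
consumed — estimating receive sensitivity from data is a hard problem the
package does not claim to solve. T2′ is derived as
$1/T2' = 1/T2^* - 1/T2$; voxels with fitted $T2^* \ge T2$ (non-physical,
possible under noise) are masked invalid rather than clipped, which keeps
region means unbiased at the cost of a slightly truncated voxel set.

The entire synthesis–fit loop is exactly invertible without noise and bias:
the round-trip property (`max` relative error < 1e−6, in practice ~1e−13)
is enforced by the test suite and is the main guard against sign and
convention errors in either direction.

## The cortical-ribbon surrogate

Real studies use surface reconstruction; the package uses a voxel
surrogate. A synthetic MP-RAGE contrast is computed from the fitted maps
with the closed-form inversion-recovery expression
$S = PD\sin\alpha\,(1 - 2e^{-TI/T1} + e^{-TR/T1})$ (TI 900 ms, TR 1.9 s,
α 9°; ideal inversion, full relaxation — the full shot-train recursion
adds nothing at the fidelity level of this phantom). Segmentation is a
three-class Gaussian mixture on the intensity histogram (classes ordered
CSF < GM < WM); an *oracle mode* consumes the ground-truth labels instead,
and is the default in the statistical analyses so that their results do not
inherit segmentation error. GM Dice against truth at SNR 50 is ≥ 0.95.

Thickness is measured per ribbon voxel as the Euclidean distance to the
nearest WM voxel plus the distance to the nearest CSF voxel minus one voxel
(center-to-center → boundary-to-boundary correction), using an exact
separable distance transform; on analytic slabs and spherical shells the
global mean is correct to within half a voxel. On the 2 mm default grid the
estimator compresses the between-subject thickness range somewhat (a
staircase effect), but the mapping is monotone and the measured global
thickness correlates > 0.98 with truth, so age correlations survive with
only mild attenuation.

Lobes are fixed angular sectors around the brain centroid — frontal:
anterior 100°; occipital: posterior 60°; the remaining band split into a
dorsal (parietal) and ventral-lateral (temporal) part, per hemisphere by
the sign of the lateral coordinate. The parcellation is deterministic,
hemisphere-symmetric and partitions the ribbon exactly. TIV is the tissue
voxel count times the voxel volume.

## The statistics

Three levels, as in cortical-aging studies:

1. **Global**: per-subject mean and sample SD (n − 1 throughout; the
   convention is not dictated by the calibration sources) over valid ribbon
   voxels; Pearson correlations with age, plain and partial (least-squares
   residualization on TIV and sex; p from the t transform with
   df = n − 2 − k). The partial-correlation route is verified against the
   correlation-matrix-inverse identity to 1e−10.
2. **Voxelwise**: maps smoothed on the ribbon with a mask-normalized
   Gaussian kernel (FWHM 10 mm default, σ = FWHM/2.3548; normalization by
   the smoothed mask prevents bleed-in from outside the ribbon and leaves
   constants invariant); voxelwise Pearson r with age; suprathreshold
   voxels (p < 0.05) clustered by 6-connectivity *separately by sign*
   (hot/cold families); cluster-wise p from the permutation null of the
   **map-wise maximum cluster size over both signs**,
   $p = (1 + \#\{\max_\mathrm{perm} \ge s\})/(1 + B)$. Using the combined
   maximum (rather than one null per sign) controls the family-wise error
   of the whole map at α = 0.05 exactly — the package verifies a 5 %
   empirical type-I rate over 200 smoothed null cohorts — where per-sign
   nulls at 0.05 each would give ≈ 10 %. On tiny unsmoothed ribbons the
   integer cluster sizes tie heavily and the test becomes conservative
   (rates well below nominal), which is valid but worth knowing. For n ≤ 8
   an exhaustive mode enumerates all n! permutations and is tested against
   brute-force enumeration.
3. **Lobar**: hemisphere-averaged regional means per lobe; r with age, and
   r with regional thickness partialling TIV; significance flagged at
   p < 0.05, uncorrected across lobes/parameters (each parameter is
   analyzed independently).

Subjects share the grid, so the voxelwise analysis uses a template ribbon
(voxels valid in every subject) in place of surface normalization.

## Problem sizes and numerical choices

* Default desk scale: 64³ voxels at 2 mm, n = 40 subjects, SNR 50,
  ±10 % bias fields. One cohort through the full chain takes ~30 s on one
  CPU; the 20-cohort closed-loop summary ~10 minutes.
* Signal floor for all fits: 3× the noise SD estimated from the eight
  corner patches of the volume (with the truncated-Gaussian/Rayleigh
  correction), so background voxels never enter a fit.
* VFA voxels with slope outside (0, 1) or effective angle ≥ 90°, decay fits
  with non-negative log-slope or fewer than two usable echoes, and B1
  voxels with ratio outside (−1, 1) are masked invalid; masked voxels are
  NA, never silently imputed.
* The weighted log-linear decay fit (weights = squared signal) agrees with
  nonlinear least squares to < 1 % in the median at SNR 40; the nonlinear
  route is available (`method = "nls"`) and serves as the test oracle.
* An option to drop the first spin echo stands in for
  stimulated/secondary-echo corrections, whose published internals are out
  of scope here; motion, B0-distortion and imperfect-spoiling corrections
  are likewise out of scope (the synthesis does not generate those
  artifacts).
* Seeds: every stochastic stage takes an explicit seed and restores the
  caller's RNG state; identical configuration + seed reproduces every
  volume, CSV and manifest hash bit-exactly.

## What passing the closed loop does and does not show

The closed-loop acceptance runs 20 independent 40-subject cohorts through
synthesis → fitting → oracle ribbon → global statistics and compares the
seed-averaged recovered correlations and cohort means with the calibration
targets. T1, T2, T2′ and thickness correlations come back within a few
hundredths, and the cohort means of T1 and T2′ within ~1 %, which shows the
chain is unbiased *under the generator's assumptions*: linear age effects,
Gaussian residuals, mono-exponential decays, smooth bias fields, no motion,
no partial-volume mixing beyond grid quantization, and a geometry far
simpler than a folded cortex. It does not validate the chain against those
missing realities, and says nothing about non-linear aging trajectories
(the generator has none).

## Known limitations

* **The derived T2\* trend is not near-null.** With T2 and T2′ carrying
  their calibrated trends and T2\* derived as their harmonic composition,
  the implied global T2\*–age correlation is ≈ −0.25 at the subject-mean
  level, and ≈ −0.36 after voxelwise averaging (the within-cortex T2′
  spread puts more weight on low-T2′ voxels, where T2\* is most sensitive
  to the T2′ shift). A measured near-zero T2\*–age correlation alongside a
  strong T2′ effect — as reported in human cohorts, where T2\* is measured
  independently and T2′ derived, each with its own error — cannot be
  reproduced by an exact deterministic composition: the three calibration
  targets are mutually inconsistent under this design. The package keeps
  the design (the T2′ effect is the quantity of interest and stays exact)
  and reports the composite T2\* correlation as what it is.
* The within-cortex spatial SD of T2\* is likewise implied (~16 ms), not
  the published ~43 ms.
* The voxel-based thickness estimator is systematically comparable to, but
  not identical with, mesh-based cortical thickness; on the 2 mm grid it
  compresses between-subject differences monotonically.
* The phantom has no gyral folding, so lobe sectors are angular conventions
  rather than anatomy; they are meant for regional-statistics plumbing, not
  for anatomical claims.
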