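# cortexage

Closed-loop simulation of multiparametric quantitative-MRI (qMRI) studies of
cortical aging.

Cross-sectional qMRI studies report that, across healthy adulthood, global
cortical T1 decreases with age (r ≈ −0.42), T2 increases (r ≈ 0.45), the
reversible transverse relaxation time T2′ — a surrogate for tissue iron —
decreases strongly (r ≈ −0.72), T2\* and proton density (PD) show no clear
global trend, and cortical thickness declines (r ≈ −0.44). Those numbers sit
at the end of a long measurement chain: multi-contrast acquisition, voxelwise
relaxometry, cortical segmentation, surface sampling, correlation statistics
with nuisance covariates, and permutation-corrected cluster inference.

`cortexage` rebuilds that entire chain on digital brain phantoms whose
cortical parameters carry *known* linear age effects, so that the chain can
be audited end to end: a linear aging model is calibrated from published
population statistics via

    b = r · s / s_age        (slope, units per year)
    σ_res = s · sqrt(1 − r²) (between-subject residual SD)

phantom cohorts are generated from it, the full acquisition set is
synthesized — a variable-flip-angle FLASH pair (TR 16.4 ms, α 4°/24°), a
4-echo fast-spin-echo stack (TE 17–120 ms), an 8-echo gradient-echo stack
(TE 10–52 ms), a B1 calibration pair and a TE-difference pair (ΔTE 6.7 ms),
with ±10 % transmit/receive bias fields and SNR-50 noise — then every map is
re-fitted voxelwise (B1, T1, PD with CSF-anchored scaling, T2, T2\*,
T2′ = 1/(1/T2\* − 1/T2)), a cortical-ribbon surrogate is built with a
distance-transform thickness estimator and an angular lobe parcellation, and
the global / lobar / voxelwise correlation statistics are computed, the last
with Gaussian smoothing and max-cluster-size permutation correction.

Intended users: imaging methodologists who want a transparent, fully seeded
test bed for cortical qMRI analysis pipelines, and anyone who needs
realistic-but-controlled NIfTI fixtures with known ground truth.

## Worked example

```r
library(cortexage)

model <- default_aging_model()
model
#> Linear cortical aging model (reference age 45 y, age SD 14.97 y)
#>   T1        baseline   1528.75  slope  -1.14123 /y  sigma_res   36.809  (r* -0.421)
#>   PD        baseline     79.48  slope  +0.03547 /y  sigma_res    1.772  (r* +0.287)
#>   T2        baseline     86.99  slope  +0.12396 /y  sigma_res    3.734  (r* +0.445)
#>   T2prime   baseline    201.50  slope  -1.08673 /y  sigma_res   15.500  (r* -0.724)
#>   thickness baseline      2.45  slope  -0.00237 /y  sigma_res    0.072  (r* -0.444)

# simulate a 12-subject cohort, synthesize + fit all maps, measure thickness,
# and return per-subject global cortical values (one row per subject)
d <- cohort_global_means(
  n = 12, seed = 2024,
  geometry = geometry_config(dim = 48, voxel_mm = 2,
                             semi_axes_mm = c(32, 40, 32),
                             ventricle_semi_axes_mm = c(5, 9, 5))
)
round(head(d[, c("age_years", "T1", "T2", "T2star", "T2prime", "thickness_mm")], 4), 2)
#>   age_years      T1    T2 T2star T2prime thickness_mm
#> 1     62.52 1477.52 84.82  54.28  181.87         2.52
#> 2     35.69 1604.31 88.65  57.74  196.06         2.53
#> 3     54.38 1560.79 82.33  56.00  207.23         2.51
#> 4     55.31 1516.84 83.00  52.89  177.28         2.52

correlate(d$T2prime, d$age_years, parameter = "T2prime")
#> global correlation [T2prime]: r = -0.549, p = 0.06479 (n = 12, df = 10)
correlate(d$T2prime, d$age_years, covariates = d[, c("tiv_ml", "sex")],
          parameter = "T2prime")
#> global correlation [T2prime] (partial): r = -0.534, p = 0.112 (n = 12, df = 8) | tiv_ml, sex
```

The fitted global T2′ of each simulated subject falls with age (slope
−1.09 ms/year injected by the model), and at n = 12 the recovered
correlation (−0.55) is a noisy estimate of the calibrated −0.724 — at the
study-scale n = 40, averaged over cohorts, it recovers to within a few
hundredths. The partial correlation (controlling TIV and sex) barely moves,
as expected when the nuisance variables are independent of age.

The disk pipeline (NIfTI volumes, CSV covariates, JSON sidecars and a hashed
run manifest) runs all four stages in order:

```r
run_pipeline(system.file("extdata", "example_cohort.yaml", package = "cortexage"),
             out_dir = "run", seed = 1)
```

or from a shell via the thin CLI wrapper:

```sh
Rscript inst/cli/cortexage.R run --config inst/extdata/example_cohort.yaml --out run --seed 1
```

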