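#' Simulate, acquire and fit one cohort; return per-subject global values
#'
#' The closed-loop measurement chain for one cohort: phantom generation,
#' acquisition synthesis, voxelwise map fitting, ribbon definition (oracle
#' ground-truth labels by default, so the statistics do not inherit
#' segmentation error), distance-transform thickness, and per-subject means
#' of every fitted map over the valid ribbon voxels.
#'
#' @param n number of subjects.
#' @param seed cohort seed.
#' @param model an [aging_model][calibrate_aging_model].
#' @param geometry a [geometry_config()].
#' @param protocol an [acquisition_protocol()].
#' @param oracle_ribbon logical; `TRUE` uses ground-truth tissue masks,
#'   `FALSE` runs MP-RAGE synthesis + GMM segmentation.
#' @param age_range,sex_counts passed to [generate_cohort()].
#' @return data.frame with one row per subject: `subject_id`, `age_years`,
#'   `sex`, `tiv_ml`, fitted ribbon means `T1`, `PD`, `T2`, `T2star`,
#'   `T2prime`, measured `thickness_mm`, plus ground-truth columns
#'   (`true_*`) for diagnostics.
#' @export
cohort_global_means <- function(n = 40, seed = 1L,
                                model = default_aging_model(),
                                geometry = geometry_config(),
                                protocol = acquisition_protocol(),
                                oracle_ribbon = TRUE,
                                age_range = c(19, 71), sex_counts = NULL) {
  lb <- phantom_labels()
  cohort <- generate_cohort(n, age_range, sex_counts, model, geometry,
                            seed = seed, build = FALSE)
  cv <- cohort$covariates
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- build_phantom(cv$age_years[i], cv$sex[i], model, geometry,
                        seed = cohort$subject_seeds[i])
    bundle <- synthesize_acquisition(ph, protocol,
                                     seed = cohort$subject_seeds[i] %% 1000000L + i)
    vent <- ph$labels == lb[["ventricle"]]
    qm <- fit_qmaps(bundle, csf_mask = vent)
    if (oracle_ribbon) {
      ribbon <- ph$labels == lb[["gm"]]
      wm <- ph$labels == lb[["wm"]]
      csf <- ph$labels == lb[["csf"]] | vent
    } else {
      rbm <- build_ribbon_model(qm, brain_mask = ph$labels > 0,
                                truth_labels = ph$labels, method = "gmm",
                                voxel_mm = ph$voxel_mm)
      ribbon <- rbm$ribbon; wm <- rbm$wm; csf <- rbm$csf
    }
    th <- measure_thickness(ribbon, wm, csf, ph$voxel_mm)
    fitted <- vapply(c("T1", "PD", "T2", "T2star", "T2prime"), function(p) {
      v <- qm[[p]][ribbon & qm$masks[[p]]]
      mean(v[is.finite(v)])
    }, numeric(1))
    rows[[i]] <- data.frame(
      subject_id = cv$subject_id[i], age_years = cv$age_years[i],
      sex = cv$sex[i], tiv_ml = ph$tiv_ml,
      T1 = fitted[["T1"]], PD = fitted[["PD"]], T2 = fitted[["T2"]],
      T2star = fitted[["T2star"]], T2prime = fitted[["T2prime"]],
      thickness_mm = th$global_mean,
      true_T1 = ph$param_means[["T1"]], true_T2 = ph$param_means[["T2"]],
      true_T2prime = ph$param_means[["T2prime"]],
      true_thickness = ph$thickness_mm,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Multi-seed recovery of the cohort-level aging statistics
#'
#' Repeats the closed-loop chain of [cohort_global_means()] over several
#' cohort seeds and summarizes, per parameter: the mean (over seeds) of the
#' Pearson correlation between the fitted global cortical value and age,
#' and the mean cohort average of the fitted values.
#'
#' @param n_seeds number of independent cohorts.
#' @param n subjects per cohort.
#' @param base_seed master seed; per-cohort seeds are drawn from it.
#' @param model,geometry,protocol forwarded to [cohort_global_means()].
#' @param oracle_ribbon forwarded to [cohort_global_means()].
#' @param verbose print one line per seed.
#' @return list `per_seed` (data.frame: seed plus r_ and mean_ columns per
#'   parameter), `r_mean` (named vector of seed-averaged correlations),
#'   `cohort_mean` (named vector of seed-averaged cohort means), `n`,
#'   `n_seeds`.
#' @export
recover_aging_statistics <- function(n_seeds = 20, n = 40, base_seed = 1L,
                                     model = default_aging_model(),
                                     geometry = geometry_config(),
                                     protocol = acquisition_protocol(),
                                     oracle_ribbon = TRUE, verbose = FALSE) {
  seeds <- with_seed(base_seed, sample.int(2147483646L, n_seeds))
  params <- c("T1", "PD", "T2", "T2star", "T2prime", "thickness_mm")
  per_seed <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    d <- cohort_global_means(n = n, seed = seeds[s], model = model,
                             geometry = geometry, protocol = protocol,
                             oracle_ribbon = oracle_ribbon)
    r <- vapply(params, function(p) cor(d[[p]], d$age_years), numeric(1))
    mu <- vapply(params, function(p) mean(d[[p]]), numeric(1))
    per_seed[[s]] <- data.frame(
      seed = seeds[s], t(setNames(r, paste0("r_", params))),
      t(setNames(mu, paste0("mean_", params)))
    )
    if (verbose) {
      message(sprintf("seed %d/%d: r(T2prime) = %+0.3f", s, n_seeds,
                      r[["T2prime"]]))
    }
  }
  per_seed <- do.call(rbind, per_seed)
  list(
    per_seed = per_seed,
    r_mean = colMeans(per_seed[paste0("r_", params)]),
    cohort_mean = colMeans(per_seed[paste0("mean_", params)]),
    n = n, n_seeds = n_seeds
  )
}
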