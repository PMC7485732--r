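test_that("labels are disjoint and tile the head; maps are physical", {
  ph <- fixture_phantom()$phantom
  lb <- phantom_labels()
  expect_true(all(ph$labels %in% lb))
  tissue <- ph$labels > 0
  # physicality: 0 < T2* <= T2 < T1, PD in (0, 110]
  expect_true(all(ph$maps$T2star[tissue] > 0))
  expect_true(all(ph$maps$T2star[tissue] <= ph$maps$T2[tissue] + 1e-12))
  expect_true(all(ph$maps$T2[tissue] < ph$maps$T1[tissue]))
  expect_true(all(ph$maps$PD[tissue] > 0 & ph$maps$PD[tissue] <= 110))
  # outside the head there is no signal source
  expect_true(all(ph$maps$PD[!tissue] == 0))
  # T2* is exactly the harmonic composition of T2 and T2'
  expect_equal(
    1 / ph$maps$T2star[tissue],
    1 / ph$maps$T2[tissue] + 1 / ph$maps$T2prime[tissue],
    tolerance = 1e-12
  )
})

test_that("GM shell thickness matches the model value within quantization", {
  # 2.45 mm target on a 1 mm grid -> measured within about half a voxel
  g <- small_geometry(dim = 96, voxel_mm = 1, center_jitter = FALSE)
  m <- default_aging_model(spatial = FALSE)
  for (p in names(m$params)) m$params[[p]]$sigma_res <- 0
  ph <- build_phantom(m$reference_age, "F", m, g, seed = 1)
  th <- measure_thickness(gm_mask(ph), wm_mask(ph), csf_mask_all(ph),
                          voxel_mm = 1)
  expect_gt(th$global_mean, 1.95)
  expect_lt(th$global_mean, 2.95)
  # sigma_res = 0 at the reference age: cortical T1 mean is the baseline
  gm <- gm_mask(ph)
  expect_equal(mean(ph$maps$T1[gm]), 1528.75, tolerance = 1e-6)
})

test_that("TIV follows the ellipsoid scaling law", {
  g1 <- small_geometry(dim = 48, voxel_mm = 2, center_jitter = FALSE,
                       subject_scale_sd = 0)
  g2 <- geometry_config(dim = 96, voxel_mm = 2, center_jitter = FALSE,
                        subject_scale_sd = 0,
                        semi_axes_mm = g1$semi_axes_mm * 2,
                        ventricle_semi_axes_mm = g1$ventricle_semi_axes_mm * 2)
  ph1 <- build_phantom(45, "F", geometry = g1, seed = 3)
  ph2 <- build_phantom(45, "F", geometry = g2, seed = 3)
  expect_equal(ph2$tiv_ml / ph1$tiv_ml, 8, tolerance = 0.02)
})

test_that("too-thin cortex raises a geometry error", {
  m <- default_aging_model()
  m$params$thickness$baseline <- 1.2 # below one 2 mm voxel
  m$params$thickness$sigma_res <- 0
  expect_error(build_phantom(45, "F", m, small_geometry(), seed = 1),
               "GM shell thinner than one voxel")
})

test_that("cohorts honor demographics and are seed-reproducible", {
  g <- small_geometry(dim = 32, voxel_mm = 2)
  co <- generate_cohort(40, model = default_aging_model(), geometry = g,
                        seed = 5, build = FALSE)
  cv <- co$covariates
  expect_equal(nrow(cv), 40)
  expect_equal(sum(cv$sex == "M"), 19) # 19 of 40 male
  expect_equal(sum(cv$sex == "M") / 40 * 100, 47.5)
  expect_true(all(cv$age_years >= 19 & cv$age_years <= 71))
  # uniform ages on 19-71 have population SD 15.01; sample SD is near it
  expect_gt(sd(cv$age_years), 12)
  expect_lt(sd(cv$age_years), 18)
  expect_error(generate_cohort(10, sex_counts = c(M = 4, F = 5)),
               "sum to n")

  # bit-exact reproducibility of built phantoms under the same seed
  co1 <- generate_cohort(3, geometry = g, seed = 11)
  co2 <- generate_cohort(3, geometry = g, seed = 11)
  expect_identical(co1$covariates, co2$covariates)
  expect_identical(co1$subjects[[2]]$maps, co2$subjects[[2]]$maps)
  expect_identical(co1$subjects[[3]]$labels, co2$subjects[[3]]$labels)
  # and the unbuilt route yields the same subject-level true means
  co3 <- generate_cohort(3, geometry = g, seed = 11, build = FALSE)
  expect_equal(co3$true_means, co1$true_means)
})

test_that("zero-slope model leaves only residual differences between subjects", {
  m <- null_aging_model(spatial = FALSE)
  g <- small_geometry(dim = 32, voxel_mm = 2)
  co <- generate_cohort(3, model = m, geometry = g, seed = 2, build = FALSE)
  tm <- co$true_means
  expect_true(all(abs(tm[, "T1"] - 1528.75) < 5 * 40.58))
  expect_gt(sd(tm[, "T1"]), 0) # residual noise present
})

test_that("regional slope multipliers inject lobe-specific effects", {
  m <- default_aging_model(spatial = FALSE)
  m$lobe_multipliers <- list(frontal = 2, occipital = 0)
  for (p in names(m$params)) m$params[[p]]$sigma_res <- 0
  g <- small_geometry(center_jitter = FALSE)
  ph_old <- build_phantom(65, "F", m, g, seed = 1)
  lob <- parcellate_lobes(gm_mask(ph_old), g$voxel_mm)
  tab <- lobe_table()
  t1 <- ph_old$maps$T1
  front <- lob$labels %in% tab$code[tab$lobe == "frontal"]
  occ <- lob$labels %in% tab$code[tab$lobe == "occipital"]
  base <- aging_model_mean(m, "T1", m$reference_age)
  slope20 <- m$params$T1$slope * (65 - m$reference_age)
  expect_equal(mean(t1[front]), base + 2 * slope20, tolerance = 0.02)
  expect_equal(mean(t1[occ]), base, tolerance = 0.02)
})
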