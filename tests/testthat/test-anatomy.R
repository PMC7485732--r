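test_that("MP-RAGE contrast is WM-bright and matches the closed form", {
  # closed form, evaluated independently
  ir <- function(pd, t1, ti = 900, tr = 1900, a = 9) {
    pd * sin(a * pi / 180) * (1 - 2 * exp(-ti / t1) + exp(-tr / t1))
  }
  t1 <- array(c(850, 1500, 1300, 4000), c(4, 1, 1))
  pd <- array(c(70, 80, 80, 100), c(4, 1, 1))
  mp <- synthesize_mprage(t1, pd)
  # WM (short T1) brighter than GM (long T1)
  expect_gt(mp$contrast[1], mp$contrast[2])
  # rescaling is affine: check against the raw closed form
  raw <- ir(pd, t1)
  expect_equal(cor(as.vector(mp$contrast), as.vector(raw)), 1,
               tolerance = 1e-12)
  expect_equal(range(mp$contrast), c(0, 1000))
  # PD = 0 gives the minimum signal
  mp0 <- synthesize_mprage(array(c(1300, 1300), c(2, 1, 1)),
                           array(c(0, 80), c(2, 1, 1)))
  expect_equal(mp0$contrast[1], 0)
})

test_that("GMM segmentation is perfect on well-separated noiseless classes", {
  ph <- build_phantom(45, "F", default_aging_model(spatial = FALSE),
                      small_geometry(), seed = 9)
  mp <- synthesize_mprage(ph$maps$T1, ph$maps$PD)
  seg <- segment_ribbon(mp$contrast, ph$labels > 0, method = "gmm",
                        truth_labels = ph$labels)
  expect_equal(unname(seg$dice), c(1, 1, 1))
  # oracle mode bypasses segmentation entirely
  seg_o <- segment_ribbon(mp$contrast, ph$labels > 0, method = "oracle",
                          truth_labels = ph$labels)
  expect_identical(seg_o$ribbon, gm_mask(ph))
})

test_that("segmentation stays accurate on fitted maps at SNR 50", {
  fx <- fixture_phantom()
  ph <- fx$phantom
  b <- synthesize_acquisition(ph, acquisition_protocol(snr = 50), seed = 21)
  qm <- fit_qmaps(b, csf_mask = vent_mask(ph))
  rbm <- build_ribbon_model(qm, ph$labels > 0, truth_labels = ph$labels,
                            method = "gmm", voxel_mm = ph$voxel_mm)
  expect_gte(rbm$dice[["gm"]], 0.95)
})

test_that("thickness estimator is exact on a slab within half a voxel", {
  # 2.4 mm slab on a 0.5 mm grid
  vox <- 0.5
  dm <- c(12, 12, 40)
  z <- (seq_len(dm[3]) - 0.5) * vox # voxel centers, slab from z = 5
  zlab <- ifelse(z < 5, 3L, ifelse(z < 7.4, 2L, 1L))
  lab <- aperm(array(zlab, c(dm[3], dm[1], dm[2])), c(2, 3, 1))
  th <- measure_thickness(lab == 2L, lab == 3L, lab == 1L, vox)
  expect_gt(th$global_mean, 2.15)
  expect_lt(th$global_mean, 2.65)
})

test_that("thickness estimator is exact on a spherical shell", {
  # shell with inner radius 30 mm, outer 33 mm -> 3 mm thick
  vox <- 1
  dm <- c(80, 80, 80)
  cc <- (seq_len(80) - 40.5) * vox
  r <- sqrt(outer(outer(cc^2, cc^2, `+`), cc^2, `+`))
  ribbon <- r >= 30 & r < 33
  wm <- r < 30
  csf <- r >= 33 & r < 38
  th <- measure_thickness(ribbon, wm, csf, vox)
  expect_equal(th$global_mean, 3, tolerance = 0.5 / 3)
  expect_error(measure_thickness(ribbon, array(FALSE, dm), csf, vox),
               "empty boundary mask")
})

test_that("cohort-mean measured thickness is close to the 2.45 mm baseline", {
  d <- lapply(1:6, function(i) {
    ph <- build_phantom(35 + i * 3, if (i %% 2) "M" else "F",
                        geometry = small_geometry(), seed = 100 + i)
    measure_thickness(gm_mask(ph), wm_mask(ph), csf_mask_all(ph),
                      ph$voxel_mm)$global_mean
  })
  expect_lt(abs(mean(unlist(d)) - 2.45), 0.2)
})

test_that("lobe sectors partition the ribbon symmetrically", {
  g <- small_geometry(center_jitter = FALSE, subject_scale_sd = 0)
  ph <- build_phantom(45, "F", geometry = g, seed = 2)
  lob <- parcellate_lobes(gm_mask(ph), g$voxel_mm)
  # union of the 8 sectors is exactly the ribbon
  expect_identical(lob$labels > 0, gm_mask(ph))
  # left/right counts match within 1 percent (mirror symmetry)
  tab <- lob$table
  left <- tab$n_voxels[tab$hemisphere == "left"]
  right <- tab$n_voxels[tab$hemisphere == "right"]
  expect_true(all(abs(left - right) / pmax(left, right) <= 0.01))
  expect_error(parcellate_lobes(array(FALSE, dim(ph$labels)), 2),
               "empty ribbon")
})

test_that("TIV is the voxel-count times the voxel volume", {
  m <- array(FALSE, c(64, 64, 64))
  m[seq_len(64 * 64 * 32)] <- TRUE # half the grid
  expect_equal(compute_tiv(m, 2), 131072 * 8 / 1000) # 1048.576 mL
})
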