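arr <- function(x, d = c(2, 2, 2)) array(x, dim = d)

test_that("fit_b1 inverts the cosine saturation model", {
  ref <- arr(10)
  # ratio 0.5 at beta 60 -> kappa exactly 1
  b <- fit_b1(ref, ref * 0.5, nominal_beta = 60)
  expect_equal(unique(as.vector(b$kappa)), 1, tolerance = 1e-12)
  # ratio 0.400 -> kappa about 1.107
  b2 <- fit_b1(ref, ref * 0.4, nominal_beta = 60)
  expect_equal(unique(as.vector(b2$kappa)), 1.1070, tolerance = 1e-4)
  # degenerate ratio 1 -> kappa 0, masked invalid
  b3 <- fit_b1(ref, ref, nominal_beta = 60)
  expect_true(all(!b3$mask))
  expect_true(all(is.na(b3$kappa)))
  # swapped acquisition order is detected
  expect_error(fit_b1(ref * 0.4, ref, nominal_beta = 60),
               "acquisition-order error")
})

test_that("fit_monoexp is exact on noiseless decays", {
  dm <- c(3, 3, 3)
  for (cse in list(list(td = 80, te = c(17, 86, 103, 120)),
                   list(td = 55, te = seq(10, 52, 6)))) {
    stack <- array(0, c(dm, length(cse$te)))
    for (i in seq_along(cse$te)) {
      stack[, , , i] <- 100 * exp(-cse$te[i] / cse$td)
    }
    f <- fit_monoexp(stack, cse$te)
    expect_equal(as.vector(f$tdecay), rep(cse$td, prod(dm)),
                 tolerance = 1e-10)
    expect_equal(as.vector(f$s0), rep(100, prod(dm)), tolerance = 1e-10)
    expect_true(all(f$r2 > 1 - 1e-12))
  }
})

test_that("voxels with non-decaying or too-few echoes are masked", {
  te <- c(10, 20, 30)
  stack <- array(0, c(1, 1, 2, 3))
  stack[1, 1, 1, ] <- 100 * exp(te / 50) # growing signal: invalid
  stack[1, 1, 2, ] <- c(100, 0, 0) # single usable echo: invalid
  f <- fit_monoexp(stack, te)
  expect_true(all(!f$mask))
  expect_true(all(is.na(f$tdecay)))
})

test_that("log-linear weighted fit is nearly unbiased against the nls oracle", {
  # Monte-Carlo: 600 noisy draws of a T2 = 90 ms voxel at SNR 40
  te <- c(17, 86, 103, 120)
  n <- 600
  withr::with_seed(7, {
    s <- outer(rep(100, n), exp(-te / 90)) + rnorm(n * 4, 0, 100 / 40)
  })
  s[s < 0] <- 0
  stack <- array(s, c(n, 1, 1, 4))
  ll <- fit_monoexp(stack, te)
  nl <- fit_monoexp(stack, te, method = "nls")
  m_ll <- median(ll$tdecay, na.rm = TRUE)
  m_nl <- median(nl$tdecay, na.rm = TRUE)
  expect_lt(abs(m_ll - m_nl) / m_nl, 0.01)
  expect_lt(abs(m_ll - 90) / 90, 0.03)
})

test_that("noisy VFA T1 is recovered within 2 percent in the median", {
  # 1000 Monte-Carlo draws of one voxel at SNR 50
  t1 <- 1300; tr <- 16.4; angles <- c(4, 24)
  s_true <- vapply(angles, function(a) {
    spgr_signal(80, t1, 60, a, tr, 6.7)
  }, numeric(1))
  n <- 1000
  withr::with_seed(11, {
    s1 <- arr(s_true[1] + rnorm(n, 0, s_true[2] / 50), c(n, 1, 1))
    s2 <- arr(s_true[2] + rnorm(n, 0, s_true[2] / 50), c(n, 1, 1))
  })
  f <- fit_t1_vfa(s1, s2, angles, tr)
  expect_lt(abs(median(f$t1, na.rm = TRUE) - t1) / t1, 0.02)
})

test_that("noiseless fitters agree with the brute-force nls oracle", {
  # oracle equivalence on a handful of tissue voxels of the fixture bundle
  fx <- fixture_phantom()
  ph <- fx$phantom; b <- fx$bundle
  idx <- which(ph$labels == phantom_labels()[["gm"]])[c(1, 50, 200)]
  ij <- arrayInd(idx, dim(ph$labels))
  sub_stack <- function(s) {
    out <- array(0, c(nrow(ij), 1, 1, dim(s)[4]))
    for (e in seq_len(dim(s)[4])) {
      out[, 1, 1, e] <- s[cbind(ij, e)]
    }
    out
  }
  te <- b$protocol$fse_te
  ll <- fit_monoexp(sub_stack(b$fse), te)
  nl <- fit_monoexp(sub_stack(b$fse), te, method = "nls")
  expect_equal(as.vector(ll$tdecay), as.vector(nl$tdecay), tolerance = 1e-6)
  expect_equal(as.vector(ll$tdecay), ph$maps$T2[idx], tolerance = 1e-6)
})

test_that("T2' derivation satisfies its algebraic identities", {
  t2 <- arr(100)
  # T2* = T2/2 -> T2' = T2
  d <- derive_t2prime(t2, t2 / 2)
  expect_equal(as.vector(d$t2prime), rep(100, 8), tolerance = 1e-12)
  # printed-value check: T2 = 86.99, T2* = 61.60 -> T2' = 211.05
  d2 <- derive_t2prime(arr(86.99), arr(61.60))
  expect_equal(unique(as.vector(d2$t2prime)), 211.0503, tolerance = 1e-4)
  # T2* = T2 (infinite T2') and T2* > T2 are masked, not clipped
  d3 <- derive_t2prime(t2, t2)
  expect_true(all(!d3$mask) && all(is.na(d3$t2prime)))
  d4 <- derive_t2prime(t2, t2 * 1.2)
  expect_true(all(!d4$mask))
})

test_that("fitted T2' is monotone in ground-truth T2' (noiseless)", {
  te_fse <- c(17, 86, 103, 120); te_ge <- seq(10, 52, 6)
  t2 <- 90
  t2p_grid <- seq(120, 320, by = 40)
  fitted <- vapply(t2p_grid, function(t2p) {
    t2s <- 1 / (1 / t2 + 1 / t2p)
    fse <- array(rep(80 * exp(-te_fse / t2), each = 1), c(1, 1, 1, 4))
    ge <- array(rep(80 * exp(-te_ge / t2s), each = 1), c(1, 1, 1, 8))
    f2 <- fit_monoexp(fse, te_fse)$tdecay[1]
    f2s <- fit_monoexp(ge, te_ge)$tdecay[1]
    derive_t2prime(array(f2, c(1, 1, 1)), array(f2s, c(1, 1, 1)))$t2prime[1]
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
  expect_equal(fitted, t2p_grid, tolerance = 1e-8)
})

test_that("TE-difference pair recovers the pairwise T2*", {
  # T2* = 50 ms, dTE = 6.7 -> ratio exp(-6.7/50) = 0.8745
  expect_equal(exp(-6.7 / 50), 0.8746, tolerance = 1e-4)
  pair <- array(0, c(2, 2, 2, 2))
  pair[, , , 1] <- 90
  pair[, , , 2] <- 90 * exp(-6.7 / 50)
  pd <- fit_pd(
    intercept = arr(10), t1 = arr(1300), tr = 16.4, te_pair = pair,
    te_vfa = 6.7, dte = 6.7, receive_field = 1,
    csf_mask = arr(c(TRUE, rep(FALSE, 7)))
  )
  expect_equal(unique(as.vector(pd$t2star_pair)), 50, tolerance = 1e-9)
  expect_error(
    fit_pd(arr(10), arr(1300), 16.4, pair, 6.7, 6.7, 1,
           csf_mask = arr(FALSE)),
    "calibration error"
  )
})

test_that("noiseless PD equals ground truth after CSF scaling", {
  fx <- fixture_phantom()
  ph <- fx$phantom
  qm <- fit_qmaps(fx$bundle, csf_mask = vent_mask(ph))
  gm <- gm_mask(ph) & qm$masks$PD
  expect_equal(mean(qm$PD[gm]), mean(ph$maps$PD[gm_mask(ph)]),
               tolerance = 1e-6)
  # ventricle CSF sits at 100 p.u. by construction
  vent <- vent_mask(ph) & qm$masks$PD
  expect_equal(median(qm$PD[vent]), 100, tolerance = 1e-9)
})

test_that("masks are sound: no non-finite values among valid voxels", {
  ph <- fixture_phantom()$phantom
  b <- synthesize_acquisition(ph, acquisition_protocol(snr = 30), seed = 5)
  qm <- fit_qmaps(b, csf_mask = vent_mask(ph))
  for (p in c("T1", "PD", "T2", "T2star", "T2prime")) {
    v <- qm[[p]][qm$masks[[p]]]
    expect_true(all(is.finite(v)), label = paste("finite", p))
    expect_true(all(v > 0), label = paste("positive", p))
  }
  ok <- qm$masks$T2prime
  expect_true(all(qm$T2star[ok] < qm$T2[ok]))
})
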