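test_that("global summary computes per-subject means and sample SDs", {
  dm <- c(4, 4, 4)
  cons <- array(100, dm)
  rib <- array(TRUE, dm)
  gs <- global_summary(list(list(T1 = cons)), list(rib))
  expect_equal(gs$per_subject$mean, 100)
  expect_equal(gs$per_subject$sd, 0)

  # two-voxel ribbon {80, 120}: mean 100, sample SD 28.284
  two <- array(NA_real_, dm)
  two[1] <- 80; two[2] <- 120
  rib2 <- array(FALSE, dm); rib2[1:2] <- TRUE
  gs2 <- global_summary(list(list(T2 = two)), list(rib2))
  expect_equal(gs2$per_subject$mean, 100)
  expect_equal(gs2$per_subject$sd, 28.2843, tolerance = 1e-4)

  expect_warning(
    global_summary(list(list(T1 = cons), list(T1 = cons)),
                   list(rib, array(FALSE, dm))),
    "empty ribbon"
  )
})

test_that("correlate matches hand-computed Pearson values", {
  expect_equal(correlate(1:5, 1:5)$r, 1)
  r <- correlate(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(r$r, 0.8) # sum of deviation products 8 / sqrt(10 * 10)
  expect_equal(r$df, 3)
  expect_error(correlate(1:5, rep(1, 5)), "zero variance")
  expect_error(correlate(1:2, 2:3), "n too small")
})

test_that("partial correlation equals the correlation-matrix-inverse oracle", {
  # brute-force oracle: r_xy.z = -inv(R)[1,2] / sqrt(inv(R)[1,1] inv(R)[2,2])
  oracle <- function(x, y, z) {
    R <- cor(cbind(x, y, z))
    P <- solve(R)
    -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  }
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(8:30, 1)
      z <- matrix(rnorm(2 * n), n, 2)
      x <- rnorm(n) + z %*% c(0.5, -0.3)
      y <- rnorm(n) + z %*% c(-0.2, 0.7)
      got <- correlate(as.vector(x), as.vector(y), covariates = z)$r
      expect_equal(got, oracle(x, y, z), tolerance = 1e-10)
    }
  })
})

test_that("partial correlation converges to plain r for irrelevant covariates", {
  withr::with_seed(5, {
    n <- 4000
    x <- rnorm(n); y <- 0.5 * x + rnorm(n); z <- rnorm(n)
  })
  plain <- correlate(x, y)$r
  part <- correlate(x, y, covariates = data.frame(z = z))$r
  expect_equal(part, plain, tolerance = 0.01)
})

test_that("smoothing preserves constants, masses and the identity at fwhm 0", {
  dm <- c(12, 12, 12)
  mask <- array(FALSE, dm); mask[3:10, 3:10, 3:10] <- TRUE
  v <- array(rnorm(prod(dm)), dm)
  # fwhm = 0 is the identity on the mask
  s0 <- smooth_map(v, 0, voxel_mm = 2, mask = mask)
  expect_equal(s0[mask], v[mask])
  expect_true(all(is.na(s0[!mask])))
  # constant maps are unchanged (mask-normalized partition of unity)
  cons <- array(7, dm)
  sc <- smooth_map(cons, 10, voxel_mm = 2, mask = mask)
  expect_equal(sc[mask], rep(7, sum(mask)), tolerance = 1e-12)
  # no bleed-in: values outside the mask do not affect the result
  v2 <- v; v2[!mask] <- 1e6
  expect_equal(smooth_map(v, 10, 2, mask), smooth_map(v2, 10, 2, mask))
})

test_that("delta mass is preserved under interior smoothing", {
  dm <- c(29, 29, 29)
  mask <- array(TRUE, dm)
  v <- array(0, dm); v[15, 15, 15] <- 5 # interior: kernel never hits an edge
  s <- smooth_map(v, 8, voxel_mm = 2, mask = mask)
  expect_equal(sum(s), 5, tolerance = 1e-9)
})

test_that("cluster p-values equal brute-force exhaustive enumeration", {
  # 3 x 3 single-slice toy ribbon, n = 6 subjects, all 720 permutations
  dm <- c(3, 3, 1)
  ribbon <- array(TRUE, dm)
  n <- 6
  ages <- c(22, 30, 41, 48, 57, 66)
  withr::with_seed(13, {
    maps <- lapply(seq_len(n), function(i) {
      array(rnorm(9), dm) + ages[i] * 0.08 * array(c(1, 1, 0, 1, 0, 0, 0, 0, 0), dm)
    })
  })
  rep_ <- mapwise_correlation(maps, ages, ribbon, threshold_p = 0.05,
                              exhaustive = TRUE)

  # independent brute-force oracle: recursive flood fill + direct loops
  flood_sizes <- function(sel_mat) {
    seen <- matrix(FALSE, 3, 3)
    sizes <- integer(0)
    for (i in 1:3) for (j in 1:3) {
      if (sel_mat[i, j] && !seen[i, j]) {
        stack <- list(c(i, j)); size <- 0
        while (length(stack)) {
          p <- stack[[1]]; stack <- stack[-1]
          if (p[1] < 1 || p[1] > 3 || p[2] < 1 || p[2] > 3) next
          if (seen[p[1], p[2]] || !sel_mat[p[1], p[2]]) next
          seen[p[1], p[2]] <- TRUE; size <- size + 1
          stack <- c(stack, list(p + c(1, 0), p - c(1, 0),
                                 p + c(0, 1), p - c(0, 1)))
        }
        sizes <- c(sizes, size)
      }
    }
    sizes
  }
  vox_vals <- sapply(maps, function(m) as.vector(m[, , 1])) # 9 x 6
  stat_sizes <- function(a) {
    rs <- apply(vox_vals, 1, function(v) cor(v, a))
    ps <- 2 * pt(-abs(rs * sqrt(4 / (1 - rs^2))), 4)
    list(pos = flood_sizes(matrix(ps < 0.05 & rs > 0, 3, 3)),
         neg = flood_sizes(matrix(ps < 0.05 & rs < 0, 3, 3)))
  }
  perms <- NULL
  for (p1 in 1:6) for (p2 in setdiff(1:6, p1)) for (p3 in setdiff(1:6, c(p1, p2)))
    for (p4 in setdiff(1:6, c(p1, p2, p3))) for (p5 in setdiff(1:6, c(p1, p2, p3, p4)))
      perms <- c(perms, list(c(p1, p2, p3, p4, p5,
                               setdiff(1:6, c(p1, p2, p3, p4, p5)))))
  expect_length(perms, 720)
  null_max <- sapply(perms, function(pm) {
    s <- stat_sizes(ages[pm])
    max(c(0, s$pos, s$neg)) # map-wise max over both signs
  })
  obs <- stat_sizes(ages)
  expect_gte(nrow(rep_$clusters), 1)
  for (i in seq_len(nrow(rep_$clusters))) {
    cl <- rep_$clusters[i, ]
    expect_equal(cl$p, mean(null_max >= cl$size))
  }
  # the observed clusters themselves agree with the oracle
  expect_setequal(rep_$clusters$size[rep_$clusters$sign == "pos"], obs$pos)
})

test_that("cluster inference localizes an injected regional effect", {
  m <- default_aging_model(spatial = FALSE)
  m$lobe_multipliers <- list(frontal = 1, parietal = 0, temporal = 0,
                             occipital = 0)
  for (p in names(m$params)) m$params[[p]]$sigma_res <- 0
  g <- small_geometry(dim = 32, voxel_mm = 2, center_jitter = FALSE,
                      subject_scale_sd = 0)
  ages <- seq(20, 70, length.out = 12)
  phs <- lapply(seq_along(ages), function(i) {
    build_phantom(ages[i], "F", m, g, seed = 300 + i)
  })
  ribbon <- gm_mask(phs[[1]])
  lob <- parcellate_lobes(ribbon, g$voxel_mm)
  maps <- lapply(phs, function(p) p$maps$T2prime)
  rep_ <- mapwise_correlation(maps, ages, ribbon, n_perm = 200, seed = 4)
  sig <- rep_$clusters[rep_$clusters$significant & rep_$clusters$sign == "neg", ]
  expect_gte(nrow(sig), 1)
  tab <- lobe_table()
  front_codes <- tab$code[tab$lobe == "frontal"]
  in_front <- lob$labels %in% front_codes & rep_$labels %in% sig$id
  expect_gte(sum(in_front) / sum(rep_$labels %in% sig$id), 0.9)
})

test_that("lobar analysis averages hemispheres and flags significance", {
  # hand-built scalar check: left/right lobe values {a, b} average to (a+b)/2
  dm <- c(6, 6, 2)
  lab <- array(0L, dm)
  lab[1, 1, 1] <- 1L; lab[6, 1, 1] <- 5L # frontal left/right
  lab[1, 3, 1] <- 2L; lab[6, 3, 1] <- 6L # parietal
  lab[1, 4, 2] <- 3L; lab[6, 4, 2] <- 7L # temporal
  lab[1, 6, 1] <- 4L; lab[6, 6, 1] <- 8L # occipital
  n <- 8
  ages <- seq(20, 69, length.out = n)
  maps <- list(); lobes <- list(); thick <- list()
  set.seed(17)
  for (i in seq_len(n)) {
    v <- array(NA_real_, dm)
    v[lab == 1L] <- 10 + ages[i]; v[lab == 5L] <- 20 + ages[i] # frontal a, b
    v[lab %in% c(2L, 6L)] <- 50 + rnorm(1)
    v[lab %in% c(3L, 7L)] <- 60 + rnorm(1)
    v[lab %in% c(4L, 8L)] <- 70 + rnorm(1)
    maps[[i]] <- list(X = v)
    lobes[[i]] <- lab
    tv <- array(NA_real_, dm); tv[lab > 0] <- 2.5 + rnorm(1, 0, 0.01)
    thick[[i]] <- tv
  }
  res <- lobar_analysis(maps, lobes, ages, thick, tiv = rep(1000, n))
  fr <- res$regional_means[res$regional_means$lobe == "frontal", ]
  expect_equal(fr$value, 15 + ages) # (10+a + 20+a)/2
  tabf <- res$table[res$table$lobe == "frontal" & res$table$parameter == "X", ]
  expect_equal(tabf$r_age, 1, tolerance = 1e-12)
  expect_true(tabf$sig_age)
})

test_that("null correlations are flagged at about the nominal 5 percent rate", {
  withr::with_seed(23, {
    hits <- replicate(400, {
      correlate(rnorm(40), rnorm(40))$p < 0.05
    })
  })
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})
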