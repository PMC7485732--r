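#' Build one digital brain phantom
#'
#' Constructs the nested-ellipsoid label volume (WM core, cortical GM shell
#' of age-dependent thickness, outer CSF layer, one ventricle) and the
#' voxelwise ground-truth T1, PD, T2, T2* maps. The cortical-GM shell is
#' delimited by an approximate Euclidean distance to the pial surface so its
#' thickness is uniform; cortical parameter values are the subject-level
#' means drawn from the aging model plus, optionally, a fixed smooth spatial
#' profile scaled to the model's within-cortex SD. Ground-truth T2* is
#' derived voxelwise from T2 and T2' via 1/T2* = 1/T2 + 1/T2', so the
#' reversible component carries the injected age effect exactly.
#'
#' @param age age in years.
#' @param sex `"M"` or `"F"`.
#' @param model an [aging_model][calibrate_aging_model] (must contain
#'   parameters T1, PD, T2, T2prime, thickness).
#' @param geometry a [geometry_config()].
#' @param seed integer seed for the subject-level random draws.
#' @return an object of class `subject_phantom`: `labels` (integer array,
#'   see [phantom_labels()]), `maps` (list of T1/PD/T2/T2star/T2prime
#'   arrays; 0 outside the head), `age`, `sex`, `tiv_ml`, `thickness_mm`
#'   (true shell thickness), `param_means` (subject-level true cortical
#'   means), `voxel_mm`, `geometry`, `seed`.
#' @export
build_phantom <- function(age, sex = "F", model = default_aging_model(),
                          geometry = geometry_config(), seed = 1L) {
  g <- geometry
  with_seed(seed, {
    scale <- exp(rnorm(1, 0, g$subject_scale_sd)) *
      if (identical(sex, "M")) g$male_scale else 1
    jitter <- if (g$center_jitter) runif(3, -0.5, 0.5) * g$voxel_mm else c(0, 0, 0)
    means <- drop(draw_subject_means(model, age))
    build_phantom_deterministic(age, sex, means, scale, jitter, model, g, seed)
  })
}

# deterministic core, separated so tests can pin subject-level draws
build_phantom_deterministic <- function(age, sex, means, scale, jitter,
                                        model, g, seed = NA_integer_) {
  vox <- g$voxel_mm
  semi <- g$semi_axes_mm * scale
  fov2 <- g$dim * vox / 2
  if (any(semi + abs(jitter) >= fov2 - vox)) {
    stop("geometry error: scaled ellipsoid does not fit the grid")
  }

  thick <- unname(means["thickness"])
  if (!is.finite(thick) || thick < vox) {
    stop("geometry error: GM shell thinner than one voxel (",
         signif(thick, 3), " mm at ", vox, " mm)")
  }

  co <- coord_arrays(g$dim, vox, center = jitter)
  ux <- co$x / semi[1]; uy <- co$y / semi[2]; uz <- co$z / semi[3]
  m <- sqrt(ux^2 + uy^2 + uz^2)
  # first-order Euclidean distance to the outer surface (positive inside)
  gn <- sqrt((co$x / semi[1]^2)^2 + (co$y / semi[2]^2)^2 + (co$z / semi[3]^2)^2)
  d_in <- ifelse(m > 1e-6, (1 - m) * m / gn, max(semi))

  lab <- array(phantom_labels()[["background"]], dim = g$dim)
  inside <- d_in >= 0
  csf_th <- g$csf_thickness_mm
  lab[inside] <- phantom_labels()[["csf"]]
  lab[inside & d_in >= csf_th] <- phantom_labels()[["gm"]]
  lab[inside & d_in >= csf_th + thick] <- phantom_labels()[["wm"]]
  vsemi <- g$ventricle_semi_axes_mm * scale
  mv <- sqrt((co$x / vsemi[1])^2 + (co$y / vsemi[2])^2 + (co$z / vsemi[3])^2)
  lab[mv <= 1 & lab == phantom_labels()[["wm"]]] <- phantom_labels()[["ventricle"]]

  gm <- lab == phantom_labels()[["gm"]]
  wm <- lab == phantom_labels()[["wm"]]
  csf <- lab == phantom_labels()[["csf"]] | lab == phantom_labels()[["ventricle"]]
  if (!any(gm) || !any(wm)) stop("geometry error: degenerate tissue classes")

  # regional slope multipliers (default 1 everywhere)
  mult <- 1
  if (!is.null(model$lobe_multipliers)) {
    sec <- lobe_sector(co$x[gm], co$y[gm], co$z[gm],
                       g$frontal_deg, g$occipital_deg)
    tab <- lobe_table()
    mult <- rep(1, sum(gm))
    for (ln in names(model$lobe_multipliers)) {
      codes <- tab$code[tab$lobe == ln]
      mult[sec %in% codes] <- model$lobe_multipliers[[ln]]
    }
  }

  floors <- c(T1 = 200, PD = 1, T2 = 15, T2prime = 15)
  maps <- list()
  for (p in c("T1", "PD", "T2", "T2prime")) {
    vol <- array(0, dim = g$dim)
    vol[wm] <- g$wm[[p]]
    vol[csf] <- g$csf[[p]]
    e <- model$params[[p]]
    resid <- unname(means[p]) - aging_model_mean(model, p, age)
    gmval <- e$baseline + mult * e$slope * (age - model$reference_age) + resid
    if (e$cortex_sd > 0) {
      prof <- spatial_profile(p, ux[gm], uy[gm], uz[gm])
      prof <- (prof - mean(prof)) / sample_sd(prof)
      prof <- pmin(pmax(prof, -2.5), 2.5)
      gmval <- gmval + e$cortex_sd * prof
    }
    vol[gm] <- pmax(gmval, floors[[p]])
    if (p == "PD") vol <- pmin(vol, 110)
    maps[[p]] <- vol
  }
  t2star <- array(0, dim = g$dim)
  tissue <- lab > 0
  t2star[tissue] <- 1 / (1 / maps$T2[tissue] + 1 / maps$T2prime[tissue])
  maps$T2star <- t2star
  maps <- maps[c("T1", "PD", "T2", "T2star", "T2prime")]

  structure(
    list(
      labels = lab, maps = maps, age = age, sex = sex,
      tiv_ml = sum(tissue) * vox^3 / 1000,
      thickness_mm = thick,
      param_means = means, scale = scale, jitter = jitter,
      voxel_mm = vox, geometry = g, model = model, seed = seed
    ),
    class = "subject_phantom"
  )
}

#' @export
print.subject_phantom <- function(x, ...) {
  cat(sprintf(
    "subject_phantom: age %.1f y, sex %s, grid %s @ %g mm, TIV %.0f mL, cortical thickness %.2f mm\n",
    x$age, x$sex, paste(dim(x$labels), collapse = "x"), x$voxel_mm,
    x$tiv_ml, x$thickness_mm
  ))
  invisible(x)
}

#' Generate a cohort of digital brain phantoms
#'
#' Ages are drawn uniformly on `age_range` (a uniform law on 19-71 years has
#' population SD 15.01, matching the reference cohort's 14.97). Sexes are
#' assigned deterministically to the configured counts, then shuffled by the
#' seed. Identical seeds reproduce the cohort bit-exactly.
#'
#' @param n number of subjects (>= 1; the statistics layer requires >= 3).
#' @param age_range two ages in years, min < max.
#' @param sex_counts named vector `c(M = ..., F = ...)` summing to `n`;
#'   default splits 47.5 percent male (19/40), rounding down.
#' @param model an [aging_model][calibrate_aging_model].
#' @param geometry a [geometry_config()].
#' @param seed integer seed.
#' @param build logical; if `FALSE`, return demographics and subject-level
#'   true means only (no volumes), for scalar-level calibration checks.
#' @return an object of class `cohort`: `subjects` (list of
#'   `subject_phantom` or `NULL` if `build = FALSE`), `covariates`
#'   (data.frame subject_id, age_years, sex, tiv_ml), `true_means`
#'   (subjects x parameters matrix), `model`, `geometry`, `seed`.
#' @export
generate_cohort <- function(n = 40, age_range = c(19, 71),
                            sex_counts = NULL,
                            model = default_aging_model(),
                            geometry = geometry_config(),
                            seed = 1L, build = TRUE) {
  if (n < 1) stop("configuration error: n must be >= 1")
  if (diff(age_range) <= 0) stop("configuration error: degenerate age range")
  if (is.null(sex_counts)) {
    nm <- floor(n * 19 / 40)
    sex_counts <- c(M = nm, F = n - nm)
  }
  if (sum(sex_counts) != n) {
    stop("configuration error: sex counts must sum to n")
  }
  with_seed(seed, {
    ages <- runif(n, age_range[1], age_range[2])
    sexes <- sample(rep(names(sex_counts), times = sex_counts))
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    subjects <- vector("list", n)
    tiv <- rep(NA_real_, n)
    true_means <- NULL
    for (i in seq_len(n)) {
      if (build) {
        subjects[[i]] <- build_phantom(ages[i], sexes[i], model, geometry,
                                       seed = sub_seeds[i])
        tiv[i] <- subjects[[i]]$tiv_ml
        tm <- subjects[[i]]$param_means
      } else {
        tm <- with_seed(sub_seeds[i], {
          # consume the geometry draws in build_phantom's order so the
          # subject-level means match a built cohort with the same seed
          rnorm(1, 0, geometry$subject_scale_sd)
          if (geometry$center_jitter) runif(3, -0.5, 0.5)
          drop(draw_subject_means(model, ages[i]))
        })
      }
      true_means <- rbind(true_means, tm)
    }
    rownames(true_means) <- NULL
    structure(
      list(
        subjects = subjects,
        covariates = data.frame(
          subject_id = sprintf("sub-%02d", seq_len(n)),
          age_years = ages, sex = sexes, tiv_ml = tiv,
          stringsAsFactors = FALSE
        ),
        true_means = true_means, subject_seeds = sub_seeds,
        model = model, geometry = geometry, seed = seed
      ),
      class = "cohort"
    )
  })
}

#' @export
print.cohort <- function(x, ...) {
  cv <- x$covariates
  cat(sprintf(
    "cohort: %d subjects, age %.1f +/- %.1f y (range %.0f-%.0f), %d M / %d F\n",
    nrow(cv), mean(cv$age_years), sample_sd(cv$age_years),
    min(cv$age_years), max(cv$age_years),
    sum(cv$sex == "M"), sum(cv$sex == "F")
  ))
  invisible(x)
}
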