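#' Estimate the noise SD from background patches
#'
#' Pools the eight corner cubes of the volume (assumed to lie outside the
#' head) and corrects the sample SD for the truncation (Gaussian magnitude
#' data clipped at zero) or Rayleigh (Rician) background distribution.
#'
#' @param vol 3D signal array.
#' @param patch edge length of each corner cube in voxels.
#' @param model `"gaussian"` or `"rician"` noise model.
#' @return estimated noise SD (scalar).
#' @export
estimate_noise_sd <- function(vol, patch = 6, model = "gaussian") {
  d <- dim(vol)
  ix <- function(n) c(seq_len(patch), n - patch + seq_len(patch))
  vals <- vol[ix(d[1]), ix(d[2]), ix(d[3])]
  # clipped N(0, s): SD = 0.584 s ; Rayleigh: SD = 0.655 s
  sd(vals) / if (model == "rician") 0.655 else 0.584
}

# place a vector of per-voxel values back into a 3D array (NA elsewhere)
scatter <- function(values, idx, dm, fill = NA_real_) {
  out <- array(fill, dim = dm)
  out[idx] <- values
  out
}

#' Map the relative transmit field B1 from a saturation-prepared pair
#'
#' The prepared volume's longitudinal magnetization is scaled by
#' cos(kappa * beta), so kappa = arccos(prepared / reference) / beta.
#'
#' @param reference,prepared 3D volumes on the same grid.
#' @param nominal_beta nominal saturation angle in degrees, in (0, 90].
#' @param floor signal floor; voxels with reference signal below it are
#'   masked invalid.
#' @param mask optional logical array restricting the fit.
#' @return list `kappa` (3D array, NA where invalid) and `mask`.
#' @export
fit_b1 <- function(reference, prepared, nominal_beta = 60, floor = 0,
                   mask = NULL) {
  stopifnot(identical(dim(reference), dim(prepared)),
            nominal_beta > 0, nominal_beta <= 90)
  dm <- dim(reference)
  idx <- if (is.null(mask)) seq_along(reference) else which(mask)
  rf <- reference[idx]; pp <- prepared[idx]
  bright <- rf > max(floor, 0)
  ratio <- pp / rf
  if (any(bright) && mean(ratio[bright] > 1.05) > 0.5) {
    stop("acquisition-order error: prepared volume brighter than reference")
  }
  kappa <- acos(pmin(pmax(ratio, -1), 1)) / (nominal_beta * pi / 180)
  valid <- bright & is.finite(ratio) & ratio < 1 & ratio > -1 &
    kappa > 0 & kappa <= 2
  kappa[!valid] <- NA_real_
  list(kappa = scatter(kappa, idx, dm),
       mask = scatter(valid, idx, dm, fill = FALSE))
}

#' Variable-flip-angle T1 fit (two-point linearization)
#'
#' Plots S_i/sin(kappa alpha_i) against S_i/tan(kappa alpha_i); the exact
#' line through the two points has slope exp(-TR/T1), giving
#' T1 = -TR / log(slope). The intercept equals
#' PD_app (1 - exp(-TR/T1)) with PD_app carrying the receive-sensitivity
#' and residual-T2* factors, and is returned for the PD chain.
#'
#' @param s1,s2 volumes acquired at the two flip angles.
#' @param alpha_deg the two nominal excitation angles (degrees).
#' @param tr repetition time (ms).
#' @param kappa relative transmit-field map (scalar or array); effective
#'   angles are kappa * alpha. Voxels with an effective angle >= 90
#'   degrees or a slope outside (0, 1) are masked.
#' @param floor signal floor for masking.
#' @param mask optional logical array restricting the fit.
#' @return list `t1`, `intercept`, `mask` (arrays; NA where invalid).
#' @export
fit_t1_vfa <- function(s1, s2, alpha_deg, tr, kappa = 1, floor = 0,
                       mask = NULL) {
  stopifnot(identical(dim(s1), dim(s2)), length(alpha_deg) == 2, tr > 0)
  dm <- dim(s1)
  idx <- if (is.null(mask)) seq_along(s1) else which(mask)
  kp <- if (length(kappa) == 1) rep(kappa, length(idx)) else kappa[idx]
  a1 <- kp * alpha_deg[1] * pi / 180
  a2 <- kp * alpha_deg[2] * pi / 180
  v1 <- s1[idx]; v2 <- s2[idx]
  ok <- is.finite(a1) & a1 > 0 & a2 > 0 & a1 < pi / 2 & a2 < pi / 2 &
    abs(a1 - a2) > 1e-9 & v1 > max(floor, 0) & v2 > max(floor, 0)
  y1 <- v1 / sin(a1); x1 <- v1 / tan(a1)
  y2 <- v2 / sin(a2); x2 <- v2 / tan(a2)
  dx <- x2 - x1
  slope <- (y2 - y1) / dx
  valid <- ok & is.finite(slope) & dx != 0 & slope > 0 & slope < 1
  t1 <- rep(NA_real_, length(idx))
  inter <- rep(NA_real_, length(idx))
  t1[valid] <- -tr / log(slope[valid])
  inter[valid] <- y1[valid] - slope[valid] * x1[valid]
  if (!any(valid)) stop("fit error: no valid voxels in VFA T1 fit")
  list(t1 = scatter(t1, idx, dm), intercept = scatter(inter, idx, dm),
       mask = scatter(valid, idx, dm, fill = FALSE))
}

#' Mono-exponential decay fit over a multi-echo stack
#'
#' Log-linear weighted least squares with weights equal to the squared
#' signal (the variance-stabilizing choice for log-transformed magnitude
#' data); the decay time is -1/slope. A nonlinear least-squares route
#' (`method = "nls"`) is available as a slower reference.
#'
#' @param stack 4D array (x, y, z, echo).
#' @param te echo times in ms, one per stack volume.
#' @param floor signal floor: echoes at or below it get zero weight; voxels
#'   with fewer than 2 usable echoes, or a non-negative log-slope, are
#'   masked.
#' @param drop_first_echo logical; ignore the first echo (coarse surrogate
#'   for stimulated/secondary-echo contamination of the first spin echo).
#' @param method `"loglinear"` (default) or `"nls"`.
#' @param mask optional logical array restricting the fit.
#' @return list `s0`, `tdecay`, `r2` (weighted R-squared of the log fit)
#'   and `mask` (arrays; NA where invalid).
#' @export
fit_monoexp <- function(stack, te, floor = 0, drop_first_echo = FALSE,
                        method = c("loglinear", "nls"), mask = NULL) {
  method <- match.arg(method)
  stopifnot(length(dim(stack)) == 4, dim(stack)[4] == length(te))
  if (drop_first_echo) {
    stack <- stack[, , , -1, drop = FALSE]
    te <- te[-1]
  }
  ne <- length(te)
  if (ne < 2) stop("fit error: need at least 2 echoes")
  dm <- dim(stack)[1:3]
  nvox <- prod(dm)
  idx <- if (is.null(mask)) seq_len(nvox) else which(mask)
  v <- matrix(stack, ncol = ne)[idx, , drop = FALSE]
  use <- v > max(floor, 0)
  w <- v * v * use
  y <- log(pmax(v, 1e-300))
  y[!use] <- 0
  wy <- w * y
  ones <- rep(1, ne)
  W <- as.vector(w %*% ones)
  Sx <- as.vector(w %*% te)
  Sxx <- as.vector(w %*% te^2)
  Sy <- as.vector(wy %*% ones)
  Sxy <- as.vector(wy %*% te)
  Syy <- as.vector((wy * y) %*% ones)
  den <- W * Sxx - Sx^2
  slope <- (W * Sxy - Sx * Sy) / den
  inter <- (Sy - slope * Sx) / W
  nvalid <- as.vector(use %*% ones)
  valid <- nvalid >= 2 & den > 0 & is.finite(slope) & slope < 0
  # weighted R^2 of the log-linear fit, from the accumulated moments
  ssr <- Syy - 2 * inter * Sy - 2 * slope * Sxy + inter^2 * W +
    2 * inter * slope * Sx + slope^2 * Sxx
  sst <- Syy - Sy^2 / W
  r2 <- rep(NA_real_, length(idx))
  r2[valid] <- 1 - pmax(ssr[valid], 0) / pmax(sst[valid], .Machine$double.xmin)
  r2[valid & sst <= 0] <- 1
  tdecay <- rep(NA_real_, length(idx))
  s0 <- rep(NA_real_, length(idx))
  tdecay[valid] <- -1 / slope[valid]
  s0[valid] <- exp(inter[valid])

  if (method == "nls") {
    for (i in which(valid)) {
      ok <- use[i, ]
      df <- data.frame(s = v[i, ok], t = te[ok])
      fit <- try(minpack.lm::nlsLM(
        s ~ s0 * exp(-t / td), data = df,
        start = list(s0 = s0[i], td = tdecay[i]),
        control = minpack.lm::nls.lm.control(maxiter = 100)
      ), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        cf <- stats::coef(fit)
        s0[i] <- cf[["s0"]]; tdecay[i] <- cf[["td"]]
        if (tdecay[i] <= 0) valid[i] <- FALSE
      }
    }
    tdecay[!valid] <- NA_real_
    s0[!valid] <- NA_real_
  }

  list(s0 = scatter(s0, idx, dm), tdecay = scatter(tdecay, idx, dm),
       r2 = scatter(r2, idx, dm), mask = scatter(valid, idx, dm, fill = FALSE))
}

#' Proton-density map from the VFA intercept
#'
#' Removes the residual saturation factor (1 - exp(-TR/T1)), the residual
#' T2* weighting exp(-TE_vfa/T2*) estimated from the TE-difference pair,
#' and the receive-coil sensitivity, then scales the result so the
#' ventricle-CSF median equals 100 percentage units.
#'
#' @param intercept intercept volume from [fit_t1_vfa()].
#' @param t1 fitted T1 volume (ms).
#' @param tr VFA repetition time (ms).
#' @param te_pair 4D array with the two TE-difference volumes.
#' @param te_vfa echo time of the VFA acquisition (ms).
#' @param dte echo-time difference of the pair (ms).
#' @param receive_field receive-sensitivity estimate (array or 1).
#' @param csf_mask logical array of ventricle-CSF voxels used for the
#'   100 p.u. calibration.
#' @param floor signal floor for the pair.
#' @return list `pd`, `t2star_pair`, `mask`, `scale`.
#' @export
fit_pd <- function(intercept, t1, tr, te_pair, te_vfa, dte,
                   receive_field = 1, csf_mask, floor = 0) {
  stopifnot(length(dim(te_pair)) == 4, dim(te_pair)[4] == 2)
  if (missing(csf_mask) || !any(csf_mask)) {
    stop("calibration error: empty CSF mask")
  }
  dm <- dim(intercept)
  s1 <- te_pair[, , , 1]; s2 <- te_pair[, , , 2]
  okp <- s1 > max(floor, 0) & s2 > 0 & s2 < s1
  t2sp <- array(NA_real_, dm)
  t2sp[okp] <- -dte / log(s2[okp] / s1[okp])
  m0 <- intercept / (1 - exp(-tr / t1))
  pd <- m0 * exp(te_vfa / t2sp) / receive_field
  mask <- is.finite(pd) & pd > 0 & okp
  pd[!mask] <- NA_real_
  csf_vals <- pd[csf_mask & mask]
  if (!length(csf_vals)) stop("calibration error: no valid CSF voxels")
  scale <- 100 / median(csf_vals)
  list(pd = pd * scale, t2star_pair = t2sp, mask = mask, scale = scale)
}

#' Reversible transverse relaxation time T2' from T2 and T2*
#'
#' 1/T2' = 1/T2* - 1/T2. Voxels with T2* >= T2 (non-physical under noise)
#' are masked invalid rather than clipped, preserving unbiased region
#' means.
#'
#' @param t2,t2star fitted volumes (ms; NA allowed).
#' @return list `t2prime` (NA where invalid) and `mask`.
#' @export
derive_t2prime <- function(t2, t2star) {
  stopifnot(identical(dim(t2), dim(t2star)))
  mask <- is.finite(t2) & is.finite(t2star) & t2star > 0 & t2star < t2
  t2p <- array(NA_real_, dim(t2))
  t2p[mask] <- 1 / (1 / t2star[mask] - 1 / t2[mask])
  list(t2prime = t2p, mask = mask)
}

#' Fit all quantitative maps from an acquisition bundle
#'
#' Runs the full voxelwise chain: B1 (kappa) from the saturation pair,
#' T1/intercept from the VFA pair using B1-corrected angles, T2 from the
#' spin-echo stack, T2* from the gradient-echo stack (log-linear weighted
#' fits), PD from the VFA intercept with TE-pair T2* correction,
#' receive-field removal and ventricle-CSF scaling, and T2' from T2 and
#' T2*. Voxels with a high-angle VFA signal below the floor (3 x the
#' estimated noise SD) are excluded from all fits.
#'
#' @param bundle an [synthesize_acquisition()] result.
#' @param csf_mask logical array of ventricle-CSF voxels (PD calibration).
#' @param receive_field receive-sensitivity field: `"known"` consumes the
#'   synthetic field stored in the bundle (simulation mode), `"none"` uses
#'   a unit field, or pass a numeric array estimate.
#' @param noise_sd noise SD used for the signal floor; default estimates it
#'   from background patches of the first VFA volume.
#' @param drop_first_echo drop the first spin echo in the T2 fit.
#' @param method decay-fit method, `"loglinear"` or `"nls"`.
#' @return an object of class `qmaps`: maps `T1`, `PD`, `T2`, `T2star`,
#'   `T2prime` (NA where invalid), `masks` per map, `r2` (list with the T2
#'   and T2* weighted R-squared volumes), `b1` (kappa map), `noise_sd`,
#'   `floor`.
#' @export
fit_qmaps <- function(bundle, csf_mask, receive_field = c("known", "none"),
                      noise_sd = NULL, drop_first_echo = FALSE,
                      method = "loglinear") {
  pr <- bundle$protocol
  if (is.character(receive_field)) {
    receive_field <- switch(match.arg(receive_field),
      known = bundle$receive_field, none = 1
    )
  }
  if (is.null(noise_sd)) {
    noise_sd <- if (bundle$noise_sd > 0) {
      estimate_noise_sd(bundle$vfa[, , , 1], model = pr$noise_model)
    } else 0
  }
  floor <- 3 * noise_sd
  # restrict all fits to voxels with usable high-angle VFA signal
  brain <- if (floor > 0) bundle$vfa[, , , 2] > floor else bundle$vfa[, , , 2] > 0

  b1 <- fit_b1(bundle$b1[, , , 1], bundle$b1[, , , 2], pr$b1_beta, floor,
               mask = brain)
  kappa <- b1$kappa
  kappa[!b1$mask] <- 1 # fall back to nominal angles where B1 is unusable
  vfa <- fit_t1_vfa(bundle$vfa[, , , 1], bundle$vfa[, , , 2],
                    pr$vfa_angles, pr$vfa_tr, kappa, floor, mask = brain)
  t2f <- fit_monoexp(bundle$fse, pr$fse_te, floor,
                     drop_first_echo = drop_first_echo, method = method,
                     mask = brain)
  t2sf <- fit_monoexp(bundle$ge, pr$ge_te, floor, method = method,
                      mask = brain)
  pdf_ <- fit_pd(vfa$intercept, vfa$t1, pr$vfa_tr, bundle$tepair,
                 pr$vfa_te, pr$tepair_dte, receive_field, csf_mask, floor)
  t2p <- derive_t2prime(t2f$tdecay, t2sf$tdecay)

  structure(
    list(
      T1 = vfa$t1, PD = pdf_$pd, T2 = t2f$tdecay, T2star = t2sf$tdecay,
      T2prime = t2p$t2prime,
      masks = list(T1 = vfa$mask, PD = pdf_$mask, T2 = t2f$mask,
                   T2star = t2sf$mask, T2prime = t2p$mask, B1 = b1$mask),
      r2 = list(T2 = t2f$r2, T2star = t2sf$r2),
      b1 = b1$kappa, noise_sd = noise_sd, floor = floor
    ),
    class = "qmaps"
  )
}

#' @export
print.qmaps <- function(x, ...) {
  cat("qmaps:", paste(names(x$masks)[-6], collapse = ", "),
      sprintf("(signal floor %.3g)\n", x$floor))
  for (p in c("T1", "PD", "T2", "T2star", "T2prime")) {
    v <- x[[p]][x$masks[[p]]]
    cat(sprintf("  %-7s median %9.2f  valid voxels %d\n",
                p, median(v), sum(x$masks[[p]])))
  }
  invisible(x)
}
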