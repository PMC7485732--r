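#' Spoiled gradient-echo steady-state signal
#'
#' \deqn{S = R \; PD \; \sin(\kappa\alpha)\frac{1 - E_1}{1 - \cos(\kappa\alpha) E_1}
#'       e^{-TE/T2^*}, \qquad E_1 = e^{-TR/T1}}
#'
#' @param pd,t1,t2star parameter maps (arrays or scalars; ms, p.u.).
#' @param alpha_deg nominal excitation angle (degrees).
#' @param tr,te repetition and echo time (ms).
#' @param kappa relative transmit-field scale (actual angle = kappa * alpha).
#' @param receive receive-sensitivity factor.
#' @return signal, same shape as the inputs.
#' @export
spgr_signal <- function(pd, t1, t2star, alpha_deg, tr, te,
                        kappa = 1, receive = 1) {
  a <- kappa * alpha_deg * pi / 180
  ok <- pd > 0 & t1 > 0 & t2star > 0
  e1 <- exp(-tr / ifelse(ok, t1, 1))
  s <- receive * pd * sin(a) * (1 - e1) / (1 - cos(a) * e1) *
    exp(-te / ifelse(ok, t2star, 1))
  s * ok
}

# Spin-echo signal with long-TR (full-relaxation) assumption.
se_signal <- function(pd, t2, te, receive = 1) {
  ok <- pd > 0 & t2 > 0
  receive * pd * exp(-te / ifelse(ok, t2, 1)) * ok
}

#' Smooth random multiplicative bias field
#'
#' A random second-order polynomial in grid-normalized coordinates, scaled
#' so its maximum absolute deviation from 1 equals `amplitude`. Draws from
#' the current RNG stream.
#'
#' @param dim grid size (length 3).
#' @param amplitude peak relative deviation from unity (e.g. 0.1 for +/-10
#'   percent); 0 returns a unit field.
#' @return numeric 3D array.
#' @export
random_bias_field <- function(dim, amplitude = 0.1) {
  if (amplitude == 0) return(array(1, dim = dim))
  co <- coord_arrays(dim, voxel_mm = 2 / max(dim)) # normalized to ~[-1, 1]
  u <- co$x * max(dim) / dim[1]; v <- co$y * max(dim) / dim[2]
  w <- co$z * max(dim) / dim[3]
  cf <- rnorm(9)
  p <- cf[1] * u + cf[2] * v + cf[3] * w + cf[4] * u * v + cf[5] * u * w +
    cf[6] * v * w + cf[7] * u^2 + cf[8] * v^2 + cf[9] * w^2
  1 + amplitude * p / max(abs(p))
}

add_noise <- function(vol, sd, model) {
  if (sd <= 0) return(vol)
  if (model == "rician") {
    d <- dim(vol)
    vol <- sqrt((vol + rnorm(length(vol), 0, sd))^2 +
                  rnorm(length(vol), 0, sd)^2)
    dim(vol) <- d
  } else {
    vol <- vol + rnorm(length(vol), 0, sd)
    vol[vol < 0] <- 0 # magnitude data are non-negative
  }
  vol
}

#' Synthesize all MRI acquisitions from a phantom
#'
#' Applies the spoiled-GE, spin-echo and saturation-prepared forward models
#' to the phantom's ground-truth maps, multiplies in smooth transmit (kappa)
#' and receive bias fields, and adds noise whose SD is the mean noiseless
#' cortical-GM signal of the high-angle VFA volume divided by the protocol
#' SNR. With `snr = Inf` and `bias_amplitude = 0` the synthesis is exactly
#' invertible by the fitters in this package (round-trip property).
#'
#' @param phantom a [build_phantom()] result.
#' @param protocol an [acquisition_protocol()].
#' @param seed integer seed for the bias fields and noise realization.
#' @return an `acquisition_bundle`: 4D arrays `vfa` (2 volumes), `fse` (one
#'   per spin echo), `ge` (one per gradient echo), `b1` (reference,
#'   prepared), `tepair` (2 volumes), plus `kappa_field`, `receive_field`,
#'   `noise_sd`, `protocol`, `voxel_mm`, `seed`.
#' @export
synthesize_acquisition <- function(phantom, protocol = acquisition_protocol(),
                                   seed = 1L) {
  pr <- protocol
  mp <- phantom$maps
  dm <- dim(phantom$labels)
  nvox <- prod(dm)
  with_seed(seed, {
    kappa <- random_bias_field(dm, pr$bias_amplitude)
    receive <- random_bias_field(dm, pr$bias_amplitude)

    # evaluate the forward models on tissue voxels only (signal is zero
    # elsewhere by construction)
    tidx <- which(mp$PD > 0 & mp$T1 > 0 & mp$T2star > 0)
    pd <- mp$PD[tidx]; t1 <- mp$T1[tidx]; t2 <- mp$T2[tidx]
    t2s <- mp$T2star[tidx]
    kp <- kappa[tidx]; rc <- receive[tidx]

    spgr_v <- function(alpha_deg, tr, te) {
      a <- kp * alpha_deg * pi / 180
      e1 <- exp(-tr / t1)
      rc * pd * sin(a) * (1 - e1) / (1 - cos(a) * e1) * exp(-te / t2s)
    }
    stack_of <- function(cols) {
      out <- array(0, dim = c(dm, length(cols)))
      for (i in seq_along(cols)) {
        out[tidx + (i - 1) * nvox] <- cols[[i]]
      }
      out
    }
    vfa <- stack_of(lapply(pr$vfa_angles, spgr_v, tr = pr$vfa_tr,
                           te = pr$vfa_te))
    fse <- stack_of(lapply(pr$fse_te, function(te) rc * pd * exp(-te / t2)))
    ge <- stack_of(lapply(pr$ge_te, function(te) {
      spgr_v(pr$ge_alpha, pr$ge_tr, te)
    }))
    b1_ref <- spgr_v(pr$b1_alpha, pr$b1_tr, pr$b1_te)
    # saturation prepulse scales longitudinal magnetization by cos(kappa*beta)
    b1 <- stack_of(list(b1_ref, b1_ref * cos(kp * pr$b1_beta * pi / 180)))
    tepair <- stack_of(lapply(0:1, function(i) {
      spgr_v(pr$tepair_alpha, pr$tepair_tr, pr$tepair_te1 + i * pr$tepair_dte)
    }))

    gm <- phantom$labels == phantom_labels()[["gm"]]
    gm_ref <- mean(vfa[, , , 2][gm])
    noise_sd <- if (is.finite(pr$snr)) gm_ref / pr$snr else 0
    if (noise_sd > 0) {
      vfa <- add_noise(vfa, noise_sd, pr$noise_model)
      fse <- add_noise(fse, noise_sd, pr$noise_model)
      ge <- add_noise(ge, noise_sd, pr$noise_model)
      b1 <- add_noise(b1, noise_sd, pr$noise_model)
      tepair <- add_noise(tepair, noise_sd, pr$noise_model)
    }

    structure(
      list(
        vfa = vfa, fse = fse, ge = ge, b1 = b1, tepair = tepair,
        kappa_field = kappa, receive_field = receive,
        noise_sd = noise_sd, gm_ref_signal = gm_ref,
        protocol = pr, voxel_mm = phantom$voxel_mm, seed = seed
      ),
      class = "acquisition_bundle"
    )
  })
}
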