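#' Acquisition protocol for the simulated session
#'
#' Defaults mirror a 3 T multiparametric relaxometry session: a spoiled
#' gradient-echo (FLASH) variable-flip-angle pair (TR 16.4 ms, TE 6.7 ms,
#' flip angles 4 and 24 degrees) for T1/PD, a four-echo fast-spin-echo stack
#' (TE 17/86/103/120 ms) for T2, an eight-echo gradient-echo stack
#' (TE 10-52 ms, step 6) for T2*, a saturation-prepared/reference pair for
#' B1, and a gradient-echo pair with a TE difference of 6.7 ms for the
#' residual-T2* correction of PD.
#'
#' @param vfa_tr,vfa_te,vfa_angles VFA repetition/echo time (ms) and the two
#'   excitation angles (degrees, distinct).
#' @param fse_te,ge_te echo-time lists (ms), strictly increasing.
#' @param ge_tr,ge_alpha gradient-echo stack TR (ms) and excitation angle.
#' @param b1_beta nominal saturation angle of the B1 pair (degrees).
#' @param b1_tr,b1_te,b1_alpha readout parameters of the B1 pair (ms, deg).
#' @param tepair_te1,tepair_dte first echo time and echo-time difference of
#'   the PD correction pair (ms).
#' @param tepair_tr,tepair_alpha readout parameters of that pair.
#' @param snr signal-to-noise ratio: mean noiseless cortical-GM signal of the
#'   high-angle VFA volume divided by the noise SD. `Inf` disables noise.
#' @param noise_model `"gaussian"` (additive, default) or `"rician"`
#'   (magnitude of complex noise).
#' @param bias_amplitude peak relative amplitude of the smooth transmit
#'   (kappa) and receive bias fields (0 disables them).
#' @return an `acquisition_protocol` list.
#' @export
acquisition_protocol <- function(vfa_tr = 16.4, vfa_te = 6.7,
                                 vfa_angles = c(4, 24),
                                 fse_te = c(17, 86, 103, 120),
                                 ge_te = seq(10, 52, by = 6),
                                 ge_tr = 2400, ge_alpha = 30,
                                 b1_beta = 60, b1_tr = 11, b1_te = 5,
                                 b1_alpha = 11,
                                 tepair_te1 = 6, tepair_dte = 6.7,
                                 tepair_tr = 2400, tepair_alpha = 30,
                                 snr = 50, noise_model = c("gaussian", "rician"),
                                 bias_amplitude = 0.1) {
  noise_model <- match.arg(noise_model)
  stopifnot(
    vfa_tr > 0, vfa_te > 0, all(fse_te > 0), all(ge_te > 0),
    b1_beta > 0, b1_beta <= 90, tepair_te1 > 0, tepair_dte > 0, snr > 0
  )
  if (length(vfa_angles) != 2 || vfa_angles[1] == vfa_angles[2]) {
    stop("VFA needs two distinct flip angles")
  }
  if (is.unsorted(fse_te, strictly = TRUE) ||
      is.unsorted(ge_te, strictly = TRUE)) {
    stop("echo-time lists must be strictly increasing")
  }
  structure(
    list(
      vfa_tr = vfa_tr, vfa_te = vfa_te, vfa_angles = vfa_angles,
      fse_te = fse_te, ge_te = ge_te, ge_tr = ge_tr, ge_alpha = ge_alpha,
      b1_beta = b1_beta, b1_tr = b1_tr, b1_te = b1_te, b1_alpha = b1_alpha,
      tepair_te1 = tepair_te1, tepair_dte = tepair_dte,
      tepair_tr = tepair_tr, tepair_alpha = tepair_alpha,
      snr = snr, noise_model = noise_model, bias_amplitude = bias_amplitude
    ),
    class = "acquisition_protocol"
  )
}
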