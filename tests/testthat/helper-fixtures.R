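# Shared fixtures: a desk-scale geometry small enough for fast tests.

small_geometry <- function(dim = 48, voxel_mm = 2, ...) {
  geometry_config(
    dim = dim, voxel_mm = voxel_mm,
    semi_axes_mm = c(32, 40, 32) * (dim * voxel_mm) / 96,
    ventricle_semi_axes_mm = c(5, 9, 5) * (dim * voxel_mm) / 96,
    ...
  )
}

noiseless_protocol <- function(...) {
  acquisition_protocol(snr = Inf, bias_amplitude = 0, ...)
}

# one cached phantom + noiseless bundle for round-trip style tests
fixture_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- build_phantom(45, "F", default_aging_model(),
                          small_geometry(), seed = 42L)
      cache <<- list(
        phantom = ph,
        bundle = synthesize_acquisition(ph, noiseless_protocol(), seed = 7L)
      )
    }
    cache
  }
})

gm_mask <- function(ph) ph$labels == phantom_labels()[["gm"]]
wm_mask <- function(ph) ph$labels == phantom_labels()[["wm"]]
csf_mask_all <- function(ph) {
  ph$labels == phantom_labels()[["csf"]] |
    ph$labels == phantom_labels()[["ventricle"]]
}
vent_mask <- function(ph) ph$labels == phantom_labels()[["ventricle"]]
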