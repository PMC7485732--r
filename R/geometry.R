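#' Phantom geometry configuration
#'
#' Nested-ellipsoid head geometry on an isotropic grid: an outer
#' brain-plus-CSF ellipsoid, a cortical gray-matter shell of age-dependent
#' thickness under a sulcal/outer CSF layer, a white-matter core, and one
#' ventricle. Axes follow the RAS+ convention: x lateral (left negative),
#' y anterior, z superior.
#'
#' @param dim grid size, one integer (cubic) or three; each >= 32.
#' @param voxel_mm isotropic voxel size in mm.
#' @param semi_axes_mm outer ellipsoid semi-axes (x, y, z) in mm.
#' @param csf_thickness_mm thickness of the outer CSF layer in mm.
#' @param ventricle_semi_axes_mm semi-axes of the central ventricle in mm.
#' @param subject_scale_sd SD of the log-normal per-subject global scale
#'   factor (drives TIV variability).
#' @param male_scale multiplicative head-size factor for male subjects
#'   (about +8 percent TIV), making TIV a meaningful nuisance covariate.
#' @param center_jitter logical; draw a sub-voxel random center offset per
#'   subject to decorrelate grid-quantization error across subjects.
#' @param frontal_deg,occipital_deg angular widths of the anterior (frontal)
#'   and posterior (occipital) lobe sectors, degrees.
#' @param wm,csf named vectors of white-matter / CSF ground-truth values
#'   (T1, PD, T2, T2prime; ms and p.u.). Fixed literature-style defaults:
#'   these tissues carry no age effect here.
#' @return a `geometry_config` list.
#' @export
geometry_config <- function(dim = 64, voxel_mm = 2,
                            semi_axes_mm = c(45, 55, 45),
                            csf_thickness_mm = 3,
                            ventricle_semi_axes_mm = c(7, 13, 7),
                            subject_scale_sd = 0.02,
                            male_scale = 1.025,
                            center_jitter = TRUE,
                            frontal_deg = 100, occipital_deg = 60,
                            wm = c(T1 = 850, PD = 69, T2 = 75, T2prime = 150),
                            csf = c(T1 = 4000, PD = 100, T2 = 1800,
                                    T2prime = 5000)) {
  if (length(dim) == 1) dim <- rep(dim, 3)
  if (any(dim < 32)) stop("geometry error: grid must be at least 32^3")
  fov <- dim * voxel_mm
  if (any(2 * semi_axes_mm >= fov - 2 * voxel_mm)) {
    stop("geometry error: outer ellipsoid does not fit the grid")
  }
  structure(
    list(
      dim = as.integer(dim), voxel_mm = voxel_mm,
      semi_axes_mm = semi_axes_mm, csf_thickness_mm = csf_thickness_mm,
      ventricle_semi_axes_mm = ventricle_semi_axes_mm,
      subject_scale_sd = subject_scale_sd, male_scale = male_scale,
      center_jitter = center_jitter,
      frontal_deg = frontal_deg, occipital_deg = occipital_deg,
      wm = wm, csf = csf
    ),
    class = "geometry_config"
  )
}

#' Label codes used by the phantom
#'
#' @return named integer vector: background 0, outer (sulcal) CSF 1,
#'   cortical GM 2, WM 3, ventricle CSF 4.
#' @export
phantom_labels <- function() {
  c(background = 0L, csf = 1L, gm = 2L, wm = 3L, ventricle = 4L)
}

# Angular lobe sector of points (x, y, z) relative to a centroid.
# Returns integer codes 1..8; see lobe_table(). Hemisphere-symmetric by
# construction (azimuth measured from the anterior axis using |x|).
lobe_sector <- function(x, y, z, frontal_deg = 100, occipital_deg = 60) {
  az <- atan2(abs(x), y) * 180 / pi # 0 anterior .. 180 posterior
  lobe <- ifelse(az <= frontal_deg / 2, 1L, # frontal
    ifelse(az >= 180 - occipital_deg / 2, 4L, # occipital
      ifelse(z >= 0, 2L, 3L) # parietal dorsal / temporal ventral
    )
  )
  lobe + ifelse(x >= 0, 4L, 0L) # right hemisphere offset
}

#' Lobe label lookup table
#'
#' @return data.frame with columns `code`, `lobe`, `hemisphere`.
#' @export
lobe_table <- function() {
  data.frame(
    code = 1:8,
    lobe = rep(c("frontal", "parietal", "temporal", "occipital"), 2),
    hemisphere = rep(c("left", "right"), each = 4),
    stringsAsFactors = FALSE
  )
}

# Smooth, fixed, within-cortex spatial profiles for the cortical maps, as
# functions of ellipsoid-normalized coordinates. Distinct low-order patterns
# per parameter; standardized (mean 0, SD 1) over the GM shell downstream.
spatial_profile <- function(param, ux, uy, uz) {
  switch(param,
    T1 = uz + 0.6 * ux * uy,
    PD = uy - 0.4 * ux^2,
    T2 = ux^2 - uz^2 + 0.3 * uy,
    T2prime = uy * uz + 0.5 * ux^2 - 0.3 * uz,
    stop("no spatial profile for parameter ", param)
  )
}
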