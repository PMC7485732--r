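#' Write a 3D/4D volume as NIfTI-1
#'
#' RAS+ orientation with an isotropic diagonal affine; the voxel size is
#' stored in the header.
#'
#' @param vol numeric array (NA written as-is).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_mm isotropic voxel size in mm.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, voxel_mm) {
  nd <- length(dim(vol))
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(rep(voxel_mm, 3), rep(1, max(nd - 3, 0)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume written by [write_volume()]
#'
#' @param path file path.
#' @return list `data` (plain array) and `voxel_mm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       voxel_mm = RNifti::pixdim(img)[1])
}

#' Write / read the per-subject covariate table
#'
#' CSV with header row, UTF-8, columns `subject_id`, `age_years`, `sex`,
#' `tiv_ml`.
#'
#' @param covariates data.frame with those columns.
#' @param path file path.
#' @return the path (write) or the data.frame (read).
#' @export
write_covariates <- function(covariates, path) {
  stopifnot(all(c("subject_id", "age_years", "sex", "tiv_ml") %in%
                  names(covariates)))
  write.csv(covariates, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

# JSON sidecar helpers (protocol / fit settings / cluster tables)
write_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_sidecar <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
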