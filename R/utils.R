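#' Run code with a temporarily seeded RNG
#'
#' Seeds the generator, evaluates `expr`, and restores the caller's RNG state,
#' so seeded simulation helpers never perturb the session stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# voxel-center coordinates (mm) of an isotropic grid, origin at the volume
# center so phantom geometry is grid-size independent
grid_coords <- function(dim, voxel_mm) {
  ax <- lapply(dim, function(n) (seq_len(n) - (n + 1) / 2) * voxel_mm)
  list(x = ax[[1]], y = ax[[2]], z = ax[[3]])
}

# 3D arrays of the x/y/z coordinate at every voxel
coord_arrays <- function(dim, voxel_mm, center = c(0, 0, 0)) {
  cc <- grid_coords(dim, voxel_mm)
  list(
    x = array(rep(cc$x - center[1], times = dim[2] * dim[3]), dim = dim),
    y = array(rep(rep(cc$y - center[2], each = dim[1]), times = dim[3]), dim = dim),
    z = array(rep(cc$z - center[3], each = dim[1] * dim[2]), dim = dim)
  )
}

#' Euclidean distance transform of a 3D mask
#'
#' Exact Euclidean distance (in voxel units) from every voxel to the nearest
#' `TRUE` voxel of `mask`, computed with the separable lower-envelope
#' algorithm. Voxels in a volume containing no `TRUE` voxel return `NA`.
#'
#' @param mask logical 3D array.
#' @return numeric 3D array of distances in voxel units.
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
#' d <- edt3d(m)
#' d[1, 3, 3] # 2 voxels from the seed
#' @export
edt3d <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  .edt3d_cpp(as.logical(mask), as.integer(dim(mask)))
}

# sample standard deviation, tolerant of length-1 input
sample_sd <- function(x) if (length(x) < 2) 0 else sd(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
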