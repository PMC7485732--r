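#' Mask-normalized Gaussian smoothing of a ribbon-restricted map
#'
#' Separable Gaussian smoothing with sigma = fwhm / 2.3548 (converted from
#' mm to voxels), normalized by the smoothed mask so no values bleed in
#' from outside the ribbon: out = G*(map on mask) / G*(mask), evaluated on
#' the mask. A constant map is therefore unchanged (partition of unity) and
#' `fwhm = 0` is the identity.
#'
#' @param vol 3D map (values outside `mask` are ignored).
#' @param fwhm_mm kernel full width at half maximum in mm (>= 0).
#' @param voxel_mm isotropic voxel size in mm.
#' @param mask logical array; smoothing is restricted to it. Default: all
#'   finite voxels of `vol`.
#' @return 3D array, smoothed on the mask, NA outside.
#' @export
smooth_map <- function(vol, fwhm_mm, voxel_mm, mask = NULL) {
  stopifnot(fwhm_mm >= 0)
  if (is.null(mask)) mask <- is.finite(vol)
  if (fwhm_mm == 0) {
    out <- vol
    out[!mask] <- NA_real_
    return(out)
  }
  sigma_vox <- fwhm_mm / 2.354820045 / voxel_mm
  r <- max(1L, ceiling(3 * sigma_vox))
  kern <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  kern <- kern / sum(kern)

  conv_axis <- function(x, axis) {
    out <- array(0, dim = dim(x))
    n <- dim(x)[axis]
    for (j in -r:r) {
      w <- kern[j + r + 1]
      src <- seq_len(n) + j
      ok <- src >= 1 & src <= n
      if (!any(ok)) next
      dst <- which(ok)
      s <- src[ok]
      if (axis == 1) out[dst, , ] <- out[dst, , ] + w * x[s, , ]
      if (axis == 2) out[, dst, ] <- out[, dst, ] + w * x[, s, ]
      if (axis == 3) out[, , dst] <- out[, , dst] + w * x[, , s]
    }
    out
  }
  gauss3 <- function(x) conv_axis(conv_axis(conv_axis(x, 1), 2), 3)

  v0 <- vol
  v0[!mask] <- 0
  v0[!is.finite(v0)] <- 0
  num <- gauss3(v0)
  den <- gauss3(array(as.numeric(mask), dim = dim(vol)))
  out <- num / den
  out[!mask] <- NA_real_
  out
}

# connected components (6-connectivity) among the given linear voxel
# indices of a grid with dimensions dm; returns a membership vector
connected_components_6 <- function(idx, dm) {
  if (!length(idx)) return(integer(0))
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  pos <- arrayInd(idx, dm)
  inset <- integer(prod(dm))
  inset[idx] <- seq_along(idx)
  edges <- NULL
  strides <- c(1L, nx, nx * ny)
  for (ax in 1:3) {
    ok <- pos[, ax] < dm[ax]
    nb <- idx[ok] + strides[ax]
    hit <- inset[nb] > 0
    if (any(hit)) {
      edges <- rbind(edges, cbind(inset[idx[ok]][hit], inset[nb][hit]))
    }
  }
  if (is.null(edges)) return(seq_along(idx))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  igraph::components(g)$membership[seq_along(idx)]
}

# voxelwise Pearson r of the rows of a (voxels x subjects) matrix with v
rowwise_cor <- function(m, v) {
  vc <- v - mean(v)
  mc <- m - rowMeans(m)
  num <- as.vector(mc %*% vc)
  den <- sqrt(rowSums(mc^2) * sum(vc^2))
  ifelse(den > 0, num / den, 0)
}

# max suprathreshold cluster size per sign for one age vector
max_cluster_sizes <- function(m, v, idx, dm, r_crit) {
  r <- rowwise_cor(m, v)
  out <- c(pos = 0L, neg = 0L)
  for (sgn in c(1, -1)) {
    sel <- if (sgn > 0) r > r_crit else r < -r_crit
    if (any(sel)) {
      memb <- connected_components_6(idx[sel], dm)
      out[if (sgn > 0) "pos" else "neg"] <- max(tabulate(memb))
    }
  }
  out
}

#' Voxelwise correlation map with permutation cluster correction
#'
#' Computes the Pearson correlation of each ribbon voxel's values with age,
#' forms clusters of suprathreshold voxels (voxelwise p below
#' `threshold_p`, 6-connectivity, separately by sign, matching the separate
#' hot/cold maps of surface-based analyses) and assesses each observed
#' cluster against the permutation null distribution of the map-wise
#' maximum suprathreshold cluster size (the larger of the positive and
#' negative maxima per permutation, so the family-wise error across the
#' whole map is alpha). Cluster-wise
#' p = (1 + #\{perm max >= observed\}) / (1 + n_perm); with
#' `exhaustive = TRUE` all n! permutations (identity included) are
#' enumerated and p = #\{perm max >= observed\} / n!.
#'
#' @param maps list of 3D maps (one per subject) on a shared template grid,
#'   or a (voxels x subjects) matrix together with `ribbon`.
#' @param ages numeric vector of ages, one per subject.
#' @param ribbon logical template ribbon mask.
#' @param threshold_p voxelwise cluster-forming threshold (default 0.05).
#' @param n_perm number of random permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @param exhaustive enumerate all permutations (requires n <= 8).
#' @param alpha cluster-wise significance level (default 0.05).
#' @return object of class `cluster_report`: `r_map`, `p_map` (3D arrays,
#'   NA off-ribbon), `clusters` (data.frame: id, sign, size, p,
#'   significant), `labels` (3D cluster-id array), `null_max` (per-sign
#'   permutation maxima), `n_perm`, `threshold_p`, `alpha`, `n`.
#' @export
mapwise_correlation <- function(maps, ages, ribbon, threshold_p = 0.05,
                                n_perm = 1000, seed = 1L,
                                exhaustive = FALSE, alpha = 0.05) {
  n <- length(ages)
  dm <- dim(ribbon)
  idx <- which(ribbon)
  m <- if (is.matrix(maps)) maps else {
    do.call(cbind, lapply(maps, function(a) {
      if (!identical(dim(a), dm)) stop("alignment error: subject grid mismatch")
      a[idx]
    }))
  }
  stopifnot(nrow(m) == length(idx), ncol(m) == n)
  if (anyNA(m)) stop("alignment error: NA map values on the template ribbon")
  if (!exhaustive && n_perm < 100) stop("n_perm must be >= 100")

  df <- n - 2
  # critical |r| for the voxelwise cluster-forming threshold
  tcrit <- stats::qt(1 - threshold_p / 2, df)
  r_crit <- tcrit / sqrt(df + tcrit^2)

  r <- rowwise_cor(m, ages)
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)

  labels <- array(0L, dim = dm)
  clusters <- NULL
  cl_id <- 0L
  obs <- list()
  for (sgn in c(1, -1)) {
    sel <- if (sgn > 0) p < threshold_p & r > 0 else p < threshold_p & r < 0
    sizes <- integer(0)
    if (any(sel)) {
      memb <- connected_components_6(idx[sel], dm)
      sizes <- tabulate(memb)
      for (k in seq_along(sizes)) {
        cl_id <- cl_id + 1L
        labels[idx[sel][memb == k]] <- cl_id
        clusters <- rbind(clusters, data.frame(
          id = cl_id, sign = if (sgn > 0) "pos" else "neg",
          size = sizes[k], p = NA_real_, stringsAsFactors = FALSE
        ))
      }
    }
    obs[[if (sgn > 0) "pos" else "neg"]] <- sizes
  }

  perms <- if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8")
    all_permutations(n)
  } else {
    with_seed(seed, replicate(n_perm, sample.int(n), simplify = FALSE))
  }
  null_max <- vapply(perms, function(pm) {
    max_cluster_sizes(m, ages[pm], idx, dm, r_crit)
  }, c(pos = 0, neg = 0))

  if (!is.null(clusters)) {
    B <- length(perms)
    # map-wise null: the maximum suprathreshold cluster size over both sign
    # families per permutation, so the family-wise error across the whole
    # map is controlled at alpha
    nm <- pmax(null_max["pos", ], null_max["neg", ])
    clusters$p <- vapply(seq_len(nrow(clusters)), function(i) {
      if (exhaustive) {
        sum(nm >= clusters$size[i]) / B
      } else {
        (1 + sum(nm >= clusters$size[i])) / (1 + B)
      }
    }, numeric(1))
    clusters$significant <- clusters$p < alpha
    clusters <- clusters[order(-clusters$size), ]
    rownames(clusters) <- NULL
  } else {
    clusters <- data.frame(id = integer(0), sign = character(0),
                           size = integer(0), p = numeric(0),
                           significant = logical(0))
  }

  r_map <- array(NA_real_, dm); r_map[idx] <- r
  p_map <- array(NA_real_, dm); p_map[idx] <- p
  structure(
    list(r_map = r_map, p_map = p_map, clusters = clusters, labels = labels,
         null_max = null_max, n_perm = length(perms),
         threshold_p = threshold_p, alpha = alpha, n = n,
         exhaustive = exhaustive),
    class = "cluster_report"
  )
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf(
    "voxelwise correlation (n = %d, %s%d permutations, cluster-forming p < %g)\n",
    x$n, if (x$exhaustive) "exhaustive " else "", x$n_perm, x$threshold_p
  ))
  if (nrow(x$clusters)) print(head(x$clusters, 10)) else cat("  no clusters\n")
  invisible(x)
}

# all permutations of 1..n (n <= 8), as a list of integer vectors
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      v <- integer(n)
      v[i] <- n
      v[-i] <- s
      out[[k]] <- v
    }
  }
  out
}
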