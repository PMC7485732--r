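#' Lobar correlation analysis
#'
#' For each lobe (hemisphere-averaged: the mean of the left and right
#' regional means) and each parameter: the Pearson correlation of the
#' regional value with age, and the partial correlation of the regional
#' value with the regional cortical thickness controlling for TIV.
#' Significance is flagged at p < 0.05.
#'
#' @param maps list (per subject) of named lists of parameter maps.
#' @param lobes list (per subject) of integer lobe-label arrays
#'   ([lobe_table()] codes; 0 off-ribbon).
#' @param ages numeric vector of ages.
#' @param thickness list (per subject) of thickness maps (mm, NA
#'   off-ribbon).
#' @param tiv numeric vector of total intracranial volumes (mL).
#' @param alpha significance threshold (default 0.05).
#' @return list `regional_means` (data.frame subject x lobe x parameter)
#'   and `table` (data.frame: lobe, parameter, r_age, p_age, sig_age,
#'   r_thickness, p_thickness, sig_thickness, n).
#' @export
lobar_analysis <- function(maps, lobes, ages, thickness, tiv, alpha = 0.05) {
  n <- length(maps)
  stopifnot(length(lobes) == n, length(ages) == n,
            length(thickness) == n, length(tiv) == n)
  tab <- lobe_table()
  lobe_names <- unique(tab$lobe)
  params <- names(maps[[1]])

  # hemisphere-averaged regional mean of a map for one subject
  regional_mean <- function(vol, lab, lobe) {
    codes <- tab$code[tab$lobe == lobe]
    halves <- vapply(codes, function(k) {
      v <- vol[lab == k]
      v <- v[is.finite(v)]
      if (!length(v)) NA_real_ else mean(v)
    }, numeric(1))
    mean(halves) # (left + right) / 2
  }

  rows <- list()
  for (i in seq_len(n)) {
    for (lb in lobe_names) {
      vals <- vapply(params, function(p) {
        regional_mean(maps[[i]][[p]], lobes[[i]], lb)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = i, lobe = lb, parameter = params, value = unname(vals),
        thickness = regional_mean(thickness[[i]], lobes[[i]], lb),
        stringsAsFactors = FALSE
      )
    }
  }
  rm_df <- do.call(rbind, rows)

  out <- list()
  for (lb in lobe_names) {
    for (p in params) {
      d <- rm_df[rm_df$lobe == lb & rm_df$parameter == p, ]
      keep <- is.finite(d$value) & is.finite(d$thickness)
      if (sum(keep) < nrow(d)) {
        warning("lobe ", lb, ", parameter ", p, ": ",
                sum(!keep), " subject(s) without valid voxels excluded")
      }
      d <- d[keep, ]
      ca <- correlate(d$value, ages[d$subject], level = "lobe", parameter = p)
      ct <- correlate(d$value, d$thickness,
                      covariates = data.frame(tiv = tiv[d$subject]),
                      level = "lobe", parameter = p)
      out[[length(out) + 1L]] <- data.frame(
        lobe = lb, parameter = p,
        r_age = ca$r, p_age = ca$p, sig_age = ca$p < alpha,
        r_thickness = ct$r, p_thickness = ct$p,
        sig_thickness = ct$p < alpha, n = nrow(d),
        stringsAsFactors = FALSE
      )
    }
  }
  list(regional_means = rm_df, table = do.call(rbind, out))
}
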