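#' Per-subject cortical means and SDs, with cohort aggregation
#'
#' For each subject and parameter, the mean and sample SD (n - 1
#' denominator) of the map over the subject's valid ribbon voxels; the
#' cohort table aggregates the per-subject values as mean +/- SD across
#' subjects. Subjects with an empty ribbon are excluded with a warning.
#'
#' @param maps list (one element per subject) of named lists of 3D parameter
#'   maps (NA treated as invalid).
#' @param ribbons list of logical ribbon masks, one per subject.
#' @param subject_ids optional character vector of subject identifiers.
#' @return list `per_subject` (data.frame: subject_id, parameter, mean, sd,
#'   n_voxels) and `cohort` (data.frame: parameter, mean_of_means,
#'   sd_of_means, mean_of_sds, sd_of_sds, n_subjects).
#' @export
global_summary <- function(maps, ribbons, subject_ids = NULL) {
  stopifnot(length(maps) == length(ribbons))
  n <- length(maps)
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%02d", seq_len(n))
  rows <- list()
  for (i in seq_len(n)) {
    rb <- ribbons[[i]]
    if (!any(rb)) {
      warning("subject ", subject_ids[i], " has an empty ribbon; excluded")
      next
    }
    for (p in names(maps[[i]])) {
      v <- maps[[i]][[p]][rb]
      v <- v[is.finite(v)]
      if (!length(v)) {
        warning("subject ", subject_ids[i], ": no valid ", p,
                " voxels on the ribbon; excluded for this parameter")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_ids[i], parameter = p,
        mean = mean(v), sd = sample_sd(v), n_voxels = length(v),
        stringsAsFactors = FALSE
      )
    }
  }
  per_subject <- do.call(rbind, rows)
  if (is.null(per_subject)) stop("no subject with a non-empty ribbon")
  cohort <- do.call(rbind, lapply(split(per_subject, per_subject$parameter),
    function(d) data.frame(
      parameter = d$parameter[1],
      mean_of_means = mean(d$mean), sd_of_means = sample_sd(d$mean),
      mean_of_sds = mean(d$sd), sd_of_sds = sample_sd(d$sd),
      n_subjects = nrow(d), stringsAsFactors = FALSE
    )
  ))
  rownames(cohort) <- NULL
  list(per_subject = per_subject, cohort = cohort)
}

#' Pearson or partial Pearson correlation with a t-test p-value
#'
#' Without covariates: plain Pearson r with the two-sided t transform
#' (df = n - 2). With covariates: both variables are replaced by their
#' residuals after least-squares projection on an intercept plus the
#' covariates, and the correlation of the residuals is tested with
#' df = n - 2 - k.
#'
#' @param x,y numeric vectors (finite, same length).
#' @param covariates optional numeric matrix or data.frame of k nuisance
#'   variables (factors/characters are expanded via `model.matrix`).
#' @param level label stored in the report (global/lobe/voxel).
#' @param parameter optional parameter name for the report.
#' @return object of class `correlation_report`: `r`, `p`, `n`, `df`,
#'   `covariates`, `level`, `parameter`.
#' @export
correlate <- function(x, y, covariates = NULL, level = "global",
                      parameter = NA_character_) {
  stopifnot(length(x) == length(y))
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite")
  }
  n <- length(x)
  k <- 0
  cov_names <- character(0)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    cov_names <- names(cv)
    mm <- stats::model.matrix(~., data = cv)
    k <- ncol(mm) - 1
    if (n < 3 + k) stop("n too small: need at least 3 + #covariates subjects")
    x <- stats::lm.fit(mm, x)$residuals
    y <- stats::lm.fit(mm, y)$residuals
  } else if (n < 3) {
    stop("n too small: need at least 3 subjects")
  }
  if (sample_sd(x) == 0 || sample_sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  r <- cor(x, y)
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df)
  structure(
    list(r = r, p = p, n = n, df = df, covariates = cov_names,
         level = level, parameter = parameter),
    class = "correlation_report"
  )
}

#' @export
print.correlation_report <- function(x, ...) {
  cv <- if (length(x$covariates)) {
    paste0(" | ", paste(x$covariates, collapse = ", "))
  } else ""
  cat(sprintf("%s correlation%s%s: r = %+0.3f, p = %.4g (n = %d, df = %d)%s\n",
              x$level,
              if (is.na(x$parameter)) "" else paste0(" [", x$parameter, "]"),
              if (length(x$covariates)) " (partial)" else "",
              x$r, x$p, x$n, x$df, cv))
  invisible(x)
}
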