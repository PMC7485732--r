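subject_dirs <- function(dir) {
  d <- sort(list.dirs(dir, recursive = FALSE))
  d[grepl("sub-\\d+$", d)]
}

#' Pipeline stage: simulate the cohort and its acquisitions
#'
#' Writes, per subject, the ground-truth label and parameter volumes and
#' every synthesized acquisition stack as NIfTI, plus the cohort covariate
#' CSV and a protocol sidecar.
#'
#' @param config a `pipeline_config` (see [default_pipeline_config()]).
#' @param out_dir output directory (created if needed).
#' @return character vector of written files, invisibly.
#' @export
stage_simulate <- function(config, out_dir) {
  obj <- config_objects(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ch <- config$cohort
  cohort <- generate_cohort(ch$n, ch$age_range, ch$sex_counts, obj$model,
                            obj$geometry, seed = ch$seed, build = FALSE)
  files <- character(0)
  vox <- obj$geometry$voxel_mm
  for (i in seq_len(ch$n)) {
    cv <- cohort$covariates[i, ]
    ph <- build_phantom(cv$age_years, cv$sex, obj$model, obj$geometry,
                        seed = cohort$subject_seeds[i])
    bundle <- synthesize_acquisition(
      ph, obj$protocol, seed = cohort$subject_seeds[i] %% 1000000L + i
    )
    cohort$covariates$tiv_ml[i] <- ph$tiv_ml
    sd_ <- file.path(out_dir, cv$subject_id)
    dir.create(file.path(sd_, "truth"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(sd_, "acq"), showWarnings = FALSE)
    files <- c(files,
      write_volume(ph$labels, file.path(sd_, "truth", "labels.nii.gz"), vox))
    for (p in names(ph$maps)) {
      files <- c(files, write_volume(
        ph$maps[[p]], file.path(sd_, "truth", paste0(p, ".nii.gz")), vox))
    }
    for (s in c("vfa", "fse", "ge", "b1", "tepair")) {
      files <- c(files, write_volume(
        bundle[[s]], file.path(sd_, "acq", paste0(s, ".nii.gz")), vox))
    }
    files <- c(files, write_volume(
      bundle$receive_field, file.path(sd_, "acq", "receive_field.nii.gz"), vox))
  }
  files <- c(files,
    write_covariates(cohort$covariates, file.path(out_dir, "covariates.csv")),
    write_sidecar(config$protocol %||% list(),
                  file.path(out_dir, "protocol.json")))
  invisible(files)
}

#' Pipeline stage: fit quantitative maps for every subject
#'
#' Reads the acquisition stacks written by [stage_simulate()], runs
#' [fit_qmaps()] (ventricle mask from the truth labels; receive field from
#' the stored synthetic field — simulation mode) and writes the fitted
#' maps with a JSON sidecar of fit settings.
#'
#' @param config a `pipeline_config`.
#' @param dir the run directory.
#' @param drop_first_echo,method forwarded to [fit_qmaps()].
#' @return written files, invisibly.
#' @export
stage_fitmaps <- function(config, dir, drop_first_echo = FALSE,
                          method = "loglinear") {
  obj <- config_objects(config)
  files <- character(0)
  for (sd_ in subject_dirs(dir)) {
    acq <- lapply(
      setNames(nm = c("vfa", "fse", "ge", "b1", "tepair")),
      function(s) read_volume(file.path(sd_, "acq", paste0(s, ".nii.gz")))$data
    )
    rf <- read_volume(file.path(sd_, "acq", "receive_field.nii.gz"))
    labels <- read_volume(file.path(sd_, "truth", "labels.nii.gz"))$data
    bundle <- structure(
      c(acq, list(receive_field = rf$data, protocol = obj$protocol,
                  voxel_mm = rf$voxel_mm)),
      class = "acquisition_bundle"
    )
    # the noise level is re-estimated from the background patches of the
    # reloaded data (noiseless runs estimate ~0 and keep an all-pass floor)
    noise_sd <- if (is.finite(obj$protocol$snr)) {
      estimate_noise_sd(acq$vfa[, , , 1], model = obj$protocol$noise_model)
    } else 0
    qm <- fit_qmaps(bundle,
                    csf_mask = labels == phantom_labels()[["ventricle"]],
                    noise_sd = noise_sd,
                    drop_first_echo = drop_first_echo, method = method)
    dir.create(file.path(sd_, "maps"), showWarnings = FALSE)
    for (p in c("T1", "PD", "T2", "T2star", "T2prime")) {
      files <- c(files, write_volume(
        qm[[p]], file.path(sd_, "maps", paste0(p, ".nii.gz")), rf$voxel_mm))
    }
    files <- c(files,
      write_volume(qm$b1, file.path(sd_, "maps", "B1.nii.gz"), rf$voxel_mm),
      write_volume(qm$r2$T2, file.path(sd_, "maps", "r2_T2.nii.gz"),
                   rf$voxel_mm),
      write_sidecar(list(drop_first_echo = drop_first_echo, method = method,
                         noise_sd = qm$noise_sd, floor = qm$floor),
                    file.path(sd_, "maps", "fit_settings.json")))
  }
  invisible(files)
}

#' Pipeline stage: anatomy (ribbon, thickness, lobes, TIV)
#'
#' @param config a `pipeline_config`.
#' @param dir the run directory.
#' @return written files, invisibly.
#' @export
stage_anatomy <- function(config, dir) {
  files <- character(0)
  for (sd_ in subject_dirs(dir)) {
    t1 <- read_volume(file.path(sd_, "maps", "T1.nii.gz"))
    pd <- read_volume(file.path(sd_, "maps", "PD.nii.gz"))$data
    labels <- read_volume(file.path(sd_, "truth", "labels.nii.gz"))$data
    rbm <- build_ribbon_model(
      list(T1 = t1$data, PD = pd), brain_mask = labels > 0,
      truth_labels = labels,
      method = if (isTRUE(config$anatomy$oracle_ribbon)) "oracle" else "gmm",
      voxel_mm = t1$voxel_mm
    )
    dir.create(file.path(sd_, "anat"), showWarnings = FALSE)
    out <- list(mprage = rbm$contrast, ribbon = rbm$ribbon * 1,
                wm = rbm$wm * 1, csf = rbm$csf * 1,
                thickness = rbm$thickness, lobes = rbm$lobes * 1)
    for (nm in names(out)) {
      files <- c(files, write_volume(
        out[[nm]], file.path(sd_, "anat", paste0(nm, ".nii.gz")),
        t1$voxel_mm))
    }
    files <- c(files, write_sidecar(
      list(tiv_ml = rbm$tiv_ml, global_thickness_mm = rbm$global_thickness_mm,
           dice = as.list(rbm$dice), method = rbm$method,
           lobe_codes = lobe_table()),
      file.path(sd_, "anat", "anatomy.json")))
  }
  invisible(files)
}

#' Pipeline stage: cohort statistics
#'
#' Global per-subject means/SDs and age correlations (plain and partial
#' for TIV + sex), the lobar correlation table, and — for the configured
#' parameters — smoothed voxelwise correlation maps with permutation
#' cluster correction on the common template ribbon (voxels valid in every
#' subject).
#'
#' @param config a `pipeline_config`.
#' @param dir the run directory.
#' @return written files, invisibly.
#' @export
stage_stats <- function(config, dir) {
  st <- config$stats
  cv <- read_covariates(file.path(dir, "covariates.csv"))
  sds <- subject_dirs(dir)
  n <- length(sds)
  if (n != nrow(cv)) stop("covariates do not match subject directories")
  if (n < 3) stop("n too small: need at least 3 subjects for statistics")

  params <- c("T1", "PD", "T2", "T2star", "T2prime")
  vox <- NULL
  maps <- list(); ribbons <- list(); lobes <- list(); thick <- list()
  tiv <- numeric(n)
  for (i in seq_len(n)) {
    mp <- lapply(setNames(nm = params), function(p) {
      read_volume(file.path(sds[i], "maps", paste0(p, ".nii.gz")))$data
    })
    rb <- read_volume(file.path(sds[i], "anat", "ribbon.nii.gz"))
    vox <- rb$voxel_mm
    maps[[i]] <- mp
    ribbons[[i]] <- rb$data > 0.5
    lobes[[i]] <- array(as.integer(round(
      read_volume(file.path(sds[i], "anat", "lobes.nii.gz"))$data
    )), dim = dim(rb$data))
    thick[[i]] <- read_volume(file.path(sds[i], "anat", "thickness.nii.gz"))$data
    tiv[i] <- read_sidecar(file.path(sds[i], "anat", "anatomy.json"))$tiv_ml
  }

  dir.create(file.path(dir, "stats"), showWarnings = FALSE)
  files <- character(0)

  gs <- global_summary(maps, ribbons, cv$subject_id)
  thick_mean <- vapply(seq_len(n), function(i) {
    mean(thick[[i]][ribbons[[i]]], na.rm = TRUE)
  }, numeric(1))
  write.csv(gs$per_subject, file.path(dir, "stats", "global_per_subject.csv"),
            row.names = FALSE)
  write.csv(gs$cohort, file.path(dir, "stats", "global_summary.csv"),
            row.names = FALSE)

  glob <- list()
  wide <- split(gs$per_subject$mean, gs$per_subject$parameter)
  values <- c(wide, list(thickness = thick_mean))
  for (p in names(values)) {
    plain <- correlate(values[[p]], cv$age_years, parameter = p)
    part <- correlate(values[[p]], cv$age_years,
                      covariates = data.frame(tiv = tiv, sex = cv$sex),
                      parameter = p)
    glob[[p]] <- data.frame(
      parameter = p, r = plain$r, p = plain$p,
      r_partial = part$r, p_partial = part$p, n = plain$n
    )
  }
  write.csv(do.call(rbind, glob),
            file.path(dir, "stats", "global_correlations.csv"),
            row.names = FALSE)
  files <- c(files, file.path(dir, "stats", c(
    "global_per_subject.csv", "global_summary.csv", "global_correlations.csv"
  )))

  lob <- lobar_analysis(maps, lobes, cv$age_years, thick, tiv,
                        alpha = st$alpha)
  write.csv(lob$table, file.path(dir, "stats", "lobar_correlations.csv"),
            row.names = FALSE)
  files <- c(files, file.path(dir, "stats", "lobar_correlations.csv"))

  cluster_out <- list()
  for (p in st$mapwise_parameters %||% character(0)) {
    template <- Reduce(`&`, lapply(seq_len(n), function(i) {
      ribbons[[i]] & is.finite(maps[[i]][[p]])
    }))
    if (!any(template)) next
    sm <- lapply(seq_len(n), function(i) {
      smooth_map(maps[[i]][[p]], st$fwhm_mm, vox, template)
    })
    rep_ <- mapwise_correlation(sm, cv$age_years, template,
                                threshold_p = st$threshold_p,
                                n_perm = st$n_perm, seed = config$cohort$seed,
                                alpha = st$alpha)
    files <- c(files,
      write_volume(rep_$r_map, file.path(dir, "stats",
                                         paste0("rmap_", p, ".nii.gz")), vox),
      write_volume(rep_$p_map, file.path(dir, "stats",
                                         paste0("pmap_", p, ".nii.gz")), vox))
    cluster_out[[p]] <- rep_$clusters
  }
  files <- c(files, write_sidecar(cluster_out,
                                  file.path(dir, "stats", "clusters.json")))
  invisible(files)
}

#' Run the full pipeline: simulate, fit, anatomy, statistics
#'
#' Executes the four stages in order, timing each; a stage failure marks
#' the stage failed in the manifest and skips the remaining stages, leaving
#' earlier artifacts intact. The manifest lists every artifact with its
#' MD5 hash, the configuration hash and the seed, so identical
#' configuration + seed reproduce identical manifests.
#'
#' @param config a `pipeline_config`, or a YAML path for [load_config()].
#' @param out_dir run directory.
#' @param seed optional override of `config$cohort$seed`.
#' @param verbose print stage timings.
#' @return the manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         seed = NULL, verbose = TRUE) {
  if (is.character(config)) config <- load_config(config)
  config <- validate_config(config)
  if (!is.null(seed)) config$cohort$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stages <- list(
    simulate = function() stage_simulate(config, out_dir),
    fitmaps = function() stage_fitmaps(config, out_dir),
    anatomy = function() stage_anatomy(config, out_dir),
    stats = function() stage_stats(config, out_dir)
  )
  manifest <- list(
    config_hash = config_hash(config), seed = config$cohort$seed,
    stages = list(), artifacts = list()
  )
  failed <- FALSE
  for (nm in names(stages)) {
    if (failed) {
      manifest$stages[[nm]] <- list(status = "skipped")
      next
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(stages[[nm]](), error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      manifest$stages[[nm]] <- list(status = "failed",
                                    error = conditionMessage(res),
                                    seconds = round(dt, 2))
      message("stage ", nm, " FAILED: ", conditionMessage(res))
      failed <- TRUE
    } else {
      manifest$stages[[nm]] <- list(status = "ok", seconds = round(dt, 2))
      if (verbose) message(sprintf("stage %-8s ok (%.1f s)", nm, dt))
    }
  }
  arts <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  arts <- arts[basename(arts) != "manifest.json"]
  manifest$artifacts <- data.frame(
    path = sub(paste0("^", out_dir, "/?"), "", arts),
    md5 = unname(tools::md5sum(arts)), stringsAsFactors = FALSE
  )
  write_sidecar(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
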