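#' Default pipeline configuration
#'
#' Nested list mirroring the module configurations: `cohort` (n, age_range,
#' sex_counts, seed), `aging_model` (r, sd, baseline, sd_age,
#' reference_age, cortex_sd), `geometry`, `protocol`, `anatomy`
#' (oracle_ribbon) and `stats` (fwhm_mm, n_perm, threshold_p, alpha,
#' mapwise parameter list). The desk-scale default is a 40-subject cohort
#' on a 64^3 grid at 2 mm.
#'
#' @return a `pipeline_config` list.
#' @export
default_pipeline_config <- function() {
  m <- default_aging_model()
  structure(
    list(
      cohort = list(n = 40, age_range = c(19, 71), sex_counts = NULL,
                    seed = 1L),
      aging_model = list(
        r = vapply(m$params, `[[`, numeric(1), "r_target"),
        sd = vapply(m$params, `[[`, numeric(1), "sd_between"),
        baseline = vapply(m$params, `[[`, numeric(1), "baseline"),
        cortex_sd = vapply(m$params, `[[`, numeric(1), "cortex_sd"),
        sd_age = m$sd_age, reference_age = m$reference_age
      ),
      geometry = list(dim = 64, voxel_mm = 2),
      protocol = list(snr = 50, noise_model = "gaussian",
                      bias_amplitude = 0.1),
      anatomy = list(oracle_ribbon = TRUE),
      stats = list(fwhm_mm = 10, n_perm = 500, threshold_p = 0.05,
                   alpha = 0.05, mapwise_parameters = c("T2prime"))
    ),
    class = "pipeline_config"
  )
}

# deep merge of a partial user config into the defaults
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_pipeline_config()]; the result is
#' validated.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a validated `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    # keep YAML-1.1 boolean-like scalars (n, y, on, off...) as literal
    # strings so a key like "n:" survives; real true/false still map to
    # logicals below
    user <- yaml::read_yaml(path, handlers = list(
      "bool#no" = function(x) if (tolower(x) %in% c("false", "no")) FALSE else x,
      "bool#yes" = function(x) if (tolower(x) %in% c("true", "yes")) TRUE else x
    ))
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg$cohort, {
    if (n < 1) stop("config error: cohort n must be >= 1")
    if (diff(range(age_range)) <= 0) stop("config error: bad age range")
  })
  am <- cfg$aging_model
  if (any(abs(unlist(am$r)) >= 1)) stop("config error: |r| must be < 1")
  if (cfg$stats$fwhm_mm < 0) stop("config error: negative smoothing FWHM")
  structure(cfg, class = "pipeline_config")
}

# instantiate module objects from the config
config_objects <- function(cfg) {
  am <- cfg$aging_model
  list(
    model = calibrate_aging_model(
      r = unlist(am$r), sd = unlist(am$sd), baseline = unlist(am$baseline),
      sd_age = am$sd_age, reference_age = am$reference_age,
      cortex_sd = if (!is.null(am$cortex_sd)) unlist(am$cortex_sd) else NULL,
      lobe_multipliers = am$lobe_multipliers
    ),
    geometry = do.call(geometry_config, cfg$geometry),
    protocol = do.call(acquisition_protocol, cfg$protocol)
  )
}

# stable hash of the configuration (via canonical JSON serialization)
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
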