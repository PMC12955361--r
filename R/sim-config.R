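# Simulation configuration for the synthetic cohort generator.

#' Simulation configuration
#'
#' Holds every knob of the synthetic-cohort generator. Defaults reproduce
#' the statistical structure of the study cohort the package emulates:
#' ~64 subjects, per-subject mean glucose ~ Normal(257, 57) mg/dL truncated
#' to 80-450, glucose CV ~ Normal(44, 10)% truncated to 23-62%, AGR
#' centred at the reference constant 65.1 mL/mg (SD 6, a modelling choice
#' — no population AGR spread is published), three wears of 10-14 days at
#' 15-min cadence with gaps up to 48 h, sensor-reportable range 40-500
#' mg/dL, and multiplicative assay noise of 2% CV (laboratory) and 4% CV
#' (point of care).
#'
#' @param n_subjects Number of subjects.
#' @param seed Master seed; per-subject/per-wear substreams are derived
#'   from it by stable hashing.
#' @param wear_days_range Min/max wear length in days (default `c(10, 14)`).
#' @param gap_hours_max Maximum gap between wears, hours (default 48).
#' @param cadence_minutes Reading cadence, minutes (default 15).
#' @param sensor_min,sensor_max Sensor-reportable range, mg/dL (40, 500).
#' @param mg_mean,mg_sd Cohort mean-glucose distribution, mg/dL (257, 57),
#'   truncated to `mg_range`.
#' @param mg_range Truncation bounds for subject mean glucose (80, 450).
#' @param cv_mean,cv_sd,cv_min,cv_max Glucose CV distribution in percent
#'   (44, 10, truncated to 23-62).
#' @param agr_mean,agr_sd Between-subject AGR distribution, mL/mg
#'   (65.1, 6), truncated positive.
#' @param a1c_assay_cv_lab,a1c_assay_cv_poc Multiplicative lognormal assay
#'   CV in percent (2, 4). Set to 0 for noise-free A1c.
#' @param ou_mean_reversion Mean-reversion rate of the stochastic glucose
#'   component, 1/hours (default 0.5, ~2 h correlation time).
#' @param diurnal_amplitude_frac Amplitude of the diurnal sinusoid as a
#'   fraction of the subject's mean glucose (default 0.1).
#' @param meals_per_day Expected meal-excursion pulses per day (default 3).
#' @return An object of class `sim_config` (named list).
#' @export
sim_config <- function(n_subjects = 64,
                       seed = 1L,
                       wear_days_range = c(10, 14),
                       gap_hours_max = 48,
                       cadence_minutes = 15,
                       sensor_min = 40,
                       sensor_max = 500,
                       mg_mean = 257,
                       mg_sd = 57,
                       mg_range = c(80, 450),
                       cv_mean = 44,
                       cv_sd = 10,
                       cv_min = 23,
                       cv_max = 62,
                       agr_mean = 65.1,
                       agr_sd = 6,
                       a1c_assay_cv_lab = 2,
                       a1c_assay_cv_poc = 4,
                       ou_mean_reversion = 0.5,
                       diurnal_amplitude_frac = 0.1,
                       meals_per_day = 3) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              seed = as.integer(seed),
              wear_days_range = as.numeric(wear_days_range),
              gap_hours_max = gap_hours_max,
              cadence_minutes = cadence_minutes,
              sensor_min = sensor_min,
              sensor_max = sensor_max,
              mg_mean = mg_mean, mg_sd = mg_sd,
              mg_range = as.numeric(mg_range),
              cv_mean = cv_mean, cv_sd = cv_sd,
              cv_min = cv_min, cv_max = cv_max,
              agr_mean = agr_mean, agr_sd = agr_sd,
              a1c_assay_cv_lab = a1c_assay_cv_lab,
              a1c_assay_cv_poc = a1c_assay_cv_poc,
              ou_mean_reversion = ou_mean_reversion,
              diurnal_amplitude_frac = diurnal_amplitude_frac,
              meals_per_day = meals_per_day)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_subjects < 1L) {
    stop("n_subjects must be at least 1", call. = FALSE)
  }
  if (cfg$sensor_min >= cfg$sensor_max) {
    stop("sensor_min must be below sensor_max", call. = FALSE)
  }
  if (length(cfg$wear_days_range) != 2L ||
      cfg$wear_days_range[1] > cfg$wear_days_range[2]) {
    stop("wear_days_range must be c(min, max) with min <= max",
         call. = FALSE)
  }
  if (cfg$mg_range[1] >= cfg$mg_range[2] || cfg$cv_min >= cfg$cv_max) {
    stop("truncation bounds inverted", call. = FALSE)
  }
  if (cfg$cv_min < 0 || cfg$cv_max >= 100) {
    stop("cv truncation bounds must lie in [0, 100)", call. = FALSE)
  }
  if (cfg$gap_hours_max <= 0 || cfg$cadence_minutes <= 0) {
    stop("gap_hours_max and cadence_minutes must be positive",
         call. = FALSE)
  }
  if (cfg$mg_sd < 0 || cfg$cv_sd < 0 || cfg$agr_sd < 0 ||
      cfg$a1c_assay_cv_lab < 0 || cfg$a1c_assay_cv_poc < 0) {
    stop("standard deviations and assay CVs must be non-negative",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Read a simulation configuration from a flat YAML file
#'
#' Keys mirror the [sim_config()] arguments; unknown keys are an error,
#' missing keys take their defaults.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, raw)
}

#' Write a simulation configuration to YAML
#' @param config A `sim_config`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
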