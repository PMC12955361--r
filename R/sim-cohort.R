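# Synthetic-cohort generator: subject profiles, CGM traces, A1c
# measurements and the four standard tables, with known ground-truth
# glycation parameters so the whole pipeline is testable without patient
# data.
#
# Trace model (no trace model is published for the cohort emulated here):
# a stationary AR(1)/Ornstein-Uhlenbeck component + one diurnal sinusoid +
# Poisson meal-excursion pulses, then rescaled so the realized pre-clamp
# mean and CV match the subject's targets exactly; readings are finally
# clamped to the sensor-reportable range. Rescaling pre-clamp gives exact
# control of the target moments; clamping can shift realized moments
# slightly for high-CV subjects.

# Deterministic substream seeds: one master seed, per-(subject, wear, tag)
# seeds derived by a stable polynomial string hash. Keeps every draw
# reproducible and independent of evaluation order.
.hash_string <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  h
}

.sub_seed <- function(master, ...) {
  key <- paste(..., sep = "|")
  as.integer((as.numeric(master) * 48271 + .hash_string(key)) %% 2147483647)
}

# Truncated-normal draws by inverse-CDF; exact and seed-stable.
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

#' Draw synthetic subject profiles
#'
#' Per-subject glycemic targets: mean glucose from a truncated
#' Normal(`mg_mean`, `mg_sd`) on `mg_range`; glucose CV from a truncated
#' Normal(`cv_mean`, `cv_sd`) on \[`cv_min`, `cv_max`\]; true AGR from a
#' Normal(`agr_mean`, `agr_sd`) truncated positive. Covariates are drawn
#' with the cohort frequencies the generator emulates: ~45% children, 48%
#' female, 13% sickle-cell trait (hemoglobin AS), 10% low G6PD, income
#' split 14/25/21/40% (very poor / poor / low / mid-high); children's
#' Tanner stages are mostly prepubertal (52% stage 1, 31% stage 2) and
#' young adults are Tanner 5.
#'
#' @param config A [sim_config()].
#' @return data.frame of class `subject_profiles`, one row per subject:
#'   `subject_id`, `target_mg`, `target_cv`, `true_agr`, `age_group`,
#'   `sex`, `tanner`, `income`, `hb_as`, `g6pd_low`, `ferritin`,
#'   `hemoglobin`, `rdw_cv`.
#' @export
draw_profiles <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  set.seed(.sub_seed(config$seed, "profiles"))
  subject_id <- sprintf("S%03d", seq_len(n))
  target_mg <- .rtruncnorm(n, config$mg_mean, config$mg_sd,
                           config$mg_range[1], config$mg_range[2])
  target_cv <- .rtruncnorm(n, config$cv_mean, config$cv_sd,
                           config$cv_min, config$cv_max)
  true_agr <- .rtruncnorm(n, config$agr_mean, config$agr_sd, lower = 1e-6)
  age_group <- sample(c("child", "young_adult"), n, replace = TRUE,
                      prob = c(0.45, 0.55))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.48, 0.52))
  tanner <- integer(n)
  is_child <- age_group == "child"
  tanner[is_child] <- sample(1:5, sum(is_child), replace = TRUE,
                             prob = c(0.52, 0.31, 0.10, 0.04, 0.03))
  tanner[!is_child] <- 5L
  income <- sample(c("very_poor", "poor", "low", "mid_high"), n,
                   replace = TRUE, prob = c(0.14, 0.25, 0.21, 0.40))
  hb_as <- stats::runif(n) < 0.13
  g6pd_low <- stats::runif(n) < 0.10
  ferritin <- stats::rlnorm(n, log(50), 0.6)
  hemoglobin <- .rtruncnorm(n, 13.5, 1.3, 9, 18)
  rdw_cv <- .rtruncnorm(n, 13.5, 1.5, 11, 20)
  out <- data.frame(subject_id = subject_id,
                    target_mg = target_mg,
                    target_cv = target_cv,
                    true_agr = true_agr,
                    age_group = age_group,
                    sex = sex,
                    tanner = tanner,
                    income = income,
                    hb_as = hb_as,
                    g6pd_low = g6pd_low,
                    ferritin = ferritin,
                    hemoglobin = hemoglobin,
                    rdw_cv = rdw_cv,
                    stringsAsFactors = FALSE)
  class(out) <- c("subject_profiles", class(out))
  out
}

#' Simulate one sensor wear for one subject
#'
#' Generates readings at the configured cadence over a wear length drawn
#' uniformly in `wear_days_range`. The glucose process is subject baseline
#' + mean-reverting AR(1) noise + a diurnal sinusoid + meal pulses
#' (Poisson-count, exponential-decay excursions), linearly rescaled so the
#' realized pre-clamp mean equals `target_mg` and the pre-clamp population
#' CV equals `target_cv` exactly, then clamped to the sensor range.
#'
#' @param profile One row of [draw_profiles()] output (or an equivalent
#'   named list with `subject_id`, `target_mg`, `target_cv`).
#' @param wear_index Wear number, 1-3.
#' @param config A [sim_config()].
#' @param seed Optional integer seed for this wear; by default derived
#'   from `config$seed`, the subject id and the wear index.
#' @param start `POSIXct` start time of the wear (default
#'   2024-01-01 00:00 UTC).
#' @return A `glucose_trace` with additional fields `preclamp_mean` and
#'   `preclamp_cv` (the realized moments before clamping).
#' @export
simulate_trace <- function(profile, wear_index, config = sim_config(),
                           seed = NULL,
                           start = as.POSIXct("2024-01-01 00:00:00",
                                              tz = "UTC")) {
  stopifnot(inherits(config, "sim_config"))
  wear_index <- as.integer(wear_index)
  if (wear_index < 1L || wear_index > 3L) {
    stop("wear_index must be 1, 2 or 3", call. = FALSE)
  }
  profile <- as.list(profile)
  if (is.null(seed)) {
    seed <- .sub_seed(config$seed, profile$subject_id, wear_index, "trace")
  }
  set.seed(seed)

  days <- stats::runif(1, config$wear_days_range[1],
                       config$wear_days_range[2])
  dt_h <- config$cadence_minutes / 60
  n <- floor(days * 24 / dt_h) + 1L
  t_h <- (seq_len(n) - 1L) * dt_h

  # stationary AR(1) (discretised Ornstein-Uhlenbeck), unit variance
  a <- exp(-config$ou_mean_reversion * dt_h)
  eps <- stats::rnorm(n)
  ou <- numeric(n)
  ou[1] <- eps[1]
  for (i in seq_len(n - 1L)) {
    ou[i + 1L] <- a * ou[i] + sqrt(1 - a^2) * eps[i + 1L]
  }

  phase <- stats::runif(1, 0, 24)
  diurnal <- sin(2 * pi * (t_h + phase) / 24)

  n_meals <- stats::rpois(1, config$meals_per_day * days)
  meals <- numeric(n)
  if (n_meals > 0) {
    meal_t <- stats::runif(n_meals, 0, max(t_h))
    meal_a <- stats::rexp(n_meals, 1)
    for (k in seq_len(n_meals)) {
      after <- t_h >= meal_t[k]
      meals[after] <- meals[after] +
        meal_a[k] * exp(-(t_h[after] - meal_t[k]) / 1.5)
    }
  }

  raw <- ou + config$diurnal_amplitude_frac * 4 * diurnal + meals
  target_sd <- profile$target_cv / 100 * profile$target_mg
  raw_sd <- sqrt(mean((raw - mean(raw))^2))
  g <- if (target_sd == 0 || raw_sd == 0) {
    rep(profile$target_mg, n)
  } else {
    profile$target_mg + (raw - mean(raw)) * (target_sd / raw_sd)
  }

  preclamp_mean <- mean(g)
  preclamp_sd <- sqrt(mean((g - preclamp_mean)^2))
  timestamps <- start + t_h * 3600
  tr <- glucose_trace(profile$subject_id, wear_index, timestamps, g,
                      clamp = TRUE)
  tr$preclamp_mean <- preclamp_mean
  tr$preclamp_cv <- if (preclamp_mean > 0) {
    100 * preclamp_sd / preclamp_mean
  } else {
    0
  }
  tr
}

#' Simulate an A1c measurement from the kinetic model
#'
#' Noise-free value from the forward kinetic model with the subject's true
#' AGR at the supplied trailing mean glucose, then multiplicative
#' lognormal assay noise with CV `a1c_assay_cv_lab` or `a1c_assay_cv_poc`
#' (percent; the lognormal factor has expectation 1). With assay CV 0 the
#' value is exactly `forward_a1c(trailing_mg, true_agr)`.
#'
#' @param profile Profile row with `true_agr`.
#' @param trailing_mg Trailing mean glucose, mg/dL (> 0).
#' @param config A [sim_config()].
#' @param assay `"lab"` or `"poc"`.
#' @param seed Optional integer seed (default derived from the config seed
#'   and the subject id).
#' @param constants A [glycation_constants()] object.
#' @return A1c in NGSP %, in (0, 100).
#' @export
simulate_a1c <- function(profile, trailing_mg, config = sim_config(),
                         assay = c("lab", "poc"), seed = NULL,
                         constants = glycation_constants()) {
  assay <- match.arg(assay)
  profile <- as.list(profile)
  .check_mg(trailing_mg)
  a1c <- forward_a1c(trailing_mg, profile$true_agr, constants)
  cv <- switch(assay, lab = config$a1c_assay_cv_lab,
               poc = config$a1c_assay_cv_poc) / 100
  if (cv > 0) {
    if (is.null(seed)) {
      seed <- .sub_seed(config$seed, profile$subject_id, assay, "a1c")
    }
    set.seed(seed)
    sigma <- sqrt(log(1 + cv^2))
    a1c <- a1c * exp(stats::rnorm(length(a1c)) * sigma - sigma^2 / 2)
  }
  pmin(pmax(a1c, 1e-6), 100 - 1e-6)
}

#' Simulate a full synthetic cohort
#'
#' Draws profiles, simulates three consecutive wears per subject separated
#' by gaps drawn uniformly in (0, `gap_hours_max`\] hours, and generates
#' laboratory and point-of-care A1c at the end of each wear. Visit-1 A1c
#' uses the wear-1 mean glucose, visit-2 the clamped readings pooled over
#' wears 1-2 (the AGR calibration window), visit-3 the readings pooled
#' over all three wears. All glucose pooling is equal-weight per clamped
#' reading — exactly what the analysis pipeline recomputes, so with assay
#' noise disabled AGR recovery is exact.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `readings.csv`,
#'   `visits.csv`, `covariates.csv` and `truth.csv` there.
#' @return List of data.frames `readings`, `visits`, `covariates`,
#'   `truth` (invisible paths in attribute `paths` when written).
#' @export
simulate_cohort <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  profiles <- draw_profiles(config)

  readings_list <- list()
  visits_list <- list()
  for (i in seq_len(nrow(profiles))) {
    prof <- profiles[i, ]
    start <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
    glucose_sofar <- list()
    for (w in 1:3) {
      tr <- simulate_trace(prof, w, config, start = start)
      readings_list[[length(readings_list) + 1L]] <- data.frame(
        subject_id = tr$subject_id,
        sensor_index = tr$sensor_index,
        timestamp = format(tr$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
        glucose_mgdl = tr$glucose_mgdl,
        stringsAsFactors = FALSE)
      glucose_sofar[[w]] <- tr$glucose_mgdl
      wear_end <- tr$timestamp[length(tr$timestamp)]

      trailing_mg <- if (w == 1L) {
        mean(glucose_sofar[[1]])
      } else {
        mean(unlist(glucose_sofar[seq_len(w)]))
      }
      for (assay in c("lab", "poc")) {
        a1c <- simulate_a1c(prof, trailing_mg, config, assay,
                            seed = .sub_seed(config$seed, prof$subject_id,
                                             w, assay, "visit"))
        visits_list[[length(visits_list) + 1L]] <- data.frame(
          subject_id = prof$subject_id,
          visit = w,
          assay = assay,
          a1c_percent = a1c,
          date = format(wear_end, "%Y-%m-%d"),
          stringsAsFactors = FALSE)
      }
      set.seed(.sub_seed(config$seed, prof$subject_id, w, "gap"))
      gap_h <- stats::runif(1, min(1, config$gap_hours_max),
                            config$gap_hours_max)
      start <- wear_end + gap_h * 3600
    }
  }

  readings <- do.call(rbind, readings_list)
  visits <- do.call(rbind, visits_list)
  covariates <- profiles[, c("subject_id", "age_group", "sex", "tanner",
                             "income", "hb_as", "g6pd_low", "ferritin",
                             "hemoglobin", "rdw_cv")]
  truth <- profiles[, c("subject_id", "true_agr", "target_mg",
                        "target_cv")]
  class(covariates) <- "data.frame"
  class(truth) <- "data.frame"

  out <- list(readings = readings, visits = visits,
              covariates = covariates, truth = truth)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- character(0)
    for (nm in names(out)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(out[[nm]], p, row.names = FALSE)
      paths[nm] <- p
    }
    attr(out, "paths") <- paths
  }
  out
}
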