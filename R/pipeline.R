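# End-to-end pipeline: QC -> glycemic metrics -> AGR calibration -> pA1c
# -> cohort statistics, plus readers/writers for the standard tables.

#' Read the visits table
#' @param path CSV with columns `subject_id`, `visit`, `assay`,
#'   `a1c_percent`, `date`.
#' @return data.frame.
#' @export
read_visits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "visit", "assay", "a1c_percent")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("visits file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!df$assay %in% c("lab", "poc"))
  if (length(bad)) {
    stop("unknown assay at row ", bad[1], ": ", df$assay[bad[1]],
         call. = FALSE)
  }
  df
}

#' Read the covariates table
#' @param path CSV with `subject_id` plus covariate columns.
#' @return data.frame.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df)) {
    stop("covariates file is missing column(s): subject_id", call. = FALSE)
  }
  df
}

.get_a1c <- function(visits, subject, visit, assay) {
  sel <- visits$subject_id == subject & visits$visit == visit &
    visits$assay == assay
  if (sum(sel) == 0L) return(NA_real_)
  visits$a1c_percent[which(sel)[1]]
}

#' Build per-subject glycation records
#'
#' For every protocol-valid subject: calibration mean glucose (wears 1-2
#' pooled), the visit-2 laboratory A1c, the AGR from the two, the visit-3
#' A1cs, the pA1c (visit-3 laboratory A1c personalized with the AGR), and
#' the evaluation mean glucose (all wears pooled). POC A1c is never used
#' for AGR calibration.
#'
#' @param wearsets List of `wearset` objects (protocol-valid ones are
#'   used; others are skipped).
#' @param visits Visits data.frame (see [read_visits()]).
#' @param constants A [glycation_constants()] object.
#' @return data.frame of class `glycation_records`: one row per subject
#'   with `subject_id`, `calibration_mg`, `calibration_a1c`, `agr`,
#'   `visit3_a1c_lab`, `visit3_a1c_poc`, `pa1c`, `evaluation_mg`.
#' @export
build_glycation_records <- function(wearsets, visits,
                                    constants = glycation_constants()) {
  rows <- lapply(wearsets, function(ws) {
    if (!ws$protocol_valid) return(NULL)
    calib <- pool_metrics(ws, c(1L, 2L))
    eval_m <- pool_metrics(ws, c(1L, 2L, 3L))
    a1c2 <- .get_a1c(visits, ws$subject_id, 2L, "lab")
    a1c3_lab <- .get_a1c(visits, ws$subject_id, 3L, "lab")
    a1c3_poc <- .get_a1c(visits, ws$subject_id, 3L, "poc")
    if (is.na(a1c2) || is.na(a1c3_lab)) {
      stop("missing laboratory A1c for subject ", ws$subject_id,
           call. = FALSE)
    }
    agr <- compute_agr(calib$mean_glucose, a1c2, constants)
    data.frame(subject_id = ws$subject_id,
               calibration_mg = calib$mean_glucose,
               calibration_a1c = a1c2,
               agr = agr,
               visit3_a1c_lab = a1c3_lab,
               visit3_a1c_poc = a1c3_poc,
               pa1c = compute_pa1c(a1c3_lab, agr, constants),
               evaluation_mg = eval_m$mean_glucose,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no protocol-valid subjects", call. = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("glycation_records", class(out))
  out
}

#' Run the full cohort analysis pipeline
#'
#' Stages: wear-protocol QC (protocol-invalid subjects excluded with a
#' logged reason) -> glycemic metrics (wears 1-2 pooled for calibration
#' mean glucose, all wears for evaluation mean glucose) -> per-subject AGR
#' from the calibration window and visit-2 laboratory A1c -> pA1c applied
#' to the visit-3 A1c -> model comparison (mean glucose vs laboratory
#' A1c, POC A1c and pA1c), Spearman correlation of glucose CV with % time
#' below 54 mg/dL, Welch t-tests of metabolic variables between children
#' and young adults, stepwise-AIC covariate-adjusted fits, and the
#' correlation power calculation.
#'
#' @param readings Readings data.frame or CSV path.
#' @param visits Visits data.frame or CSV path.
#' @param covariates Covariates data.frame or CSV path.
#' @param constants A [glycation_constants()] object.
#' @param power_rho,power_n,alpha Parameters of the design power
#'   calculation carried in the result (defaults: rho 0.52, n 60, alpha
#'   0.05).
#' @param out_dir Optional output directory: writes `analysis.json` plus
#'   tidy CSV mirrors `metrics.csv`, `agr.csv`, `pa1c.csv`.
#' @return List of class `cohort_result`: `fits`, `records`, `metrics`,
#'   `spearman_cv_hypo`, `welch_age`, `stepwise`, `power`, `exclusions`,
#'   `n_analyzed`.
#' @export
run_pipeline <- function(readings, visits, covariates,
                         constants = glycation_constants(),
                         power_rho = 0.52, power_n = 60, alpha = 0.05,
                         out_dir = NULL) {
  traces <- if (is.character(readings)) {
    read_readings(readings)
  } else {
    as_traces(readings)
  }
  if (is.character(visits)) visits <- read_visits(visits)
  if (is.character(covariates)) covariates <- read_covariates(covariates)

  by_subject <- split(traces,
                      vapply(traces, function(t) t$subject_id,
                             character(1)))
  wearsets <- lapply(by_subject, qc_wearset)

  exclusions <- list()
  for (ws in wearsets) {
    if (!ws$protocol_valid) {
      reason <- if (length(ws$wears) < 3L) {
        sprintf("only %d wear(s) present", length(ws$wears))
      } else if (!all(ws$qc$valid)) {
        sprintf("wear(s) %s under 10 days",
                paste(ws$qc$sensor_index[!ws$qc$valid], collapse = ","))
      } else {
        "inter-wear gap over 48 h"
      }
      exclusions[[ws$subject_id]] <- reason
      message("excluding subject ", ws$subject_id, ": ", reason)
    }
  }
  valid_sets <- Filter(function(ws) ws$protocol_valid, wearsets)
  if (length(valid_sets) < 3L) {
    stop("fewer than 3 protocol-valid subjects; cannot run cohort stage",
         call. = FALSE)
  }

  metrics <- metrics_table(valid_sets)
  records <- build_glycation_records(valid_sets, visits, constants)
  fits <- compare_predictors(records)

  all_scope <- metrics[metrics$scope == "all", ]
  all_scope <- all_scope[match(records$subject_id, all_scope$subject_id), ]
  rho_cv_hypo <- spearman_cor(all_scope$cv, all_scope$pct_below_54)

  cov_rows <- covariates[match(records$subject_id,
                               covariates$subject_id), , drop = FALSE]
  welch_age <- NULL
  if ("age_group" %in% names(cov_rows) &&
      length(unique(stats::na.omit(cov_rows$age_group))) == 2L) {
    grp <- cov_rows$age_group
    groups <- sort(unique(stats::na.omit(grp)))
    vars <- c("mean_glucose", "cv", "pct_below_70", "pct_in_70_180",
              "pct_above_180")
    welch_age <- lapply(stats::setNames(vars, vars), function(v) {
      a <- all_scope[[v]][grp == groups[1]]
      b <- all_scope[[v]][grp == groups[2]]
      if (length(a) >= 2L && length(b) >= 2L) welch_t(a, b) else NULL
    })
    attr(welch_age, "groups") <- groups
  }

  candidate_cols <- intersect(
    c("age_group", "sex", "tanner", "income", "hb_as", "g6pd_low",
      "ferritin", "hemoglobin", "rdw_cv"),
    names(cov_rows))
  stepwise <- NULL
  if (length(candidate_cols) && nrow(records) >= 10L) {
    stepwise <- lapply(
      stats::setNames(c("visit3_a1c_lab", "pa1c"),
                      c("lab_a1c", "pa1c")),
      function(pred) {
        tab <- cbind(primary = records[[pred]],
                     cov_rows[, candidate_cols, drop = FALSE])
        sw <- tryCatch(
          stepwise_aic(records$evaluation_mg, tab, candidate_cols),
          error = function(e) NULL)
        if (is.null(sw)) return(NULL)
        list(selected = sw$selected, summary = sw$summary)
      })
  }

  power <- list(rho = power_rho, n = power_n, alpha = alpha,
                power_fisher_z = correlation_power(power_rho, power_n,
                                                   alpha))

  result <- structure(
    list(fits = fits,
         records = records,
         metrics = metrics,
         spearman_cv_hypo = rho_cv_hypo,
         welch_age = welch_age,
         stepwise = stepwise,
         power = power,
         exclusions = exclusions,
         n_analyzed = nrow(records)),
    class = "cohort_result")

  if (!is.null(out_dir)) {
    write_cohort_result(result, out_dir)
  }
  result
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects analyzed, %d excluded\n",
              x$n_analyzed, length(x$exclusions)))
  cat("\nMean glucose vs A1c variants:\n")
  print(x$fits, row.names = FALSE, digits = 3)
  cat(sprintf("\nSpearman (CV, %% time < 54 mg/dL): %.2f\n",
              x$spearman_cv_hypo))
  cat(sprintf("Design power (rho = %.2f, n = %d): %.3f\n",
              x$power$rho, x$power$n, x$power$power_fisher_z))
  invisible(x)
}

#' Write a cohort result to disk
#'
#' Emits `analysis.json` (fit summaries, correlation, tests, power,
#' exclusion log) and tidy CSV mirrors `metrics.csv`, `agr.csv`,
#' `pa1c.csv`.
#'
#' @param result A `cohort_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort_result <- function(result, out_dir) {
  stopifnot(inherits(result, "cohort_result"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  json <- list(
    n_analyzed = result$n_analyzed,
    exclusions = result$exclusions,
    fits = result$fits,
    spearman_cv_vs_pct_below_54 = result$spearman_cv_hypo,
    welch_age = result$welch_age,
    stepwise = result$stepwise,
    power = result$power)
  jsonlite::write_json(json, file.path(out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  utils::write.csv(result$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(
    result$records[, c("subject_id", "calibration_mg", "calibration_a1c",
                       "agr")],
    file.path(out_dir, "agr.csv"), row.names = FALSE)
  utils::write.csv(
    result$records[, c("subject_id", "visit3_a1c_lab", "visit3_a1c_poc",
                       "agr", "pa1c", "evaluation_mg")],
    file.path(out_dir, "pa1c.csv"), row.names = FALSE)
  invisible(out_dir)
}
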