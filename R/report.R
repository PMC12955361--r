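# Human-readable markdown report from a completed analysis directory.

.fmt_glucose <- function(mgdl) {
  sprintf("%.0f mg/dL (%.1f mmol/L)", mgdl,
          convert_glucose(mgdl, "mgdl_to_mmoll"))
}

.fmt_a1c <- function(ngsp) {
  sprintf("%.1f%% (%.0f mmol/mol)", ngsp,
          convert_a1c(ngsp, "ngsp_to_ifcc", round_result = TRUE))
}

#' Render a markdown report from an analysis directory
#'
#' Reads `analysis.json`, `pa1c.csv` and `metrics.csv` (as written by
#' [run_pipeline()] / the `analyze` subcommand) and renders `report.md`:
#' cohort summary, glycemic metrics, AGR/pA1c table and the
#' model-comparison fits, with glucose in mg/dL and mmol/L (1 decimal)
#' and A1c in NGSP % and integer IFCC mmol/mol.
#'
#' @param in_dir Directory holding the analysis outputs.
#' @param out_dir Directory for `report.md` (created if needed).
#' @return Path of the written report, invisibly.
#' @export
render_report <- function(in_dir, out_dir) {
  analysis_path <- file.path(in_dir, "analysis.json")
  if (!file.exists(analysis_path)) {
    stop("analysis.json not found in ", in_dir, call. = FALSE)
  }
  an <- jsonlite::read_json(analysis_path, simplifyVector = TRUE)
  pa1c_tab <- utils::read.csv(file.path(in_dir, "pa1c.csv"),
                              stringsAsFactors = FALSE)
  metrics <- utils::read.csv(file.path(in_dir, "metrics.csv"),
                             stringsAsFactors = FALSE)
  pooled <- metrics[metrics$scope == "all", ]

  lines <- c(
    "# Personalized A1c cohort report",
    "",
    sprintf("Subjects analyzed: %d (excluded: %d).", an$n_analyzed,
            length(an$exclusions)),
    "",
    "## Cohort glycemic summary (all wears pooled)",
    "",
    sprintf("- Mean glucose: %s (cohort mean of per-subject means)",
            .fmt_glucose(mean(pooled$mean_glucose))),
    sprintf("- Glucose CV: %.0f%% +/- %.0f%%", mean(pooled$cv),
            stats::sd(pooled$cv)),
    sprintf("- %% time 70-180 mg/dL (3.9-10.0 mmol/L): %.0f%%",
            mean(pooled$pct_in_70_180)),
    sprintf("- %% time > 250 mg/dL (13.9 mmol/L): %.0f%%",
            mean(pooled$pct_above_250)),
    sprintf("- %% time < 54 mg/dL (3.0 mmol/L): %.1f%%",
            mean(pooled$pct_below_54)),
    sprintf("- Spearman correlation of CV with %% time < 54 mg/dL: %.2f",
            an$spearman_cv_vs_pct_below_54),
    "",
    "## A1c personalization",
    "",
    sprintf("- Mean laboratory A1c (visit 3): %s",
            .fmt_a1c(mean(pa1c_tab$visit3_a1c_lab))),
    sprintf("- Mean pA1c: %s", .fmt_a1c(mean(pa1c_tab$pa1c))),
    sprintf("- Mean AGR: %.1f mL/mg (reference glycator: 65.1 mL/mg)",
            mean(pa1c_tab$agr)),
    "",
    "## How well does each A1c variant track mean glucose?",
    "",
    "| predictor | slope | intercept | R^2 | r | RMSE (mg/dL) | n |",
    "|---|---|---|---|---|---|---|")
  fits <- as.data.frame(an$fits)
  for (i in seq_len(nrow(fits))) {
    lines <- c(lines, sprintf(
      "| %s | %.1f | %.1f | %.2f | %.2f | %.1f | %d |",
      fits$predictor_name[i], fits$slope[i], fits$intercept[i],
      fits$r_squared[i], fits$pearson_r[i], fits$rmse[i],
      as.integer(fits$n[i])))
  }
  lines <- c(
    lines, "",
    "## Design power",
    "",
    sprintf(paste0("- Power to detect r = %.2f with n = %d at two-sided ",
                   "alpha = %.2f: %.3f (Fisher z)"),
            an$power$rho, an$power$n, an$power$alpha,
            an$power$power_fisher_z),
    "")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
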