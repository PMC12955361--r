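# Cohort-level statistics: simple regression summaries of mean glucose on
# each A1c variant, Spearman correlation, Welch t-tests, stepwise-AIC
# covariate adjustment, and the correlation power calculation.

#' Simple linear regression summary
#'
#' Ordinary least squares of `y` on `x` via [stats::lm()], summarised the
#' way the model-comparison stage needs: slope, intercept, R-squared (1 -
#' RSS/TSS), the signed Pearson r, and RMSE = sqrt(RSS/n) (divisor n, the
#' error of the estimate on the fitted scale).
#'
#' @param x Predictor values (non-constant, length >= 3).
#' @param y Response values, same length.
#' @param predictor_name Label carried into the summary.
#' @return One-row data.frame of class `fit_summary`: `predictor_name`,
#'   `slope`, `intercept`, `r_squared`, `pearson_r`, `rmse`, `n`.
#' @export
fit_simple <- function(x, y, predictor_name = NULL) {
  if (is.null(predictor_name)) {
    predictor_name <- paste(deparse(substitute(x)), collapse = "")
  }
  predictor_name <- as.character(predictor_name)[1]
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant; no regression possible",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  r <- if (tss == 0) 0 else stats::cor(x, y)
  out <- data.frame(predictor_name = predictor_name,
                    slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]),
                    r_squared = r2,
                    pearson_r = r,
                    rmse = sqrt(rss / n),
                    n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("fit_summary", class(out))
  out
}

#' Compare how A1c variants track mean glucose
#'
#' On an identical subject set, fits evaluation mean glucose against the
#' visit-3 laboratory A1c, the visit-3 point-of-care A1c and the pA1c, and
#' additionally the POC A1c against the laboratory A1c (method agreement).
#' Returns the four fit summaries stacked.
#'
#' @param records data.frame with columns `evaluation_mg`,
#'   `visit3_a1c_lab`, `visit3_a1c_poc`, `pa1c` (one row per subject;
#'   rows with any missing field are dropped).
#' @return data.frame of four `fit_summary` rows: `lab_a1c`, `poc_a1c`,
#'   `pa1c` (each predicting mean glucose) and `poc_vs_lab`.
#' @export
compare_predictors <- function(records) {
  need <- c("evaluation_mg", "visit3_a1c_lab", "visit3_a1c_poc", "pa1c")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records missing field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[stats::complete.cases(records[, need]), , drop = FALSE]
  if (nrow(records) < 3L) {
    stop("need at least 3 complete records", call. = FALSE)
  }
  out <- rbind(
    fit_simple(records$visit3_a1c_lab, records$evaluation_mg, "lab_a1c"),
    fit_simple(records$visit3_a1c_poc, records$evaluation_mg, "poc_a1c"),
    fit_simple(records$pa1c, records$evaluation_mg, "pa1c"),
    fit_simple(records$visit3_a1c_lab, records$visit3_a1c_poc,
               "poc_vs_lab"))
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties). When either
#' variable is entirely tied the correlation is undefined; 0 is returned
#' with a warning, a documented convention.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Spearman's rho.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("degenerate ranks (all values tied); returning 0")
    return(0)
  }
  stats::cor(rx, ry)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and
#' a two-sided p-value, via [stats::t.test()].
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return Named list `t`, `df`, `p`, plus the group means.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic),
       df = unname(ht$parameter),
       p = unname(ht$p.value),
       mean_a = mean(group_a),
       mean_b = mean(group_b))
}

#' Stepwise-AIC covariate selection around a primary predictor
#'
#' Bidirectional stepwise selection with [stats::step()], starting from
#' the model `response ~ primary` and scoped between that model (lower)
#' and `response ~ primary + all candidates` (upper). The primary
#' predictor is never dropped. AIC follows the `extractAIC` convention
#' n*log(RSS/n) + 2*(number of coefficients); only AIC differences matter
#' for selection. Complete cases only; a rank-deficient design after
#' factor expansion is an error naming the aliased columns.
#'
#' @param response Numeric response vector.
#' @param covariate_table data.frame holding `primary` and all candidate
#'   columns (categoricals as character/factor, expanded to indicators by
#'   the model matrix).
#' @param candidates Character vector of candidate covariate names; order
#'   fixes deterministic tie-breaks.
#' @param primary Name of the always-included predictor column.
#' @return List with `formula` (selected model), `selected` (candidate
#'   names retained), `fit` (the `lm`), and `summary` (a `fit_summary`-like
#'   row: r_squared, rmse, n of the selected model).
#' @export
stepwise_aic <- function(response, covariate_table, candidates,
                         primary = "primary") {
  stopifnot(is.data.frame(covariate_table))
  missing_cols <- setdiff(c(primary, candidates), names(covariate_table))
  if (length(missing_cols)) {
    stop("covariate_table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dat <- covariate_table[, c(primary, candidates), drop = FALSE]
  dat$.response <- as.numeric(response)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  for (nm in names(dat)) if (is.character(dat[[nm]])) {
    dat[[nm]] <- factor(dat[[nm]])
  }

  full_formula <- stats::reformulate(c(primary, candidates),
                                     response = ".response")
  mm <- stats::model.matrix(full_formula, dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  base_fit <- stats::lm(stats::reformulate(primary, ".response"),
                        data = dat)
  sel <- stats::step(base_fit,
                     scope = list(lower = stats::reformulate(primary),
                                  upper = full_formula),
                     direction = "both", trace = 0)
  rss <- sum(stats::residuals(sel)^2)
  tss <- sum((dat$.response - mean(dat$.response))^2)
  term_labels <- attr(stats::terms(sel), "term.labels")
  list(formula = stats::formula(sel),
       selected = setdiff(term_labels, primary),
       fit = sel,
       summary = data.frame(r_squared = 1 - rss / tss,
                            rmse = sqrt(rss / nrow(dat)),
                            n = nrow(dat),
                            n_terms = length(term_labels)))
}

#' Power to detect a correlation
#'
#' Power of the two-sided test of H0: rho = 0 at level `alpha` when the
#' true correlation is `rho` and the sample size is `n`. The `fisher_z`
#' method is the closed form Phi(sqrt(n-3) * atanh(rho) - z_(1-alpha/2));
#' `monte_carlo` simulates `n_sims` bivariate-normal cohorts and reports
#' the rejection fraction of [stats::cor.test()].
#'
#' @param rho True correlation, in (0, 1).
#' @param n Sample size (>= 4).
#' @param alpha Two-sided significance level (default 0.05).
#' @param method `"fisher_z"` (default) or `"monte_carlo"`.
#' @param n_sims Number of simulated cohorts for `monte_carlo`.
#' @param seed Seed for `monte_carlo`.
#' @return Power as a fraction in (0, 1).
#' @examples
#' correlation_power(0.52, 60)  # about 0.99
#' @export
correlation_power <- function(rho, n, alpha = 0.05,
                              method = c("fisher_z", "monte_carlo"),
                              n_sims = 10000, seed = 1L) {
  method <- match.arg(method)
  if (!is.numeric(rho) || rho <= 0 || rho >= 1) {
    stop("rho must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (n < 4) stop("n must be at least 4", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  if (method == "fisher_z") {
    z_crit <- stats::qnorm(1 - alpha / 2)
    return(stats::pnorm(sqrt(n - 3) * atanh(rho) - z_crit))
  }
  set.seed(seed)
  rejections <- 0L
  for (s in seq_len(n_sims)) {
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
    if (stats::cor.test(x, y)$p.value < alpha) rejections <- rejections + 1L
  }
  rejections / n_sims
}
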