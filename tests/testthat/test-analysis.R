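# Cohort statistics: OLS summaries, Spearman, Welch, stepwise AIC, power.

test_that("fit_simple matches the hand least-squares oracle", {
  # normal equations by hand on x = 1..5, y = (2, 2, 3, 5, 5):
  # slope 0.9, intercept 0.7, RSS 1.10, TSS 9.2
  f <- fit_simple(1:5, c(2, 2, 3, 5, 5), "hand")
  expect_equal(f$slope, 0.9, tolerance = 1e-12)
  expect_equal(f$intercept, 0.7, tolerance = 1e-12)
  expect_equal(f$r_squared, 1 - 1.1 / 9.2, tolerance = 1e-12)
  expect_equal(f$rmse, sqrt(1.1 / 5), tolerance = 1e-12)
  expect_equal(f$pearson_r, sqrt(1 - 1.1 / 9.2), tolerance = 1e-12)
})

test_that("fit_simple handles perfect fits and validates input", {
  x <- seq(1, 10)
  f <- fit_simple(x, 2 * x + 1, "perfect")
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$rmse, 0, tolerance = 1e-9)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_error(fit_simple(rep(1, 5), 1:5), "constant")
  expect_error(fit_simple(1:4, 1:5), "lengths differ")
  expect_error(fit_simple(1:2, 1:2), "at least 3")
})

test_that("fit_simple agrees with a normal-equations oracle on random data", {
  # independent oracle: solve (X'X) b = X'y directly
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    x <- rnorm(n)
    y <- 1.5 * x + rnorm(n)
    X <- cbind(1, x)
    b <- solve(t(X) %*% X, t(X) %*% y)
    rss <- sum((y - X %*% b)^2)
    tss <- sum((y - mean(y))^2)
    f <- fit_simple(x, y)
    expect_equal(f$intercept, b[1], tolerance = 1e-9)
    expect_equal(f$slope, b[2], tolerance = 1e-9)
    expect_equal(f$r_squared, 1 - rss / tss, tolerance = 1e-9)
    expect_equal(f$rmse, sqrt(rss / n), tolerance = 1e-9)
    expect_equal(f$r_squared, f$pearson_r^2, tolerance = 1e-9)
  }
})

test_that("printed R^2 and r are mutually consistent", {
  # arithmetic sanity on the reported pairing: r = 0.63 implies R^2 ~ 0.40
  expect_equal(0.63^2, 0.40, tolerance = 0.01)
  expect_equal(0.92^2, 0.84, tolerance = 0.01)
})

test_that("compare_predictors fits all four summaries on one subject set", {
  recs <- simulate_records_fast(sim_config(n_subjects = 40, seed = 2))
  fits <- compare_predictors(recs)
  expect_equal(fits$predictor_name,
               c("lab_a1c", "poc_a1c", "pa1c", "poc_vs_lab"))
  expect_true(all(fits$n == 40))
  expect_true(all(fits$r_squared >= 0 & fits$r_squared <= 1))
  expect_equal(fits$r_squared, fits$pearson_r^2, tolerance = 1e-9)
  expect_error(compare_predictors(recs[1:2, ]), "at least 3")
  expect_error(compare_predictors(recs[, -which(names(recs) == "pa1c")]),
               "missing field")
})

test_that("with no AGR heterogeneity and no noise, pA1c equals measured A1c", {
  cfg <- sim_config(n_subjects = 25, seed = 4, agr_sd = 0,
                    a1c_assay_cv_lab = 0, a1c_assay_cv_poc = 0)
  recs <- simulate_records_fast(cfg)
  expect_equal(recs$pa1c, recs$visit3_a1c_lab, tolerance = 1e-9)
  fits <- compare_predictors(recs)
  expect_equal(fits$r_squared[fits$predictor_name == "pa1c"],
               fits$r_squared[fits$predictor_name == "lab_a1c"],
               tolerance = 1e-9)
})

test_that("pA1c out-fits measured A1c under AGR heterogeneity", {
  wins <- 0L
  n_reps <- 50L
  for (rep in seq_len(n_reps)) {
    recs <- simulate_records_fast(sim_config(n_subjects = 64,
                                             seed = 5000 + rep))
    fits <- compare_predictors(recs)
    d <- fits$r_squared[fits$predictor_name == "pa1c"] -
      fits$r_squared[fits$predictor_name == "lab_a1c"]
    if (d > 0) wins <- wins + 1L
  }
  expect_gte(wins / n_reps, 0.95)
})

test_that("spearman_cor is rank-based with the documented conventions", {
  expect_equal(spearman_cor(1:10, (1:10)^3), 1)
  expect_equal(spearman_cor(1:10, -(1:10)^3), -1)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 1, 2)), -0.5)
  # agrees with the reference implementation, including ties
  set.seed(8)
  for (i in 1:10) {
    x <- sample(1:5, 30, replace = TRUE)
    y <- x + sample(1:5, 30, replace = TRUE)
    expect_equal(spearman_cor(x, y),
                 cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  expect_warning(z <- spearman_cor(1:5, rep(2, 5)), "degenerate")
  expect_equal(z, 0)
  expect_error(spearman_cor(1:3, 1:4), "lengths differ")
})

test_that("welch_t matches the hand Welch/Satterthwaite formulas", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  # hand: means 2 and 3, both variances 1, se = sqrt(2/3), df = 4
  res <- welch_t(a, b)
  expect_equal(res$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-1 / sqrt(2 / 3), 4), tolerance = 1e-12)
  ident <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  # a real shift is detected at large n
  set.seed(3)
  shift <- welch_t(rnorm(500), rnorm(500) + 1)
  expect_lt(shift$p, 1e-6)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("stepwise AIC recovers a planted signal and ignores pure noise", {
  set.seed(77)
  n <- 500
  tab <- data.frame(primary = rnorm(n),
                    signal = rnorm(n),
                    noise1 = rnorm(n),
                    noise2 = rnorm(n),
                    cat_noise = sample(c("a", "b", "c"), n,
                                       replace = TRUE))
  y <- 2 * tab$primary + 1.5 * tab$signal + rnorm(n)
  sel <- stepwise_aic(y, tab, c("signal", "noise1", "noise2",
                                "cat_noise"))
  expect_true("signal" %in% sel$selected)
  # under the null, no candidate should usually survive
  y0 <- 3 * tab$primary + rnorm(n)
  sel0 <- stepwise_aic(y0, tab, c("noise1", "noise2", "cat_noise"))
  expect_lte(length(sel0$selected), 1)
  expect_true(attr(terms(sel0$fit), "term.labels")[1] == "primary")
})

test_that("stepwise AIC errors on aliased candidate columns", {
  set.seed(10)
  tab <- data.frame(primary = rnorm(50), c1 = rnorm(50))
  tab$c2 <- tab$c1
  expect_error(stepwise_aic(rnorm(50), tab, c("c1", "c2")),
               "aliased")
})

test_that("Fisher-z power matches its closed form and the null limit", {
  # Phi(sqrt(57) * atanh(0.52) - 1.959964) ~ 0.9916
  expect_equal(correlation_power(0.52, 60), 0.9916057, tolerance = 1e-6)
  # rho -> 0 gives power -> alpha
  expect_equal(correlation_power(1e-9, 60), 0.025, tolerance = 1e-3)
  # monotone in n
  powers <- vapply(c(10, 20, 40, 80, 160), function(n) {
    correlation_power(0.52, n)
  }, numeric(1))
  expect_true(all(diff(powers) > 0))
  expect_error(correlation_power(1.2, 60), "rho")
  expect_error(correlation_power(0.5, 3), "at least 4")
})

test_that("Monte-Carlo power agrees with Fisher z within simulation error", {
  p_mc <- correlation_power(0.52, 60, method = "monte_carlo",
                            n_sims = 2000, seed = 42)
  p_z <- correlation_power(0.52, 60)
  se <- sqrt(p_z * (1 - p_z) / 2000)
  expect_lt(abs(p_mc - p_z), 3 * se + 1e-12)
})
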