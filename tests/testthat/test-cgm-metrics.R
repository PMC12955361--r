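# CGM ingestion, wear QC, and consensus glycemic metrics.

test_that("glycemic bands match the hand count on a 5-reading trace", {
  m <- compute_metrics(c(50, 60, 100, 200, 300))
  expect_equal(m$pct_below_54, 20)
  expect_equal(m$pct_below_70, 40)
  expect_equal(m$pct_in_70_180, 20)
  expect_equal(m$pct_above_180, 40)
  expect_equal(m$pct_above_250, 20)
  expect_equal(m$n_readings, 5)
})

test_that("mean, population SD and CV follow the pinned conventions", {
  m <- compute_metrics(c(100, 300))
  expect_equal(m$mean_glucose, 200)
  expect_equal(m$sd_glucose, 100)  # divisor n, not n-1
  expect_equal(m$cv, 50)
  m2 <- compute_metrics(rep(100, 96))
  expect_equal(m2$mean_glucose, 100)
  expect_equal(m2$cv, 0)
  expect_equal(m2$pct_in_70_180, 100)
  expect_error(compute_metrics(numeric(0)), "at least one")
})

test_that("band boundaries: 70 and 180 are in range, below/above strict", {
  m <- compute_metrics(c(54, 70, 180, 250))
  expect_equal(m$pct_below_54, 0)    # 54 is not < 54
  expect_equal(m$pct_below_70, 25)   # only the 54
  expect_equal(m$pct_in_70_180, 50)  # 70 and 180 inclusive
  expect_equal(m$pct_above_180, 25)  # only the 250
  expect_equal(m$pct_above_250, 0)   # 250 is not > 250
})

test_that("band partition and nesting invariants hold on random traces", {
  set.seed(99)
  for (i in 1:20) {
    g <- runif(200, 40, 500)
    m <- compute_metrics(g)
    expect_equal(m$pct_below_70 + m$pct_in_70_180 + m$pct_above_180, 100,
                 tolerance = 1e-9)
    expect_lte(m$pct_below_54, m$pct_below_70)
    expect_lte(m$pct_above_250, m$pct_above_180)
    expect_equal(m$cv, 100 * m$sd_glucose / m$mean_glucose,
                 tolerance = 1e-12)
    # permutation invariance
    expect_equal(compute_metrics(sample(g))[, 1:8], m[, 1:8])
  }
})

test_that("reading traces clamps out-of-range glucose and validates schema", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "readings.csv")
  df <- data.frame(
    subject_id = "S1", sensor_index = 1,
    timestamp = format(as.POSIXct("2024-01-01", tz = "UTC") +
                         (0:3) * 900, "%Y-%m-%dT%H:%M:%SZ"),
    glucose_mgdl = c(520, 100, 35, 200))
  write.csv(df, path, row.names = FALSE)
  expect_message(traces <- read_readings(path), "2 reading\\(s\\) clamped")
  expect_equal(traces[[1]]$glucose_mgdl, c(500, 100, 40, 200))
  expect_equal(traces[[1]]$n_clamped, 2L)

  write.csv(df[, -4], path, row.names = FALSE)
  expect_error(read_readings(path), "glucose_mgdl")

  df_dup <- rbind(df, df[1, ])
  write.csv(df_dup, path, row.names = FALSE)
  expect_error(read_readings(path), "duplicate")

  df_bad <- df
  df_bad$timestamp[2] <- "not-a-time"
  write.csv(df_bad, path, row.names = FALSE)
  expect_error(read_readings(path), "timestamp")
})

test_that("well-formed multi-subject file yields sorted per-wear traces", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "readings.csv")
  rows <- expand.grid(subject_id = c("A", "B"), sensor_index = 1:3)
  df <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    ts <- as.POSIXct("2024-01-01", tz = "UTC") + (0:9) * 900
    data.frame(subject_id = rows$subject_id[i],
               sensor_index = rows$sensor_index[i],
               timestamp = format(rev(ts), "%Y-%m-%dT%H:%M:%SZ"),
               glucose_mgdl = 100 + (0:9))
  }))
  write.csv(df, path, row.names = FALSE)
  traces <- read_readings(path)
  expect_length(traces, 6)
  for (tr in traces) {
    expect_false(is.unsorted(tr$timestamp, strictly = TRUE))
  }
})

test_that("wear-protocol QC applies the 10-day and 48-hour rules", {
  ok <- qc_wearset(make_wearset_traces(days = c(12, 12, 12),
                                       gap_hours = c(24, 24)))
  expect_true(ok$protocol_valid)
  expect_equal(ok$qc$days_covered, c(12, 12, 12))
  expect_equal(ok$gaps_between_wears, c(24, 24), tolerance = 1e-9)

  short <- qc_wearset(make_wearset_traces(days = c(9.5, 12, 12),
                                          gap_hours = c(24, 24)))
  expect_false(short$protocol_valid)
  expect_equal(short$qc$valid, c(FALSE, TRUE, TRUE))

  # boundary: exactly 10 days passes, a 49 h gap fails, 48 h passes
  boundary <- qc_wearset(make_wearset_traces(days = c(10, 12, 12),
                                             gap_hours = c(48, 24)))
  expect_true(boundary$protocol_valid)
  gap49 <- qc_wearset(make_wearset_traces(days = c(12, 12, 12),
                                          gap_hours = c(49, 24)))
  expect_false(gap49$protocol_valid)

  two <- qc_wearset(make_wearset_traces(days = c(12, 12),
                                        gap_hours = 24))
  expect_false(two$protocol_valid)

  mixed <- c(make_wearset_traces("S1", days = c(12, 12), gap_hours = 24),
             make_wearset_traces("S2", days = 12, gap_hours = numeric(0)))
  expect_error(qc_wearset(mixed), "mixed subjects")
})

test_that("pooled metrics equal metrics of the concatenated readings", {
  traces <- make_wearset_traces(days = c(11, 12, 13))
  # give the wears distinct glucose so pooling is informative
  set.seed(5)
  for (w in 1:3) {
    traces[[w]]$glucose_mgdl <- runif(length(traces[[w]]$glucose_mgdl),
                                      60, 400)
  }
  ws <- qc_wearset(traces)
  pooled <- pool_metrics(ws, c(1, 2, 3))
  oracle <- compute_metrics(unlist(lapply(traces,
                                          function(t) t$glucose_mgdl)))
  expect_equal(pooled[, 1:9], oracle[, 1:9])
  # idempotence: pooling one wear equals that wear's metrics
  expect_equal(pool_metrics(ws, 1)[, 1:9],
               compute_metrics(traces[[1]])[, 1:9])
})

test_that("pooling is reading-weighted, not a mean of wear means", {
  t1 <- make_trace("S1", 1, rep(100, 961))   # 10 days + 1 reading
  t2 <- make_trace("S1", 2, rep(200, 2881),  # 30 days worth of readings
                   start = t1$timestamp[961] + 3600)
  # relax per-wear day rule; this test is about the weighting
  ws <- qc_wearset(list(t1, t2), min_days = 5)
  pooled <- pool_metrics(ws, c(1, 2))
  expect_equal(pooled$mean_glucose, (961 * 100 + 2881 * 200) / 3842)
  expect_error(pool_metrics(ws, 3), "missing")
})

test_that("metrics_table emits per-wear and pooled scopes for valid sets", {
  ws <- qc_wearset(make_wearset_traces(days = c(12, 12, 12)))
  tab <- metrics_table(list(ws))
  expect_setequal(tab$scope, c("wear1", "wear2", "wear3", "wears12",
                               "all"))
  # calibration scope uses wears 1-2 only
  cal <- tab[tab$scope == "wears12", ]
  expect_equal(cal$n_readings,
               sum(tab$n_readings[tab$scope %in% c("wear1", "wear2")]))
})
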