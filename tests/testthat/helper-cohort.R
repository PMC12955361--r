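# Shared fixtures for the test suite. Everything is generated in code.

# Small, fast cohort config for end-to-end tests.
tiny_config <- function(n = 4, seed = 7, ...) {
  sim_config(n_subjects = n, seed = seed, ...)
}

# Build a glucose trace with evenly spaced readings.
make_trace <- function(subject_id = "S1", sensor_index = 1,
                       glucose = rep(150, 96 * 12),
                       start = as.POSIXct("2024-01-01 00:00:00",
                                          tz = "UTC"),
                       cadence_min = 15) {
  n <- length(glucose)
  ts <- start + (seq_len(n) - 1) * cadence_min * 60
  glucose_trace(subject_id, sensor_index, ts, glucose)
}

# Three consecutive wears for one subject: days per wear and gap hours
# are configurable so QC boundaries can be probed.
make_wearset_traces <- function(subject_id = "S1",
                                days = c(12, 12, 12),
                                gap_hours = c(24, 24),
                                glucose_level = 150) {
  start <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
  traces <- list()
  for (w in seq_along(days)) {
    n <- days[w] * 96 + 1
    traces[[w]] <- make_trace(subject_id, w, rep(glucose_level, n),
                              start = start)
    end <- traces[[w]]$timestamp[n]
    if (w < length(days)) start <- end + gap_hours[w] * 3600
  }
  traces
}

# Cohort simulated at the subject level: mean glucose held at its target
# (the steady-state limit of the trace generator, which rescales each
# trace to its target moments), with assay noise applied through
# simulate_a1c and AGR/pA1c computed by the package functions. Used for
# replicate studies where trace-level detail is irrelevant.
simulate_records_fast <- function(config) {
  profiles <- draw_profiles(config)
  n <- nrow(profiles)
  a1c2 <- numeric(n)
  a1c3_lab <- numeric(n)
  a1c3_poc <- numeric(n)
  for (i in seq_len(n)) {
    prof <- profiles[i, ]
    a1c2[i] <- simulate_a1c(prof, prof$target_mg, config, "lab",
                            seed = config$seed * 7 + i)
    a1c3_lab[i] <- simulate_a1c(prof, prof$target_mg, config, "lab",
                                seed = config$seed * 13 + 1000 + i)
    a1c3_poc[i] <- simulate_a1c(prof, prof$target_mg, config, "poc",
                                seed = config$seed * 17 + 2000 + i)
  }
  agr <- compute_agr(profiles$target_mg, a1c2)
  data.frame(subject_id = profiles$subject_id,
             calibration_mg = profiles$target_mg,
             calibration_a1c = a1c2,
             agr = agr,
             visit3_a1c_lab = a1c3_lab,
             visit3_a1c_poc = a1c3_poc,
             pa1c = compute_pa1c(a1c3_lab, agr),
             evaluation_mg = profiles$target_mg,
             true_agr = profiles$true_agr)
}
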