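# CGM ingestion, wear-protocol QC, and consensus glycemic metrics.
#
# Protocol: three consecutive blinded sensor wears of 10-14 days each, with
# no more than 48 h between wears; a subject's protocol is valid when all
# three wears cover >= 10 days and every inter-wear gap is <= 48 h.
# Sensor-reportable glucose range is 40-500 mg/dL; out-of-range values are
# clamped on ingestion (metrics are computed on what the device would
# report).

SENSOR_MIN_MGDL <- 40
SENSOR_MAX_MGDL <- 500

#' Construct a glucose trace for one sensor wear
#'
#' @param subject_id Subject identifier (scalar character).
#' @param sensor_index Wear number, 1-3.
#' @param timestamp `POSIXct` vector (UTC), strictly increasing.
#' @param glucose_mgdl Numeric glucose readings, mg/dL.
#' @param clamp Clamp readings into the sensor-reportable range 40-500
#'   mg/dL (default `TRUE`); the number clamped is kept in the
#'   `n_clamped` attribute-like list field.
#' @return An object of class `glucose_trace`.
#' @export
glucose_trace <- function(subject_id, sensor_index, timestamp, glucose_mgdl,
                          clamp = TRUE) {
  stopifnot(length(subject_id) == 1L, length(sensor_index) == 1L,
            length(timestamp) == length(glucose_mgdl))
  sensor_index <- as.integer(sensor_index)
  if (is.na(sensor_index) || sensor_index < 1L || sensor_index > 3L) {
    stop("sensor_index must be 1, 2 or 3", call. = FALSE)
  }
  if (!inherits(timestamp, "POSIXct")) {
    stop("timestamp must be POSIXct", call. = FALSE)
  }
  if (length(timestamp) == 0L) {
    stop("a glucose trace needs at least one reading", call. = FALSE)
  }
  if (is.unsorted(timestamp, strictly = TRUE)) {
    stop("timestamps must be strictly increasing within a wear",
         call. = FALSE)
  }
  n_clamped <- 0L
  if (clamp) {
    out_of_range <- glucose_mgdl < SENSOR_MIN_MGDL |
      glucose_mgdl > SENSOR_MAX_MGDL
    n_clamped <- sum(out_of_range)
    glucose_mgdl <- pmin(pmax(glucose_mgdl, SENSOR_MIN_MGDL),
                         SENSOR_MAX_MGDL)
  }
  structure(
    list(subject_id = as.character(subject_id),
         sensor_index = sensor_index,
         timestamp = timestamp,
         glucose_mgdl = as.numeric(glucose_mgdl),
         n_clamped = as.integer(n_clamped)),
    class = "glucose_trace"
  )
}

#' @export
print.glucose_trace <- function(x, ...) {
  cat(sprintf("<glucose_trace> subject %s, wear %d: %d readings over %.1f days (%d clamped)\n",
              x$subject_id, x$sensor_index, length(x$glucose_mgdl),
              trace_days(x), x$n_clamped))
  invisible(x)
}

#' Timestamp span of a trace in days
#' @param trace A `glucose_trace`.
#' @return Days covered (span of first to last timestamp).
#' @export
trace_days <- function(trace) {
  as.numeric(difftime(trace$timestamp[length(trace$timestamp)],
                      trace$timestamp[1], units = "days"))
}

#' Read CGM readings from CSV into glucose traces
#'
#' Expects columns `subject_id`, `sensor_index`, `timestamp` (ISO-8601
#' UTC), `glucose_mgdl`. Rows are grouped by (subject, sensor), sorted by
#' timestamp, and out-of-range glucose is clamped to 40-500 mg/dL with a
#' count reported via message.
#'
#' @param path Path to a readings CSV.
#' @return Named list of `glucose_trace` objects (names
#'   `subject_id.sensor_index`), ordered by subject then wear.
#' @export
read_readings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_traces(df)
}

#' Convert a readings data.frame to glucose traces
#'
#' Same contract as [read_readings()] but starting from an in-memory
#' data.frame (e.g. straight out of [simulate_cohort()]).
#'
#' @param df data.frame with columns `subject_id`, `sensor_index`,
#'   `timestamp`, `glucose_mgdl`.
#' @return Named list of `glucose_trace` objects.
#' @export
as_traces <- function(df) {
  need <- c("subject_id", "sensor_index", "timestamp", "glucose_mgdl")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("readings file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ts <- if (inherits(df$timestamp, "POSIXct")) {
    df$timestamp
  } else {
    # try each format on the whole column; NA marks unparseable rows
    parsed <- lapply(c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                       "%Y-%m-%d %H:%M:%OS"),
                     function(fmt) {
                       as.POSIXct(strptime(df$timestamp, fmt, tz = "UTC"))
                     })
    parsed[[which.max(vapply(parsed, function(p) sum(!is.na(p)),
                             integer(1)))]]
  }
  if (any(is.na(ts))) {
    bad <- which(is.na(ts))[1]
    stop("unparseable timestamp at row ", bad, ": ", df$timestamp[bad],
         call. = FALSE)
  }
  df$timestamp <- ts
  key <- paste(df$subject_id, df$sensor_index, format(ts, "%Y-%m-%dT%H:%M:%S"))
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop("duplicate (subject, sensor, timestamp) row ", bad, ": ",
         key[bad], call. = FALSE)
  }
  df <- df[order(df$subject_id, df$sensor_index, df$timestamp), ]
  groups <- split(df, list(df$subject_id, df$sensor_index), drop = TRUE)
  traces <- lapply(groups, function(g) {
    glucose_trace(g$subject_id[1], g$sensor_index[1], g$timestamp,
                  g$glucose_mgdl)
  })
  ord <- order(vapply(traces, function(t) t$subject_id, character(1)),
               vapply(traces, function(t) t$sensor_index, integer(1)))
  traces <- traces[ord]
  total_clamped <- sum(vapply(traces, function(t) t$n_clamped, integer(1)))
  if (total_clamped > 0) {
    message(total_clamped, " reading(s) clamped to [", SENSOR_MIN_MGDL,
            ", ", SENSOR_MAX_MGDL, "] mg/dL")
  }
  names(traces) <- vapply(traces, function(t) {
    paste0(t$subject_id, ".", t$sensor_index)
  }, character(1))
  traces
}

#' QC a subject's wear protocol
#'
#' Builds a `wearset` from 1-3 traces of a single subject: per-wear days
#' covered (timestamp span) and validity (>= `min_days`), gaps between
#' consecutive wears (end of wear k to start of wear k+1), and overall
#' protocol validity: all three wears present and valid, every gap <=
#' `max_gap_hours`.
#'
#' @param traces List of `glucose_trace` objects for one subject.
#' @param min_days Minimum days of sensor data per wear (default 10).
#' @param max_gap_hours Maximum hours allowed between wears (default 48).
#' @return An object of class `wearset` with fields `subject_id`, `wears`,
#'   `qc` (data.frame: sensor_index, days_covered, valid),
#'   `gaps_between_wears` (hours), `protocol_valid`.
#' @export
qc_wearset <- function(traces, min_days = 10, max_gap_hours = 48) {
  if (inherits(traces, "glucose_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L, length(traces) <= 3L)
  ids <- unique(vapply(traces, function(t) t$subject_id, character(1)))
  if (length(ids) != 1L) {
    stop("traces from mixed subjects: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  idx <- vapply(traces, function(t) t$sensor_index, integer(1))
  traces <- traces[order(idx)]
  idx <- sort(idx)
  if (anyDuplicated(idx)) {
    stop("duplicate sensor_index within subject ", ids, call. = FALSE)
  }
  days <- vapply(traces, trace_days, numeric(1))
  valid <- days >= min_days
  gaps <- numeric(0)
  if (length(traces) > 1L) {
    gaps <- vapply(seq_len(length(traces) - 1L), function(k) {
      end_k <- traces[[k]]$timestamp[length(traces[[k]]$timestamp)]
      start_k1 <- traces[[k + 1L]]$timestamp[1]
      as.numeric(difftime(start_k1, end_k, units = "hours"))
    }, numeric(1))
  }
  protocol_valid <- length(traces) == 3L && all(valid) &&
    all(gaps <= max_gap_hours)
  structure(
    list(subject_id = ids,
         wears = traces,
         qc = data.frame(sensor_index = idx, days_covered = days,
                         valid = valid),
         gaps_between_wears = gaps,
         protocol_valid = protocol_valid),
    class = "wearset"
  )
}

#' @export
print.wearset <- function(x, ...) {
  cat(sprintf("<wearset> subject %s: %d wear(s), protocol %s\n",
              x$subject_id, length(x$wears),
              if (x$protocol_valid) "VALID" else "INVALID"))
  print(x$qc, row.names = FALSE)
  if (length(x$gaps_between_wears)) {
    cat("gaps (h):", paste(round(x$gaps_between_wears, 1), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Consensus glycemic metrics from glucose readings
#'
#' Equal weight per reading. Bands follow the international consensus:
#' time below 54 (`< 54`), below 70 (`< 70`), in range (`70 <= g <= 180`),
#' above 180 (`> 180`), above 250 (`> 250`) mg/dL. Boundary convention: 70
#' and 180 count as in range; the below/above bands are strict. SD is the
#' population SD (divisor n), and CV = 100 * SD / mean.
#'
#' @param glucose_mgdl Numeric vector of readings (>= 1), or a
#'   `glucose_trace`.
#' @param days Optional days covered, carried into the result (taken from
#'   the trace when one is supplied).
#' @return A one-row data.frame of class `glycemic_metrics`: mean_glucose,
#'   sd_glucose, cv, pct_below_54, pct_below_70, pct_in_70_180,
#'   pct_above_180, pct_above_250, n_readings, days.
#' @examples
#' compute_metrics(c(50, 60, 100, 200, 300))
#' @export
compute_metrics <- function(glucose_mgdl, days = NA_real_) {
  if (inherits(glucose_mgdl, "glucose_trace")) {
    days <- trace_days(glucose_mgdl)
    glucose_mgdl <- glucose_mgdl$glucose_mgdl
  }
  g <- as.numeric(glucose_mgdl)
  n <- length(g)
  if (n < 1L) stop("at least one glucose reading required", call. = FALSE)
  if (any(!is.finite(g))) stop("non-finite glucose reading", call. = FALSE)
  m <- mean(g)
  sd_pop <- sqrt(sum((g - m)^2) / n)
  pct <- function(mask) 100 * sum(mask) / n
  out <- data.frame(
    mean_glucose = m,
    sd_glucose = sd_pop,
    cv = 100 * sd_pop / m,
    pct_below_54 = pct(g < 54),
    pct_below_70 = pct(g < 70),
    pct_in_70_180 = pct(g >= 70 & g <= 180),
    pct_above_180 = pct(g > 180),
    pct_above_250 = pct(g > 250),
    n_readings = n,
    days = days
  )
  class(out) <- c("glycemic_metrics", class(out))
  out
}

#' Pool metrics across selected wears of a wearset
#'
#' Reading-weighted pooling: metrics are computed over the concatenated
#' readings of the selected wears (equivalent to time-weighting at a fixed
#' cadence), with `days` the sum of per-wear spans.
#'
#' @param wearset A `wearset`.
#' @param wears_used Integer subset of `c(1, 2, 3)` to pool (default all
#'   wears present).
#' @param require_valid Error if a requested wear failed its per-wear QC
#'   (default `TRUE`).
#' @return A `glycemic_metrics` row.
#' @export
pool_metrics <- function(wearset, wears_used = NULL, require_valid = TRUE) {
  stopifnot(inherits(wearset, "wearset"))
  present <- wearset$qc$sensor_index
  if (is.null(wears_used)) wears_used <- present
  wears_used <- sort(unique(as.integer(wears_used)))
  if (!all(wears_used %in% present)) {
    stop("requested wear(s) missing for subject ", wearset$subject_id, ": ",
         paste(setdiff(wears_used, present), collapse = ", "),
         call. = FALSE)
  }
  sel <- match(wears_used, present)
  if (require_valid && !all(wearset$qc$valid[sel])) {
    stop("requested wear(s) failed QC for subject ", wearset$subject_id,
         call. = FALSE)
  }
  g <- unlist(lapply(wearset$wears[sel], function(t) t$glucose_mgdl),
              use.names = FALSE)
  days <- sum(wearset$qc$days_covered[sel])
  compute_metrics(g, days = days)
}

#' Per-wear and pooled metrics table for a set of subjects
#'
#' Convenience wrapper producing the long metrics table: one row per
#' subject per scope, where scope is each wear (`wear1`..`wear3`), the
#' calibration window (`wears12`) and the full protocol (`all`). Pooled
#' scopes are only emitted when the wears they need are present and valid.
#'
#' @param wearsets List of `wearset` objects.
#' @return data.frame with columns `subject_id`, `scope` and the
#'   `glycemic_metrics` fields.
#' @export
metrics_table <- function(wearsets) {
  rows <- lapply(wearsets, function(ws) {
    out <- list()
    for (i in seq_along(ws$wears)) {
      m <- compute_metrics(ws$wears[[i]])
      out[[length(out) + 1L]] <- cbind(
        data.frame(subject_id = ws$subject_id,
                   scope = paste0("wear", ws$qc$sensor_index[i])), m)
    }
    pooled_scopes <- list(wears12 = c(1L, 2L), all = c(1L, 2L, 3L))
    for (nm in names(pooled_scopes)) {
      w <- pooled_scopes[[nm]]
      sel <- match(w, ws$qc$sensor_index)
      if (all(!is.na(sel)) && all(ws$qc$valid[sel])) {
        m <- pool_metrics(ws, w)
        out[[length(out) + 1L]] <- cbind(
          data.frame(subject_id = ws$subject_id, scope = nm), m)
      }
    }
    do.call(rbind, out)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- "data.frame"
  res
}
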