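# On-disk formats (all plain delimited text) and millisecond-to-sample
# alignment. Traces mimic a data-logger CSV export with a small comment
# header declaring the sampling rate, start time and unit.

#' Construct an accelerometer trace object
#'
#' @param ax,ay,az equal-length numeric axis signals in G units.
#' @param rate_hz sampling rate in Hz (default 800).
#' @param start_ms trace start on the session clock, in ms.
#' @param clipped logical: whether any sample hit the sensor range.
#' @return An object of class `"accel_trace"`.
#' @export
accel_trace <- function(ax, ay, az, rate_hz = 800, start_ms = 0,
                        clipped = FALSE) {
  if (length(ax) != length(ay) || length(ay) != length(az)) {
    err_input("axis arrays must have equal length")
  }
  if (!all(is.finite(ax)) || !all(is.finite(ay)) || !all(is.finite(az))) {
    err_input("axis arrays must be finite")
  }
  if (!is.numeric(rate_hz) || rate_hz <= 0) err_input("rate_hz must be > 0")
  structure(list(ax = ax, ay = ay, az = az, rate_hz = rate_hz,
                 start_ms = start_ms, unit = "G", clipped = clipped),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("accel_trace: %d samples @ %g Hz (%.2f s), unit %s%s\n",
              length(x$ax), x$rate_hz, length(x$ax) / x$rate_hz, x$unit,
              if (isTRUE(x$clipped)) " [clipped]" else ""))
  invisible(x)
}

#' Write / read an accelerometer trace file
#'
#' Delimited text with `# key: value` header lines (`rate_hz`, `start_ms`,
#' `unit`) followed by a `time_s,ax,ay,az` table. The unit must read `G`;
#' malformed rows are rejected with their line numbers.
#'
#' @param trace an [accel_trace] object.
#' @param path file path.
#' @return `read_trace` returns an [accel_trace].
#' @export
write_trace <- function(trace, path) {
  n <- length(trace$ax)
  t <- (seq_len(n) - 1) / trace$rate_hz
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# perchjump accel trace v1",
               sprintf("# rate_hz: %g", trace$rate_hz),
               sprintf("# start_ms: %g", trace$start_ms),
               "# unit: G",
               "time_s,ax,ay,az",
               sprintf("%.6f,%.5f,%.5f,%.5f", t, trace$ax, trace$ay, trace$az)),
             con)
  invisible(path)
}

parse_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)\\s*$", hdr))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[m[2]]] <- m[3]
  out
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) err_format(paste("no such file:", path))
  lines <- readLines(path)
  hdr <- parse_header(lines)
  if (is.null(hdr$rate_hz)) err_format("trace header missing rate_hz")
  if (is.null(hdr$unit)) err_format("trace header missing unit")
  if (hdr$unit != "G") {
    err_format(sprintf("trace unit must be G, got '%s'", hdr$unit))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (!length(body) || body[1] != "time_s,ax,ay,az") {
    err_format("trace file must have columns time_s,ax,ay,az")
  }
  rows <- body[-1]
  if (!length(rows)) err_format("trace file has no samples")
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(parts[lengths(parts) == 4L])), ncol = 4,
           byrow = TRUE))
  if (length(bad) || anyNA(mat)) {
    badnum <- sort(unique(c(bad, which(rowSums(is.na(mat)) > 0))))
    line_no <- which(!grepl("^#", lines))[-1][badnum] # file line numbers
    err_format(paste("malformed trace rows at lines:",
                     paste(utils::head(line_no, 10), collapse = ", ")))
  }
  if (any(diff(mat[, 1]) <= 0)) err_format("trace time column not increasing")
  accel_trace(mat[, 2], mat[, 3], mat[, 4],
              rate_hz = as.numeric(hdr$rate_hz),
              start_ms = as.numeric(hdr$start_ms %||% "0"))
}

# Nearest-sample index (1-based) for a time in seconds relative to the
# trace start; ties round toward the earlier sample. At 800 Hz the 1.25 ms
# sample period (vs 1 ms annotation resolution) dominates quantization.
time_to_sample <- function(t_s, rate_hz) {
  # small epsilon so floating-point jitter cannot flip a tie to the later
  # sample
  as.integer(ceiling(t_s * rate_hz + 0.5 - 1e-9))
}

#' Map an annotated phase to a half-open sample window
#'
#' Subtracts the session clock offset from the phase boundary timestamps,
#' maps each to the nearest sample (ties toward the earlier sample) and
#' returns the half-open 1-based index interval `[i_start, i_end)`, so each
#' sample belongs to exactly one phase even when a boundary hits a sample
#' exactly.
#'
#' @param annotation list or one-row data.frame with the millisecond event
#'   fields (`signal_ms`, `takeoff_start_ms`, `takeoff_end_ms`,
#'   `landing_start_ms`, `landing_end_ms`, `first_peck_ms`) and
#'   `clock_offset_ms`.
#' @param phase one of "standing" (Signal to Take-off start), "takeoff",
#'   "flight", "landing".
#' @param trace the [accel_trace] the events refer to.
#' @return Integer vector `c(i_start, i_end)`, half-open.
#' @export
window_to_samples <- function(annotation, phase, trace) {
  an <- as.list(annotation)
  bounds <- switch(match_enum(phase, c("standing", "takeoff", "flight",
                                       "landing"), "phase"),
    standing = c(an$signal_ms, an$takeoff_start_ms),
    takeoff = c(an$takeoff_start_ms, an$takeoff_end_ms),
    flight = c(an$takeoff_end_ms, an$landing_start_ms),
    landing = c(an$landing_start_ms, an$landing_end_ms))
  if (anyNA(unlist(bounds)) || is.null(bounds[[1]]) || is.null(bounds[[2]])) {
    err_input(sprintf("annotation lacks boundaries for phase '%s'", phase))
  }
  off <- an$clock_offset_ms %||% 0
  t0 <- (bounds[[1]] - off - trace$start_ms) / 1000
  t1 <- (bounds[[2]] - off - trace$start_ms) / 1000
  i0 <- time_to_sample(t0, trace$rate_hz)
  i1 <- time_to_sample(t1, trace$rate_hz)
  n <- length(trace$ax)
  if (i0 < 1 || i1 > n + 1) {
    err_alignment(sprintf(
      "phase '%s' window [%d, %d) outside trace of %d samples", phase, i0, i1, n))
  }
  if (i0 >= i1) {
    err_alignment(sprintf("phase '%s' maps to an empty sample window", phase))
  }
  c(i0, i1)
}

#' Write / read event-annotation tables
#'
#' One row per jump of a session: the six video event timestamps in ms
#' (First peck may be missing/censored), the balancing indicator and the
#' video-to-logger clock offset.
#'
#' @param events data.frame of annotations.
#' @param path file path.
#' @return `read_events` returns the annotation data.frame.
#' @export
write_events <- function(events, path) {
  write.csv(events, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) err_format(paste("no such file:", path))
  ev <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("jump", "signal_ms", "takeoff_start_ms", "takeoff_end_ms",
           "landing_start_ms", "landing_end_ms", "first_peck_ms",
           "balancing", "clock_offset_ms")
  if (!all(req %in% names(ev))) {
    err_format(paste("event file missing columns:",
                     paste(setdiff(req, names(ev)), collapse = ", ")))
  }
  ts <- as.matrix(ev[, c("signal_ms", "takeoff_start_ms", "takeoff_end_ms",
                         "landing_start_ms", "landing_end_ms")])
  if (any(t(apply(ts, 1, diff)) < 0)) {
    err_format("event timestamps must be nondecreasing in phase order")
  }
  ev
}

#' Write / read a hen roster table
#'
#' @param roster data.frame with hen_id, pen, hybrid and pre/post body mass.
#' @param path file path.
#' @return `read_roster` returns the roster data.frame.
#' @export
write_roster <- function(roster, path) {
  write.csv(as.data.frame(roster), path, row.names = FALSE, quote = FALSE,
            na = "NA")
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) err_format(paste("no such file:", path))
  r <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("hen_id", "pen", "hybrid", "body_mass_pre_kg", "body_mass_post_kg")
  if (!all(req %in% names(r))) {
    err_format(paste("roster file missing columns:",
                     paste(setdiff(req, names(r)), collapse = ", ")))
  }
  if (any(stats::na.omit(c(r$body_mass_pre_kg, r$body_mass_post_kg)) <= 0)) {
    err_format("roster body masses must be positive")
  }
  r
}

METRICS_SCHEMA_VERSION <- 1L

metrics_columns <- function() {
  c("session_id", "hen_id", "pen", "hybrid", "direction", "angle_class",
    "distance_cm", "day", "jump", "acclimation",
    "lat_jump", "dur_takeoff", "dur_flight", "dur_landing", "lat_peck",
    "pf_takeoff", "pf_flight", "pf_landing",
    "imp_takeoff", "imp_flight", "imp_landing",
    "balancing", "mass_kg", "units_mode")
}

#' Write / read the phase-metrics table
#'
#' Lossless round-trip of the per-jump phase metrics (the inference input).
#' The file carries a schema-version header; a mismatching schema is
#' rejected. Missing latencies (censored First peck) survive as `NA`.
#'
#' @param records data.frame of phase metrics (may be empty).
#' @param path file path.
#' @return `read_metrics` returns the metrics data.frame.
#' @export
write_metrics <- function(records, path) {
  cols <- metrics_columns()
  missing <- setdiff(cols, names(records))
  if (nrow(as.data.frame(records)) > 0 && length(missing)) {
    err_format(paste("metrics records missing columns:",
                     paste(missing, collapse = ", ")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# perchjump metrics v%d", METRICS_SCHEMA_VERSION), con)
  if (nrow(as.data.frame(records)) == 0) {
    writeLines(paste(cols, collapse = ","), con)
  } else {
    write.csv(as.data.frame(records)[, cols], con, row.names = FALSE,
              quote = FALSE, na = "NA")
  }
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) err_format(paste("no such file:", path))
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec("^# perchjump metrics v(\\d+)$", first))[[1]]
  if (length(m) != 2 || as.integer(m[2]) != METRICS_SCHEMA_VERSION) {
    err_format("metrics file schema mismatch")
  }
  rec <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!identical(names(rec), metrics_columns())) {
    err_format("metrics file column schema mismatch")
  }
  num <- c("distance_cm", "day", "jump", "acclimation", "lat_jump",
           "dur_takeoff", "dur_flight", "dur_landing", "lat_peck",
           "pf_takeoff", "pf_flight", "pf_landing", "imp_takeoff",
           "imp_flight", "imp_landing", "balancing", "mass_kg")
  for (col in num) rec[[col]] <- as.numeric(rec[[col]])
  rec
}
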