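# Truth-first trace rendering. Pulse shapes are solved from the drawn peak
# forces and impulses (amplitudes in G, widths/time constants from the
# derived phase durations), so the generator knows exactly what a perfect
# extraction should recover.

# Noiseless acceleration-magnitude profile (G) at absolute session times t_s
# for the jumps in `truth` (data.frame rows of one session).
render_profile <- function(t_s, truth, tc) {
  base <- tc$baseline_g
  prof <- rep(base, length(t_s))
  for (k in seq_len(nrow(truth))) {
    m <- truth$mass_kg[k]
    ts <- truth$takeoff_start_ms[k] / 1000
    te <- truth$takeoff_end_ms[k] / 1000
    ls <- truth$landing_start_ms[k] / 1000
    le <- truth$landing_end_ms[k] / 1000
    A_to <- max(truth$pf_takeoff[k] / m, base + 0.02)
    A_fl <- max(truth$pf_flight[k] / m, base + 0.02)
    A_ld <- max(truth$pf_landing[k] / m, base + 0.02)
    w <- tc$takeoff_mean_frac * (pi / 2) * (te - ts)
    i <- which(t_s >= ts & t_s < ts + w)
    prof[i] <- base + (A_to - base) * sin(pi * (t_s[i] - ts) / w)
    i <- which(t_s >= te & t_s < ls)
    prof[i] <- base + (A_fl - base) * abs(sin(2 * pi * tc$flap_hz *
                                                (t_s[i] - te)))
    tau <- tc$landing_tau_frac * (le - ls)
    i <- which(t_s >= ls & t_s < le)
    prof[i] <- base + (A_ld - base) * exp(-(t_s[i] - ls) / tau)
  }
  prof
}

annotation_from_truth <- function(truth) {
  # annotation timestamps are on the video clock, i.e. the true session time
  # shifted by the declared video-to-logger clock offset
  off <- truth$clock_offset_ms
  data.frame(jump = truth$jump,
             signal_ms = truth$signal_ms + off,
             takeoff_start_ms = truth$takeoff_start_ms + off,
             takeoff_end_ms = truth$takeoff_end_ms + off,
             landing_start_ms = truth$landing_start_ms + off,
             landing_end_ms = truth$landing_end_ms + off,
             first_peck_ms = truth$first_peck_ms + off,
             balancing = truth$balancing,
             clock_offset_ms = off,
             stringsAsFactors = FALSE)
}

# Realized (sample-quantized) truth for each jump, computed from the
# noiseless profile with the same window arithmetic the extraction uses.
realized_from_profile <- function(trace0, annotations, truth) {
  out <- lapply(seq_len(nrow(truth)), function(k) {
    an <- as.list(annotations[k, ])
    met <- derive_metrics(trace0, an, truth$mass_kg[k], "paper")
    data.frame(realized_pf_takeoff = met$pf_takeoff,
               realized_pf_flight = met$pf_flight,
               realized_pf_landing = met$pf_landing,
               realized_imp_takeoff = met$imp_takeoff,
               realized_imp_landing = met$imp_landing,
               realized_lat_jump = met$lat_jump,
               realized_lat_peck = met$lat_peck)
  })
  do.call(rbind, out)
}

add_noise_and_clip <- function(profile, tc) {
  n <- length(profile)
  if (tc$noise_sd_g > 0) {
    ax <- rnorm(n, 0, tc$noise_sd_g)
    ay <- rnorm(n, 0, tc$noise_sd_g)
    az <- profile + rnorm(n, 0, tc$noise_sd_g)
  } else {
    ax <- numeric(n); ay <- numeric(n); az <- profile
  }
  clipped <- any(abs(c(ax, ay, az)) > tc$range_g)
  if (clipped) {
    warning("trace samples exceed the sensor range; clipping to +/- ",
            tc$range_g, " G")
    ax <- pmin(pmax(ax, -tc$range_g), tc$range_g)
    ay <- pmin(pmax(ay, -tc$range_g), tc$range_g)
    az <- pmin(pmax(az, -tc$range_g), tc$range_g)
  }
  list(ax = ax, ay = ay, az = az, clipped = clipped)
}

#' Render the accelerometer trace for one session or one jump
#'
#' `render_session` builds the continuous 800 Hz trace of a whole test
#' session (all jumps on one time axis starting at 0 ms); `render_trace`
#' renders a single jump on its own time axis (starting one padding period
#' before the Signal). Both return the trace, the event annotations and the
#' realized ground truth: the peak forces and impulses a perfect extraction
#' recovers from the noiseless sampled profile (these differ from the latent
#' drawn values only by sample quantization).
#'
#' @param truth rows of a `jump_truth` data.frame ([draw_outcomes()]); for
#'   `render_trace`, a single row.
#' @param config a [sim_config()].
#' @param noise add Gaussian sensor noise? (`FALSE` gives the noiseless
#'   profile as the trace).
#' @param seed optional seed for the noise draw.
#' @return list with `trace` ([accel_trace]), `annotations` (data.frame, one
#'   row per jump) and `realized` (data.frame of realized metrics).
#' @export
render_session <- function(truth, config = sim_config(), noise = TRUE,
                           seed = NULL) {
  tc <- config$trace
  end_ms <- max(truth$landing_end_ms, truth$first_peck_ms, na.rm = TRUE) +
    tc$pad_s * 1000
  n <- ceiling(end_ms / 1000 * tc$rate_hz)
  t_s <- (seq_len(n) - 1) / tc$rate_hz
  prof <- render_profile(t_s, truth, tc)
  annotations <- annotation_from_truth(truth)
  trace0 <- accel_trace(numeric(n), numeric(n), prof, rate_hz = tc$rate_hz,
                        start_ms = 0)
  realized <- realized_from_profile(trace0, annotations, truth)
  tc2 <- tc
  if (!noise) tc2$noise_sd_g <- 0
  axes <- with_seed(seed, add_noise_and_clip(prof, tc2))
  list(trace = accel_trace(axes$ax, axes$ay, axes$az, rate_hz = tc$rate_hz,
                           start_ms = 0, clipped = axes$clipped),
       annotations = annotations, realized = realized)
}

#' @rdname render_session
#' @export
render_trace <- function(truth, config = sim_config(), noise = TRUE,
                         seed = NULL) {
  if (nrow(truth) != 1L) err_input("render_trace expects a single jump row")
  tc <- config$trace
  start_ms <- truth$signal_ms - tc$pad_s * 1000
  end_ms <- max(truth$landing_end_ms, truth$first_peck_ms, na.rm = TRUE) +
    tc$pad_s * 1000
  n <- ceiling((end_ms - start_ms) / 1000 * tc$rate_hz)
  t_s <- start_ms / 1000 + (seq_len(n) - 1) / tc$rate_hz
  prof <- render_profile(t_s, truth, tc)
  annotations <- annotation_from_truth(truth)
  trace0 <- accel_trace(numeric(n), numeric(n), prof, rate_hz = tc$rate_hz,
                        start_ms = start_ms)
  realized <- realized_from_profile(trace0, annotations, truth)
  tc2 <- tc
  if (!noise) tc2$noise_sd_g <- 0
  axes <- with_seed(seed, add_noise_and_clip(prof, tc2))
  list(trace = accel_trace(axes$ax, axes$ay, axes$az, rate_hz = tc$rate_hz,
                           start_ms = start_ms, clipped = axes$clipped),
       annotations = annotations, realized = realized)
}

#' Emit a complete synthetic study to disk
#'
#' Writes the roster, schedule, one trace file and one event table per test
#' session, and a ground-truth table (latent and realized values) in the
#' formats the signal I/O module reads, plus a manifest with a configuration
#' hash. Re-running with the same configuration is byte-identical.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param force overwrite an existing non-empty directory?
#' @return Invisibly, a list with the roster, schedule, truth table, output
#'   paths and the manifest lines.
#' @export
emit_dataset <- function(config = sim_config(), out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    err_input(paste("output directory not empty (use force = TRUE):", out_dir))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  roster <- simulate_roster(config)
  schedule <- make_schedule(roster, n_days = config$n_days,
                            seed = derive_seed(config$seed, 303))
  truth <- draw_outcomes(schedule, roster, config)

  write_roster(roster, file.path(out_dir, "roster.csv"))
  write_schedule(schedule, file.path(out_dir, "schedule.csv"))

  sessions <- unique(truth$session_id)
  realized_all <- vector("list", length(sessions))
  clipped_any <- logical(length(sessions))
  for (si in seq_along(sessions)) {
    s <- sessions[si]
    tr_rows <- truth[truth$session_id == s, , drop = FALSE]
    rs <- render_session(tr_rows, config, noise = TRUE,
                         seed = derive_seed(config$seed, 404, si))
    write_trace(rs$trace, file.path(out_dir, sprintf("trace_%s.csv", s)))
    write_events(rs$annotations, file.path(out_dir, sprintf("events_%s.csv", s)))
    realized_all[[si]] <- rs$realized
    clipped_any[si] <- rs$trace$clipped
  }
  truth_out <- cbind(as.data.frame(truth), do.call(rbind, realized_all))
  truth_out$clipped <- as.integer(
    clipped_any[match(truth_out$session_id, sessions)])
  write.csv(truth_out, file.path(out_dir, "truth.csv"), row.names = FALSE,
            quote = FALSE, na = "NA")

  cfg_path <- file.path(out_dir, "config.txt")
  writeLines(deparse(config, control = c("all")), cfg_path)
  files <- sort(dir(out_dir))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- c(
    "# perchjump dataset manifest v1",
    sprintf("n_sessions=%d", length(sessions)),
    sprintf("n_jumps=%d", nrow(truth)),
    sprintf("config_md5=%s", unname(tools::md5sum(cfg_path))),
    sprintf("file %s %s", files, unname(sums)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(list(roster = roster, schedule = schedule, truth = truth_out,
                 dir = out_dir, manifest = manifest))
}
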