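# Pipeline stages: simulate -> extract -> analyze, plus the flat key=value
# run configuration. Each stage is a plain function; inst/cli/perchjump.R
# wraps them for shell use.

#' Metrics table directly from ground truth
#'
#' Converts a `jump_truth` table ([draw_outcomes()]) into the phase-metrics
#' layout, using the latent outcome values as if they had been extracted
#' perfectly. Useful for testing the inference stage in isolation from
#' trace rendering.
#'
#' @param truth a `jump_truth` data.frame.
#' @param units_mode "paper" or "si" (forces/impulses scaled accordingly).
#' @return data.frame in the phase-metrics layout.
#' @export
truth_metrics <- function(truth, units_mode = "paper") {
  scale <- if (units_mode == "si") G_TO_MS2 else 1
  data.frame(
    session_id = truth$session_id, hen_id = truth$hen_id, pen = truth$pen,
    hybrid = truth$hybrid, direction = truth$direction,
    angle_class = truth$angle_class, distance_cm = truth$distance_cm,
    day = truth$day, jump = truth$jump, acclimation = truth$acclimation,
    lat_jump = truth$lat_jump, dur_takeoff = truth$dur_takeoff,
    dur_flight = truth$dur_flight, dur_landing = truth$dur_landing,
    lat_peck = ifelse(is.na(truth$first_peck_ms), NA_real_, truth$lat_peck),
    pf_takeoff = truth$pf_takeoff * scale,
    pf_flight = truth$pf_flight * scale,
    pf_landing = truth$pf_landing * scale,
    imp_takeoff = truth$imp_takeoff * scale,
    imp_flight = NA_real_,
    imp_landing = truth$imp_landing * scale,
    balancing = truth$balancing, mass_kg = truth$mass_kg,
    units_mode = units_mode, stringsAsFactors = FALSE)
}

#' Assemble the analysis table from extracted metrics
#'
#' Normalizes factor columns (reference levels 50 cm / flat / Nick Chick),
#' derives the condition and condition-within-hen groupings and the
#' calendar-date column, and (by default) drops the acclimation jump of
#' each session, which serves to acclimate the hen and is excluded from
#' analysis.
#'
#' @param metrics phase-metrics data.frame ([pj_extract()],
#'   [read_metrics()] or [truth_metrics()]).
#' @param exclude_acclimation drop jumps flagged as acclimation?
#' @return Analysis-ready data.frame.
#' @export
collect_analysis_table <- function(metrics, exclude_acclimation = TRUE) {
  tab <- as.data.frame(metrics)
  if (exclude_acclimation && "acclimation" %in% names(tab)) {
    tab <- tab[tab$acclimation == 0, , drop = FALSE]
  }
  tab$condition <- paste0(tab$distance_cm, tab$angle_class)
  tab <- prepare_analysis_factors(tab)
  rownames(tab) <- NULL
  tab
}

#' Simulate stage: write a synthetic study to disk
#'
#' Wraps [emit_dataset()] and reports the manifest.
#'
#' @param config a [sim_config()].
#' @param out_dir dataset directory.
#' @param force overwrite a non-empty directory?
#' @return Invisibly, the [emit_dataset()] result.
#' @export
pj_simulate <- function(config = sim_config(), out_dir, force = FALSE) {
  res <- emit_dataset(config, out_dir, force = force)
  message(sprintf("simulated %d sessions (%d jumps) -> %s",
                  length(unique(res$schedule$session_id)), nrow(res$truth),
                  out_dir))
  invisible(res)
}

#' Extract stage: phase metrics from traces and event tables
#'
#' Reads the roster, schedule and per-session trace/event files from a
#' dataset directory, aligns the annotated phases to samples and computes
#' the full phase-metrics row for every jump. Sessions that fail to parse
#' are logged and skipped; the run fails only when no jump succeeds.
#'
#' @param data_dir dataset directory ([pj_simulate()] layout).
#' @param out_file optional path for the metrics table ([write_metrics()]).
#' @param units_mode "paper" (kg x G) or "si" (newtons); see [keel_force()].
#' @return The metrics data.frame, invisibly if `out_file` is given.
#' @export
pj_extract <- function(data_dir, out_file = NULL,
                       units_mode = c("paper", "si")) {
  units_mode <- match.arg(units_mode)
  roster <- read_roster(file.path(data_dir, "roster.csv"))
  schedule <- read_schedule(file.path(data_dir, "schedule.csv"))
  out <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(schedule))) {
    s <- schedule$session_id[i]
    rec <- tryCatch({
      trace <- read_trace(file.path(data_dir, sprintf("trace_%s.csv", s)))
      events <- read_events(file.path(data_dir, sprintf("events_%s.csv", s)))
      ri <- match(schedule$hen_id[i], roster$hen_id)
      mass <- mean_mass(roster$body_mass_pre_kg[ri],
                        roster$body_mass_post_kg[ri])
      rows <- lapply(seq_len(nrow(events)), function(j) {
        met <- derive_metrics(trace, events[j, ], mass, units_mode)
        cbind(data.frame(session_id = s, hen_id = schedule$hen_id[i],
                         pen = schedule$pen[i], hybrid = schedule$hybrid[i],
                         direction = schedule$direction[i],
                         angle_class = schedule$angle_class[i],
                         distance_cm = schedule$distance_cm[i],
                         day = schedule$day[i], jump = events$jump[j],
                         acclimation = as.integer(events$jump[j] == 1L),
                         stringsAsFactors = FALSE),
              met)
      })
      do.call(rbind, rows)
    }, error = function(e) {
      warning(sprintf("session %s skipped: %s", s, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(rec)) n_skipped <- n_skipped + 1L else
      out[[length(out) + 1]] <- rec
  }
  if (!length(out)) err_input("extraction failed for every session")
  metrics <- do.call(rbind, out)
  metrics <- metrics[, metrics_columns()]
  if (n_skipped) message(sprintf("%d session(s) skipped", n_skipped))
  if (!is.null(out_file)) {
    write_metrics(metrics, out_file)
    return(invisible(metrics))
  }
  metrics
}

default_responses <- function() {
  c("pf_takeoff", "pf_flight", "pf_landing", "imp_takeoff", "imp_landing",
    "lat_jump", "lat_peck", "balancing")
}

# human-readable pattern string for an effect table over 1 or 2 factors
effect_pattern <- function(et, rel_tol = 0.025) {
  fac <- setdiff(names(et), c("estimate_link", "se_link", "mean", "lower",
                              "upper"))
  cmp <- function(lv, mv) {
    scale <- mean(abs(mv))
    o <- order(mv, decreasing = TRUE)
    if (abs(diff(range(mv))) <= rel_tol * scale) {
      paste(lv, collapse = " = ")
    } else paste(lv[o], collapse = " > ")
  }
  if (length(fac) == 1) {
    cmp(as.character(et[[fac]]), et$mean)
  } else if (length(fac) == 2) {
    lv1 <- unique(as.character(et[[fac[1]]]))
    parts <- vapply(lv1, function(l) {
      sub <- et[et[[fac[1]]] == l, ]
      sprintf("%s: %s", l, cmp(as.character(sub[[fac[2]]]), sub$mean))
    }, "")
    paste(parts, collapse = "; ")
  } else {
    "(3-way pattern: see effect table)"
  }
}

#' Analyze stage: fit every response x direction model
#'
#' Runs [keel_model()] for each requested response and direction, collects
#' a summary table (outcome, direction, retained effects, bootstrap p,
#' response-scale pattern), and optionally writes per-model reports and the
#' summary to a directory. Per-model failures are isolated and reported.
#'
#' @param metrics phase-metrics data.frame or path to a metrics file.
#' @param out_dir optional report directory.
#' @param responses response columns to model (default: all eight study
#'   outcomes).
#' @param directions direction subsets (default both).
#' @param alpha exclusion criterion for the reduction.
#' @param n_sim bootstrap simulations per comparison.
#' @param seed integer seed.
#' @param exclude_acclimation drop each session's first (acclimation) jump?
#' @return list with `models` (named list of [keel_model()] fits or error
#'   conditions), `summary` (data.frame), `failures` (character).
#' @export
pj_analyze <- function(metrics, out_dir = NULL,
                       responses = default_responses(),
                       directions = c("up", "down"), alpha = 0.05,
                       n_sim = 1000, seed = 1,
                       exclude_acclimation = TRUE) {
  if (is.character(metrics)) metrics <- read_metrics(metrics)
  tab <- collect_analysis_table(metrics,
                                exclude_acclimation = exclude_acclimation)
  models <- list()
  summary_rows <- list()
  failures <- character()
  for (dir in directions) for (r in responses) {
    key <- paste(r, dir, sep = ".")
    m <- tryCatch(
      keel_model(as.formula(paste(r, "~ distance * angle * hybrid")),
                 tab, direction = dir, alpha = alpha, n_sim = n_sim,
                 seed = derive_seed(seed, match(dir, c("up", "down")),
                                    match(r, responses))),
      error = function(e) e)
    models[[key]] <- m
    if (inherits(m, "error")) {
      failures <- c(failures, sprintf("%s: %s", key, conditionMessage(m)))
      next
    }
    trace <- if (!is.null(m$reduction)) m$reduction$trace else NULL
    for (nm in names(m$effects)) {
      p <- NA_real_
      if (!is.null(trace) && nm %in% trace$term) {
        p <- trace$p[max(which(trace$term == nm))]
      }
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        outcome = r, direction = dir, effect = nm, p = p,
        pattern = effect_pattern(m$effects[[nm]]), stringsAsFactors = FALSE)
    }
  }
  summary <- if (length(summary_rows)) do.call(rbind, summary_rows) else
    data.frame(outcome = character(), direction = character(),
               effect = character(), p = numeric(), pattern = character())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    for (key in names(models)) {
      if (inherits(models[[key]], "error")) next
      rep_path <- file.path(out_dir, paste0("model_", key, ".txt"))
      con <- file(rep_path, "w")
      sink(con)
      print(summary(models[[key]]))
      sink()
      close(con)
    }
    if (length(failures)) {
      writeLines(failures, file.path(out_dir, "failures.txt"))
    }
  }
  if (length(failures)) {
    warning("some models failed: ", paste(failures, collapse = "; "))
  }
  list(models = models, summary = summary, failures = failures)
}

#' Read / write the flat run configuration
#'
#' A plain `key = value` text format (one pair per line, `#` comments).
#' Recognized keys include `seed`, `units_mode`, `alpha`, `n_sim`,
#' `exclude_acclimation`, `noise_sd_g`, `peck_censor_prob`, `n_jumps`,
#' `n_per_hybrid`, `pens_per_hybrid`, `data_dir`, `metrics_file`,
#' `report_dir`. Numeric-looking values are converted.
#'
#' @param path file path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) err_format(paste("no such file:", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (l in lines) {
    kv <- regmatches(l, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", l))[[1]]
    if (length(kv) != 3) err_format(paste("malformed config line:", l))
    v <- trimws(kv[3])
    num <- suppressWarnings(as.numeric(v))
    out[[kv[2]]] <- if (!is.na(num)) num else
      if (v %in% c("true", "TRUE")) TRUE else
        if (v %in% c("false", "FALSE")) FALSE else v
  }
  alpha <- out$alpha %||% 0.05
  if (alpha <= 0 || alpha >= 1) err_input("alpha must be in (0, 1)")
  out
}

#' Run configuration to a simulation configuration
#'
#' @param rc list from [read_run_config()].
#' @return A [sim_config()] honouring the run-configuration overrides.
#' @export
run_config_to_sim <- function(rc) {
  cfg <- sim_config(
    seed = as.integer(rc$seed %||% 20200718),
    n_per_hybrid = as.integer(rc$n_per_hybrid %||% 20),
    pens_per_hybrid = as.integer(rc$pens_per_hybrid %||% 4),
    n_jumps = as.integer(rc$n_jumps %||% 5),
    peck_censor_prob = rc$peck_censor_prob %||% 0)
  if (!is.null(rc$noise_sd_g)) cfg$trace$noise_sd_g <- rc$noise_sd_g
  cfg
}
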