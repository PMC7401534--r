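# Ground-truth study generator. Latent per-jump outcomes are drawn from a
# known mixed-model structure (fixed effects of distance, angle, hybrid and
# all interactions on the transformed scale; random intercepts for pen, hen,
# condition-within-hen and crossed calendar date; jump-level residual), and
# accelerometer traces are rendered truth-first so every downstream stage can
# be checked against known values.

TERM_NAMES <- c("int", "d", "a", "h", "da", "dh", "ah", "dah")

beta_vec <- function(int = 0, d = 0, a = 0, h = 0, da = 0, dh = 0, ah = 0,
                     dah = 0) {
  c(int = int, d = d, a = a, h = h, da = da, dh = dh, ah = ah, dah = dah)
}

#' Response specification for the generator
#'
#' One continuous response of the generative mixed model: its transformation
#' (scale on which the linear model acts), fixed-effect coefficients for
#' intercept, distance (100 vs 50 cm), angle (steep vs flat), hybrid (Brown
#' Nick vs Nick Chick) and all interactions, and the random-intercept /
#' residual standard deviations.
#'
#' @param transformation "identity", "log" or "inverse".
#' @param beta named numeric vector over
#'   `c("int","d","a","h","da","dh","ah","dah")`; omitted terms are 0.
#' @param sd_pen,sd_hen,sd_condition,sd_date,sd_resid nonnegative standard
#'   deviations on the transformed scale.
#' @return A list of class `"response_spec"`.
#' @export
response_spec <- function(transformation, beta, sd_pen = 0, sd_hen = 0,
                          sd_condition = 0, sd_date = 0, sd_resid = 0) {
  transformation <- match_enum(transformation, c("identity", "log", "inverse"),
                               "transformation")
  b <- beta_vec()
  b[names(beta)] <- beta
  sds <- c(pen = sd_pen, hen = sd_hen, condition = sd_condition,
           date = sd_date, resid = sd_resid)
  if (any(sds < 0)) err_input("variance components must be >= 0")
  structure(list(transformation = transformation, beta = b, sd = sds),
            class = "response_spec")
}

# Defaults emulate the study conditions: coefficient values are set so that
# simulated outcome distributions and effect patterns sit in the ranges
# reported for trained hens (keel peak forces of roughly 3-4 N in kg x G
# units, take-off impulses of 0.25-0.55 N s, landing impulses of 1.4-2.3 N s,
# jump latencies of 1-4 s, peck latencies near 1 s, balancing rates of
# 17-58%).
default_response_specs <- function() {
  pf_sd <- list(sd_pen = 0.008, sd_hen = 0.02, sd_condition = 0.012,
                sd_date = 0.006, sd_resid = 0.045)
  log_sd <- list(sd_pen = 0.04, sd_hen = 0.10, sd_condition = 0.06,
                 sd_date = 0.03, sd_resid = 0.20)
  up <- list(
    pf_takeoff = do.call(response_spec, c(list("inverse",
      beta_vec(int = 0.315, d = -0.038)), pf_sd)),
    pf_flight = do.call(response_spec, c(list("inverse",
      beta_vec(int = 0.3115, d = -0.0191, a = 0.0561, da = -0.0636)), pf_sd)),
    pf_landing = do.call(response_spec, c(list("inverse",
      beta_vec(int = 0.3413, d = -0.0307)), pf_sd)),
    imp_takeoff = response_spec("identity",
      beta_vec(int = 0.30, d = -0.01, a = -0.03, da = 0.01),
      sd_pen = 0.006, sd_hen = 0.015, sd_condition = 0.01, sd_date = 0.005,
      sd_resid = 0.035),
    imp_landing = do.call(response_spec, c(list("log",
      beta_vec(int = 0.344, d = 0.126, a = 0.007, da = 0.365)), log_sd)),
    lat_jump = response_spec("log",
      beta_vec(int = 0.015, d = 0.594, a = -0.043, h = 0.70, da = 0.284),
      sd_pen = 0.08, sd_hen = 0.30, sd_condition = 0.12, sd_date = 0.08,
      sd_resid = 0.55),
    lat_peck = response_spec("log",
      beta_vec(int = -0.03, d = 0.08, a = 0.04, da = 0.22),
      sd_pen = 0.03, sd_hen = 0.07, sd_condition = 0.04, sd_date = 0.02,
      sd_resid = 0.15)
  )
  down <- list(
    pf_takeoff = do.call(response_spec, c(list("inverse",
      beta_vec(int = 0.295, h = -0.047)), pf_sd)),
    pf_flight = do.call(response_spec, c(list("inverse",
      beta_vec(int = 0.330, d = -0.0113, a = 0.0123, h = -0.057,
               da = -0.0702)), pf_sd)),
    pf_landing = do.call(response_spec, c(list("inverse",
      beta_vec(int = 0.352, d = -0.0319, a = -0.006, h = -0.0424,
               ah = -0.008)), pf_sd)),
    imp_takeoff = do.call(response_spec, c(list("log",
      beta_vec(int = -0.94, d = -0.223, a = 0.044, h = 0.307, da = 0.305)),
      log_sd)),
    imp_landing = do.call(response_spec, c(list("log",
      beta_vec(int = 0.42, d = 0.249, h = 0.08)), log_sd)),
    lat_jump = response_spec("log",
      beta_vec(int = 0.70, d = 0.52, a = 0.28),
      sd_pen = 0.08, sd_hen = 0.30, sd_condition = 0.12, sd_date = 0.08,
      sd_resid = 0.55),
    lat_peck = response_spec("log",
      beta_vec(int = -0.05, d = 0.11, a = -0.03, h = -0.166, da = 0.17),
      sd_pen = 0.03, sd_hen = 0.07, sd_condition = 0.04, sd_date = 0.02,
      sd_resid = 0.15)
  )
  list(up = up, down = down)
}

default_balancing_specs <- function() {
  sds <- list(sd_pen = 0.2, sd_hen = 0.5, sd_condition = 0.3, sd_date = 0.2)
  list(
    up = do.call(response_spec, c(list("identity",
      beta_vec(int = -1.2, d = -0.10, a = -0.39, da = 1.90)), sds)),
    down = do.call(response_spec, c(list("identity",
      beta_vec(int = -0.59, d = 0.75)), sds))
  )
}

#' Trace-shape configuration for the generator
#'
#' @param rate_hz sampling rate (800 Hz sensor).
#' @param range_g sensor range in G (samples are clipped to +/- range).
#' @param noise_sd_g additive Gaussian noise sd per axis, in G.
#' @param baseline_g standing-still acceleration magnitude; 1 G because the
#'   raw magnitude includes gravity (no baseline subtraction anywhere).
#' @param flap_hz wingbeat frequency of the flight-phase flapping signal.
#' @param takeoff_mean_frac fraction of the peak-minus-baseline amplitude
#'   that the take-off phase mean reaches; fixes the thrust pulse width.
#' @param landing_tau_frac landing impact decay time constant as a fraction
#'   of the landing-phase duration.
#' @param flight_speed_ms median flight speed in m/s (sets flight duration
#'   from the jump distance).
#' @param flight_speed_sdlog lognormal sd of flight speed.
#' @param pad_s standing padding before the signal and after the last event
#'   of each jump, in seconds.
#' @return list of trace parameters.
#' @export
trace_config <- function(rate_hz = 800, range_g = 200, noise_sd_g = 0.03,
                         baseline_g = 1, flap_hz = 8,
                         takeoff_mean_frac = 0.5, landing_tau_frac = 0.45,
                         flight_speed_ms = 2.3, flight_speed_sdlog = 0.12,
                         pad_s = 0.5) {
  if (noise_sd_g < 0) err_input("noise_sd_g must be >= 0")
  if (rate_hz <= 0) err_input("rate_hz must be > 0")
  list(rate_hz = rate_hz, range_g = range_g, noise_sd_g = noise_sd_g,
       baseline_g = baseline_g, flap_hz = flap_hz,
       takeoff_mean_frac = takeoff_mean_frac,
       landing_tau_frac = landing_tau_frac,
       flight_speed_ms = flight_speed_ms,
       flight_speed_sdlog = flight_speed_sdlog, pad_s = pad_s)
}

#' Full simulation configuration
#'
#' Defines one synthetic study: roster composition, body-mass distributions,
#' per-response generative mixed models ([response_spec()]), balancing-
#' probability logit models, trace-shape parameters ([trace_config()]) and
#' session structure (5 jumps per session, the first an acclimation jump).
#'
#' @param seed integer master seed; every derived draw is deterministic
#'   given it.
#' @param n_per_hybrid focal hens per hybrid (20 in the study).
#' @param pens_per_hybrid pens per hybrid (4 in the study; 4-7 hens/pen).
#' @param n_jumps jumps per test session (5; the first acclimates the hen).
#' @param n_days testing days (16).
#' @param body_mass named list per hybrid with `mean` and `sd` in kg. The
#'   study reports no masses; these defaults (Brown Nick 2.0 +/- 0.15 kg,
#'   Nick Chick 1.6 +/- 0.12 kg) are invented, configurable plumbing.
#' @param responses nested list `list(up = ..., down = ...)` of
#'   [response_spec()]s (see `perchjump:::default_response_specs`).
#' @param balancing per-direction [response_spec()]s giving the logit-scale
#'   balancing model (residual sd ignored; the Bernoulli draw is the
#'   jump-level noise).
#' @param trace [trace_config()] list.
#' @param clock_offset_ms video-to-logger clock offset written into every
#'   annotation (a declared per-session field here; offset estimation from
#'   video is out of scope).
#' @param peck_censor_prob probability that First peck is unobserved.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 20200718, n_per_hybrid = 20,
                       pens_per_hybrid = 4, n_jumps = 5, n_days = 16,
                       body_mass = list(
                         "Nick Chick" = c(mean = 1.6, sd = 0.12),
                         "Brown Nick" = c(mean = 2.0, sd = 0.15)),
                       responses = default_response_specs(),
                       balancing = default_balancing_specs(),
                       trace = trace_config(),
                       clock_offset_ms = 0,
                       peck_censor_prob = 0) {
  if (n_jumps < 1) err_input("n_jumps must be >= 1")
  if (peck_censor_prob < 0 || peck_censor_prob >= 1) {
    err_input("peck_censor_prob must be in [0, 1)")
  }
  structure(list(seed = seed, n_per_hybrid = n_per_hybrid,
                 pens_per_hybrid = pens_per_hybrid, n_jumps = n_jumps,
                 n_days = n_days, body_mass = body_mass,
                 responses = responses, balancing = balancing, trace = trace,
                 clock_offset_ms = clock_offset_ms,
                 peck_censor_prob = peck_censor_prob),
            class = "sim_config")
}

#' Simulate a hen roster
#'
#' Hens are blocked by hybrid into pens (hybrids never share a pen, as in
#' the study barn), with per-pen counts drawn uniformly from the valid
#' 4-7-hens-per-pen compositions. Pre-study body mass is drawn per hen from
#' the hybrid's distribution; post-study mass adds a small growth increment.
#'
#' @param config a [sim_config()].
#' @return data.frame with `hen_id`, `pen`, `hybrid`, `body_mass_pre_kg`,
#'   `body_mass_post_kg`.
#' @export
simulate_roster <- function(config = sim_config()) {
  with_seed(derive_seed(config$seed, 101), {
    hybrids <- names(config$body_mass)
    np <- config$pens_per_hybrid
    n <- config$n_per_hybrid
    lo <- 4L; hi <- 7L
    if (n < lo * np || n > hi * np) {
      err_input(sprintf(
        "infeasible pen counts: %d hens cannot fill %d pens with %d-%d hens each",
        n, np, lo, hi))
    }
    out <- list()
    pen_no <- 0
    for (hy in hybrids) {
      # base occupancy of 4 per pen, remaining hens placed into the up-to-3
      # free slots per pen drawn uniformly without replacement
      slots <- rep(seq_len(np), each = hi - lo)
      extra <- n - lo * np
      counts <- lo + tabulate(slots[sample(length(slots), extra)], np)
      for (k in seq_len(np)) {
        pen_no <- pen_no + 1
        m <- config$body_mass[[hy]]
        pre <- pmax(0.8, rnorm(counts[k], m["mean"], m["sd"]))
        post <- pmax(0.8, pre + rnorm(counts[k], 0.05, 0.05))
        out[[length(out) + 1]] <- data.frame(
          pen = sprintf("P%d", pen_no), hybrid = hy,
          body_mass_pre_kg = round(pre, 3), body_mass_post_kg = round(post, 3),
          stringsAsFactors = FALSE)
      }
    }
    roster <- do.call(rbind, out)
    roster <- cbind(hen_id = sprintf("H%02d", seq_len(nrow(roster))), roster)
    rownames(roster) <- NULL
    roster
  })
}

back_transform_scalar <- function(x, kind) {
  switch(kind, identity = x, log = exp(x), inverse = 1 / x)
}

# Draw one response for all jumps of one direction subset; returns values on
# the response (back-transformed) scale.
draw_response <- function(spec, X, pen, hen, cond, date) {
  n <- nrow(X)
  eta <- drop(X %*% spec$beta)
  re <- function(f, sd) {
    lev <- unique(f)
    b <- rnorm(length(lev), 0, sd)
    b[match(f, lev)]
  }
  eta <- eta + re(pen, spec$sd["pen"]) + re(hen, spec$sd["hen"]) +
    re(cond, spec$sd["condition"]) + re(date, spec$sd["date"]) +
    rnorm(n, 0, spec$sd["resid"])
  # keep responses strictly positive (forces, impulses and latencies are)
  eta <- switch(spec$transformation,
                identity = pmax(eta, 0.02),
                inverse = pmax(eta, 0.02),
                log = pmax(eta, -10))
  back_transform_scalar(eta, spec$transformation)
}

#' Draw ground-truth outcomes for every jump of a schedule
#'
#' For each continuous response the value is `X beta + b_pen + b_hen +
#' b_condition(hen) + b_date + eps` on the transformed scale, then
#' back-transformed; the balancing indicator is Bernoulli with the same
#' random structure on the logit scale. Take-off and landing durations are
#' then derived so that the drawn peak force and impulse are exactly
#' realizable by the trace shapes (truth-first rendering); flight duration
#' follows from the jump distance and a lognormal flight speed. Event
#' boundaries are laid out on the session timeline at millisecond
#' resolution.
#'
#' @param schedule a schedule from [make_schedule()].
#' @param roster the matching roster.
#' @param config a [sim_config()].
#' @return data.frame of class `"jump_truth"`, one row per jump, with
#'   session/jump ids, the six event timestamps (ms), latent peak forces
#'   (kg x G "N"), impulses (N s), latencies (s) and the balancing flag.
#' @export
draw_outcomes <- function(schedule, roster, config = sim_config()) {
  if (!all(schedule$hen_id %in% roster$hen_id)) {
    err_input("schedule and roster are inconsistent (unknown hen ids)")
  }
  with_seed(derive_seed(config$seed, 202), {
    nj <- config$n_jumps
    df <- as.data.frame(schedule)[rep(seq_len(nrow(schedule)), each = nj), ]
    df$jump <- rep(seq_len(nj), nrow(schedule))
    df$acclimation <- as.integer(df$jump == 1L)
    ri <- match(df$hen_id, roster$hen_id)
    df$mass_kg <- vapply(ri, function(i) {
      mean_mass(roster$body_mass_pre_kg[i], roster$body_mass_post_kg[i])
    }, numeric(1))
    df$condition <- paste0(df$distance_cm, df$angle_class)
    d <- as.numeric(df$distance_cm == 100)
    a <- as.numeric(df$angle_class == "steep")
    h <- as.numeric(df$hybrid == "Brown Nick")
    X <- cbind(int = 1, d = d, a = a, h = h, da = d * a, dh = d * h,
               ah = a * h, dah = d * a * h)

    resp_names <- c("pf_takeoff", "pf_flight", "pf_landing", "imp_takeoff",
                    "imp_landing", "lat_jump", "lat_peck")
    for (r in resp_names) df[[r]] <- NA_real_
    df$balancing <- NA_integer_
    for (dir in c("up", "down")) {
      idx <- which(df$direction == dir)
      if (!length(idx)) next
      for (r in resp_names) {
        df[[r]][idx] <- draw_response(
          config$responses[[dir]][[r]], X[idx, , drop = FALSE],
          df$pen[idx], df$hen_id[idx], df$session_id[idx], df$day[idx])
      }
      bs <- config$balancing[[dir]]
      etab <- drop(X[idx, , drop = FALSE] %*% bs$beta)
      re <- function(f, sd) {
        lev <- unique(f); b <- rnorm(length(lev), 0, sd); b[match(f, lev)]
      }
      etab <- etab + re(df$pen[idx], bs$sd["pen"]) +
        re(df$hen_id[idx], bs$sd["hen"]) +
        re(df$session_id[idx], bs$sd["condition"]) +
        re(df$day[idx], bs$sd["date"])
      df$balancing[idx] <- rbinom(length(idx), 1, plogis(etab))
    }

    # physically derived phase durations (truth-first: peak and impulse fixed)
    tc <- config$trace
    base <- tc$baseline_g
    A_to <- pmax(df$pf_takeoff / df$mass_kg, base + 0.02)
    A_ld <- pmax(df$pf_landing / df$mass_kg, base + 0.02)
    tau_mean <- tc$landing_tau_frac * (1 - exp(-1 / tc$landing_tau_frac))
    df$dur_takeoff <- pmin(1.5, pmax(0.02, df$imp_takeoff /
      (df$mass_kg * (base + (A_to - base) * tc$takeoff_mean_frac))))
    df$dur_landing <- pmin(2.5, pmax(0.05, df$imp_landing /
      (df$mass_kg * (base + (A_ld - base) * tau_mean))))
    speed <- exp(rnorm(nrow(df), log(tc$flight_speed_ms),
                       tc$flight_speed_sdlog))
    df$dur_flight <- pmax(0.08, (df$distance_cm / 100) / speed)

    # censoring of the first peck
    censor <- runif(nrow(df)) < config$peck_censor_prob

    # Session timeline in ms. Event boundaries are snapped to the common
    # grid of whole milliseconds and sample times (5 ms at 800 Hz, i.e.
    # coarser than the 240 fps video frames they mimic), so each annotated
    # boundary falls exactly on a sample and phase windows never leak a
    # sample across the contact discontinuity.
    grid_ms <- 1000 / gcd_int(1000, round(tc$rate_hz))
    snap <- function(x) round(x / grid_ms) * grid_ms
    pad <- tc$pad_s * 1000
    df$signal_ms <- NA_real_
    for (s in unique(df$session_id)) {
      j <- which(df$session_id == s)
      t0 <- pad
      for (k in j) {
        df$signal_ms[k] <- snap(t0)
        t_end <- t0 + 1000 * (df$lat_jump[k] + df$dur_takeoff[k] +
                                df$dur_flight[k] + df$dur_landing[k] +
                                df$lat_peck[k])
        t0 <- t_end + 2 * pad
      }
    }
    df$takeoff_start_ms <- snap(df$signal_ms + 1000 * df$lat_jump)
    df$takeoff_end_ms <- snap(df$takeoff_start_ms + 1000 * df$dur_takeoff)
    df$landing_start_ms <- snap(df$takeoff_end_ms + 1000 * df$dur_flight)
    df$landing_end_ms <- snap(df$landing_start_ms + 1000 * df$dur_landing)
    df$first_peck_ms <- ifelse(censor, NA_real_,
                               snap(df$landing_end_ms + 1000 * df$lat_peck))
    df$clock_offset_ms <- config$clock_offset_ms
    rownames(df) <- NULL
    class(df) <- c("jump_truth", "data.frame")
    df
  })
}
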