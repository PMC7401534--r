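# Factorial geometry of the perch-positioning experiment and the
# counterbalanced session schedule.

PLATFORM_HEIGHT_CM <- c(up = 60, down = 135)

#' Angle in degrees for a direction and angle class
#'
#' The experiment uses within-direction angle classes: for upward jumps
#' "flat" is 30 degrees and "steep" 60 degrees from the horizontal; for
#' downward jumps "flat" is 15 degrees and "steep" 30 degrees. Angles are
#' measured from the horizontal at the take-off platform.
#'
#' @param direction "up" or "down".
#' @param angle_class "flat" or "steep".
#' @return Angle from the horizontal in degrees.
#' @examples
#' angle_for("up", "flat")    # 30
#' angle_for("down", "steep") # 30
#' @export
angle_for <- function(direction, angle_class) {
  direction <- match_enum(direction, c("up", "down"), "direction")
  angle_class <- match_enum(angle_class, c("flat", "steep"), "angle_class")
  map <- list(up = c(flat = 30, steep = 60), down = c(flat = 15, steep = 30))
  unname(map[[direction]][angle_class])
}

#' Resolve the landing-perch geometry for one condition
#'
#' The take-off platform sits at 60 cm (upward jumps) or 135 cm (downward
#' jumps) above the ground. The stated distance is the diagonal from platform
#' to perch, so the perch height is
#' \code{platform_height +/- distance * sin(angle)} (plus for upward, minus
#' for downward) and the horizontal offset is \code{distance * cos(angle)}.
#'
#' @param direction "up" or "down".
#' @param angle_class "flat" or "steep".
#' @param distance_cm diagonal platform-to-perch distance in cm (50 or 100
#'   in the study; any positive value is accepted).
#' @return A list with `direction`, `angle_class`, `distance_cm`,
#'   `angle_deg`, `platform_height_cm`, `perch_height_cm`,
#'   `horizontal_offset_cm`.
#' @examples
#' resolve_geometry("up", "flat", 50)$perch_height_cm     # 85
#' resolve_geometry("down", "steep", 100)$perch_height_cm # 85
#' @export
resolve_geometry <- function(direction, angle_class, distance_cm) {
  direction <- match_enum(direction, c("up", "down"), "direction")
  angle_class <- match_enum(angle_class, c("flat", "steep"), "angle_class")
  if (!is.numeric(distance_cm) || distance_cm <= 0) {
    err_input("distance_cm must be a positive number")
  }
  ang <- angle_for(direction, angle_class)
  rad <- ang * pi / 180
  platform <- unname(PLATFORM_HEIGHT_CM[direction])
  sgn <- if (direction == "up") 1 else -1
  list(direction = direction, angle_class = angle_class,
       distance_cm = distance_cm, angle_deg = ang,
       platform_height_cm = platform,
       perch_height_cm = platform + sgn * distance_cm * sin(rad),
       horizontal_offset_cm = distance_cm * cos(rad))
}

#' The eight test conditions of the 2x2x2 design
#'
#' One row per cell of the direction x angle class x distance design, with
#' the derived geometry columns. The condition label (e.g. "100steep") is
#' the 4-level within-direction condition factor used as a random-effect
#' grouping in the analysis.
#'
#' @return A data.frame with 8 rows.
#' @export
perch_conditions <- function() {
  grid <- expand.grid(distance_cm = c(50, 100),
                      angle_class = c("flat", "steep"),
                      direction = c("up", "down"),
                      stringsAsFactors = FALSE)
  geo <- lapply(seq_len(nrow(grid)), function(i) {
    resolve_geometry(grid$direction[i], grid$angle_class[i], grid$distance_cm[i])
  })
  out <- data.frame(
    direction = grid$direction,
    angle_class = grid$angle_class,
    distance_cm = grid$distance_cm,
    angle_deg = vapply(geo, `[[`, numeric(1), "angle_deg"),
    platform_height_cm = vapply(geo, `[[`, numeric(1), "platform_height_cm"),
    perch_height_cm = vapply(geo, `[[`, numeric(1), "perch_height_cm"),
    horizontal_offset_cm = vapply(geo, `[[`, numeric(1), "horizontal_offset_cm"),
    stringsAsFactors = FALSE
  )
  out$condition <- paste0(out$distance_cm, out$angle_class)
  out
}

#' Ramp length from platform height and incline
#'
#' The home pens offer a ramp from the floor to the elevated platform; its
#' length is the hypotenuse `height / sin(incline)`, reported to 2 decimals.
#'
#' @param platform_height_m platform height above the floor in metres.
#' @param incline_deg ramp angle from the floor in degrees, in (0, 90].
#' @return Ramp length in metres, rounded to 2 decimals.
#' @examples
#' ramp_length(1.3, 47) # 1.78
#' @export
ramp_length <- function(platform_height_m, incline_deg) {
  if (!is.numeric(platform_height_m) || platform_height_m <= 0) {
    err_input("platform_height_m must be positive")
  }
  if (!is.numeric(incline_deg) || incline_deg <= 0 || incline_deg > 90) {
    err_input("incline_deg must be in (0, 90]")
  }
  round(platform_height_m / sin(incline_deg * pi / 180), 2)
}

# Balanced (Williams) Latin square of even order n: each treatment appears
# once per row and column, and immediate-order effects are balanced.
williams_square <- function(n) {
  first <- integer(n)
  first[1] <- 0
  lo <- 1; hi <- n - 1
  for (j in 2:n) {
    if (j %% 2 == 0) { first[j] <- lo; lo <- lo + 1 } else { first[j] <- hi; hi <- hi - 1 }
  }
  sq <- matrix(0L, n, n)
  for (i in seq_len(n)) sq[i, ] <- (first + (i - 1)) %% n
  sq + 1L
}

#' Generate the counterbalanced test schedule
#'
#' Each hen is tested once per condition. Pens are split into two day-groups
#' (stratified by hybrid) that alternate testing days; with the default 16
#' days each group has 8 testing days and every hen performs one session per
#' testing day of its group. The order of conditions over a hen's days
#' follows rows of a balanced Latin square, with rows assigned within
#' hybrid-by-group strata in seeded random order so that condition order is
#' counterbalanced between hybrids, individuals and time of day. The
#' within-day session order rotates pens and hens across days so that no
#' condition is systematically tested early or late.
#'
#' @param roster data.frame with columns `hen_id`, `pen`, `hybrid` (see
#'   [simulate_roster()]).
#' @param n_days total number of testing days; must equal twice the number
#'   of conditions (default 16).
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @param balance_tol counterbalance tolerance: the maximum allowed absolute
#'   difference between any condition's mean within-day order and the grand
#'   mean order, as a fraction of the largest within-day order (a 3-sigma
#'   sampling-noise floor applies for small rosters, where mean orders
#'   fluctuate even under perfect counterbalancing).
#' @return A data.frame of class `"jump_schedule"` with columns
#'   `session_id`, `day`, `order`, `hen_id`, `pen`, `hybrid`, `direction`,
#'   `angle_class`, `distance_cm`, plus a `"balance"` attribute with the
#'   counterbalance diagnostics.
#' @export
make_schedule <- function(roster, n_days = 16, seed = 1, balance_tol = 0.2) {
  req <- c("hen_id", "pen", "hybrid")
  if (!is.data.frame(roster) || !all(req %in% names(roster))) {
    err_input("roster must be a data.frame with hen_id, pen, hybrid columns")
  }
  conds <- perch_conditions()
  ncond <- nrow(conds)
  if (n_days != 2 * ncond) {
    err_input(sprintf(
      "counterbalancing infeasible: n_days must be %d (one session per hen per group day); got %d",
      2 * ncond, n_days))
  }
  with_seed(seed, {
    pens <- unique(roster$pen)
    pen_hybrid <- vapply(pens, function(p) roster$hybrid[match(p, roster$pen)], "")
    # split pens into two day-groups, balancing hybrids between groups
    group_of <- setNames(integer(length(pens)), pens)
    for (h in unique(pen_hybrid)) {
      ph <- pens[pen_hybrid == h]
      g <- rep(1:2, length.out = length(ph))
      group_of[ph] <- g
    }
    days_of_group <- list(seq(1, n_days, by = 2), seq(2, n_days, by = 2))

    sq <- williams_square(ncond)
    # assign Latin-square rows within (group, hybrid) strata
    roster$group <- group_of[roster$pen]
    cond_order <- matrix(NA_integer_, nrow(roster), ncond)
    for (g in 1:2) for (h in unique(roster$hybrid)) {
      idx <- which(roster$group == g & roster$hybrid == h)
      if (!length(idx)) next
      rows <- rep(sample.int(ncond), length.out = length(idx))
      cond_order[idx, ] <- sq[rows, , drop = FALSE]
    }

    recs <- vector("list", n_days)
    for (d in seq_len(n_days)) {
      g <- if (d %% 2 == 1) 1 else 2
      gidx <- which(roster$group == g)
      if (!length(gidx)) next
      day_rank <- (d + 1) %/% 2 # 1..ncond within group
      # pens (and hens within pens) are tested in a per-day seeded order so
      # that no condition is systematically tested early or late
      # (time-of-day counterbalancing)
      gpens <- pens[group_of[pens] == g]
      if (length(gpens) > 1) gpens <- sample(gpens)
      ord_idx <- unlist(lapply(gpens, function(p) {
        hp <- gidx[roster$pen[gidx] == p]
        if (length(hp) > 1) sample(hp) else hp
      }))
      ci <- cond_order[ord_idx, day_rank]
      recs[[d]] <- data.frame(
        day = d, order = seq_along(ord_idx),
        hen_id = roster$hen_id[ord_idx], pen = roster$pen[ord_idx],
        hybrid = roster$hybrid[ord_idx],
        direction = conds$direction[ci], angle_class = conds$angle_class[ci],
        distance_cm = conds$distance_cm[ci], stringsAsFactors = FALSE)
    }
    sched <- do.call(rbind, recs)
    sched <- sched[order(sched$day, sched$order), , drop = FALSE]
    sched <- cbind(session_id = sprintf("S%03d", seq_len(nrow(sched))), sched)
    rownames(sched) <- NULL

    # counterbalance diagnostic: mean within-day order per condition
    cond_lab <- paste(sched$direction, sched$angle_class, sched$distance_cm)
    mean_ord <- tapply(sched$order, cond_lab, mean)
    dev <- abs(mean_ord - mean(sched$order))
    max_order <- max(sched$order)
    balance <- data.frame(condition = names(mean_ord),
                          mean_order = as.numeric(mean_ord),
                          deviation = as.numeric(dev), stringsAsFactors = FALSE)
    # flag systematic imbalance, not sampling noise: allow at least a
    # 3-sigma mean-order fluctuation for small designs
    noise_floor <- 3 * sd(sched$order) / sqrt(min(table(cond_lab)))
    if (any(dev > max(balance_tol * max_order, noise_floor))) {
      err_input(paste0(
        "counterbalancing failed: condition mean within-day order deviates ",
        "by more than the tolerance; diagnostics: ",
        paste(sprintf("%s=%.2f", balance$condition, balance$deviation),
              collapse = ", ")))
    }
    attr(sched, "balance") <- balance
    attr(sched, "seed") <- seed
    class(sched) <- c("jump_schedule", "data.frame")
    sched
  })
}

#' @export
print.jump_schedule <- function(x, ...) {
  cat(sprintf("Perch-transition schedule: %d sessions, %d hens, %d days\n",
              nrow(x), length(unique(x$hen_id)), length(unique(x$day))))
  print.data.frame(head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... %d more sessions\n", nrow(x) - 6))
  invisible(x)
}

#' Write / read a schedule table
#'
#' Plain comma-separated text with the documented column set.
#' @param schedule a schedule data.frame from [make_schedule()].
#' @param path file path.
#' @return `read_schedule` returns the schedule data.frame.
#' @export
write_schedule <- function(schedule, path) {
  write.csv(as.data.frame(schedule), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) err_format(paste("no such file:", path))
  sched <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("session_id", "day", "order", "hen_id", "pen", "hybrid",
           "direction", "angle_class", "distance_cm")
  if (!all(req %in% names(sched))) {
    err_format(paste("schedule file missing columns:",
                     paste(setdiff(req, names(sched)), collapse = ", ")))
  }
  class(sched) <- c("jump_schedule", "data.frame")
  sched
}
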