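test_that("acceleration magnitude is the Euclidean norm", {
  expect_equal(accel_magnitude(3, 4, 0), 5)
  expect_equal(accel_magnitude(0, 0, 0), 0)
  set.seed(7)
  ax <- rnorm(50); ay <- rnorm(50); az <- rnorm(50)
  # brute-force per-element recomputation
  oracle <- vapply(seq_len(50), function(i) {
    sqrt(sum(c(ax[i], ay[i], az[i])^2))
  }, numeric(1))
  expect_equal(accel_magnitude(ax, ay, az), oracle)
  expect_error(accel_magnitude(1:3, 1:2, 1:3),
               class = "perchjump_input_error")
})

test_that("force conventions: kg x G 'paper' mode and SI newtons", {
  expect_equal(keel_force(100, 1.5), 150)
  expect_equal(keel_force(100, 1.5, "si"), 1.5 * 100 * 9.80665)
  expect_equal(keel_force(0, 2), 0)
  expect_equal(keel_force(0, 2, "si"), 0)
  expect_error(keel_force(1, 0), class = "perchjump_input_error")
  # the two modes differ by exactly standard gravity
  a <- runif(20, 0, 10)
  expect_equal(keel_force(a, 1.7, "si") / keel_force(a, 1.7, "paper"),
               rep(9.80665, 20))
})

test_that("mean body mass averages pre/post and falls back with warning", {
  expect_equal(mean_mass(1.6, 1.8), 1.7)
  expect_equal(mean_mass(2.0, 2.0), 2.0)
  expect_warning(m <- mean_mass(1.6, NA), "missing")
  expect_equal(m, 1.6)
  expect_error(mean_mass(NA, NA), class = "perchjump_input_error")
})

make_pulse_trace <- function(n = 400, rate = 800, amp = 3, base = 1) {
  t <- (seq_len(n) - 1) / rate
  az <- base + (amp - base) * sin(pi * t / (n / rate))
  accel_trace(numeric(n), numeric(n), az, rate_hz = rate)
}

test_that("peak force matches closed forms and a brute-force scan", {
  tr <- make_pulse_trace(n = 400, amp = 3)
  w <- c(1L, 401L)
  # half-sine of amplitude 3 G: peak = mass x 3 within sample quantization
  expect_equal(peak_force(tr, w, 2), 6, tolerance = 1e-4)
  const <- accel_trace(numeric(10), numeric(10), rep(1.5, 10))
  expect_equal(peak_force(const, c(1L, 11L), 2), 3)
  set.seed(42)
  rnd <- accel_trace(rnorm(200), rnorm(200), rnorm(200))
  w2 <- c(17L, 130L)
  mag <- sqrt(rnd$ax^2 + rnd$ay^2 + rnd$az^2)
  expect_equal(peak_force(rnd, w2, 1.3), 1.3 * max(mag[17:129]))
  expect_error(peak_force(rnd, c(10L, 10L), 1), class = "perchjump_alignment_error")
})

test_that("impulse is mean force times duration and is additive", {
  # constant 2 N over 0.5 s
  n <- 400
  const <- accel_trace(numeric(n), numeric(n), rep(1, n)) # 1 G
  expect_equal(impulse(const, c(1L, 401L), 2), 2 * 0.5)
  # half-sine pulse amplitude A over window T: mean = (2/pi) A
  rate <- 800; T <- 0.5; n <- rate * T; A <- 4
  t <- (seq_len(n) - 1) / rate
  tr <- accel_trace(numeric(n), numeric(n), A * sin(pi * t / T))
  expect_equal(impulse(tr, c(1L, n + 1L), 1), (2 / pi) * A * T,
               tolerance = 2 / n)
  # splitting a window: impulses add to the whole
  left <- impulse(tr, c(1L, 151L), 1)
  right <- impulse(tr, c(151L, n + 1L), 1)
  expect_equal(left + right, impulse(tr, c(1L, n + 1L), 1))
})

test_that("max force is never below mean force in any window", {
  set.seed(9)
  tr <- accel_trace(rnorm(300), rnorm(300), 1 + abs(rnorm(300)))
  for (i in 1:20) {
    a <- sample(250, 1); b <- a + sample(40, 1)
    w <- c(a, b)
    dur <- (b - a) / tr$rate_hz
    expect_gte(peak_force(tr, w, 1.5), impulse(tr, w, 1.5) / dur)
  }
})

test_that("derive_metrics computes the full outcome set per jump", {
  cfg <- constant_config(clock_offset_ms = 40)
  st <- small_truth(cfg)
  one <- st$truth[1, , drop = FALSE]
  rs <- render_trace(one, cfg, noise = FALSE)
  ri <- match(one$hen_id, st$roster$hen_id)
  mass <- mean_mass(st$roster$body_mass_pre_kg[ri],
                    st$roster$body_mass_post_kg[ri])
  met <- derive_metrics(rs$trace, rs$annotations[1, ], mass)
  expect_equal(met$pf_takeoff, rs$realized$realized_pf_takeoff)
  expect_equal(met$imp_landing, rs$realized$realized_imp_landing)
  expect_equal(met$lat_jump, (one$takeoff_start_ms - one$signal_ms) / 1000)
  # scale equivariance in mass: forces/impulses double, latencies unchanged
  met2 <- derive_metrics(rs$trace, rs$annotations[1, ], 2 * mass)
  for (col in c("pf_takeoff", "pf_flight", "pf_landing", "imp_takeoff",
                "imp_landing")) {
    expect_equal(met2[[col]], 2 * met[[col]])
  }
  expect_equal(met2$lat_jump, met$lat_jump)
  expect_equal(met2$dur_flight, met$dur_flight)
  # paper vs si differ by exactly g everywhere
  met_si <- derive_metrics(rs$trace, rs$annotations[1, ], mass, "si")
  expect_equal(met_si$pf_landing / met$pf_landing, 9.80665)
  expect_equal(met_si$imp_takeoff / met$imp_takeoff, 9.80665)
})

test_that("censored first peck yields a missing latency only", {
  cfg <- constant_config()
  st <- small_truth(cfg)
  one <- st$truth[1, , drop = FALSE]
  rs <- render_trace(one, cfg, noise = FALSE)
  an <- rs$annotations[1, ]
  an$first_peck_ms <- NA
  met <- derive_metrics(rs$trace, an, 1.8)
  expect_true(is.na(met$lat_peck))
  expect_false(anyNA(met[c("pf_takeoff", "pf_flight", "pf_landing",
                           "imp_takeoff", "imp_landing", "lat_jump")]))
})

test_that("metrics are invariant to a common time + offset shift", {
  cfg <- constant_config()
  st <- small_truth(cfg)
  one <- st$truth[1, , drop = FALSE]
  rs <- render_trace(one, cfg, noise = FALSE)
  an <- rs$annotations[1, ]
  shifted <- an
  for (f in c("signal_ms", "takeoff_start_ms", "takeoff_end_ms",
              "landing_start_ms", "landing_end_ms", "first_peck_ms")) {
    shifted[[f]] <- shifted[[f]] + 1000
  }
  shifted$clock_offset_ms <- shifted$clock_offset_ms + 1000
  expect_equal(derive_metrics(rs$trace, shifted, 1.8),
               derive_metrics(rs$trace, an, 1.8))
})
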