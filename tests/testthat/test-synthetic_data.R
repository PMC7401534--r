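test_that("the default roster reproduces the study composition", {
  roster <- simulate_roster(sim_config())
  expect_equal(nrow(roster), 40L)
  expect_equal(length(unique(roster$pen)), 8L)
  expect_true(all(table(roster$pen) >= 4 & table(roster$pen) <= 7))
  expect_equal(unname(table(roster$hybrid)), c(20L, 20L),
               ignore_attr = TRUE)
  # hybrids never share a pen
  expect_true(all(rowSums(table(roster$pen, roster$hybrid) > 0) == 1))
  expect_true(all(roster$body_mass_pre_kg > 0))
  expect_identical(roster, simulate_roster(sim_config()))
  expect_error(simulate_roster(sim_config(n_per_hybrid = 30)),
               class = "perchjump_input_error")
})

test_that("zero-variance, zero-effect outcomes equal the back-transformed intercept", {
  cfg <- constant_config()
  st <- small_truth(cfg)
  tr <- st$truth
  expect_equal(unique(round(tr$pf_takeoff, 10)), 1 / 0.30)
  expect_equal(unique(round(tr$imp_takeoff, 10)), 0.30)
  expect_equal(unique(round(tr$imp_landing, 10)), exp(0.40))
  expect_equal(unique(round(tr$lat_peck, 10)), 1)
})

test_that("a distance coefficient shows up as the empirical mean difference", {
  # identity-scale response, large distance effect, only residual noise;
  # oracle: direct averaging over >= 1e4 draws
  specs <- default_response_specs()
  specs$up$imp_takeoff <- response_spec("identity",
                                        c(int = 2, d = 1.5), sd_resid = 0.3)
  specs$down$imp_takeoff <- specs$up$imp_takeoff
  cfg <- small_config(seed = 404, n_per_hybrid = 12, pens_per_hybrid = 2,
                      n_jumps = 5, responses = specs)
  draws <- do.call(rbind, lapply(1:11, function(i) {
    cfg$seed <- 404 + i
    st <- small_truth(cfg)
    st$truth[, c("distance_cm", "imp_takeoff")]
  }))
  expect_gt(nrow(draws), 1e4)
  diff <- mean(draws$imp_takeoff[draws$distance_cm == 100]) -
    mean(draws$imp_takeoff[draws$distance_cm == 50])
  mc_se <- 0.3 * sqrt(4 / nrow(draws))
  expect_lt(abs(diff - 1.5), 4 * mc_se)
})

test_that("a zero-logit balancing model yields a 50% balancing rate", {
  bal <- list(up = response_spec("identity", c(int = 0)),
              down = response_spec("identity", c(int = 0)))
  cfg <- small_config(seed = 7, n_per_hybrid = 12, n_jumps = 5,
                      balancing = bal)
  st <- small_truth(cfg)
  rate <- mean(st$truth$balancing)
  n <- nrow(st$truth)
  expect_lt(abs(rate - 0.5), 4 * sqrt(0.25 / n))
})

test_that("event boundaries are strictly ordered within every jump", {
  st <- small_truth(small_config(peck_censor_prob = 0.2))
  tr <- st$truth
  expect_true(all(tr$signal_ms < tr$takeoff_start_ms))
  expect_true(all(tr$takeoff_start_ms < tr$takeoff_end_ms))
  expect_true(all(tr$takeoff_end_ms < tr$landing_start_ms))
  expect_true(all(tr$landing_start_ms < tr$landing_end_ms))
  ok <- !is.na(tr$first_peck_ms)
  expect_true(any(!ok)) # censoring occurred
  expect_true(all(tr$landing_end_ms[ok] <= tr$first_peck_ms[ok]))
})

test_that("noiseless rendering recovers the drawn truth", {
  cfg <- small_config(trace = trace_config(noise_sd_g = 0))
  st <- small_truth(cfg)
  s1 <- st$truth$session_id[1]
  rows <- st$truth[st$truth$session_id == s1, ]
  rs <- render_session(rows, cfg, noise = FALSE)
  # realized == latent within boundary quantization (5 ms grid at 800 Hz)
  grid_s <- 0.005
  expect_equal(rs$realized$realized_pf_takeoff, rows$pf_takeoff,
               tolerance = 1e-3)
  expect_equal(rs$realized$realized_pf_landing, rows$pf_landing,
               tolerance = 1e-3)
  bound <- rows$pf_takeoff * grid_s + 1e-6
  expect_true(all(abs(rs$realized$realized_imp_takeoff - rows$imp_takeoff)
                  <= bound))
  expect_equal(rs$realized$realized_lat_jump, rows$lat_jump,
               tolerance = 5e-3)
})

test_that("trace length follows the documented span arithmetic", {
  cfg <- constant_config()
  st <- small_truth(cfg)
  one <- st$truth[1, , drop = FALSE]
  rs <- render_trace(one, cfg, noise = FALSE)
  span_ms <- max(one$landing_end_ms, one$first_peck_ms, na.rm = TRUE) +
    cfg$trace$pad_s * 1000 - (one$signal_ms - cfg$trace$pad_s * 1000)
  expect_equal(length(rs$trace$az), span_ms / 1000 * 800, tolerance = 1)
})

test_that("a peak beyond the sensor range warns and sets the clipping flag", {
  cfg <- constant_config()
  st <- small_truth(cfg)
  one <- st$truth[1, , drop = FALSE]
  one$pf_takeoff <- one$mass_kg * 400 # 400 G, beyond +/-200 G
  expect_warning(rs <- render_trace(one, cfg, noise = FALSE), "range")
  expect_true(rs$trace$clipped)
  expect_lte(max(abs(rs$trace$az)), 200)
})

test_that("emitted datasets have the right shape and are byte-stable", {
  cfg <- small_config(n_per_hybrid = 4, pens_per_hybrid = 1, n_jumps = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res <- emit_dataset(cfg, d1, force = TRUE)
  n_sessions <- 8 * 8 # 8 hens x 8 conditions
  expect_length(dir(d1, pattern = "^events_"), n_sessions)
  expect_length(dir(d1, pattern = "^trace_"), n_sessions)
  expect_equal(nrow(res$truth), n_sessions * 5)
  emit_dataset(cfg, d2, force = TRUE)
  f <- dir(d1)
  expect_identical(unname(tools::md5sum(file.path(d1, f))),
                   unname(tools::md5sum(file.path(d2, f))))
})
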