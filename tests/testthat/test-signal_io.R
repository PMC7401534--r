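write_fixture_trace <- function(path, rows, rate = 800, unit = "G") {
  writeLines(c("# perchjump accel trace v1",
               sprintf("# rate_hz: %g", rate),
               "# start_ms: 0",
               sprintf("# unit: %s", unit),
               "time_s,ax,ay,az", rows), path)
}

test_that("trace files parse with header validation", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_trace(path, c("0,0,0,1", "0.00125,0,0,1", "0.0025,0,0,1"))
  tr <- read_trace(path)
  expect_s3_class(tr, "accel_trace")
  expect_length(tr$az, 3)
  expect_equal(tr$rate_hz, 800)
  expect_equal(tr$az, c(1, 1, 1))
})

test_that("unit and structural errors are rejected with diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_trace(path, "0,0,0,1", unit = "m/s2")
  expect_error(read_trace(path), "unit", class = "perchjump_format_error")
  write_fixture_trace(path, c("0,0,0,1", "0.00125,0,oops,1"))
  expect_error(read_trace(path), "lines", class = "perchjump_format_error")
  write_fixture_trace(path, c("0.01,0,0,1", "0.0,0,0,1"))
  expect_error(read_trace(path), "increasing", class = "perchjump_format_error")
})

test_that("traces round-trip through disk", {
  set.seed(3)
  tr <- accel_trace(rnorm(64), rnorm(64), 1 + rnorm(64), start_ms = 250)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$ax, tr$ax, tolerance = 1e-5)
  expect_equal(back$az, tr$az, tolerance = 1e-5)
  expect_equal(back$start_ms, 250)
})

test_that("millisecond events map to half-open sample windows", {
  tr <- accel_trace(numeric(1600), numeric(1600), rep(1, 1600))
  an <- list(signal_ms = 0, takeoff_start_ms = 100, takeoff_end_ms = 200,
             landing_start_ms = 500, landing_end_ms = 1000,
             clock_offset_ms = 0)
  # 100 ms at 800 Hz = 80 samples
  w <- window_to_samples(an, "takeoff", tr)
  expect_equal(w[2] - w[1], 80L)
  # event at an exact sample time: index = time x rate (1-based)
  expect_equal(w[1], 100 / 1000 * 800 + 1)
  expect_error(window_to_samples(an, "warmup", tr),
               class = "perchjump_input_error")
  an$landing_end_ms <- 3000
  expect_error(window_to_samples(an, "landing", tr),
               class = "perchjump_alignment_error")
})

test_that("nearest-sample mapping agrees with an exhaustive scan", {
  rate <- 800
  tr <- accel_trace(numeric(4000), numeric(4000), rep(1, 4000),
                    rate_hz = rate)
  sample_times <- (seq_len(4000) - 1) / rate * 1000
  set.seed(11)
  for (i in 1:200) {
    t0 <- runif(1, 10, 2000)
    t1 <- t0 + runif(1, 20, 1500)
    an <- list(takeoff_start_ms = t0, takeoff_end_ms = t1,
               clock_offset_ms = 0)
    w <- window_to_samples(an, "takeoff", tr)
    # oracle: nearest sample by brute force, ties toward the earlier sample
    near <- function(t) {
      d <- abs(sample_times - t)
      which(d == min(d))[1]
    }
    expect_equal(w[1], near(t0))
    expect_equal(w[2], near(t1))
  }
})

test_that("alignment is translation-equivariant in the clock offset", {
  tr <- accel_trace(numeric(2000), numeric(2000), rep(1, 2000))
  base <- list(takeoff_start_ms = 312, takeoff_end_ms = 844,
               clock_offset_ms = 0)
  w0 <- window_to_samples(base, "takeoff", tr)
  for (delta in c(13, 100, 997.5)) {
    sh <- list(takeoff_start_ms = 312 + delta, takeoff_end_ms = 844 + delta,
               clock_offset_ms = delta)
    expect_identical(window_to_samples(sh, "takeoff", tr), w0)
  }
})

test_that("metrics tables round-trip losslessly, including missing pecks", {
  cfg <- small_config(peck_censor_prob = 0.3,
                      trace = trace_config(noise_sd_g = 0))
  st <- small_truth(cfg)
  met <- truth_metrics(st$truth)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics(met, path)
  back <- read_metrics(path)
  expect_true(anyNA(back$lat_peck))
  expect_equal(back$lat_peck, met$lat_peck)
  num <- vapply(met, is.numeric, logical(1))
  for (col in names(met)[num]) expect_equal(back[[col]], met[[col]])
  for (col in names(met)[!num]) expect_equal(back[[col]], met[[col]])
})

test_that("empty metrics lists produce a readable header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics(data.frame(), path)
  back <- read_metrics(path)
  expect_equal(nrow(back), 0L)
  expect_identical(names(back), perchjump:::metrics_columns())
})

test_that("schema mismatches are format errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# perchjump metrics v99", "session_id"), path)
  expect_error(read_metrics(path), "schema",
               class = "perchjump_format_error")
})

test_that("event tables validate timestamp ordering", {
  path <- withr::local_tempfile(fileext = ".csv")
  ev <- data.frame(jump = 1, signal_ms = 100, takeoff_start_ms = 90,
                   takeoff_end_ms = 200, landing_start_ms = 300,
                   landing_end_ms = 400, first_peck_ms = 500,
                   balancing = 0, clock_offset_ms = 0)
  write_events(ev, path)
  expect_error(read_events(path), "nondecreasing",
               class = "perchjump_format_error")
})
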