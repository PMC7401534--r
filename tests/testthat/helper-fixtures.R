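# Shared fixtures, built in code.

# small study: 8 hens in 2 pens per hybrid block is too small for the
# 4-7/pen rule, so scale pens with hens
small_config <- function(seed = 20200718, n_per_hybrid = 8,
                         pens_per_hybrid = 2, n_jumps = 3, ...) {
  sim_config(seed = seed, n_per_hybrid = n_per_hybrid,
             pens_per_hybrid = pens_per_hybrid, n_jumps = n_jumps, ...)
}

small_truth <- function(cfg = small_config(), schedule_seed = 1) {
  roster <- simulate_roster(cfg)
  sched <- make_schedule(roster, seed = schedule_seed)
  list(roster = roster, schedule = sched,
       truth = draw_outcomes(sched, roster, cfg))
}

small_analysis_table <- function(cfg = small_config(), schedule_seed = 1) {
  st <- small_truth(cfg, schedule_seed)
  collect_analysis_table(truth_metrics(st$truth))
}

# a generator config with every variance component and coefficient zeroed
constant_config <- function(...) {
  specs <- lapply(list(
    pf_takeoff = list("inverse", 0.30), pf_flight = list("inverse", 0.31),
    pf_landing = list("inverse", 0.32), imp_takeoff = list("identity", 0.30),
    imp_landing = list("log", 0.40), lat_jump = list("log", 0.40),
    lat_peck = list("log", 0.00)), function(a) {
      response_spec(a[[1]], c(int = a[[2]]))
    })
  bal <- list(up = response_spec("identity", c(int = 0)),
              down = response_spec("identity", c(int = 0)))
  small_config(responses = list(up = specs, down = specs), balancing = bal,
               trace = trace_config(noise_sd_g = 0), ...)
}

# simple one-grouping mixed data for inference unit tests
toy_lmm_data <- function(n_group = 16, per_group = 3, beta_x = 0,
                         sd_group = 0.7, sd_resid = 1, seed = 1) {
  set.seed(seed)
  g <- factor(rep(seq_len(n_group), each = per_group))
  x <- factor(rep(c("a", "b"), length.out = n_group * per_group))
  y <- beta_x * (x == "b") + rep(rnorm(n_group, 0, sd_group), each = per_group) +
    rnorm(n_group * per_group, 0, sd_resid)
  data.frame(g = g, x = x, y = as.numeric(y))
}
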