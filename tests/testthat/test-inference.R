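test_that("transformations are exact inverse pairs and swap CI endpoints", {
  expect_equal(transform_values(4, "inverse"), 0.25)
  expect_equal(back_transform_values(0.25, "inverse"), 4)
  set.seed(2)
  x <- rexp(100) + 0.01
  for (k in c("identity", "log", "inverse")) {
    expect_equal(back_transform_values(transform_values(x, k), k), x)
  }
  # CI (0.2, 0.5) on the inverse scale maps to (2, 5) with endpoints swapped
  ci <- back_transform_interval(0.2, 0.5, "inverse")
  expect_equal(ci$lower, 2)
  expect_equal(ci$upper, 5)
  expect_error(transform_values(c(1, -1), "log"),
               class = "perchjump_input_error")
})

test_that("the transformation table matches the analysis defaults", {
  expect_equal(default_transformation("pf_takeoff", "up"), "inverse")
  expect_equal(default_transformation("pf_flight", "down"), "inverse")
  expect_equal(default_transformation("pf_landing", "up"), "inverse")
  expect_equal(default_transformation("imp_takeoff", "up"), "identity")
  expect_equal(default_transformation("imp_takeoff", "down"), "log")
  expect_equal(default_transformation("imp_landing", "up"), "log")
  expect_equal(default_transformation("lat_jump", "down"), "log")
  expect_equal(default_transformation("lat_peck", "up"), "log")
  expect_equal(default_transformation("balancing", "down"), "binomial")
})

test_that("marginality violations are rejected", {
  expect_error(
    perchjump:::check_marginality(~ distance + distance:angle),
    class = "perchjump_input_error")
  expect_silent(perchjump:::check_marginality(~ distance * angle * hybrid))
})

test_that("an LMM with no simulated group variance matches OLS", {
  cfg <- small_config(n_per_hybrid = 8, pens_per_hybrid = 2)
  specs <- default_response_specs()
  for (d in c("up", "down")) {
    specs[[d]]$imp_takeoff <- response_spec("identity",
      c(int = 2, d = 0.5, a = 0.3, h = 0.2, da = 0.25), sd_resid = 0.4)
  }
  cfg$responses <- specs
  tab <- small_analysis_table(cfg)
  spec <- model_spec("imp_takeoff", family = "gaussian",
                     transformation = "identity", direction = "up")
  fit <- fit_lmm(spec, tab)
  sub <- tab[tab$direction == "up", ]
  ols <- lm(imp_takeoff ~ distance * angle * hybrid, sub)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-4)
  expect_true(fit$singular) # all group variances truly zero
})

test_that("variance components match ANOVA method-of-moments on balanced data", {
  # one grouping, 20 groups x 10: MS_between = n sigma_g^2 + sigma_e^2
  set.seed(31)
  n_g <- 20; n_per <- 10
  g <- factor(rep(seq_len(n_g), each = n_per))
  y <- rep(rnorm(n_g, 0, 0.8), each = n_per) + rnorm(n_g * n_per, 0, 0.5)
  d <- data.frame(g = g, y = y)
  fit <- fit_lmm(model_spec("y", fixed = ~1, random = "g"), d, reml = TRUE)
  aov_tab <- anova(lm(y ~ g, d))
  ms_b <- aov_tab$`Mean Sq`[1]; ms_w <- aov_tab$`Mean Sq`[2]
  mom_sg <- sqrt((ms_b - ms_w) / n_per)
  vc <- fit$varcomp
  expect_equal(vc$sdcor[vc$grp == "g"], mom_sg, tolerance = 1e-3)
  expect_equal(vc$sdcor[vc$grp == "Residual"], sqrt(ms_w), tolerance = 1e-2)
})

test_that("duplicating rows leaves ML fixed-effect estimates unchanged", {
  # with the covariate balanced within groups the fixed-effect estimator is
  # a contrast of cell means, invariant to the GLS reweighting duplication
  # induces
  d <- toy_lmm_data(beta_x = 0.8, per_group = 4, seed = 5)
  spec <- model_spec("y", fixed = ~x, random = "g")
  f1 <- fit_lmm(spec, d)
  f2 <- fit_lmm(spec, rbind(d, d))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
})

test_that("a zero-variance binomial GLMM matches plain logistic regression", {
  set.seed(8)
  n <- 600
  x <- factor(rep(c("a", "b"), n / 2))
  g <- factor(rep(1:20, each = n / 20))
  y <- rbinom(n, 1, plogis(-0.4 + 0.9 * (x == "b")))
  d <- data.frame(y = y, x = x, g = g)
  fit <- fit_glmm_binomial(model_spec("y", fixed = ~x, family = "binomial",
                                      random = "g", jump_re = FALSE), d)
  ref <- glm(y ~ x, binomial, d)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-3)
})

test_that("an intercept-only balanced binomial fit sits near logit zero", {
  set.seed(9)
  d <- data.frame(y = rep(c(0, 1), 100), g = factor(rep(1:20, each = 10)))
  fit <- fit_glmm_binomial(model_spec("y", fixed = ~1, family = "binomial",
                                      random = "g", jump_re = FALSE), d)
  expect_lt(abs(unname(coef(fit))[1]), 0.05)
})

test_that("groupings with a single level are dropped with a message", {
  d <- toy_lmm_data(seed = 2)
  d$pen <- "only" # degenerate
  spec <- model_spec("y", fixed = ~x, random = c("pen", "g"))
  expect_message(fit <- fit_lmm(spec, d), "pen")
  expect_false("pen" %in% fit$varcomp$grp)
})

test_that("comparing a model with itself gives T = 0 and p = 1", {
  d <- toy_lmm_data(seed = 3)
  spec <- model_spec("y", fixed = ~x, random = "g")
  f <- fit_lmm(spec, d)
  pb <- pb_modcomp(f, f, n_sim = 19, seed = 1)
  expect_equal(pb$stat, 0)
  expect_equal(pb$p, 1)
})

test_that("the devfun and refit bootstrap engines agree", {
  d <- toy_lmm_data(beta_x = 0.5, seed = 6)
  full <- fit_lmm(model_spec("y", fixed = ~x, random = "g"), d)
  red <- fit_lmm(model_spec("y", fixed = ~1, random = "g"), d)
  p1 <- pb_modcomp(full, red, n_sim = 60, seed = 12, engine = "devfun")
  p2 <- pb_modcomp(full, red, n_sim = 60, seed = 12, engine = "refit")
  expect_equal(p1$stat, p2$stat, tolerance = 1e-6)
  expect_equal(p1$p, p2$p)
  expect_equal(sort(p1$t_star), sort(p2$t_star), tolerance = 1e-4)
})

test_that("a strong effect attains the smallest possible p-value", {
  d <- toy_lmm_data(beta_x = 3, sd_group = 0.3, seed = 7)
  full <- fit_lmm(model_spec("y", fixed = ~x, random = "g"), d)
  red <- fit_lmm(model_spec("y", fixed = ~1, random = "g"), d)
  pb <- pb_modcomp(full, red, n_sim = 99, seed = 2)
  expect_equal(pb$p, 1 / 100)
})

test_that("bootstrap p-values are invariant to grouping-level relabeling", {
  d <- toy_lmm_data(beta_x = 0.6, seed = 10)
  d2 <- d
  levels(d2$g) <- paste0("pen_", rev(levels(d$g)))
  spec_f <- model_spec("y", fixed = ~x, random = "g")
  spec_r <- model_spec("y", fixed = ~1, random = "g")
  p1 <- pb_modcomp(fit_lmm(spec_f, d), fit_lmm(spec_r, d), n_sim = 40,
                   seed = 5)
  p2 <- pb_modcomp(fit_lmm(spec_f, d2), fit_lmm(spec_r, d2), n_sim = 40,
                   seed = 5)
  expect_equal(p1$p, p2$p)
  expect_equal(p1$stat, p2$stat, tolerance = 1e-6)
})

test_that("reduction respects marginality around a simulated interaction", {
  specs <- default_response_specs()
  specs$up$imp_takeoff <- response_spec("identity",
    c(int = 2, d = 0.1, a = 0.1, da = 1.2), sd_hen = 0.1, sd_resid = 0.25)
  cfg <- small_config(seed = 99, responses = specs, n_jumps = 4)
  tab <- small_analysis_table(cfg)
  spec <- model_spec("imp_takeoff", family = "gaussian",
                     transformation = "identity", direction = "up")
  red <- backward_reduce(spec, tab, alpha = 0.05, n_sim = 60, seed = 3)
  kept <- attr(terms(red$spec$fixed), "term.labels")
  expect_true("distance:angle" %in% kept)
  expect_true(all(c("distance", "angle") %in% kept))
  # with distance:angle retained throughout, its marginal main effects are
  # never even eligible for testing
  expect_false(any(red$trace$term %in% c("distance", "angle")))
})

test_that("effect tables equal cell means for an identity, balanced fit", {
  d <- toy_lmm_data(beta_x = 1.2, per_group = 4, seed = 12)
  fit <- fit_lmm(model_spec("y", fixed = ~x, random = "g"), d, reml = TRUE)
  et <- estimate_effects(fit, "x")
  # balanced one-factor design: model-based means equal the OLS cell means
  cm <- tapply(fitted(lm(y ~ x, d)), d$x, mean)
  expect_equal(et$mean, as.vector(cm[as.character(et$x)]), tolerance = 1e-3)
  expect_true(all(et$lower <= et$mean & et$mean <= et$upper))
})

test_that("inverse-scale effect tables order their endpoints correctly", {
  cfg <- small_config()
  tab <- small_analysis_table(cfg)
  fit <- fit_lmm(model_spec("pf_landing", family = "gaussian",
                            transformation = "inverse", direction = "up"),
                 tab, reml = TRUE)
  et <- estimate_effects(fit, c("distance", "angle"))
  expect_equal(nrow(et), 4L)
  expect_true(all(et$lower < et$mean & et$mean < et$upper))
  # means on the response scale are the reciprocal of the link estimates
  expect_equal(et$mean, 1 / et$estimate_link)
})

test_that("binomial effect tables are probabilities", {
  cfg <- small_config()
  tab <- small_analysis_table(cfg)
  fit <- fit_glmm_binomial(model_spec("balancing", family = "binomial",
                                      direction = "up"), tab)
  et <- estimate_effects(fit, "distance")
  expect_true(all(et$mean > 0 & et$mean < 1))
  expect_true(all(et$lower > 0 & et$upper < 1))
})

test_that("quantile residuals are deterministic and flag outliers", {
  d <- toy_lmm_data(seed = 13)
  fit <- fit_lmm(model_spec("y", fixed = ~x, random = "g"), d, reml = TRUE)
  q1 <- simulate_quantile_residuals(fit, n_sim = 100, seed = 4)
  q2 <- simulate_quantile_residuals(fit, n_sim = 100, seed = 4)
  expect_identical(q1$quantiles, q2$quantiles)
  expect_true(all(q1$quantiles > 0 & q1$quantiles < 1))
  # an observation far outside its simulations pins to the boundary
  d2 <- d
  d2$y[1] <- d2$y[1] + 100
  fit2 <- fit_lmm(model_spec("y", fixed = ~x, random = "g"), d2)
  q3 <- simulate_quantile_residuals(fit2, n_sim = 100, seed = 4)
  expect_equal(unname(q3$quantiles[1]), max(q3$quantiles))
  expect_gt(q3$quantiles[1], 1 - 1 / 100)
})

test_that("quantile residuals are calibrated for a well-specified model", {
  # under the true model the KS uniformity p-value is rarely tiny
  ok <- vapply(1:20, function(i) {
    d <- toy_lmm_data(n_group = 12, per_group = 4, sd_group = 0.4,
                      seed = 100 + i)
    fit <- fit_lmm(model_spec("y", fixed = ~1, random = "g"), d)
    simulate_quantile_residuals(fit, n_sim = 120, seed = i)$ks_p > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("variance components are recovered and tighten with study size", {
  est <- function(nh, pph, seed) {
    cfg <- sim_config(seed = seed, n_per_hybrid = nh, pens_per_hybrid = pph)
    r <- simulate_roster(cfg)
    s <- make_schedule(r, seed = seed)
    tab <- collect_analysis_table(truth_metrics(draw_outcomes(s, r, cfg)))
    f <- fit_lmm(model_spec("imp_landing", family = "gaussian",
                            transformation = "log", direction = "up"),
                 tab, reml = TRUE)
    setNames(f$varcomp$sdcor, f$varcomp$grp)
  }
  true_sd <- c(hen = 0.10, condition_hen = 0.06, Residual = 0.20)
  v_study <- est(20, 4, 1234)   # the study's size: 40 hens, 8 pens
  v_big <- est(100, 20, 1234)   # hen count x5
  expect_true(all(abs(v_study[names(true_sd)] - true_sd) / true_sd < 0.5))
  expect_true(all(abs(v_big[names(true_sd)] - true_sd) / true_sd < 0.3))
})
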