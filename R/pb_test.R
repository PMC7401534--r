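# Parametric-bootstrap likelihood-ratio model comparison: simulate response
# vectors from the reduced (null) fit -- including new random-effect and
# residual draws -- refit both models on each, and compare the observed LRT
# statistic to the simulated reference distribution.
#
# Two refitting engines: "devfun" rebuilds each model's lme4 deviance
# function once, swaps the simulated response in place and re-optimizes
# (orders of magnitude faster than a full refit); "refit" uses lme4::refit.
# Both give the same statistics up to optimizer tolerance and are
# cross-checked in the test suite.

as_ml_fit <- function(x, data = NULL) {
  if (inherits(x, "model_spec")) {
    if (is.null(data)) err_input("data required when passing a model_spec")
    return(fit_spec(x, data, reml = FALSE))
  }
  if (!inherits(x, "keel_fit")) {
    err_input("pass a model_spec or keel_fit")
  }
  if (isTRUE(x$reml)) {
    x$model <- lme4::refitML(x$model)
    x$reml <- FALSE
    x$logLik <- as.numeric(logLik(x$model))
  }
  x
}

check_nesting <- function(full, reduced) {
  ft <- attr(terms(formula(full$model, fixed.only = TRUE)), "term.labels")
  rt <- attr(terms(formula(reduced$model, fixed.only = TRUE)), "term.labels")
  if (!all(rt %in% ft)) {
    err_input("reduced model is not nested in the full model")
  }
}

# Deviance-function handle for a fitted (ML) merMod: a function of the
# covariance parameters (and, for GLMMs, fixed effects) whose response can
# be swapped in place via the lme4 response module.
build_devfun <- function(model) {
  frame <- model@frame
  is_glmm <- lme4::isGLMM(model)
  if (is_glmm) {
    dd <- lme4::glmer(formula(model), data = frame,
                      family = model@resp$family, nAGQ = 1,
                      devFunOnly = TRUE)
    start <- c(lme4::getME(model, "theta"), lme4::fixef(model))
  } else {
    dd <- lme4::lmer(formula(model), data = frame, REML = FALSE,
                     devFunOnly = TRUE)
    start <- lme4::getME(model, "theta")
  }
  lower <- environment(dd)$lower
  if (length(lower) < length(start)) {
    lower <- c(lower, rep(-Inf, length(start) - length(lower)))
  }
  list(dev = dd, resp = environment(dd)$resp,
       start = pmax(start, ifelse(is.finite(lower), lower + 1e-8, start)),
       lower = lower)
}

min_deviance <- function(df, y) {
  df$resp$setResp(y)
  if (length(df$start) == 1L) {
    hi <- max(5, 10 * df$start)
    opt <- stats::optimize(df$dev, c(df$lower, hi))
    # guard against an optimum at the upper bracket
    while (opt$minimum > 0.98 * hi && hi < 1e4) {
      hi <- hi * 10
      opt <- stats::optimize(df$dev, c(df$lower, hi))
    }
    opt$objective
  } else {
    lo <- ifelse(is.finite(df$lower), df$lower, -1e6)
    opt <- minqa::bobyqa(df$start, df$dev, lower = lo,
                         control = list(rhobeg = 0.4, rhoend = 1e-8))
    min(opt$fval, df$dev(df$start))
  }
}

#' Parametric-bootstrap likelihood-ratio test
#'
#' Simulates `n_sim` response vectors from the reduced ML fit (new
#' random-effect and residual/Bernoulli draws), refits both models on each
#' simulated response, and computes the bootstrap p-value
#' `p = (1 + #\{T* >= T_obs\}) / (n_ok + 1)` where `T* = 2 (logLik_full -
#' logLik_reduced)` and `n_ok` counts successful refits (the finite-sample
#' correction keeps p strictly positive). Refit failures are counted; more
#' than 10% invalidates the test.
#'
#' @param full,reduced [model_spec()]s (with `data`) or fitted
#'   [fit_lmm()]/[fit_glmm_binomial()] objects; REML fits are refitted by
#'   ML. The reduced model must be nested in the full model.
#' @param data data.frame, required when specs are passed.
#' @param n_sim number of bootstrap simulations (default 200; use 1000 for
#'   final analyses).
#' @param seed integer seed; the test is deterministic given it.
#' @param engine "devfun" (fast in-place response swap on the lme4
#'   deviance function) or "refit" (lme4::refit); the engines agree up to
#'   optimizer tolerance.
#' @return Object of class `"pb_test"`: observed statistic, simulated
#'   statistics, count, p-value, failure count, validity flag.
#' @export
pb_modcomp <- function(full, reduced, data = NULL, n_sim = 200, seed = 1,
                       engine = c("devfun", "refit")) {
  engine <- match.arg(engine)
  full <- as_ml_fit(full, data)
  reduced <- as_ml_fit(reduced, data)
  check_nesting(full, reduced)
  t_obs <- max(0, 2 * (full$logLik - reduced$logLik))
  sims <- with_seed(derive_seed(seed, 7),
                    simulate(reduced$model, nsim = n_sim))
  t_star <- rep(NA_real_, n_sim)
  if (engine == "devfun") {
    df_full <- build_devfun(full$model)
    df_red <- build_devfun(reduced$model)
    for (b in seq_len(n_sim)) {
      t_star[b] <- tryCatch({
        y <- as.numeric(sims[[b]])
        max(0, min_deviance(df_red, y) - min_deviance(df_full, y))
      }, error = function(e) NA_real_)
    }
  } else {
    for (b in seq_len(n_sim)) {
      t_star[b] <- tryCatch({
        y <- sims[[b]]
        rf <- suppressMessages(suppressWarnings(lme4::refit(reduced$model, y)))
        ff <- suppressMessages(suppressWarnings(lme4::refit(full$model, y)))
        max(0, 2 * (as.numeric(logLik(ff)) - as.numeric(logLik(rf))))
      }, error = function(e) NA_real_)
    }
  }
  n_fail <- sum(is.na(t_star))
  ok <- t_star[!is.na(t_star)]
  count <- sum(ok >= t_obs - 1e-6)
  p <- (count + 1) / (length(ok) + 1)
  structure(list(stat = t_obs, n_sim = n_sim, n_ok = length(ok),
                 n_fail = n_fail, count = count, p = p, seed = seed,
                 valid = n_fail <= 0.1 * n_sim,
                 t_star = ok),
            class = "pb_test")
}

#' @export
print.pb_test <- function(x, ...) {
  cat(sprintf("Parametric bootstrap LRT: stat = %.3f, p = %.4f (%d sims%s)\n",
              x$stat, x$p, x$n_ok,
              if (x$n_fail) sprintf(", %d refits failed", x$n_fail) else ""))
  if (!x$valid) cat("WARNING: > 10% refit failures; test invalid\n")
  invisible(x)
}
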