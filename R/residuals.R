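# Simulated quantile residuals: the observed value's quantile within
# posterior-predictive simulations of the fitted model (new random-effect
# draws), uniform under a well-specified model.

#' Simulated quantile residuals for a mixed-model fit
#'
#' For each observation, simulates `n_sim` replicate responses from the
#' fitted model (unconditional on the estimated random effects, i.e. with
#' new random-effect draws) and records the quantile of the observed value
#' within its simulated distribution, using mid-ranks for ties so the
#' result is deterministic given the seed. Under a well-specified model the
#' quantiles are approximately standard uniform; a Kolmogorov-Smirnov
#' uniformity test summarizes the diagnostic.
#'
#' @param fit a [fit_lmm()]/[fit_glmm_binomial()] result.
#' @param n_sim number of simulations per observation (250).
#' @param seed integer seed.
#' @return Object of class `"quantile_residuals"`: `quantiles` (one per
#'   observation, in (0, 1)), `ks_stat`, `ks_p`, `n_sim`, `seed`.
#' @export
simulate_quantile_residuals <- function(fit, n_sim = 250, seed = 1) {
  if (!inherits(fit, "keel_fit")) err_input("fit must be a keel_fit")
  model <- fit$model
  sims <- with_seed(derive_seed(seed, 11),
                    simulate(model, nsim = n_sim))
  sims <- as.matrix(as.data.frame(sims))
  y <- model@resp$y
  below <- rowSums(sims < y)
  ties <- rowSums(sims == y)
  q <- (below + (ties + 1) / 2) / (n_sim + 1)
  ks <- suppressWarnings(ks.test(q, "punif"))
  structure(list(quantiles = q, ks_stat = unname(ks$statistic),
                 ks_p = ks$p.value, n_sim = n_sim, seed = seed),
            class = "quantile_residuals")
}

#' @export
print.quantile_residuals <- function(x, ...) {
  cat(sprintf(
    "Simulated quantile residuals (%d sims): KS = %.4f, p = %.4f\n",
    x$n_sim, x$ks_stat, x$ks_p))
  invisible(x)
}

#' @export
plot.quantile_residuals <- function(x, ...) {
  n <- length(x$quantiles)
  plot.default(ppoints(n), sort(x$quantiles),
               xlab = "uniform quantiles", ylab = "observed quantiles",
               main = "Simulated quantile residuals", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}
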