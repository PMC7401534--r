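# Front-end modelling interface: one fitting function returning a classed
# object with the usual methods.

#' Fit a perch-transition outcome model
#'
#' Fits the study's hierarchical model for one response and one jump
#' direction: the response is transformed (inverse/log/identity per the
#' default transformation table, or as requested), modelled with fixed
#' effects from `formula` (by default the full distance x angle x hybrid
#' factorial) and random intercepts for pen, hen within pen, condition
#' within hen, and crossed calendar date. Binary balancing outcomes use a
#' binomial-logit mixed model. When `reduce = TRUE` the full model is
#' simplified by stepwise-backwards parametric-bootstrap reduction
#' ([backward_reduce()]; exclusion criterion p > `alpha`), ML is used for
#' all comparisons, and the final Gaussian model is refitted with REML for
#' reporting. Back-transformed effect estimates are computed for every
#' retained term, and simulated quantile residuals for the final fit.
#'
#' Analyses are always run separately per direction because the angle
#' classes mean different geometric angles for upward and downward jumps;
#' the model never pools directions.
#'
#' @param formula model formula, e.g. `pf_landing ~ distance * angle *
#'   hybrid`. The left-hand side names a column of `data`.
#' @param data analysis table (see [collect_analysis_table()]) with the
#'   response, the fixed-effect factors and grouping columns `pen`, `hen`,
#'   `condition_hen` (or `condition`, from which it is derived) and `date`.
#' @param direction "up" or "down".
#' @param family "gaussian" or "binomial"; by default binomial for the
#'   `balancing` response, gaussian otherwise.
#' @param transformation response transformation; defaults to the study's
#'   transformation table ([default_transformation()]) when the response
#'   name is recognized, identity otherwise.
#' @param reduce run the backward reduction? (`FALSE` keeps the full model.)
#' @param alpha exclusion criterion for the reduction.
#' @param n_sim parametric-bootstrap simulations per comparison (1000 for
#'   final analyses; smaller values speed up exploratory runs).
#' @param seed integer seed controlling every stochastic step.
#' @param n_sim_residuals simulations for the quantile-residual diagnostic.
#' @return Object of class `"keel_model"`.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_per_hybrid = 8, pens_per_hybrid = 2, n_jumps = 3)
#' roster <- simulate_roster(cfg)
#' sched <- make_schedule(roster, seed = 1)
#' truth <- draw_outcomes(sched, roster, cfg)
#' tab <- collect_analysis_table(truth_metrics(truth))
#' m <- keel_model(pf_landing ~ distance * angle * hybrid, tab,
#'                 direction = "up", n_sim = 49, seed = 1)
#' print(m)
#' }
#' @export
keel_model <- function(formula, data, direction = c("up", "down"),
                       family = NULL, transformation = NULL, reduce = TRUE,
                       alpha = 0.05, n_sim = 1000, seed = 1,
                       n_sim_residuals = 250) {
  direction <- match.arg(direction)
  response <- all.vars(formula[[2]])
  if (length(response) != 1) err_input("formula needs a single response")
  if (is.null(family)) {
    family <- if (response == "balancing") "binomial" else "gaussian"
  }
  if (is.null(transformation)) {
    transformation <- tryCatch(default_transformation(response, direction),
                               error = function(e) "identity")
    if (transformation == "binomial") transformation <- "identity"
  }
  data <- prepare_analysis_factors(data)
  fixed <- formula(delete.response(terms(formula)))
  spec <- model_spec(response, fixed = fixed, family = family,
                     transformation = transformation, direction = direction)
  reduction <- NULL
  final_spec <- spec
  if (reduce) {
    reduction <- backward_reduce(spec, data, alpha = alpha, n_sim = n_sim,
                                 seed = seed)
    final_spec <- reduction$spec
  }
  final_fit <- if (family == "gaussian") {
    fit_lmm(final_spec, data, reml = TRUE)
  } else {
    fit_glmm_binomial(final_spec, data)
  }
  labels <- attr(terms(final_spec$fixed), "term.labels")
  top <- droppable_terms(labels) # maximal retained terms
  effects <- lapply(top, function(t) {
    estimate_effects(final_fit, term_vars(t))
  })
  names(effects) <- top
  if (!length(effects)) {
    effects <- list(overall = estimate_effects(final_fit, character(0)))
  }
  diagnostics <- simulate_quantile_residuals(final_fit,
                                             n_sim = n_sim_residuals,
                                             seed = seed)
  structure(list(call = match.call(), response = response,
                 direction = direction, family = family,
                 transformation = transformation, alpha = alpha,
                 n_sim = n_sim, seed = seed,
                 full_spec = spec, reduction = reduction,
                 final_spec = final_spec, fit = final_fit,
                 effects = effects, diagnostics = diagnostics,
                 data = data),
            class = "keel_model")
}

#' Standardize the analysis-table factor columns
#'
#' Ensures `distance`, `angle`, `hybrid` are factors with the study's
#' reference levels (50 cm, flat, Nick Chick), and derives the
#' condition-within-hen grouping `condition_hen` when absent.
#'
#' @param data analysis table.
#' @return The data with normalized factor columns.
#' @export
prepare_analysis_factors <- function(data) {
  if ("distance_cm" %in% names(data) && !"distance" %in% names(data)) {
    data$distance <- data$distance_cm
  }
  if ("angle_class" %in% names(data) && !"angle" %in% names(data)) {
    data$angle <- data$angle_class
  }
  if ("distance" %in% names(data) && !is.factor(data$distance)) {
    d <- sub("\\s*cm$", "", as.character(data$distance))
    data$distance <- factor(paste0(d, " cm"), levels = c("50 cm", "100 cm"))
  }
  if ("angle" %in% names(data) && !is.factor(data$angle)) {
    data$angle <- factor(data$angle, levels = c("flat", "steep"))
  }
  if ("hybrid" %in% names(data) && !is.factor(data$hybrid)) {
    lv <- c("Nick Chick", "Brown Nick")
    data$hybrid <- factor(data$hybrid,
                          levels = c(intersect(lv, unique(data$hybrid)),
                                     setdiff(unique(data$hybrid), lv)))
  }
  if (!"hen" %in% names(data) && "hen_id" %in% names(data)) {
    data$hen <- data$hen_id
  }
  if (!"condition_hen" %in% names(data) && "hen" %in% names(data)) {
    if ("condition" %in% names(data)) {
      data$condition_hen <- interaction(data$hen, data$condition, drop = TRUE)
    } else if (all(c("distance", "angle") %in% names(data))) {
      data$condition_hen <- interaction(data$hen, data$distance, data$angle,
                                        drop = TRUE)
    }
  }
  if (!"date" %in% names(data) && "day" %in% names(data)) {
    data$date <- data$day
  }
  data
}

#' @export
print.keel_model <- function(x, ...) {
  cat(sprintf("Perch-transition model: %s, %sward jumps [%s%s]\n",
              x$response, x$direction, x$family,
              if (x$family == "gaussian")
                paste0(", ", x$transformation, " transformation") else ""))
  labels <- attr(terms(x$final_spec$fixed), "term.labels")
  cat("retained fixed effects:",
      if (length(labels)) paste(labels, collapse = ", ") else
        "(intercept only)", "\n")
  for (nm in names(x$effects)) {
    cat(nm, ":\n", sep = "")
    print(x$effects[[nm]], ...)
  }
  invisible(x)
}

#' @export
summary.keel_model <- function(object, ...) {
  structure(list(model = object), class = "summary.keel_model")
}

#' @export
print.summary.keel_model <- function(x, ...) {
  m <- x$model
  print(m)
  if (!is.null(m$reduction)) {
    cat("\n")
    print(m$reduction)
  }
  cat("\nfinal fit:\n")
  print(m$fit)
  cat("\n")
  print(m$diagnostics)
  invisible(x)
}

#' @export
coef.keel_model <- function(object, ...) lme4::fixef(object$fit$model)

#' Population-level predictions on the response scale
#'
#' @param object a [keel_model()].
#' @param newdata data.frame with the model's factor columns; defaults to
#'   the analysis data.
#' @param type "response" (back-transformed) or "link" (transformed scale).
#' @param ... unused.
#' @return Numeric vector of predictions (random effects set to zero).
#' @export
predict.keel_model <- function(object, newdata = NULL,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  frame <- object$fit$model@frame
  if (is.null(newdata)) newdata <- frame
  newdata <- prepare_analysis_factors(newdata)
  for (v in all.vars(object$final_spec$fixed)) {
    if (is.factor(frame[[v]])) {
      newdata[[v]] <- factor(newdata[[v]], levels = levels(frame[[v]]))
    }
  }
  X <- model.matrix(object$final_spec$fixed, newdata)
  beta <- lme4::fixef(object$fit$model)
  eta <- drop(X[, names(beta), drop = FALSE] %*% beta)
  if (type == "link") return(eta)
  if (object$family == "binomial") plogis(eta) else
    back_transform_values(eta, object$transformation)
}

#' Simulate responses from the fitted model
#'
#' Draws new random effects and residuals/Bernoulli outcomes from the final
#' fit and returns simulations on the response scale.
#'
#' @param object a [keel_model()].
#' @param nsim number of simulated response vectors.
#' @param seed integer seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns.
#' @export
simulate.keel_model <- function(object, nsim = 1, seed = NULL, ...) {
  sims <- with_seed(seed, simulate(object$fit$model, nsim = nsim))
  if (object$family == "gaussian") {
    sims[] <- lapply(sims, back_transform_values, object$transformation)
  }
  sims
}

#' Residuals of a perch-transition model
#'
#' @param object a [keel_model()].
#' @param type "quantile" (simulated quantile residuals, uniform under a
#'   correct model) or "response" (raw residuals on the transformed scale).
#' @param ... unused.
#' @return Numeric vector.
#' @export
residuals.keel_model <- function(object, type = c("quantile", "response"),
                                 ...) {
  type <- match.arg(type)
  if (type == "quantile") return(object$diagnostics$quantiles)
  residuals(object$fit$model)
}

#' Diagnostic plots for a perch-transition model
#'
#' Left: uniform QQ plot of the simulated quantile residuals. Right:
#' quantile residuals against fitted values.
#'
#' @param x a [keel_model()].
#' @param ... passed to the panel plots.
#' @export
plot.keel_model <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(x$diagnostics, ...)
  plot.default(fitted(x$fit$model), x$diagnostics$quantiles,
               xlab = "fitted (transformed scale)",
               ylab = "quantile residual",
               main = x$response, ...)
  abline(h = c(0.25, 0.5, 0.75), lty = 3)
  invisible(x)
}
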