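# Mixed-model fitting: Gaussian (lmer) and binomial-logit (glmer) models
# with the study's random structure -- random intercepts for pen, hen within
# pen, condition within hen, and crossed calendar date; the within-session
# jump index is the finest level and is absorbed into the residual for
# Gaussian models (it can be kept explicit for binomial models).

#' Declarative mixed-model specification
#'
#' @param response name of the response column (already on the analysis
#'   scale after `transformation` is applied by the fitting functions).
#' @param fixed right-hand-side formula of fixed effects, by default the
#'   full three-way factorial `~ distance * angle * hybrid`.
#' @param family "gaussian" or "binomial" (logit link).
#' @param transformation "identity", "log" or "inverse"; must be "identity"
#'   for the binomial family.
#' @param random character vector of random-intercept grouping columns, in
#'   nesting order. Defaults to `pen`, `hen`, `condition_hen` (the
#'   condition-within-hen level, one per test session) and the crossed
#'   `date`. Groupings with fewer than 2 observed levels are dropped with a
#'   message at fit time.
#' @param direction which direction subset the model is for ("up" or
#'   "down"); analyses never pool directions.
#' @param jump_re keep an explicit observation-level (jump) random
#'   intercept? Only meaningful for binomial models.
#' @return list of class `"model_spec"`.
#' @export
model_spec <- function(response, fixed = ~ distance * angle * hybrid,
                       family = c("gaussian", "binomial"),
                       transformation = "identity",
                       random = c("pen", "hen", "condition_hen", "date"),
                       direction = NULL, jump_re = NULL) {
  family <- match.arg(family)
  transformation <- match_enum(transformation,
                               c("identity", "log", "inverse"),
                               "transformation")
  if (family == "binomial" && transformation != "identity") {
    err_input("binomial models use the logit link; transformation must be identity")
  }
  if (is.null(jump_re)) jump_re <- family == "binomial"
  structure(list(response = response, fixed = fixed, family = family,
                 transformation = transformation, random = random,
                 direction = direction, jump_re = jump_re),
            class = "model_spec")
}

# enforce marginality: every term's lower-order marginal terms must be
# present
check_marginality <- function(fixed) {
  tl <- attr(terms(fixed), "term.labels")
  for (t in tl) {
    vars <- strsplit(t, ":", fixed = TRUE)[[1]]
    if (length(vars) > 1) {
      for (k in seq_len(length(vars) - 1)) {
        sub <- utils::combn(vars, k, simplify = FALSE)
        for (s in sub) {
          hit <- vapply(tl, function(u) {
            uv <- strsplit(u, ":", fixed = TRUE)[[1]]
            length(uv) == length(s) && setequal(uv, s)
          }, logical(1))
          if (!any(hit)) {
            err_input(sprintf(
              "model violates marginality: interaction %s present without %s",
              t, paste(s, collapse = ":")))
          }
        }
      }
    }
  }
  invisible(tl)
}

build_formula <- function(spec, data) {
  check_marginality(spec$fixed)
  groups <- spec$random
  used <- groups[vapply(groups, function(g) {
    # a grouping needs at least 2 levels, and fewer levels than rows --
    # a one-observation-per-level grouping is absorbed into the residual
    g %in% names(data) && length(unique(data[[g]])) >= 2 &&
      length(unique(data[[g]])) < nrow(data)
  }, logical(1))]
  dropped <- setdiff(groups, used)
  if (length(dropped)) {
    message("dropping unusable random groupings (< 2 levels or one ",
            "observation per level): ", paste(dropped, collapse = ", "))
  }
  if (spec$jump_re && "jump_obs" %in% names(data)) used <- c(used, "jump_obs")
  rhs <- paste(deparse(spec$fixed[[2]]), collapse = " ")
  if (length(used)) {
    rhs <- paste(rhs, paste(sprintf("(1 | %s)", used), collapse = " + "),
                 sep = " + ")
  }
  list(formula = as.formula(paste(".response_t ~", rhs)), groups = used)
}

prepare_model_frame <- function(spec, data) {
  if (!spec$response %in% names(data)) {
    err_input(paste("data lack response column", spec$response))
  }
  if (!is.null(spec$direction) && "direction" %in% names(data)) {
    data <- data[data$direction == spec$direction, , drop = FALSE]
  }
  vars <- all.vars(spec$fixed)
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    err_input(paste("data lack model columns:", paste(miss, collapse = ", ")))
  }
  keep <- !is.na(data[[spec$response]])
  data <- data[keep, , drop = FALSE]
  if (spec$jump_re) data$jump_obs <- seq_len(nrow(data))
  y <- data[[spec$response]]
  data$.response_t <- if (spec$family == "gaussian") {
    transform_values(y, spec$transformation)
  } else {
    if (!all(y %in% c(0, 1))) err_input("binomial response must be 0/1")
    y
  }
  data
}

new_keel_fit <- function(spec, model, reml) {
  singular <- lme4::isSingular(model, tol = 1e-4)
  msgs <- model@optinfo$conv$lme4$messages
  converged <- is.null(msgs) ||
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  vc <- as.data.frame(lme4::VarCorr(model))
  sep <- spec$family == "binomial" &&
    any(abs(lme4::fixef(model)) > 10)
  structure(list(spec = spec, model = model, reml = reml,
                 converged = converged, singular = singular,
                 separation = sep,
                 varcomp = vc[, c("grp", "sdcor")],
                 logLik = as.numeric(logLik(model)),
                 messages = msgs),
            class = "keel_fit")
}

#' Fit the Gaussian linear mixed model
#'
#' Maximizes the Gaussian mixed-model likelihood for the specified fixed
#' effects (on the transformed response scale) with random intercepts per
#' `spec$random`. ML (`reml = FALSE`) is used for all model comparisons;
#' REML for final reporting. Non-convergence is flagged, never silent;
#' singular fits (a variance component estimated at zero) are allowed and
#' flagged.
#'
#' @param spec a [model_spec()] with `family = "gaussian"`.
#' @param data data.frame containing the response, fixed-effect columns and
#'   grouping columns.
#' @param reml logical: REML (TRUE) or ML (FALSE, default).
#' @return Object of class `"keel_fit"`.
#' @export
fit_lmm <- function(spec, data, reml = FALSE) {
  if (spec$family != "gaussian") err_input("fit_lmm requires a gaussian spec")
  data <- prepare_model_frame(spec, data)
  bf <- build_formula(spec, data)
  model <- suppressMessages(lme4::lmer(
    bf$formula, data = data, REML = reml,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  new_keel_fit(spec, model, reml)
}

#' Fit the binomial-logit generalized linear mixed model
#'
#' Laplace-approximated ML fit of the logit mixed model with the same
#' random-intercept structure as the Gaussian models (plus, by default, an
#' explicit observation-level jump intercept). Complete separation is
#' detected heuristically (fixed effects running away on the logit scale)
#' and flagged.
#'
#' @inheritParams fit_lmm
#' @return Object of class `"keel_fit"`.
#' @export
fit_glmm_binomial <- function(spec, data) {
  if (spec$family != "binomial") {
    err_input("fit_glmm_binomial requires a binomial spec")
  }
  data <- prepare_model_frame(spec, data)
  bf <- build_formula(spec, data)
  model <- suppressMessages(lme4::glmer(
    bf$formula, data = data, family = binomial("logit"), nAGQ = 1,
    control = lme4::glmerControl(check.conv.singular = "ignore",
                                 calc.derivs = FALSE)))
  new_keel_fit(spec, model, reml = FALSE)
}

#' Fit a model spec (dispatching on family)
#' @inheritParams fit_lmm
#' @export
fit_spec <- function(spec, data, reml = FALSE) {
  if (spec$family == "gaussian") fit_lmm(spec, data, reml = reml)
  else fit_glmm_binomial(spec, data)
}

#' @export
print.keel_fit <- function(x, ...) {
  cat(sprintf("keel_fit: %s [%s, %s%s] %s\n", x$spec$response,
              x$spec$family, x$spec$transformation,
              if (x$reml) ", REML" else ", ML",
              if (!is.null(x$spec$direction))
                paste0("(", x$spec$direction, ")") else ""))
  cat("fixed effects:\n")
  print(round(lme4::fixef(x$model), 4))
  cat("random-effect sd:\n")
  print(x$varcomp, row.names = FALSE)
  if (!x$converged) cat("WARNING: fit did not converge\n")
  if (x$singular) cat("note: singular fit (some variance component at 0)\n")
  if (isTRUE(x$separation)) cat("WARNING: possible complete separation\n")
  invisible(x)
}

#' @export
coef.keel_fit <- function(object, ...) lme4::fixef(object$model)

#' @export
logLik.keel_fit <- function(object, ...) logLik(object$model)
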