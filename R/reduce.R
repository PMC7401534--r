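# Stepwise-backwards model reduction under marginality, with parametric-
# bootstrap tests (exclusion criterion p > alpha).

term_vars <- function(t) strsplit(t, ":", fixed = TRUE)[[1]]

# terms that may be dropped now: not marginal to any retained higher-order
# term
droppable_terms <- function(labels) {
  Filter(function(t) {
    tv <- term_vars(t)
    !any(vapply(labels, function(u) {
      uv <- term_vars(u)
      length(uv) > length(tv) && all(tv %in% uv)
    }, logical(1)))
  }, labels)
}

drop_term <- function(fixed, term) {
  labels <- setdiff(attr(terms(fixed), "term.labels"), term)
  if (length(labels)) reformulate(labels) else ~ 1
}

#' Stepwise-backwards reduction of the full model
#'
#' Starting from the full (three-way factorial) model, repeatedly tests
#' every currently droppable fixed term (those not marginal to a retained
#' higher-order interaction) with [pb_modcomp()] and removes the term with
#' the largest p-value if it exceeds `alpha`; stops when every droppable
#' term has p <= alpha. One term is removed per iteration and all models
#' are refitted before the next round. The trace records every test.
#'
#' @param spec full-model [model_spec()].
#' @param data analysis data.
#' @param alpha exclusion criterion: a term is dropped when its bootstrap
#'   p-value exceeds this (0.05).
#' @param n_sim bootstrap simulations per test.
#' @param seed integer seed (advanced deterministically across tests).
#' @return Object of class `"keel_reduction"`: `spec` (final model),
#'   `fit` (final ML fit), `trace` (data.frame of every test: iteration,
#'   term, statistic, n_sim, p, dropped).
#' @export
backward_reduce <- function(spec, data, alpha = 0.05, n_sim = 200, seed = 1) {
  if (alpha <= 0 || alpha >= 1) err_input("alpha must be in (0, 1)")
  current <- spec
  trace <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    labels <- attr(terms(current$fixed), "term.labels")
    cand <- droppable_terms(labels)
    if (!length(cand)) break
    full_fit <- fit_spec(current, data, reml = FALSE)
    tests <- lapply(seq_along(cand), function(i) {
      red_spec <- current
      red_spec$fixed <- drop_term(current$fixed, cand[i])
      red_fit <- fit_spec(red_spec, data, reml = FALSE)
      pb_modcomp(full_fit, red_fit, n_sim = n_sim,
                 seed = derive_seed(seed, iter, i))
    })
    ps <- vapply(tests, `[[`, numeric(1), "p")
    worst <- which.max(ps)
    dropped <- ps[worst] > alpha
    trace[[iter]] <- data.frame(
      iteration = iter, term = cand,
      stat = vapply(tests, `[[`, numeric(1), "stat"),
      n_sim = vapply(tests, `[[`, numeric(1), "n_ok"),
      p = ps,
      dropped = seq_along(cand) == worst & dropped,
      stringsAsFactors = FALSE)
    if (!dropped) break
    current$fixed <- drop_term(current$fixed, cand[worst])
  }
  final_fit <- fit_spec(current, data, reml = FALSE)
  structure(list(spec = current, fit = final_fit,
                 trace = do.call(rbind, trace)),
            class = "keel_reduction")
}

#' @export
print.keel_reduction <- function(x, ...) {
  labels <- attr(terms(x$spec$fixed), "term.labels")
  cat("Backward reduction (parametric bootstrap, largest p dropped per round)\n")
  if (!is.null(x$trace)) print(x$trace, row.names = FALSE, digits = 4)
  cat("retained fixed effects:",
      if (length(labels)) paste(labels, collapse = ", ") else "(intercept only)",
      "\n")
  invisible(x)
}
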