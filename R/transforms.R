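# Response transformations used by the analysis: identity, log and inverse
# (1/x). The inverse is order-reversing, so back-transformed interval
# endpoints must be swapped.

#' Transform / back-transform response values
#'
#' @param values numeric vector; must be positive for "log" and "inverse".
#' @param kind "identity", "log" or "inverse".
#' @return Transformed (or back-transformed) values.
#' @examples
#' transform_values(4, "inverse")      # 0.25
#' back_transform_values(0.25, "inverse") # 4
#' @export
transform_values <- function(values, kind = c("identity", "log", "inverse")) {
  kind <- match.arg(kind)
  if (kind != "identity") {
    bad <- which(!is.na(values) & values <= 0)
    if (length(bad)) {
      err_input(sprintf("%s transformation needs positive values; offending rows: %s",
                        kind, paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  switch(kind, identity = values, log = log(values), inverse = 1 / values)
}

#' @rdname transform_values
#' @export
back_transform_values <- function(values, kind = c("identity", "log",
                                                   "inverse")) {
  kind <- match.arg(kind)
  if (kind == "inverse") {
    bad <- which(!is.na(values) & values <= 0)
    if (length(bad)) {
      err_input(sprintf("inverse back-transformation needs positive values; offending rows: %s",
                        paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  switch(kind, identity = values, log = exp(values), inverse = 1 / values)
}

#' Back-transform a confidence interval to the response scale
#'
#' Applies the inverse transformation to both endpoints and swaps them when
#' the mapping is order-reversing (the "inverse" kind), so that
#' `lower <= upper` always holds on the response scale.
#'
#' @param lower,upper interval endpoints on the transformed scale.
#' @param kind "identity", "log" or "inverse".
#' @return list with `lower` and `upper` on the response scale.
#' @export
back_transform_interval <- function(lower, upper, kind = c("identity", "log",
                                                           "inverse")) {
  kind <- match.arg(kind)
  lo <- back_transform_values(lower, kind)
  hi <- back_transform_values(upper, kind)
  if (kind == "inverse") list(lower = hi, upper = lo) else
    list(lower = lo, upper = hi)
}

#' Default response transformation table
#'
#' The analysis transforms each response before Gaussian mixed modelling:
#' peak forces are inverse-transformed; take-off impulse is untransformed
#' for upward jumps and log-transformed for downward jumps; landing impulse
#' and both latencies are log-transformed; balancing is binary (no
#' transformation, binomial-logit family).
#'
#' @param response one of "pf_takeoff", "pf_flight", "pf_landing",
#'   "imp_takeoff", "imp_landing", "lat_jump", "lat_peck", "balancing".
#' @param direction "up" or "down".
#' @return The transformation name, or "binomial" for balancing.
#' @export
default_transformation <- function(response, direction = c("up", "down")) {
  direction <- match.arg(direction)
  switch(response,
         pf_takeoff = , pf_flight = , pf_landing = "inverse",
         imp_takeoff = if (direction == "up") "identity" else "log",
         imp_landing = , lat_jump = , lat_peck = "log",
         balancing = "binomial",
         err_input(paste("unknown response:", response)))
}
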