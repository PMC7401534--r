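# Internal helpers: classed error conditions and seed management.

pj_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "perchjump_error")))
}

err_input <- function(msg, ...) pj_stop("perchjump_input_error", msg, ...)
err_format <- function(msg, ...) pj_stop("perchjump_format_error", msg, ...)
err_alignment <- function(msg, ...) pj_stop("perchjump_alignment_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic small-integer sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  x <- 0
  for (p in parts) x <- (x * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(x)
}

gcd_int <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

match_enum <- function(x, choices, what) {
  if (length(x) != 1L || is.na(x) || !x %in% choices) {
    err_input(sprintf("%s must be one of: %s (got '%s')",
                      what, paste(choices, collapse = ", "),
                      paste(x, collapse = ",")))
  }
  x
}
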