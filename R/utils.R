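#' Round half away from zero
#'
#' Deterministic rounding used wherever fractional expected counts are turned
#' into integers (e.g. expected de novo counts per gene): halves round away
#' from zero, so `round_half_up(0.5) == 1`, unlike [base::round()]'s
#' round-half-even. Lower bounding at zero is left to the caller.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4, -0.5))
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Six classifier covariates, in canonical order.
covariate_names <- function() {
  c("af", "loeuf", "ccr", "fdr_tada_dd", "obs_lof", "exp_lof")
}

# Scoped RNG: evaluates expr under a fixed seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tadard <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_fraction <- function(x, name, allow_na = FALSE) {
  bad <- if (allow_na) !is.na(x) & (x < 0 | x > 1) else is.na(x) | x < 0 | x > 1
  if (any(bad)) {
    stop_tadard("`%s` must lie in [0, 1]; offending value(s): %s",
                name, paste(utils::head(x[bad], 3), collapse = ", "))
  }
  invisible(x)
}
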