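# Internal helpers: classed conditions and seeded evaluation.

tz_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "tz_error"), call = call))
}

# domain / validation errors share a class so the CLI can map them to exit 2
tz_domain_error <- function(msg) tz_error(msg, "tz_domain_error")
tz_insufficient_data <- function(msg) tz_error(msg, "tz_insufficient_data")
tz_degenerate_error <- function(msg) tz_error(msg, "tz_degenerate_error")
tz_range_error <- function(msg) tz_error(msg, "tz_range_error")
tz_parse_error <- function(msg) tz_error(msg, "tz_parse_error")
tz_protocol_error <- function(msg) tz_error(msg, "tz_protocol_error")
tz_calibration_failure <- function(msg) tz_error(msg, "tz_calibration_failure")

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    tz_domain_error(sprintf("`%s` must be a single finite number", name))
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    tz_domain_error(sprintf(
      "`%s` = %g outside admissible range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"))
  invisible(x)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed))
    tz_domain_error("a finite integer `seed` is required for stochastic operations")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a distinct but reproducible child seed, kept inside 32-bit range
child_seed <- function(seed, k) {
  (as.integer(seed) * 69069L + as.integer(round(k * 1009))) %% 2147483587L
}
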