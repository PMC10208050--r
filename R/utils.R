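# internal helpers shared across modules

# stop with a classed condition so tests can target specific failures
stop_cernet <- function(msg, class = "cernet_error", ...) {
  rlang::abort(msg, class = c(class, "cernet_error"), ...)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_cernet(sprintf("`%s` must be a single finite number", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_cernet(sprintf(
      "`%s` = %s is outside %s%s, %s%s", name, format(x),
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop_cernet(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# deterministic RNG scope: every stochastic entry point funnels through here
with_rng <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
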