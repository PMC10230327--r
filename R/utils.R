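# Internal helpers: argument checking and local RNG scoping.

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop_invalid("`%s` is required and was not supplied", name)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stop_invalid("`%s` = %g is outside [%g, %g]", name, x, lower, upper)
  }
  invisible(x)
}

check_wavelengths <- function(wl, name = "wavelengths") {
  if (length(wl) == 0L) stop_invalid("`%s` must not be empty", name)
  if (!is.numeric(wl) || anyNA(wl) || any(!is.finite(wl))) {
    stop_invalid("`%s` must be finite numeric values", name)
  }
  if (length(wl) > 1L && any(diff(wl) <= 0)) {
    stop_invalid("`%s` must be strictly increasing", name)
  }
  invisible(wl)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream. Every stochastic generator in the package funnels through this.
with_local_seed <- function(seed, expr) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed)) {
    stop_invalid("a single integer `seed` is required for stochastic output")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}
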