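# Internal helpers shared across modules.

# Consistent error signalling: all user-facing input errors are
# condition class "haloquant_error" (plus a specific subclass) so tests
# and the CLI can distinguish bad input from programming errors.
stop_haloquant <- function(msg, class) {
  stop(structure(
    class = c(class, "haloquant_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         class = "invalid_parameter") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_haloquant(sprintf("`%s` must be a single finite number", name), class)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_haloquant(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), class)
  }
  invisible(x)
}

# Run `expr` under a fixed RNG seed, restoring (or clearing) the global
# seed afterwards: generators are deterministic given `seed` and leave
# no hidden state behind.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_haloquant("`seed` must be a single finite number", "invalid_parameter")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half up to a multiple
#'
#' Rounds `x` to the nearest multiple of `to`, with exact halves rounded
#' up (away from zero for positive input). This is the convention that
#' turns the mean of two method-level estimates into the published final
#' averages (e.g. mean(104900, 114600) = 109750 -> 109800).
#'
#' @param x numeric vector.
#' @param to positive multiple to round to (default 100).
#' @return numeric vector of rounded values.
#' @export
round_half_up <- function(x, to = 100) {
  check_number(to, "to", lower = 0, strict_lower = TRUE)
  floor(x / to + 0.5) * to
}

# Sample (n-1) standard deviation with the single-value convention used
# throughout: one replicate reports std 0 and a flag, not NA.
sample_sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
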