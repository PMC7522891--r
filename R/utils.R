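#' @keywords internal
"_PACKAGE"

# Internal assertion helpers. Errors name the offending argument so that
# config-validation messages are path-qualified.

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf(
      "`%s` = %g is outside the valid interval %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

#' Derive a reproducible per-unit RNG seed from a master seed and a label
#'
#' One master seed governs a whole simulated experiment; every track,
#' replicate and condition derives its own stream seed by stable hashing of
#' `(master, label)`, so results do not depend on generation order.
#'
#' @param master Master seed (integer).
#' @param ... Further components (numbers or strings) identifying the unit,
#'   e.g. a track id or a `marker/condition/replicate` label.
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  parts <- c(as.character(master), vapply(list(...), as.character, character(1)))
  h <- 0
  for (p in parts) {
    for (code in utf8ToInt(paste0(p, "|"))) {
      # 31-based rolling hash mod the Mersenne prime 2^31 - 1
      h <- (h * 31 + code) %% 2147483647
    }
  }
  as.integer(h %% 2147483645L + 1L)
}

# Evaluate expr with a locally-derived seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
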