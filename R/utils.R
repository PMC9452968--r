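# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded simulation helpers do not perturb the global
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministically derive a stream seed from a base seed and integer keys.
# Kept below 2^31 - 1 so the result is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  x <- as.double(seed %% 2147483647L)
  for (k in keys) {
    x <- (x * 48271 + as.double(k) + 1) %% 2147483629
  }
  as.integer(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a finite numeric scalar", name)
  }
  if (x < lower || x > upper) {
    stopf("'%s' must be in [%g, %g] (got %g)", name, lower, upper, x)
  }
  invisible(x)
}

# Stationary AR(1) series with marginal standard deviation `sd`.
ar1_series <- function(n, phi, sd) {
  if (sd <= 0 || n == 0L) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- stats::rnorm(n, 0, innov_sd)
  e[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(e, phi, method = "recursive"))
}


is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
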