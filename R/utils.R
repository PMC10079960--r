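## Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's random-number stream.
#'
#' @param seed integer seed, or NULL to leave the stream untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
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
  set.seed(as.integer(seed))
  expr
}

## logistic that never overflows: exp() of a large negative only; NA in, NA out
plogis_safe <- function(h) {
  p <- rep(NA_real_, length(h))
  pos <- which(h >= 0)
  neg <- which(h < 0)
  p[pos] <- 1 / (1 + exp(-h[pos]))
  eh <- exp(h[neg])
  p[neg] <- eh / (1 + eh)
  p
}

## clamp probabilities away from 0/1 before taking logs
clamp_p <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
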