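#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so generators are pure functions of their arguments
#' and never perturb a user's random stream. With `seed = NULL` the
#' expression runs against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# trapezoidal integral; thin wrapper so the integration rule lives in one place
trapz_integral <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  pracma::trapz(x, y)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
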