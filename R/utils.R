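#' @import methods
#' @importFrom stats phyper quantile dist hclust rbinom runif
#' @importFrom utils write.table head tail
NULL

# Run expr with a locally seeded RNG; the caller's RNG state is untouched.
# seed = NULL runs expr under the current global stream.
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

# scalar type guards -------------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, minimum = 1L) {
  assert_scalar_number(x, name, lower = minimum)
  if (x != as.integer(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(as.integer(x))
}

assert_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(sprintf("'%s' must be a non-empty string", name), call. = FALSE)
  invisible(x)
}

# midpoint of a 0-based half-open interval, in base pairs
interval_midpoint <- function(start, end) (start + end) / 2
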