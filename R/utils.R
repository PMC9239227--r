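#' @import methods
#' @importFrom stats setNames
NULL

## Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
## state afterwards so seeded helpers never perturb an outer simulation.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

## Linear interpolation returning the earliest x at which the non-decreasing
## curve y reaches `target`; NA if never reached.
first_crossing <- function(x, y, target) {
  if (y[1] >= target) return(x[1])
  idx <- which(y >= target)
  if (length(idx) == 0L) return(NA_real_)
  k <- idx[1]
  x0 <- x[k - 1]; x1 <- x[k]; y0 <- y[k - 1]; y1 <- y[k]
  if (y1 == y0) return(x1)
  x0 + (target - y0) / (y1 - y0) * (x1 - x0)
}
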