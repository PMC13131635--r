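#' @useDynLib thetagamma, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd var cor fft rnorm runif rpois lm coef approx spline
#'   convolve quantile median nextn lsfit rbinom
#' @importFrom utils head tail read.csv write.csv
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG so generators do not perturb the session stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Wrap angles into (-pi, pi]
#'
#' @param x angles in radians.
#' @return angles wrapped to the interval (-pi, pi].
#' @export
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}
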