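#' Wrap angles to [-pi, pi)
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval `[-pi, pi)`.
#' @export
wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Wrapped finite differences of an angle series
#'
#' @param theta angle series in radians.
#' @param lag integer step lag.
#' @return wrapped differences `theta[t] - theta[t - lag]`, length
#'   `length(theta) - lag`.
#' @export
wrap_diff <- function(theta, lag = 1L) {
  n <- length(theta)
  if (lag >= n) stop("lag must be smaller than the series length")
  wrap_angle(theta[(lag + 1L):n] - theta[1L:(n - lag)])
}

#' Shortest-arc angular distance
#'
#' @param a,b angles in radians.
#' @return `|wrap(a - b)|`, in `[0, pi]`.
#' @export
circ_dist <- function(a, b) {
  abs(wrap_angle(a - b))
}

# sample skewness (moment estimator m3 / m2^{3/2})
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

# trapezoidal weights for a uniform grid of n points with spacing h
trapz_weights <- function(n, h) {
  w <- rep(h, n)
  w[c(1L, n)] <- h / 2
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
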