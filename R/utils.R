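#' Wrap angles onto the principal branch
#'
#' Maps angles in degrees onto the interval (-180, +180], the branch used
#' throughout the package (Ramachandran convention).
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, each value in (-180, 180].
#' @export
#' @examples
#' wrap_angle(c(190, -190, 360, 180, -180))
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Log-spaced grid
#'
#' `n` points spanning `[from, to]` uniformly in log space; the frequency
#' grids used for Laplace-domain curves.
#'
#' @param from,to Positive endpoints, `from < to`.
#' @param n Number of points.
#' @return Numeric vector of length `n`.
#' @export
logspace <- function(from, to, n) {
  stopifnot(from > 0, to > from, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}

#' Composite trapezoid quadrature
#'
#' @param x Grid (uniform or not), increasing.
#' @param y Integrand values at `x`.
#' @return The trapezoid estimate of the integral.
#' @export
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# circular mean of angles in degrees, result in (-180, 180]
circular_mean <- function(x) {
  r <- x * pi / 180
  wrap_angle(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tdcf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "tdcf_error")))
}
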