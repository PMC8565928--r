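#' @importFrom rlang %||% .data
#' @importFrom stats approx quantile rlnorm runif rnorm sd var median
#' @importFrom utils head tail
NULL

deg2rad <- function(d) d * pi / 180

#' Gaussian smoothing with edge renormalization
#'
#' Convolves a series with a Gaussian kernel, renormalizing the kernel mass
#' at the edges so that constant inputs are preserved everywhere.
#'
#' @param x numeric vector.
#' @param sigma kernel standard deviation in samples.
#' @param na_zero treat NA as missing (excluded from the local average)?
#' @return smoothed numeric vector, same length as `x`.
#' @keywords internal
gauss_smooth <- function(x, sigma, na_zero = FALSE) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  n <- length(x)
  ok <- !is.na(x)
  xx <- ifelse(ok, x, 0)
  num <- stats::filter(c(rep(0, half), xx, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), as.numeric(ok), rep(0, half)), k, sides = 2)
  num <- num[(half + 1):(half + n)]
  den <- den[(half + 1):(half + n)]
  out <- as.numeric(num / den)
  out[den == 0] <- NA_real_
  out
}

# linear interpolation clamped at the ends
interp1 <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
}

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
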