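#' @useDynLib gaitretrain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Polynomial coefficients (descending powers) from roots, leading coef 1.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Design a digital Butterworth filter
#'
#' Designs low-pass, high-pass or band-pass Butterworth coefficients by the
#' standard analog-prototype / bilinear-transform route with frequency
#' prewarping, returning transfer-function coefficients normalized so that
#' `a[1] == 1`.
#'
#' @param order Filter order of the underlying one-pass design. For
#'   `type = "band"` the resulting transfer function has order `2 * order`.
#' @param cutoff Cutoff frequency in Hz (length 2 for `type = "band"`).
#' @param rate Sampling rate in Hz.
#' @param type One of `"low"`, `"high"`, `"band"`.
#' @return A list with numeric vectors `b` (numerator) and `a` (denominator).
#' @export
butter_design <- function(order, cutoff, rate, type = c("low", "high", "band")) {
  type <- match.arg(type)
  if (order < 1 || order != round(order)) stop("`order` must be a positive integer")
  if (rate <= 0) stop("`rate` must be positive")
  W <- cutoff / (rate / 2)
  if (type == "band" && length(W) != 2L) stop("band-pass needs two cutoff frequencies")
  if (type != "band" && length(W) != 1L) stop("low/high-pass need one cutoff frequency")
  if (any(W <= 0) || any(W >= 1))
    stop("cutoff frequencies must lie strictly between 0 and the Nyquist rate")

  fs <- 2
  warped <- 2 * fs * tan(pi * W / fs)
  # analog Butterworth prototype: poles on the unit left half circle
  m <- seq(-order + 1, order - 1, by = 2)
  p <- -exp(1i * pi * m / (2 * order))
  z <- complex(0)
  k <- 1

  if (type == "low") {
    p <- warped * p
    k <- k * warped^order
  } else if (type == "high") {
    k <- k * Re(prod(-p))
    p <- warped / p
    z <- rep(0 + 0i, order)
  } else {
    wo <- sqrt(warped[1] * warped[2])
    bw <- warped[2] - warped[1]
    p <- p * bw / 2
    p <- c(p + sqrt(p^2 - wo^2), p - sqrt(p^2 - wo^2))
    z <- rep(0 + 0i, order)
    k <- k * bw^order
  }

  # bilinear transform at sampling rate fs
  fs2 <- 2 * fs
  k <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c(zd, rep(-1 + 0i, length(p) - length(z)))

  b <- Re(k * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b / a[1], a = a / a[1])
}

# Steady-state initial conditions for a unit-step input (lfilter_zi analogue),
# so that filtering a constant produces that constant from sample one.
filter_zi <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (n == 1L) return(numeric(0))
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1] / a[1]
  if (n > 2L) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  IminusA <- diag(n - 1) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies an IIR filter forward and backward with odd-reflection edge padding
#' and steady-state initial conditions, cancelling phase distortion. The
#' magnitude response is applied twice, so a design-order-`n` Butterworth
#' behaves as an order-`2n` magnitude response with zero net phase.
#'
#' @param coefs List with `b` and `a`, e.g. from [butter_design()].
#' @param x Numeric vector to filter.
#' @return Filtered vector, same length as `x`.
#' @export
filtfilt_zp <- function(coefs, x) {
  b <- coefs$b; a <- coefs$a
  if (anyNA(x)) stop("input contains NA/NaN")
  padlen <- 3L * (max(length(a), length(b)) - 1L)
  n <- length(x)
  if (n <= padlen)
    stop("signal too short for zero-phase filtering: need more than ",
         padlen, " samples, got ", n)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- filter_zi(b, a)
  y <- .iir_filter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- .iir_filter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

# |H(f)|^2 magnitude response of forward-backward Butterworth low-pass:
# single pass is 1 / sqrt(1 + (f/fc)^(2n)); two passes square it.
# Used by tests as a closed-form oracle; exported for documentation purposes.
#' Theoretical magnitude response of a zero-phase Butterworth low-pass
#'
#' @param f Frequency in Hz.
#' @param cutoff Cutoff frequency in Hz.
#' @param order Design order of the one-pass filter.
#' @return Gain of the forward-backward filter at `f` (dimensionless).
#' @export
butter_zp_gain <- function(f, cutoff, order) {
  1 / (1 + (f / cutoff)^(2 * order))
}
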