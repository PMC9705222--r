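# Small FFT/axis helpers shared across the pipeline.
#
# Depth-axis convention: the centered normalized depth axis zbar has DC
# (zero-delay) at index floor(N/2) + 1, negative depths to the left, and
# positive zbar corresponds to positive analytic frequency.

#' Reorder an FFT vector so zero frequency sits at the centre
#'
#' Moves the DC bin of an FFT-ordered vector to index `floor(n/2) + 1`,
#' matching the centered normalized depth axis returned by [zbar_axis()].
#'
#' @param x vector in standard FFT order (DC first).
#' @return vector reordered to the centered axis.
#' @seealso [ifftshift()] for the inverse reordering.
#' @export
fftshift <- function(x) {
  n <- length(x)
  m <- ceiling(n / 2)
  c(x[(m + 1):n], x[1:m])
}

#' Undo [fftshift()]
#'
#' @param x vector on the centered axis (DC at `floor(n/2) + 1`).
#' @return vector in standard FFT order.
#' @export
ifftshift <- function(x) {
  n <- length(x)
  m <- floor(n / 2)
  c(x[(m + 1):n], x[1:m])
}

# inverse DFT with 1/n normalisation (base R fft(inverse=TRUE) is unnormalised)
ifft <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Unwrap a phase vector
#'
#' Sequentially removes 2*pi discontinuities: every first difference is mapped
#' into (-pi, pi] before cumulative summation. This is the standard unwrap with
#' a pi jump threshold, adequate for single-reflector calibration data where
#' the true phase is close to linear in sample index.
#'
#' @param p numeric vector of wrapped phases (radians).
#' @return numeric vector of unwrapped phases; `p[1]` is preserved.
#' @export
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  p[1] + c(0, cumsum(d))
}

# wrap scalar/vector into (-pi, pi]
wrap_pi <- function(x) x - 2 * pi * round(x / (2 * pi))
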