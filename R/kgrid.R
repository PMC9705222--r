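# Wavenumber grid and normalized depth axis.

#' Normalized depth axis
#'
#' Builds the normalized z-axis used throughout the package in place of
#' absolute depths in millimetres. For an A-line of `N` samples the axis is
#' `[-pi/2, pi/2 - pi/N]` with spacing `pi/N` when `N` is even (so it contains
#' 0 exactly, at index `floor(N/2) + 1`), and `[-pi/2, pi/2]` with spacing
#' `pi/(N - 1)` when `N` is odd. Depth bin `b` (0-based, centered) maps to
#' `zbar = (b - floor(N/2)) * pi / N` for even `N`.
#'
#' @param N integer sample count per A-line (`N >= 2`).
#' @return numeric vector of length `N`.
#' @export
zbar_axis <- function(N) {
  qc_check(length(N) == 1 && is.finite(N) && N == round(N) && N >= 2,
           "N must be a single integer >= 2", "qc_size_error")
  N <- as.integer(N)
  if (N %% 2L == 0L) {
    (seq_len(N) - 1L - N %/% 2L) * pi / N
  } else {
    seq(-pi / 2, pi / 2, length.out = N)
  }
}

#' Construct a wavenumber grid
#'
#' A `kgrid` couples a linearly spaced (k-linear) wavenumber axis with the
#' matching centered normalized depth axis. Even `N` is recommended: only then
#' does the depth axis contain zero-delay exactly and align with DFT bins.
#'
#' @param N integer sample count per A-line, at least 8.
#' @param k_min,k_max range of the wavenumber axis (arbitrary units; the
#'   pipeline only ever uses the axis through normalized coordinates).
#' @return object of class `kgrid` with fields `N`, `k`, `zbar`.
#' @examples
#' g <- make_kgrid(256)
#' g$zbar[g$N / 2 + 1]  # zero-delay
#' @export
make_kgrid <- function(N, k_min = 1, k_max = 2) {
  qc_check(length(N) == 1 && is.finite(N) && N == round(N) && N >= 8,
           "N must be a single integer >= 8", "qc_size_error")
  qc_check(k_max > k_min, "k_max must exceed k_min", "qc_size_error")
  N <- as.integer(N)
  structure(
    list(N = N, k = seq(k_min, k_max, length.out = N), zbar = zbar_axis(N)),
    class = "kgrid"
  )
}

#' @export
print.kgrid <- function(x, ...) {
  cat(sprintf("<kgrid> N = %d, k in [%g, %g], zbar in [%g, %g]\n",
              x$N, x$k[1], x$k[x$N], x$zbar[1], x$zbar[x$N]))
  invisible(x)
}

# index of zero-delay on the centered axis (exact for even N)
dc_index <- function(grid) grid$N %/% 2L + 1L

# scaled k in [-1, 1]; presets and fits use this normalized coordinate
k_unit <- function(grid) {
  k <- grid$k
  2 * (k - k[1]) / (k[length(k)] - k[1]) - 1
}

# zbar scaled to [-1, 1]
z_unit <- function(zbar) zbar / (pi / 2)
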