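# Quadrature reconstruction and depth-domain assembly.

#' Quadrature-geometry coefficients
#'
#' The ideal quadrature component can be written as a linear combination
#' `S_Q = a * S_II - b * S_I` of the two measured signals; solving the vector
#' geometry gives `a = beta / sin(dphi)` and `b = cos(dphi) / sin(dphi)`.
#' Valid whenever `dphi` stays away from 0 and pi — which is what makes the
#' same reconstruction usable for, say, the 120-degree offsets of 3x3 fiber
#' couplers, not just near-quadrature hybrids.
#'
#' @param beta amplitude ratio (channel I over channel II).
#' @param dphi phase offset (radians); `|sin(dphi)|` must exceed `min_sin`.
#' @param min_sin conditioning threshold.
#' @return list with scalars (or vectors) `a` and `b`.
#' @export
quadrature_geometry <- function(beta, dphi, min_sin = 0.1) {
  qc_check(all(abs(sin(dphi)) >= min_sin),
           "dphi too close to 0 or pi: reconstruction ill-conditioned",
           "qc_conditioning_error")
  list(a = beta / sin(dphi), b = cos(dphi) / sin(dphi))
}

#' Reconstruct the perfect quadrature signal
#'
#' Pointwise over wavenumber:
#' `S_Q = (beta_k * S_II_corr - cos(dphi_k) * S_I) / sin(dphi_k)`,
#' where `S_II_corr` is the spatially corrected channel II. With exact
#' imbalance vectors this identity is exact sample-by-sample (it is plain
#' trigonometry, not an approximation).
#'
#' @param s_I real channel-I signal.
#' @param s_II_corr real, spatially corrected channel-II signal.
#' @param beta_k,dphi_k chromatic imbalance vectors (scalars are recycled).
#' @param min_sin conditioning threshold on `|sin(dphi_k)|`.
#' @return real vector `S_Q` in exact quadrature with `s_I`.
#' @export
reconstruct_quadrature <- function(s_I, s_II_corr, beta_k, dphi_k, min_sin = 0.1) {
  qc_check(length(s_I) == length(s_II_corr), "inputs must share a length",
           "qc_shape_error")
  qc_check(all(abs(sin(dphi_k)) >= min_sin),
           "dphi_k too close to 0 or pi: reconstruction ill-conditioned",
           "qc_conditioning_error")
  (beta_k * s_II_corr - cos(dphi_k) * s_I) / sin(dphi_k)
}

#' Precompute the recurring reconstruction factors
#'
#' For repeated (e.g. real-time) use of one correction set: the spatial
#' phasor on the FFT-ordered axis and the two chromatic combination vectors
#' of the quadrature formula.
#'
#' @param cs a `correction_set`.
#' @param min_sin conditioning threshold.
#' @return list with `cz` (complex, FFT order), `a_k`, `b_k`.
#' @export
precompute_factors <- function(cs, min_sin = 0.1) {
  qc_check(all(abs(sin(cs$dphi_k)) >= min_sin),
           "dphi_k too close to 0 or pi: reconstruction ill-conditioned",
           "qc_conditioning_error")
  list(cz = ifftshift(cs$beta_z * exp(1i * cs$dphi_z)),
       a_k = cs$beta_k / sin(cs$dphi_k),
       b_k = cos(cs$dphi_k) / sin(cs$dphi_k))
}

new_depth_profile <- function(values, grid, ref = 1) {
  mag <- Mod(values)
  structure(list(values = values, zbar = grid$zbar, grid = grid,
                 db = 20 * log10(pmax(mag, .Machine$double.xmin) / ref),
                 ref = ref),
            class = "depth_profile")
}

#' Reconstruct a depth profile (A-line)
#'
#' Assembles the depth-domain complex A-line from a two-channel measurement.
#' Three modes mirror the usual processing comparison:
#' `"standard"` — FFT of channel I alone (real signal; mirror artifact fully
#' present), `"direct"` — FFT of `s_I + i * s_II` with no correction, and
#' `"calibrated"` — spatial correction of channel II, quadrature
#' reconstruction with the chromatic vectors, then FFT of `s_I + i * S_Q`.
#' The spatial correction multiplies the analytic (one-sided) spectrum of
#' channel II by the correction phasor and takes the real part back in
#' k-space. For the Hermitian transfer functions of real electronics this is
#' equivalent to filtering the real signal directly, needs no knowledge of
#' where the reflectors are, and — unlike the Hermitian-spectrum route —
#' respects the gauge freedom between the spatial and chromatic phase
#' vectors. Channel II must be background-subtracted (near-zero mean).
#'
#' @param m a `mirror_measurement`, or a real numeric vector (then `s_II`
#'   must be supplied).
#' @param cs a `correction_set` (required for `"calibrated"`).
#' @param mode processing mode.
#' @param s_II channel-II vector when `m` is a plain vector.
#' @param grid a `kgrid` when `m` is a plain vector.
#' @param ref magnitude reference for the dB scale.
#' @param min_sin conditioning threshold.
#' @return object of class `depth_profile` with complex `values`, the
#'   centered `zbar` axis and `db` magnitudes.
#' @export
reconstruct_aline <- function(m, cs = NULL,
                              mode = c("calibrated", "direct", "standard"),
                              s_II = NULL, grid = NULL, ref = 1, min_sin = 0.1) {
  mode <- match.arg(mode)
  if (inherits(m, "mirror_measurement")) {
    s_I <- m$s_I; s_II <- m$s_II; grid <- m$grid
  } else {
    s_I <- m
    qc_check(!is.null(grid), "supply grid when m is a plain vector", "qc_shape_error")
    qc_check(mode == "standard" || !is.null(s_II),
             "supply s_II for direct or calibrated reconstruction", "qc_shape_error")
  }
  if (mode == "standard") {
    return(new_depth_profile(fftshift(stats::fft(s_I)), grid, ref))
  }
  if (mode == "direct") {
    return(new_depth_profile(fftshift(stats::fft(s_I + 1i * s_II)), grid, ref))
  }
  qc_check(!is.null(cs), "calibrated mode needs a correction_set", "qc_shape_error")
  qc_check(cs$grid$N == length(s_I),
           "correction set was calibrated for a different N", "qc_n_mismatch")
  f <- precompute_factors(cs, min_sin)
  a_II <- analytic_representation(s_II, "positive")
  A2 <- stats::fft(a_II)
  # strictly one-sided: the DC and Nyquist bins carry no fringe information
  # and are the only bins on which a phase gauge would not act as a rotation
  A2[1] <- 0
  if (length(A2) %% 2 == 0) A2[length(A2) / 2 + 1] <- 0
  s_II_corr <- Re(ifft(A2 * f$cz))
  s_Q <- f$a_k * s_II_corr - f$b_k * s_I
  new_depth_profile(fftshift(stats::fft(s_I + 1i * s_Q)), grid, ref)
}

#' @export
print.depth_profile <- function(x, ...) {
  i <- which.max(Mod(x$values))
  cat(sprintf("<depth_profile> N = %d, peak %.1f dB at zbar = %.4f\n",
              length(x$values), x$db[i], x$zbar[i]))
  invisible(x)
}
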