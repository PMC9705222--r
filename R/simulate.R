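# Forward model of the dual-channel SS-OCT detection chain.

#' Reflectors in the sample arm
#'
#' @param depths reflector positions on the normalized depth axis, each inside
#'   `(-pi/2, pi/2)`.
#' @param amplitudes non-negative weights `C_m`, proportional to the amplitude
#'   reflectivity `sqrt(R_m)`; recycled to the length of `depths`.
#' @return object of class `reflector_set`.
#' @export
reflector_set <- function(depths, amplitudes = 1) {
  qc_check(length(depths) == 0 || all(is.finite(depths)),
           "depths must be finite", "qc_range_error")
  qc_check(all(abs(depths) < pi / 2),
           "reflector depths must lie inside (-pi/2, pi/2)", "qc_range_error")
  amplitudes <- rep_len(amplitudes, length(depths))
  qc_check(all(amplitudes >= 0), "amplitudes must be >= 0", "qc_range_error")
  structure(list(depths = as.numeric(depths), amplitudes = as.numeric(amplitudes)),
            class = "reflector_set")
}

#' Noise and phase-jitter specification
#'
#' Describes the stochastic imperfections of an acquisition: additive white
#' Gaussian noise (independent per channel and sample) and a per-A-line global
#' phase offset drawn uniformly from `[-jitter, jitter]` and applied
#' identically to both channels, emulating the inter-A-line phase drift of a
#' swept source.
#'
#' When `seed` is given, the generating function seeds R's RNG once and then
#' draws, in this order: (1) the `M` jitter phases, (2) the `N x M` channel-I
#' noise matrix, (3) the `N x M` channel-II noise matrix. This fixed stream
#' order makes every simulated batch reproducible from the single seed.
#'
#' @param noise_sigma standard deviation of the additive noise (signal units).
#' @param jitter half-width of the uniform per-A-line phase offset, in
#'   `[0, pi]` radians.
#' @param seed optional integer RNG seed.
#' @return object of class `noise_jitter_spec`.
#' @export
noise_jitter_spec <- function(noise_sigma = 0, jitter = 0, seed = NULL) {
  qc_check(noise_sigma >= 0, "noise_sigma must be >= 0", "qc_range_error")
  qc_check(jitter >= 0 && jitter <= pi, "jitter must lie in [0, pi]", "qc_range_error")
  structure(list(noise_sigma = noise_sigma, jitter = jitter, seed = seed),
            class = "noise_jitter_spec")
}

#' Noise level for a target single-shot SNR
#'
#' Converts a depth-domain SNR into the matching sample-domain noise sigma.
#' For a unit-amplitude real fringe the main DFT peak has magnitude `N/2`;
#' white noise of standard deviation `sigma` produces a Rayleigh-distributed
#' bin magnitude with median `sigma * sqrt(N * log(2))`. The returned sigma
#' makes `20*log10(peak / median floor)` equal `snr_db` for one A-line.
#'
#' @param snr_db target single A-line peak to median-noise-floor ratio (dB).
#' @param N samples per A-line.
#' @param amplitude fringe amplitude (default 1).
#' @return noise standard deviation.
#' @export
sigma_for_snr <- function(snr_db, N, amplitude = 1) {
  (N * amplitude / 2) / (sqrt(N * log(2)) * 10^(snr_db / 20))
}

new_raw_batch <- function(ch_I, ch_II, grid, truth = NULL) {
  qc_check(all(dim(ch_I) == dim(ch_II)), "channel matrices must share a shape",
           "qc_shape_error")
  qc_check(all(is.finite(ch_I)) && all(is.finite(ch_II)),
           "channel data must be finite", "qc_shape_error")
  structure(list(ch_I = ch_I, ch_II = ch_II, grid = grid, truth = truth),
            class = "raw_batch")
}

#' @export
print.raw_batch <- function(x, ...) {
  cat(sprintf("<raw_batch> N = %d, M = %d A-lines\n", nrow(x$ch_I), ncol(x$ch_I)))
  invisible(x)
}

# complex per-channel analytic signals (N x 1) for one unit of jitter phase 0;
# exact mode applies the RF response by multiplication on the centered depth
# axis, dirac mode evaluates it at the reflector depth only.
channel_base <- function(imb, reflectors, grid, mode) {
  N <- grid$N
  n <- seq_len(N) - 1
  u <- k_unit(grid)
  one <- function(A, Om, al, om) {
    a <- complex(length.out = N)
    for (j in seq_along(reflectors$depths)) {
      z <- reflectors$depths[j]; C <- reflectors$amplitudes[j]
      ph <- 2 * z * n - Om(u)
      if (mode == "dirac") {
        a <- a + C * A(u) * al(z) * exp(1i * (ph - om(z)))
      } else {
        a <- a + C * A(u) * exp(1i * ph)
      }
    }
    if (mode == "exact") {
      H <- al(grid$zbar) * exp(-1i * om(grid$zbar))
      a <- ifft(stats::fft(a) * ifftshift(H))
    }
    a
  }
  list(I = one(imb$A_I, imb$Omega_I, imb$alpha_I, imb$omega_I),
       II = one(imb$A_II, imb$Omega_II, imb$alpha_II, imb$omega_II))
}

#' Simulate a two-channel mirror measurement
#'
#' Generates `M` A-lines of the real-valued signals observed in the two
#' balanced detection channels for a set of reflectors. Each reflector at
#' normalized depth `zbar` contributes a fringe `2 * zbar * n` across sample
#' index `n` (so integer depth bins are pure DFT tones), shaped by the
#' chromatic envelope of each channel; the depth-dependent response is applied
#' either exactly, by multiplication in the depth domain (`mode = "exact"`,
#' the default), or in the Dirac-peak approximation, by evaluating it at the
#' reflector depth (`mode = "dirac"`). A common random phase is added to both
#' channels per A-line (jitter), then independent white noise per channel.
#'
#' @param imb a `channel_imbalance` (ground truth).
#' @param reflectors a `reflector_set`.
#' @param grid a `kgrid`.
#' @param nj a `noise_jitter_spec`.
#' @param M number of A-lines (>= 1).
#' @param mode `"exact"` or `"dirac"`.
#' @return a `raw_batch` with `N x M` channel matrices and the ground truth
#'   attached in `$truth`.
#' @export
simulate_mirror_measurement <- function(imb, reflectors, grid, nj = noise_jitter_spec(),
                                        M = 1L, mode = c("exact", "dirac")) {
  mode <- match.arg(mode)
  qc_check(M >= 1, "M must be >= 1", "qc_size_error")
  if (!is.null(nj$seed)) set.seed(nj$seed)
  base <- channel_base(imb, reflectors, grid, mode)
  N <- grid$N
  jit <- if (nj$jitter > 0) stats::runif(M, -nj$jitter, nj$jitter) else numeric(M)
  rot <- exp(1i * jit)
  ch_I <- Re(outer(base$I, rot))
  ch_II <- Re(outer(base$II, rot))
  if (nj$noise_sigma > 0) {
    ch_I <- ch_I + matrix(stats::rnorm(N * M, sd = nj$noise_sigma), N, M)
    ch_II <- ch_II + matrix(stats::rnorm(N * M, sd = nj$noise_sigma), N, M)
  }
  new_raw_batch(ch_I, ch_II, grid,
                truth = list(imbalance = imb, reflectors = reflectors, jitter = jit))
}

#' Simulate a calibration sweep of single-mirror measurements
#'
#' One `raw_batch` per requested depth, each with a single unit reflector.
#' Measurements on both sides of zero-delay (at least a few per side) are
#' needed for a usable calibration.
#'
#' @inheritParams simulate_mirror_measurement
#' @param depths vector of mirror positions on the normalized depth axis.
#' @return list of `raw_batch`, one per depth (empty list for empty input).
#' @export
simulate_mirror_sweep <- function(imb, grid, nj = noise_jitter_spec(), depths,
                                  M = 1L, mode = c("exact", "dirac")) {
  mode <- match.arg(mode)
  if (length(depths) == 0) return(list())
  if (!is.null(nj$seed)) set.seed(nj$seed)
  nj_stream <- noise_jitter_spec(nj$noise_sigma, nj$jitter, seed = NULL)
  lapply(depths, function(d) {
    simulate_mirror_measurement(imb, reflector_set(d, 1), grid, nj_stream, M, mode)
  })
}

#' Simulate a layered B-scan phantom
#'
#' Synthetic stand-in for imaging a layered sample (e.g. a roll of tape):
#' every lateral position (column) carries its own multi-reflector column.
#'
#' @inheritParams simulate_mirror_measurement
#' @param layers list with one `reflector_set` per lateral position.
#' @return list of `raw_batch` (one per column).
#' @export
simulate_bscan_phantom <- function(imb, grid, nj = noise_jitter_spec(), layers,
                                   M = 1L, mode = c("exact", "dirac")) {
  mode <- match.arg(mode)
  if (length(layers) == 0) return(list())
  if (!is.null(nj$seed)) set.seed(nj$seed)
  nj_stream <- noise_jitter_spec(nj$noise_sigma, nj$jitter, seed = NULL)
  lapply(layers, function(rs) {
    simulate_mirror_measurement(imb, rs, grid, nj_stream, M, mode)
  })
}

#' Simulate a background (reference-only) acquisition
#'
#' Noise plus optional per-channel DC/background terms, with no interference
#' fringes; the input expected by [remove_background()].
#'
#' @inheritParams simulate_mirror_measurement
#' @param dc_I,dc_II background terms: scalars or functions of scaled k.
#' @return a `raw_batch`.
#' @export
simulate_background <- function(grid, nj = noise_jitter_spec(), M = 1L,
                                dc_I = 0, dc_II = 0) {
  qc_check(M >= 1, "M must be >= 1", "qc_size_error")
  if (!is.null(nj$seed)) set.seed(nj$seed)
  u <- k_unit(grid); N <- grid$N
  b_I <- as_kfun(dc_I, "dc_I")(u); b_II <- as_kfun(dc_II, "dc_II")(u)
  mk <- function(b) {
    m <- matrix(rep(b, M), N, M)
    if (nj$noise_sigma > 0) m <- m + matrix(stats::rnorm(N * M, sd = nj$noise_sigma), N, M)
    m
  }
  # keep the documented stream order: jitter slot unused here, noise I then II
  new_raw_batch(mk(b_I), mk(b_II), grid, truth = NULL)
}

#' Integer-bin depth schedules for calibration and evaluation
#'
#' `calibration_depths()` returns `n` approximately evenly spaced mirror
#' positions on integer depth bins covering `+-span * pi/2`, skipping bins
#' within `dc_avoid_bins` of zero-delay. `heldout_depths()` returns up to `n`
#' integer-bin positions interleaved between calibration bins, restricted to
#' the inner half of the range (`|zbar| <= pi/4`) and avoiding zero-delay.
#' Integer bins make the mirror fringes pure DFT tones, so evaluation is not
#' limited by spectral leakage of off-bin peaks.
#'
#' @param grid a `kgrid`.
#' @param n number of depths requested.
#' @param span fraction of the half-range to cover (default 0.9).
#' @param dc_avoid_bins bins around zero-delay to skip.
#' @param calib depths returned by `calibration_depths()` (for interleaving).
#' @return numeric vector of normalized depths.
#' @export
calibration_depths <- function(grid, n = 31, span = 0.9, dc_avoid_bins = 4) {
  half <- grid$N / 2
  bins <- unique(round(seq(-span * half, span * half, length.out = n)))
  bins <- bins[abs(bins) >= dc_avoid_bins]
  bins * pi / grid$N
}

#' @rdname calibration_depths
#' @export
heldout_depths <- function(grid, calib, n = 16, dc_avoid_bins = 4) {
  cb <- sort(round(calib * grid$N / pi))
  mid <- round((cb[-1] + cb[-length(cb)]) / 2)
  mid <- setdiff(mid, cb)
  # inner half of the range, give or take half a calibration spacing so the
  # requested count can be honoured when midpoints straddle the boundary
  lim <- grid$N / 4 + stats::median(diff(cb)) / 2
  mid <- mid[abs(mid) >= dc_avoid_bins & abs(mid) <= lim]
  if (length(mid) > n) {
    mid <- mid[unique(round(seq(1, length(mid), length.out = n)))]
  }
  mid * pi / grid$N
}

#' Layered phantom geometry
#'
#' Builds the per-column reflector sets of a gently curved, layered synthetic
#' phantom (a stand-in for a rolled-tape sample).
#'
#' @param grid a `kgrid`.
#' @param n_cols lateral positions.
#' @param n_layers number of layers.
#' @param center depth of the first layer at the central column (normalized).
#' @param spacing layer-to-layer depth increment (normalized).
#' @param sag parabolic sag of the layers across the scan (normalized).
#' @param amplitude per-layer reflector amplitude.
#' @return list of `reflector_set`, one per column.
#' @export
phantom_layers <- function(grid, n_cols = 48, n_layers = 3, center = pi / 6,
                           spacing = pi / 24, sag = pi / 24, amplitude = 1) {
  x <- seq(-1, 1, length.out = n_cols)
  lapply(x, function(xi) {
    d <- center - sag * (1 - xi^2) + (seq_len(n_layers) - 1) * spacing
    reflector_set(d, amplitude)
  })
}
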