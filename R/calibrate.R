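# Calibration pipeline: per-depth imbalance extraction, fits along k,
# spatial-vector fitting with gauge normalization at zero-delay, spatial
# correction of channel II, and chromatic-vector averaging.

#' Calibration configuration
#'
#' Collects every tunable of the calibration pipeline with its default.
#' Defaults are discussed in the methods vignette; the most consequential are
#' the fit families (`k_method`/`z_method`) and the exclusion radii.
#'
#' @param k_method,k_degree,k_spar fit along wavenumber: `"polynomial"`
#'   (default, degree 7) or `"spline"` (smoothing spline, optional `spar`).
#' @param z_method,z_degree fit across depth: `"polynomial"` (default,
#'   degree 7; exact for smooth low-order transfer functions) or `"spline"`
#'   (natural cubic interpolation; use when sharp local features are expected
#'   and sampling is dense).
#' @param edge_frac_k fraction of samples distrusted at each spectral edge.
#' @param dc_exclusion_bins depth samples within this many bins of zero-delay
#'   are excluded from spatial fitting and chromatic averaging.
#' @param edge_frac_z fraction of the depth half-range treated as edge when
#'   excluding depths from chromatic averaging.
#' @param outlier_mad depths whose fitted chromatic curve deviates from the
#'   pointwise median by more than this many MADs anywhere are excluded.
#' @param amp_floor samples whose geometric-mean channel amplitude falls below
#'   this fraction of its maximum (i.e. below -40 dB of the spectral peak by
#'   default) are excluded from k-fits entirely: with a band-limited source
#'   they carry no light, only noise.
#' @param min_sin conditioning floor on `|sin(dphi_k)|`.
#' @param max_gap_warn warn when consecutive calibration depths are farther
#'   apart than this (normalized units).
#' @return a list of class `calibration_config`.
#' @export
calibration_config <- function(k_method = c("polynomial", "spline"), k_degree = 7,
                               k_spar = NULL,
                               z_method = c("polynomial", "spline"), z_degree = 7,
                               edge_frac_k = 0.05, dc_exclusion_bins = 3,
                               edge_frac_z = 0.02, outlier_mad = 5,
                               amp_floor = 0.01,
                               min_sin = 0.1, max_gap_warn = pi / 8) {
  structure(list(
    k_method = match.arg(k_method), k_degree = k_degree, k_spar = k_spar,
    z_method = match.arg(z_method), z_degree = z_degree,
    edge_frac_k = edge_frac_k, dc_exclusion_bins = dc_exclusion_bins,
    edge_frac_z = edge_frac_z, outlier_mad = outlier_mad,
    amp_floor = amp_floor,
    min_sin = min_sin, max_gap_warn = max_gap_warn
  ), class = "calibration_config")
}

#' Locate the mirror peak of an analytic pair
#'
#' Finds the dominant depth-domain peak of the mean channel magnitude and
#' refines its position to sub-bin precision. The default estimator is the
#' three-point complex-ratio (Jacobsen) interpolator with Candan's bias
#' correction, which is essentially exact for an unwindowed tone; a
#' three-point Gaussian (log-parabolic) fit is available for broadened
#' experimental point-spread functions.
#'
#' @param pair an `analytic_pair`.
#' @param grid a `kgrid`.
#' @param method `"jacobsen"` (default) or `"gaussian"`.
#' @return list with `zbar_peak` (normalized position), `side` (+-1) and
#'   `quality` (peak-to-median-floor, dB).
#' @export
locate_peak <- function(pair, grid, method = c("jacobsen", "gaussian")) {
  method <- match.arg(method)
  N <- grid$N
  P_I <- fftshift(stats::fft(pair$a_I))
  P_II <- fftshift(stats::fft(pair$a_II))
  mag <- (Mod(P_I) + Mod(P_II)) / 2
  p <- which.max(mag)
  # two comparable non-adjacent candidates mean the measurement is not a
  # single dominant reflector
  rival <- which(mag >= mag[p] * 10^(-3 / 20))
  qc_check(all(abs(rival - p) <= 2),
           "ambiguous peak: two non-adjacent bins within 3 dB of the maximum",
           "qc_ambiguous_peak")
  delta <- 0
  if (p > 1 && p < N) {
    m1 <- mag[p - 1]; m0 <- mag[p]; m2 <- mag[p + 1]
    if (max(m1, m2) > 1e-12 * m0) {
      if (method == "gaussian") {
        l1 <- log(m1); l0 <- log(m0); l2 <- log(m2)
        delta <- 0.5 * (l1 - l2) / (l1 - 2 * l0 + l2)
      } else {
        est <- function(P) {
          d <- -Re((P[p + 1] - P[p - 1]) / (2 * P[p] - P[p - 1] - P[p + 1]))
          d * tan(pi / N) / (pi / N)          # Candan correction
        }
        delta <- (est(P_I) + est(P_II)) / 2
      }
      if (!is.finite(delta) || abs(delta) > 1) delta <- 0
    }
  }
  keep <- setdiff(seq_len(N), max(1, p - 10):min(N, p + 10))
  quality <- 20 * log10(mag[p] / stats::median(mag[keep]))
  zbar_peak <- (p + delta - dc_index(grid)) * pi / N
  list(zbar_peak = zbar_peak, side = if (zbar_peak >= 0) 1 else -1,
       quality = quality)
}

#' Raw amplitude-ratio and phase-offset vectors
#'
#' Computes `beta(k) = amp_I / amp_II` and the phase offset
#' `dphi(k) = ph_I - ph_II` from an analytic pair, shifting `dphi` by a
#' multiple of `2*pi` so that its median lies on the branch nearest `pi/2`
#' (the ideal quadrature offset; channel II lags channel I). Channel labels
#' are fixed — swapping them maps `beta -> 1/beta` and `dphi -> -dphi` and
#' breaks the reconstruction, so consistency matters more than which physical
#' detector is called "I".
#'
#' @param pair an `analytic_pair`.
#' @return list with numeric vectors `beta` and `dphi`.
#' @export
compute_beta_dphi <- function(pair) {
  qc_check(min(pair$amp_II) > 1e-12 * max(pair$amp_II),
           "channel II amplitude vanishes somewhere: division guard tripped",
           "qc_division_guard")
  beta <- pair$amp_I / pair$amp_II
  dphi <- pair$ph_I - pair$ph_II
  dphi <- dphi - 2 * pi * round((stats::median(dphi) - pi / 2) / (2 * pi))
  # re-wrap every sample onto the branch nearest the median: unwrap slips in
  # low-SNR spectral regions otherwise leave 2*pi steps in the tail of the
  # vector, and the physical offset cannot stray a half-turn from quadrature
  med <- stats::median(dphi)
  dphi <- med + wrap_pi(dphi - med)
  list(beta = beta, dphi = dphi)
}

#' Trusted-sample mask for spectral fitting
#'
#' @param N samples per A-line.
#' @param edge_frac fraction flagged untrusted at each spectral edge.
#' @return logical vector, `TRUE` where the sample is trusted.
#' @export
trusted_mask <- function(N, edge_frac = 0.05) {
  ne <- floor(N * edge_frac)
  m <- rep(TRUE, N)
  if (ne > 0) m[c(seq_len(ne), N - seq_len(ne) + 1)] <- FALSE
  m
}

#' Smooth a raw vector along wavenumber
#'
#' Fits `raw` against a centered/scaled abscissa, excluding untrusted samples,
#' and returns the smooth fit evaluated on the full axis. The polynomial
#' route (orthogonal polynomials via `lm`) fits the original axis directly —
#' padding would introduce cusps that a global polynomial cannot follow. The
#' smoothing-spline route pads the signal with mirror copies of itself
#' (excluding the mirrored untrusted samples too), which stabilizes the fit
#' toward the spectral edges.
#'
#' @param raw numeric vector over k.
#' @param trusted logical mask (see [trusted_mask()]); `NULL` trusts all.
#' @param method `"polynomial"` (default) or `"spline"`.
#' @param degree polynomial degree.
#' @param spar optional `smooth.spline` smoothing parameter.
#' @param weights optional non-negative fit weights (e.g. the product of the
#'   two channel amplitudes, the inverse-variance weight for a ratio or a
#'   phase difference). Samples near the spectral edges of a band-limited
#'   source carry almost no light, and unweighted fitting would let their
#'   noise dominate.
#' @return fitted numeric vector, same length as `raw`.
#' @export
fit_along_k <- function(raw, trusted = NULL, method = c("polynomial", "spline"),
                        degree = 7, spar = NULL, weights = NULL) {
  method <- match.arg(method)
  N <- length(raw)
  if (is.null(trusted)) trusted <- rep(TRUE, N)
  if (is.null(weights)) weights <- rep(1, N)
  weights <- weights / max(weights)
  need <- if (method == "polynomial") degree + 2 else 6
  qc_check(sum(trusted) >= need,
           "fewer trusted samples than fit degrees of freedom",
           "qc_underdetermined")
  if (method == "polynomial") {
    x <- seq(-1, 1, length.out = N)
    df <- data.frame(x = x[trusted], y = raw[trusted], w = weights[trusted])
    m <- stats::lm(y ~ stats::poly(x, degree = degree), data = df, weights = w)
    unname(stats::predict(m, newdata = data.frame(x = x)))
  } else {
    y <- c(rev(raw), raw, rev(raw))
    ok <- c(rev(trusted), trusted, rev(trusted))
    w <- c(rev(weights), weights, rev(weights))
    x <- (seq_len(3 * N) - N - (N + 1) / 2) / N   # central block spans ~[-0.5, 0.5]
    mid <- (N + 1):(2 * N)
    ss <- if (is.null(spar)) stats::smooth.spline(x[ok], y[ok], w = w[ok])
          else stats::smooth.spline(x[ok], y[ok], w = w[ok], spar = spar)
    stats::predict(ss, x[mid])$y
  }
}

#' Extract one calibrated depth sample from a mirror measurement
#'
#' Convenience wrapper running side detection, analytic extraction, peak
#' location and k-fits for a single averaged mirror measurement.
#'
#' @param m a `mirror_measurement`.
#' @param config a [calibration_config()].
#' @param side optionally force the processing side.
#' @return object of class `depth_sample` with fields `zbar_peak`, `side`,
#'   `beta_k`, `dphi_k` (fitted vectors over k), `quality`.
#' @export
depth_sample <- function(m, config = calibration_config(), side = NULL) {
  if (is.null(side)) side <- detect_side(m)
  pair <- extract_amplitude_phase(m, side)
  pk <- locate_peak(pair, m$grid)
  raw <- compute_beta_dphi(pair)
  w <- pair$amp_I * pair$amp_II
  tm <- trusted_mask(m$grid$N, config$edge_frac_k) &
    w > config$amp_floor^2 * max(w)
  structure(list(
    zbar_peak = pk$zbar_peak, side = pk$side, quality = pk$quality,
    beta_k = fit_along_k(raw$beta, tm, config$k_method, config$k_degree,
                         config$k_spar, weights = w),
    dphi_k = fit_along_k(raw$dphi, tm, config$k_method, config$k_degree,
                         config$k_spar, weights = w)
  ), class = "depth_sample")
}

# fit scattered (z, value) pairs and evaluate on the full zbar axis
fit_over_z <- function(z, v, zout, method, degree) {
  if (method == "polynomial") {
    deg <- min(degree, length(z) - 2)
    df <- data.frame(x = z, y = v)
    m <- stats::lm(y ~ stats::poly(x, degree = deg), data = df)
    unname(stats::predict(m, newdata = data.frame(x = zout)))
  } else {
    f <- stats::splinefun(z, v, method = "natural")
    f(zout)
  }
}

#' Fit the spatial (RF) correction vectors
#'
#' Collects the fitted `beta` and `dphi` values at the central wavenumber from
#' every depth sample, drops samples too close to zero-delay (where extraction
#' is unstable), fits across the normalized depth axis and gauge-normalizes so
#' that `beta_z(0) = 1` and `dphi_z(0) = 0` — the constant chromatic part of
#' each parameter belongs to `beta_k`/`dphi_k`, not here.
#'
#' @param samples list of `depth_sample`.
#' @param grid a `kgrid`.
#' @param config a [calibration_config()].
#' @return list with numeric vectors `beta_z`, `dphi_z` over the full zbar
#'   axis, plus the retained sample positions in `z_used`.
#' @export
fit_spatial_vectors <- function(samples, grid, config = calibration_config()) {
  ic <- dc_index(grid)
  z <- vapply(samples, function(s) s$zbar_peak, numeric(1))
  bc <- vapply(samples, function(s) s$beta_k[ic], numeric(1))
  dc <- vapply(samples, function(s) s$dphi_k[ic], numeric(1))
  keep <- abs(z) >= config$dc_exclusion_bins * pi / grid$N
  z <- z[keep]; bc <- bc[keep]; dc <- dc[keep]
  qc_check(sum(z < 0) >= 4 && sum(z > 0) >= 4,
           "need at least 4 usable depth samples on each side of zero-delay",
           "qc_coverage_error")
  o <- order(z)
  z <- z[o]; bc <- bc[o]; dc <- dc[o]
  beta_z <- fit_over_z(z, bc, grid$zbar, config$z_method, config$z_degree)
  dphi_z <- fit_over_z(z, dc, grid$zbar, config$z_method, config$z_degree)
  b0 <- fit_over_z(z, bc, 0, config$z_method, config$z_degree)
  d0 <- fit_over_z(z, dc, 0, config$z_method, config$z_degree)
  list(beta_z = beta_z / b0, dphi_z = dphi_z - d0, z_used = z)
}

#' Apply the spatial (RF) correction to channel II
#'
#' Multiplies the side-aware analytic spectrum of channel II by the relative
#' transfer-function phasor `beta_z * exp(+i * dphi_z)` on the centered depth
#' axis and takes the real part back in k-space, so that the corrected channel
#' shares its depth response with channel I. (The sign of the phase factor
#' follows the package convention `dphi = ph_I - ph_II`; see the vignette.)
#' The vectors must be gauge-normalized: `beta_z = 1` and `dphi_z = 0` at
#' zero-delay, otherwise the correction would also strip the quadrature offset
#' itself.
#'
#' @param m a `mirror_measurement`.
#' @param beta_z,dphi_z spatial correction vectors over the full zbar axis.
#' @param side processing side for the analytic representation.
#' @return a `mirror_measurement` with channel II corrected.
#' @export
apply_spatial_correction <- function(m, beta_z, dphi_z,
                                     side = c("positive", "negative")) {
  side <- match.arg(side)
  i0 <- dc_index(m$grid)
  qc_check(abs(beta_z[i0] - 1) < 1e-6 && abs(dphi_z[i0]) < 1e-6,
           "spatial vectors are not gauge-normalized at zero-delay",
           "qc_gauge_error")
  a_II <- analytic_representation(m$s_II, side)
  cz <- ifftshift(beta_z * exp(1i * dphi_z))
  s_II <- Re(ifft(stats::fft(a_II) * cz))
  new_mirror_measurement(m$s_I, s_II, m$grid, m$n_averaged, m$nominal_side)
}

#' Average per-depth chromatic vectors
#'
#' After spatial correction the fitted `beta(k)` and `dphi(k)` curves should
#' be near-identical at every depth; this collects them, excludes depths close
#' to zero-delay or to the edges of the range, flags outlier depths whose
#' curve strays more than `outlier_mad` MADs from the pointwise median
#' anywhere, and averages the remainder pointwise.
#'
#' @param corrected list of `mirror_measurement` (already spatially corrected).
#' @param sides character vector of processing sides, one per measurement.
#' @param grid a `kgrid`.
#' @param config a [calibration_config()].
#' @return list with `beta_k`, `dphi_k`, and the logical `used` mask.
#' @export
compute_chromatic_vectors <- function(corrected, sides, grid,
                                      config = calibration_config()) {
  n <- length(corrected)
  B <- matrix(NA_real_, grid$N, n)
  D <- matrix(NA_real_, grid$N, n)
  z <- numeric(n)
  tm0 <- trusted_mask(grid$N, config$edge_frac_k)
  for (j in seq_len(n)) {
    pair <- extract_amplitude_phase(corrected[[j]], sides[j])
    pk <- locate_peak(pair, grid)
    raw <- compute_beta_dphi(pair)
    w <- pair$amp_I * pair$amp_II
    tm <- tm0 & w > config$amp_floor^2 * max(w)
    B[, j] <- fit_along_k(raw$beta, tm, config$k_method, config$k_degree,
                          config$k_spar, weights = w)
    D[, j] <- fit_along_k(raw$dphi, tm, config$k_method, config$k_degree,
                          config$k_spar, weights = w)
    z[j] <- pk$zbar_peak
  }
  lim <- (1 - config$edge_frac_z) * pi / 2
  used <- abs(z) >= config$dc_exclusion_bins * pi / grid$N & abs(z) <= lim
  flag_outliers <- function(M, used) {
    idx <- which(used)
    if (length(idx) < 3) return(used)
    med <- apply(M[, idx, drop = FALSE], 1, stats::median)
    madv <- apply(M[, idx, drop = FALSE], 1, stats::mad)
    # absolute floor keeps noiseless near-identical curves from flagging each
    # other over sub-1e-4 extraction ripple
    thr <- config$outlier_mad * madv + 1e-4 * (abs(med) + 1)
    bad <- vapply(idx, function(j) any(abs(M[, j] - med) > thr), logical(1))
    used[idx[bad]] <- FALSE
    used
  }
  used <- flag_outliers(B, used)
  used <- flag_outliers(D, used)
  qc_check(any(used), "no usable depths remain after exclusions",
           "qc_no_usable_depths")
  g <- guard_chromatic(rowMeans(B[, used, drop = FALSE]),
                       rowMeans(D[, used, drop = FALSE]), config$min_sin)
  list(beta_k = g$beta_k, dphi_k = g$dphi_k, used = used)
}

# Hold the chromatic vectors constant beyond the sample (walking outward from
# the spectral centre) where they leave the physically plausible band. With a
# band-limited source the outermost samples carry no light: the weighted fit
# is unconstrained there and may wander into values (beta <= 0, sin(dphi) ~ 0)
# that would poison the pointwise reconstruction formula.
guard_chromatic <- function(beta_k, dphi_k, min_sin = 0.1) {
  N <- length(beta_k)
  ctr <- N %/% 2 + 1
  ok <- beta_k > 0.2 & beta_k < 5 & abs(sin(dphi_k)) >= min_sin
  qc_check(ok[ctr], "chromatic vectors implausible at the spectral centre",
           "qc_conditioning_error")
  for (i in (ctr + 1):N) if (!ok[i] || !ok[i - 1]) {
    beta_k[i] <- beta_k[i - 1]; dphi_k[i] <- dphi_k[i - 1]; ok[i] <- FALSE
  }
  for (i in (ctr - 1):1) if (!ok[i] || !ok[i + 1]) {
    beta_k[i] <- beta_k[i + 1]; dphi_k[i] <- dphi_k[i + 1]; ok[i] <- FALSE
  }
  list(beta_k = beta_k, dphi_k = dphi_k)
}

new_correction_set <- function(beta_k, dphi_k, beta_z, dphi_z, grid,
                               fit_meta = list()) {
  structure(list(beta_k = beta_k, dphi_k = dphi_k,
                 beta_z = beta_z, dphi_z = dphi_z,
                 grid = grid, fit_meta = fit_meta),
            class = "correction_set")
}

#' Assemble a correction set
#'
#' Validating constructor for the calibration product: the chromatic vectors
#' `beta_k`, `dphi_k` (over k) and the spatial vectors `beta_z`, `dphi_z`
#' (over zbar), with the gauge fixed at zero-delay. Set `validate = FALSE` to
#' build deliberately un-gauged sets (e.g. when testing gauge invariance of
#' the reconstruction).
#'
#' @param beta_k,dphi_k,beta_z,dphi_z numeric vectors of length `grid$N`.
#' @param grid a `kgrid`.
#' @param fit_meta free-form record of how the vectors were obtained.
#' @param validate enforce the type invariants.
#' @param min_sin conditioning floor used during validation.
#' @return object of class `correction_set`.
#' @export
correction_set <- function(beta_k, dphi_k, beta_z, dphi_z, grid,
                           fit_meta = list(), validate = TRUE, min_sin = 0.1) {
  cs <- new_correction_set(beta_k, dphi_k, beta_z, dphi_z, grid, fit_meta)
  if (validate) {
    i0 <- dc_index(grid)
    qc_check(all(lengths(list(beta_k, dphi_k, beta_z, dphi_z)) == grid$N),
             "correction vectors must have length N", "qc_shape_error")
    qc_check(abs(beta_z[i0] - 1) < 1e-6 && abs(dphi_z[i0]) < 1e-6,
             "spatial vectors must be gauge-normalized at zero-delay",
             "qc_gauge_error")
    qc_check(all(beta_k > 0), "beta_k must be strictly positive", "qc_range_error")
    qc_check(min(abs(sin(dphi_k))) > min_sin,
             "sin(dphi_k) too close to zero: reconstruction ill-conditioned",
             "qc_conditioning_error")
  }
  cs
}

#' @export
print.correction_set <- function(x, ...) {
  i0 <- dc_index(x$grid)
  cat(sprintf(paste0(
    "<correction_set> N = %d\n",
    "  beta_k in [%.4f, %.4f], dphi_k in [%.4f, %.4f] rad\n",
    "  beta_z in [%.4f, %.4f], dphi_z in [%.4f, %.4f] rad (gauge: z = 0)\n"),
    x$grid$N, min(x$beta_k), max(x$beta_k), min(x$dphi_k), max(x$dphi_k),
    min(x$beta_z), max(x$beta_z), min(x$dphi_z), max(x$dphi_z)))
  invisible(x)
}

#' Run the full calibration pipeline on a mirror sweep
#'
#' Executes the four calibration stages on a list of raw mirror batches:
#' (1) conditioning — per-A-line mean removal and coherent averaging;
#' (2) per-depth extraction — analytic signals, peak location, raw
#' `beta`/`dphi` and fits along k; (3) spatial fitting — central-wavenumber
#' values fitted across depth, gauge-normalized, and applied to channel II;
#' (4) chromatic averaging over the corrected depths. Measurements must cover
#' both sides of zero-delay.
#'
#' @param sweep list of `raw_batch`, one per mirror position.
#' @param config a [calibration_config()].
#' @param background optional `raw_batch` subtracted from every measurement.
#' @return a validated `correction_set`.
#' @export
calibrate <- function(sweep, config = calibration_config(), background = NULL) {
  qc_check(length(sweep) >= 8, "need at least 8 mirror measurements",
           "qc_coverage_error")
  grid <- sweep[[1]]$grid
  # a measurement parked at zero-delay (or otherwise degenerate) cannot be
  # phase-aligned or peak-located; drop it rather than abort the sweep
  meas <- lapply(sweep, function(b) {
    tryCatch({
      if (!is.null(background)) b <- remove_background(b, background)
      coherent_average(b)
    }, qc_error = function(e) NULL)
  })
  dropped <- vapply(meas, is.null, logical(1))
  meas <- meas[!dropped]
  sides <- vapply(meas, detect_side, character(1))
  samples <- Map(function(m, s) {
    tryCatch(depth_sample(m, config, side = s), qc_error = function(e) NULL)
  }, meas, sides)
  bad <- vapply(samples, is.null, logical(1))
  if (any(dropped) || any(bad)) {
    warning(sprintf("%d mirror measurement(s) dropped as degenerate",
                    sum(dropped) + sum(bad)))
    meas <- meas[!bad]; sides <- sides[!bad]; samples <- samples[!bad]
  }
  sp <- fit_spatial_vectors(samples, grid, config)
  gaps <- diff(sort(sp$z_used))
  if (any(gaps > config$max_gap_warn)) {
    warning(sprintf("calibration depth spacing has gaps up to %.3f (> %.3f): local transfer-function features may be missed",
                    max(gaps), config$max_gap_warn))
  }
  corrected <- Map(function(m, s) apply_spatial_correction(m, sp$beta_z, sp$dphi_z, s),
                   meas, sides)
  ch <- compute_chromatic_vectors(corrected, sides, grid, config)
  correction_set(ch$beta_k, ch$dphi_k, sp$beta_z, sp$dphi_z, grid,
                 fit_meta = list(config = unclass(config),
                                 n_depths = length(sweep),
                                 depths_used = sp$z_used,
                                 chromatic_used = ch$used),
                 min_sin = config$min_sin)
}
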