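# Ground-truth channel imbalance model.
#
# The two balanced detection channels of a passively demultiplexed system
# differ by a chromatic (wavenumber-dependent) envelope A_i(k) e^{-i Omega_i(k)}
# and an RF (depth-dependent) transfer factor alpha_i(zbar) e^{-i omega_i(zbar)}.
# Phases enter the simulated signals as *lags*, so that the ideal hybrid
# (Omega_II - Omega_I = pi/2) yields ch_I = cos(ramp), ch_II = sin(ramp) and the
# measured phase offset dphi = ph_I - ph_II equals +pi/2. See the methods
# vignette for why this single convention reconciles the usual sign ambiguity.

as_kfun <- function(f, what) {
  if (is.function(f)) return(f)
  qc_check(is.numeric(f) && length(f) == 1 && is.finite(f),
           sprintf("%s must be a function or a finite scalar", what),
           "qc_type_error")
  force(f)
  function(x) rep_len(f, length(x))
}

#' Ground-truth imbalance between the two detection channels
#'
#' Container for the chromatic amplitude envelopes `A_I`, `A_II` and phases
#' `Omega_I`, `Omega_II` (functions of wavenumber `k`) and the depth-dependent
#' amplitude responses `alpha_I`, `alpha_II` and phase responses `omega_I`,
#' `omega_II` (functions of the normalized depth `zbar`). Scalars are promoted
#' to constant functions. The derived imbalance factors as
#' `beta(k, z) = (A_I * alpha_I) / (A_II * alpha_II)` and
#' `dphi(k, z) = (Omega_II - Omega_I) + (omega_II - omega_I)`.
#'
#' @param A_I,A_II chromatic amplitude envelopes (strictly positive).
#' @param Omega_I,Omega_II chromatic phases (radians).
#' @param alpha_I,alpha_II depth-dependent amplitude responses (positive; even
#'   functions of `zbar` for a physically real detection chain).
#' @param omega_I,omega_II depth-dependent phase responses (radians; odd
#'   functions of `zbar` for a physically real detection chain).
#' @return object of class `channel_imbalance`.
#' @export
channel_imbalance <- function(A_I = 1, A_II = 1,
                              Omega_I = 0, Omega_II = pi / 2,
                              alpha_I = 1, alpha_II = 1,
                              omega_I = 0, omega_II = 0) {
  imb <- structure(list(
    A_I = as_kfun(A_I, "A_I"), A_II = as_kfun(A_II, "A_II"),
    Omega_I = as_kfun(Omega_I, "Omega_I"), Omega_II = as_kfun(Omega_II, "Omega_II"),
    alpha_I = as_kfun(alpha_I, "alpha_I"), alpha_II = as_kfun(alpha_II, "alpha_II"),
    omega_I = as_kfun(omega_I, "omega_I"), omega_II = as_kfun(omega_II, "omega_II")
  ), class = "channel_imbalance")
  probe <- seq(-1, 1, length.out = 33)
  for (nm in c("A_I", "A_II")) {
    qc_check(all(imb[[nm]](probe) > 0),
             sprintf("%s must be strictly positive", nm), "qc_type_error")
  }
  for (nm in c("alpha_I", "alpha_II")) {
    qc_check(all(imb[[nm]](probe * pi / 2) > 0),
             sprintf("%s must be strictly positive", nm), "qc_type_error")
  }
  imb
}

#' Built-in imbalance presets
#'
#' Stated-world scenarios used throughout the tests and studies. All presets
#' use smooth low-order polynomials in the normalized coordinates
#' `u = k` scaled to `[-1, 1]` and `v = zbar / (pi/2)`. Every non-ideal
#' preset also carries a common Gaussian source spectral envelope
#' `W(u) = exp(-9 u^2)` (FWHM about 55% of the sweep range, ~0.01% residual
#' intensity at the band edges): real swept sources are band-limited, and a
#' hard-edged flat spectrum — the unphysical alternative — leaves wrap-around
#' spectral leakage that both biases Hilbert-based amplitude/phase extraction
#' and floors the measurable extinction near -90 dB. `W` is identical in the
#' two channels, so it cancels exactly in every imbalance ratio.
#'
#' * `"ideal"` — perfectly matched channels in exact quadrature (flat
#'   spectrum, so trivial identities hold to machine precision).
#' * `"chromatic-only"` — `beta_k` within `[0.9, 1.1]` and
#'   `dphi_k = pi/2 +- <0.1` rad, flat depth response.
#' * `"rf-only"` — matched chromatics; per-channel depth responses with
#'   `<= 10%` amplitude and `<= 0.3` rad phase variation (alpha even, omega
#'   odd in `zbar`, as for any real electronic chain).
#' * `"realistic"` — both of the above combined.
#' * `"rf-sharp"` — `"realistic"` plus a sharp AC-coupling-like amplitude dip
#'   and a sharp odd phase feature near zero-delay; this is the preset the
#'   sampling-density study exercises, since only dense axial sampling can
#'   capture the feature.
#'
#' Chromatic truths are expressed against the scaled-`k` coordinate, so preset
#' functions must be evaluated at `k_unit(grid)` by the simulator (handled
#' internally).
#'
#' @param name preset name.
#' @return a `channel_imbalance`.
#' @export
imbalance_preset <- function(name = c("ideal", "chromatic-only", "rf-only",
                                      "realistic", "rf-sharp")) {
  name <- match.arg(name)
  W <- source_envelope
  beta_k  <- function(u) 1 + 0.06 * u - 0.03 * u^2 + 0.02 * u^3
  dphi_kd <- function(u) 0.05 * u + 0.04 * u^2 - 0.03 * u^3   # dphi_k - pi/2
  alpha_I <- function(z) { v <- z_unit(z); 1 + 0.05 * v^2 - 0.04 * v^4 + 0.02 * v^6 }
  omega_II <- function(z) { v <- z_unit(z); 0.15 * v - 0.10 * v^3 + 0.05 * v^5 }
  dip      <- function(z) { v <- z_unit(z); 1 - 0.08 * exp(-(v / 0.06)^2) }
  sharp_ph <- function(z) { v <- z_unit(z); 0.2 * v * exp(-(v / 0.08)^2) }
  switch(name,
    "ideal" = channel_imbalance(),
    "chromatic-only" = channel_imbalance(
      A_I = function(u) W(u) * beta_k(u), A_II = W,
      Omega_II = function(u) pi / 2 + dphi_kd(u)
    ),
    "rf-only" = channel_imbalance(A_I = W, A_II = W,
                                  alpha_I = alpha_I, omega_II = omega_II),
    "realistic" = channel_imbalance(
      A_I = function(u) W(u) * beta_k(u), A_II = W,
      Omega_II = function(u) pi / 2 + dphi_kd(u),
      alpha_I = alpha_I, omega_II = omega_II
    ),
    "rf-sharp" = channel_imbalance(
      A_I = function(u) W(u) * beta_k(u), A_II = W,
      Omega_II = function(u) pi / 2 + dphi_kd(u),
      alpha_I = alpha_I, alpha_II = dip,
      omega_II = function(z) omega_II(z) + sharp_ph(z)
    )
  )
}

# common Gaussian source spectrum of the non-ideal presets
source_envelope <- function(u) exp(-9 * u^2)

#' Reduce a four-port model to per-channel envelopes
#'
#' Balanced detection subtracts anti-phase port pairs: channel I is ports
#' 1 and 3, channel II ports 2 and 4. The complex envelope of channel I is
#' `sqrt(TR1*TS1*IR*IS)*exp(i*phi1) - sqrt(TR3*TS3*IR*IS)*exp(i*phi3)` (channel
#' II analogously), and its magnitude/argument become `A_I`, `Omega_I`. The
#' port model cannot be inverted from measurements (only ratios survive), but
#' the forward direction is useful for constructing ground truths from
#' component specifications.
#'
#' @param ports list with fields `TS`, `TR` (each a list/vector of four
#'   transmissions in `(0, 1]`, scalars or functions of scaled k), `phi`
#'   (four port phase offsets, radians; ideal is `(n-1)*pi/2`), and scalar or
#'   function intensities `IS`, `IR`.
#' @return a `channel_imbalance` with flat (unity/zero) depth responses.
#' @export
balance_ports <- function(ports) {
  qc_check(is.list(ports) && all(c("TS", "TR", "phi") %in% names(ports)),
           "ports must be a list with TS, TR, phi", "qc_type_error")
  getf <- function(x) lapply(x, as_kfun, what = "port field")
  TS <- getf(as.list(ports$TS)); TR <- getf(as.list(ports$TR))
  phi <- getf(as.list(ports$phi))
  IS <- as_kfun(if (is.null(ports$IS)) 1 else ports$IS, "IS")
  IR <- as_kfun(if (is.null(ports$IR)) 1 else ports$IR, "IR")
  qc_check(length(TS) == 4 && length(TR) == 4 && length(phi) == 4,
           "TS, TR and phi must each have four entries", "qc_type_error")
  env_fun <- function(a, b) {
    function(u) {
      sqrt(TR[[a]](u) * TS[[a]](u) * IR(u) * IS(u)) * exp(1i * phi[[a]](u)) -
        sqrt(TR[[b]](u) * TS[[b]](u) * IR(u) * IS(u)) * exp(1i * phi[[b]](u))
    }
  }
  e_I <- env_fun(1L, 3L); e_II <- env_fun(2L, 4L)
  probe <- seq(-1, 1, length.out = 65)
  qc_check(max(Mod(e_I(probe))) > 1e-12 && max(Mod(e_II(probe))) > 1e-12,
           "ports cancel exactly: degenerate balanced envelope",
           "qc_degenerate_ports")
  channel_imbalance(
    A_I = function(u) Mod(e_I(u)),  A_II = function(u) Mod(e_II(u)),
    Omega_I = function(u) Arg(e_I(u)), Omega_II = function(u) Arg(e_II(u))
  )
}

#' Evaluate the ground-truth imbalance factors on a grid
#'
#' Returns the exact chromatic and spatial imbalance vectors implied by a
#' `channel_imbalance`, un-gauged (i.e. as the raw channel ratios, before the
#' zero-delay normalization that the calibration applies). Used as the oracle
#' in parameter-recovery tests.
#'
#' @param imb a `channel_imbalance`.
#' @param grid a `kgrid`.
#' @return list with `beta_k`, `dphi_k` (length `N`, over k) and `beta_z`,
#'   `dphi_z` (length `N`, over `zbar`).
#' @export
true_beta_dphi <- function(imb, grid) {
  u <- k_unit(grid); z <- grid$zbar
  list(
    beta_k = imb$A_I(u) / imb$A_II(u),
    dphi_k = imb$Omega_II(u) - imb$Omega_I(u),
    beta_z = imb$alpha_I(z) / imb$alpha_II(z),
    dphi_z = imb$omega_II(z) - imb$omega_I(z)
  )
}
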