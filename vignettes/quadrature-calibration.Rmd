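---
title: "Quadrature calibration for full-range OCT: model, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrature calibration for full-range OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadcal)
```

## The signal model

A passively demultiplexed swept-source OCT system measures the interference
signal on two balanced channels. For a set of reflectors with weights $C_m$
at normalized depths $\bar z_m$, sample index $n = 0,\dots,N-1$, the
simulator generates

$$
s_i(n) \;=\; \Re\Big\{\textstyle\sum_m C_m\, A_i(k_n)\,\alpha_i(\bar z_m)\,
\exp\!\big(i\,[\,2\bar z_m n + \phi_{\mathrm{jit}} - \Omega_i(k_n) -
\omega_i(\bar z_m)\,]\big)\Big\} + \varepsilon_i(n),
$$

for channels $i \in \{\mathrm{I}, \mathrm{II}\}$, where

* $A_i(k)$, $\Omega_i(k)$ are the chromatic amplitude envelope and phase of
  the channel (hybrid/coupler plus detector spectral response, and the
  common source spectrum);
* $\alpha_i(\bar z)$, $\omega_i(\bar z)$ are the depth-dependent (RF)
  amplitude and phase responses of the electronics, applied either at the
  reflector depth (Dirac-peak mode) or exactly, by multiplication on the
  centered depth axis (default);
* $\phi_{\mathrm{jit}}$ is a per-A-line global phase, identical in both
  channels; $\varepsilon_i$ is white Gaussian noise, independent per channel.

The normalized depth axis is $\bar z \in [-\pi/2, \pi/2 - \pi/N]$ with
spacing $\pi/N$ (even $N$); a reflector on an integer depth bin is a pure
DFT tone, which is what makes the package's exact identities testable.
Physical units (mm, volts) are deliberately out of scope.

Only the channel *ratios* are observable:
$\beta(k,\bar z) = \beta_k(k)\,\beta_z(\bar z)$ with
$\beta_k = A_\mathrm{I}/A_\mathrm{II}$,
$\beta_z = \alpha_\mathrm{I}/\alpha_\mathrm{II}$, and
$\Delta\varphi(k,\bar z) = \Delta\varphi_k(k) + \Delta\varphi_z(\bar z)$
with $\Delta\varphi_k = \Omega_\mathrm{II}-\Omega_\mathrm{I}$,
$\Delta\varphi_z = \omega_\mathrm{II}-\omega_\mathrm{I}$. The absolute port
transmissions and phases of the demodulation optics cannot be recovered and
are not needed.

### Sign conventions (read this before comparing with other write-ups)

Channel phases enter the simulator as *lags*, and the measured phase offset
is defined as $\Delta\varphi = \arg a_\mathrm{I} - \arg a_\mathrm{II}$
(channel II lags channel I). This single convention makes all of the
following true simultaneously, which no mixed convention does:

* an ideal hybrid ($\Omega = 0, \pi/2$) yields $s_\mathrm{I} = \cos$,
  $s_\mathrm{II} = \sin$ of the same ramp;
* the measured ideal offset is $+\pi/2$, inside $(0, \pi)$;
* a reflector at $\bar z > 0$ reconstructs on the positive half-axis with
  the standard FFT;
* the quadrature formula
  $S_Q = (\beta_k S_\mathrm{II}'' - \cos\Delta\varphi_k\, S_\mathrm{I}')/
  \sin\Delta\varphi_k$ returns the true quadrature, not its conjugate.

One consequence: the spatial correction phasor applied to the analytic
channel II is $\beta_z e^{+i\Delta\varphi_z}$ here (the same algebra is
often written with $e^{-i\Delta\varphi_z}$ under the opposite angle
convention). Swapping the channel labels maps $\beta \to 1/\beta$,
$\Delta\varphi \to -\Delta\varphi$ and breaks the reconstruction — labels
are arbitrary but must never be interchanged mid-pipeline.

### The band-limited source

Every non-ideal preset multiplies both channels by a common Gaussian source
envelope $W(u) = e^{-9u^2}$ ($u$ = wavenumber scaled to $[-1,1]$; FWHM
$\approx$ 55% of the sweep, $\sim 10^{-4}$ residual at the band edges). This
is not cosmetic. A hard-edged flat spectrum has a wrap-around discontinuity
whose spectral leakage (i) biases Hilbert-based amplitude/phase extraction
by $\sim J/(2\pi d)$ at a peak $d$ bins from zero-delay and (ii) puts a
leakage pedestal of the main peak at the mirror bin near $-90$ dB,
capping the *measurable* extinction regardless of the calibration quality.
Both artifacts vanish for a band-limited source, as in any real instrument.
$W$ is identical in the two channels and cancels exactly in every ratio.

## Calibration pipeline and tunables

`calibrate()` runs four stages; all knobs live in `calibration_config()`.

1. **Conditioning.** Per-A-line mean removal, then coherent averaging: the
   global phase of each A-line is estimated from channel I's dominant
   positive-frequency DFT bin (first A-line as anchor) and the *same*
   rotation is applied to both channels' analytic signals — independent
   per-channel alignment would destroy the inter-channel phase and with it
   the method. Degenerate measurements (e.g. a mirror parked at zero-delay)
   are dropped with a warning.
2. **Per-depth extraction.** Side-aware analytic representation (the
   one-sided projection matches the known sign of the mirror position during
   calibration only), sub-bin peak location, raw
   $\beta(k)$, $\Delta\varphi(k)$, and a smooth fit along $k$.
3. **Spatial stage.** Central-wavenumber values ($k$-index
   $\lfloor N/2\rfloor$; edge wavenumbers are fit-unstable) are collected
   across depths, samples within `dc_exclusion_bins` (default 3) of
   zero-delay are excluded, the rest is fitted over $\bar z$ and
   gauge-normalized to $\beta_z(0)=1$, $\Delta\varphi_z(0)=0$ — the constant
   chromatic part belongs to $\beta_k,\Delta\varphi_k$, and without the
   phase normalization the spatial correction would strip the $\pi/2$
   quadrature offset itself. Channel II is then corrected in the depth
   domain.
4. **Chromatic stage.** Per-depth fitted curves — now near-identical at all
   depths — are averaged pointwise, after excluding depths near zero-delay
   or the range edges (`edge_frac_z`, default 2%) and depths whose curve
   strays more than `outlier_mad` (default 5) MADs from the pointwise median
   anywhere (with an absolute floor of $10^{-4}$ so that noiseless
   near-identical curves never flag each other).

### Fitting choices

* **Along $k$** (default: weighted polynomial, degree 7; alternative:
  weighted smoothing spline). Three decisions matter and all follow from the
  band-limited source:
  * *weights* `amp_I * amp_II` — the inverse-variance weight for an
    amplitude ratio or a phase difference; unweighted fits let the dark
    spectral edges dominate;
  * an *amplitude floor* (`amp_floor`, default 1% of the spectral peak, i.e.
    $-40$ dB) below which samples are excluded outright — they contain only
    noise, and unwrapped noise phase is a random walk that no weighting
    fully neutralizes;
  * *value clamping* (`guard_chromatic`): walking outward from the spectral
    centre, the fitted vectors are held constant from the first sample where
    they leave the plausible band ($\beta \in (0.2, 5)$,
    $|\sin\Delta\varphi_k| \ge$ `min_sin`). Corrections are unknowable where
    there is no light; clamping keeps them harmless there.
  Mirror-copy padding is applied for the spline route only: padding a
  polynomial target creates cusps a global polynomial cannot follow.
* **$\Delta\varphi$ wrapping.** After shifting by a multiple of $2\pi$ so
  the median sits nearest $\pi/2$, every sample is re-wrapped onto the
  branch nearest the median. Physically the offset cannot stray a half-turn
  from quadrature; numerically this removes the $2\pi$ steps that unwrap
  slips in low-SNR spectral regions would otherwise leave in the vector (at
  50 dB single-shot SNR these slips alone cap the pipeline near 46 dB).
* **Across $\bar z$** (default: polynomial, degree 7; alternative: natural
  cubic spline interpolation). The polynomial is exact for the smooth
  low-order transfer functions of the presets — which is what makes the
  noiseless end-to-end test reach $\ge 120$ dB. The spline is the right tool
  when sharp local features are expected *and* sampling is dense; it is what
  `sampling_density_study()` uses, because only an interpolant can benefit
  from denser sampling of a local feature.
* **Peak interpolation** (`locate_peak`): default is the three-point
  complex-ratio (Jacobsen) estimator with Candan's correction — essentially
  exact for a noiseless tone ($<10^{-7}$ bins in tests). The three-point
  Gaussian (log-parabolic) fit is available for broadened experimental
  point-spread functions, but on an unwindowed tone it biases by up to
  $\sim$0.17 bins and is not the default.

## Reconstruction

`reconstruct_aline()` supports `standard` (channel I only — the mirror
artifact in full), `direct` ($S_\mathrm{I} + iS_\mathrm{II}$, no
correction), and `calibrated`. The calibrated route multiplies the strictly
one-sided analytic spectrum of channel II (DC and Nyquist bins zeroed — they
carry no fringe information) by the precomputed spatial phasor, takes the
real part, and applies the quadrature formula with the precomputed
$\beta_k/\sin\Delta\varphi_k$ and $\cos\Delta\varphi_k/\sin\Delta\varphi_k$
factors. Cost per A-line: two extra FFTs and a few pointwise operations.

**Conditioning.** The formula divides by $\sin\Delta\varphi_k$; the package
refuses to reconstruct when $|\sin\Delta\varphi_k| <$ `min_sin` (default
0.1). Anything far from $0$ and $\pi$ works — including the 120° offsets of
3×3 coupler demultiplexers, which the tests exercise explicitly.

**Gauge freedom.** Splitting a constant factor $c$ between $\beta_z$ and
$\beta_k$, or a constant phase $\psi$ between $\Delta\varphi_z$ and
$\Delta\varphi_k$, is unobservable. The reconstruction is exactly invariant
under this reparameterization whenever the channel pair satisfies the
calibrated relation (the ideal-world test asserts $10^{-10}$); on estimated
vectors the real-part projections of the pipeline leak the gauge at the
fit-residual level ($\sim10^{-6}$ here). A manifestly gauge-invariant
variant (rotating the corrected analytic channel II by $\Delta\varphi_k$)
was evaluated and rejected: it is side-asymmetric and fails for reflectors
on the negative half-range, which full-range imaging exists to support.

## Extinction metrics and the two 60 dB conventions

`extinction_ratio()` reports the reconstructed main peak over the residual
mirror peak (searched within ±3 bins of the reflected position; zero-delay
±1 bin excluded; noise floor = median magnitude excluding ±10 bins around
both peaks; all dB are $20\log_{10}$ of magnitude ratios). Two closed-form
small-error conventions coexist in the literature and both are exposed by
`analytic_extinction()`:

* *amplitude-only*: a relative mismatch $\epsilon$ leaves a residual mirror
  peak of $\epsilon/2$ while the *original* single-channel mirror peak is
  $1/2$, so on the original-over-attenuated scale the extinction is exactly
  $20\log_{10}(1/\epsilon)$ — 60 dB at 0.1%. `extinction_ratio()` reproduces
  this when given a `reference` profile from standard processing
  (`suppression_db`). The main-over-mirror ratio of the same signal is
  $6.02$ dB higher.
* *phase-only*: an offset $\delta\varphi$ gives a main-over-mirror ratio of
  $20\log_{10}(2/|\delta\varphi|)$ — 60 dB at 2 mrad.

Mixed errors combine the residual phasors in quadrature. The choice of
scale matters at the 6 dB level; the package never mixes them silently.

## What the simulator does and does not emulate

Emulated: chromatic and RF channel imbalances with exact factorization,
band-limited source, per-A-line common phase jitter, additive white noise
with a calibrated depth-domain SNR, background/DC terms, both exact and
Dirac-peak RF application, layered B-scan phantoms.

Not emulated: sweep nonlinearity (inputs are assumed k-linear; non-k-linear
sampling would create mixed $k$–$z$ terms that break the factorization),
dispersion mismatch, laser phase noise beyond the global per-A-line offset,
autocorrelation artifacts, detector saturation, and the position-dependent
noise floor visible in real systems (unexplained in the source
measurements; the simulator's floor is flat). A green test therefore
establishes the correctness of the *algorithms* under the stated model — it
does not certify performance on data violating these assumptions, most
importantly non-k-linear data.

Per-channel RF responses use $\alpha$ even and $\omega$ odd in $\bar z$
(Hermitian symmetry — the transfer function of real electronics), so the
correction phasor is Hermitian and acting on the one-sided spectrum equals
acting on the real signal. The `realistic` preset keeps all truth functions
smooth low-order polynomials (within $|\beta - 1| \le 0.1$,
$|\Delta\varphi - \pi/2| \le 0.1$ rad chromatically, $\le 10\%$ / $\le 0.3$
rad in depth); the sharp AC-coupling-like dip near zero-delay lives in the
separate `rf-sharp` preset, used by the sampling-density study — a near-DC
feature is unlearnable from 31 depths with any smooth fit, and keeping it
out of `realistic` is what makes the noiseless $\ge 120$ dB end-to-end
behaviour attainable at all.

## Degenerate inputs and numerical guards

* analytic representation refuses inputs with $|\mathrm{mean}| >
  10^{-6}\cdot$rms (Hilbert transforms are DC-sensitive; remove background
  first);
* coherent averaging refuses flat spectra (no peak to phase-align on);
* peak location refuses two comparable non-adjacent peaks (not a single
  mirror);
* spatial fitting requires $\ge 4$ usable depths per side of zero-delay;
* `correction_set()` validates the zero-delay gauge, $\beta_k > 0$ and the
  $\sin\Delta\varphi_k$ conditioning (bypassable with `validate = FALSE`
  for deliberate gauge experiments);
* all randomness flows from the single seed in `noise_jitter_spec()` with a
  documented stream order (jitter, channel-I noise, channel-II noise), so
  seeded runs are bit-reproducible, including through the CLI and its text
  serialization (`%.17g`).

## Known limitations

* Hilbert-based extraction carries a residual $\sim J/(2\pi d)$ bias from
  cross-side envelope leakage; it is negligible for band-limited sources
  and deep reflectors but grows for mirrors within a few tens of bins of
  zero-delay — one reason such depths are excluded from fitting.
* The chromatic vectors are undefined (clamped) outside the illuminated
  band; a correction set is only valid for the acquisition settings it was
  measured with (samples per A-line, sweep range, rates).
* The sampling-density study and temporal-drift questions are supported by
  re-running calibration under user-controlled perturbations; no physical
  drift model is included.
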