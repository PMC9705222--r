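test_that("quadrature geometry solves the linear-combination coefficients", {
  g <- quadrature_geometry(1, pi / 2)
  expect_equal(g$a, 1)
  expect_equal(g$b, 0, tolerance = 1e-15)
  g2 <- quadrature_geometry(1, pi / 3)
  expect_equal(g2$a, 2 / sqrt(3))
  expect_equal(g2$b, 1 / sqrt(3))
  expect_error(quadrature_geometry(1, 0.05), class = "qc_conditioning_error")

  # 120-degree offset (3x3 coupler geometry): reconstruction still exact
  N <- 256; n <- 0:(N - 1); th <- 2 * pi * 40 * n / N
  beta <- 0.95; dphi <- 2 * pi / 3
  s_I <- cos(th); s_II <- (1 / beta) * cos(th - dphi)
  expect_equal(reconstruct_quadrature(s_I, s_II, beta, dphi), sin(th),
               tolerance = 1e-12)
})

test_that("quadrature reconstruction matches the trig identity and (a,b) oracle", {
  N <- 256; n <- 0:(N - 1); th <- 2 * pi * 30 * n / N
  expect_equal(reconstruct_quadrature(cos(th), sin(th), 1, pi / 2), sin(th),
               tolerance = 1e-15)

  beta <- 0.9; dphi <- 1.2
  s_I <- cos(th); s_II <- (1 / beta) * cos(th - dphi)
  expect_equal(reconstruct_quadrature(s_I, s_II, beta, dphi), sin(th),
               tolerance = 1e-12)

  # oracle equivalence: a*S_II - b*S_I for a grid of (beta, dphi)
  for (beta in c(0.8, 1, 1.25)) for (dphi in c(0.5, pi / 2, 2.2)) {
    s_II <- (1 / beta) * cos(th - dphi)
    ab <- quadrature_geometry(beta, dphi)
    expect_equal(reconstruct_quadrature(s_I, s_II, beta, dphi),
                 ab$a * s_II - ab$b * s_I, tolerance = 1e-12)
  }
  expect_error(reconstruct_quadrature(cos(th), sin(th), 1, rep(0.01, N)),
               class = "qc_conditioning_error")
})

test_that("chromatically varying dphi still extinguishes the mirror", {
  N <- 1024; n <- 0:(N - 1); th <- 2 * pi * 200 * n / N
  u <- seq(-1, 1, length.out = N)
  beta_k <- 1 + 0.05 * u
  dphi_k <- pi / 2 + 0.3 * u            # crosses pi/2 +- 0.3 over the band
  s_I <- cos(th)
  s_II <- (1 / beta_k) * cos(th - dphi_k)
  sq <- reconstruct_quadrature(s_I, s_II, beta_k, dphi_k)
  P <- Mod(fftshift(stats::fft(s_I + 1i * sq)))
  i0 <- N / 2 + 1
  expect_lt(20 * log10(P[i0 - 200] / P[i0 + 200]), -100)
})

test_that("reconstruct_aline modes behave and check their contracts", {
  g <- make_kgrid(256)
  m <- coherent_average(simulate_mirror_measurement(
    imbalance_preset("ideal"), reflector_set(60 * pi / 256), g, M = 1))
  ident <- correction_set(rep(1, 256), rep(pi / 2, 256), rep(1, 256),
                          rep(0, 256), g)
  pc <- reconstruct_aline(m, ident, mode = "calibrated")
  pd <- reconstruct_aline(m, mode = "direct")
  expect_equal(pc$values, pd$values, tolerance = 1e-12)
  i0 <- 129
  expect_lt(Mod(pc$values[i0 - 60]) / Mod(pc$values[i0 + 60]), 1e-12)

  wrong <- correction_set(rep(1, 128), rep(pi / 2, 128), rep(1, 128),
                          rep(0, 128), make_kgrid(128))
  expect_error(reconstruct_aline(m, wrong, mode = "calibrated"),
               class = "qc_n_mismatch")
})

test_that("extinction reports match the closed-form error bounds", {
  g <- make_kgrid(1024)
  N <- 1024; n <- 0:(N - 1); b <- 128; th <- 2 * pi * b * n / N
  ref <- reconstruct_aline(cos(th), grid = g, mode = "standard")

  # perfect quadrature: numerical floor
  p0 <- reconstruct_aline(cos(th), s_II = sin(th), grid = g, mode = "direct")
  expect_gt(extinction_ratio(p0, b * pi / N)$extinction_db, 120)

  # amplitude-only: original-over-attenuated convention gives exactly 1/eps
  for (eps in c(1e-3, 1e-2, 0.1)) {
    p <- reconstruct_aline(cos(th), s_II = (1 + eps) * sin(th), grid = g,
                           mode = "direct")
    r <- extinction_ratio(p, b * pi / N, reference = ref)
    expect_equal(r$suppression_db, 20 * log10(1 / eps), tolerance = 1e-6)
    expect_equal(r$extinction_db, r$main_db - r$mirror_db)
    expect_equal(r$mirror_pos, -r$main_pos, tolerance = 1e-12)
  }

  # phase-only: main-over-mirror convention gives 2/|dphi|
  for (dp in c(0.002, 0.01)) {
    p <- reconstruct_aline(cos(th), s_II = sin(th + dp), grid = g, mode = "direct")
    r <- extinction_ratio(p, b * pi / N)
    expect_equal(r$extinction_db, 20 * log10(2 / dp), tolerance = 0.1)
  }
})

test_that("analytic extinction handles amplitude, phase, mixed and zero errors", {
  expect_equal(analytic_extinction(quadrature_error(0.001, 0)), 60)
  expect_equal(analytic_extinction(quadrature_error(0.1, 0)), 20)
  expect_equal(analytic_extinction(quadrature_error(0, 0.002)), 60, tolerance = 1e-9)
  expect_identical(analytic_extinction(quadrature_error(0, 0)), Inf)
  mixed <- analytic_extinction(quadrature_error(3e-4, 8e-4))
  expect_equal(mixed, -20 * log10(sqrt(3e-4^2 + 4e-4^2)), tolerance = 1e-12)
  expect_error(quadrature_error(-1.5, 0), class = "qc_range_error")
})

test_that("measured and analytic extinction agree within 0.1 dB for small errors", {
  g <- make_kgrid(1024)
  N <- 1024; n <- 0:(N - 1); b <- 200; th <- 2 * pi * b * n / N
  ref <- reconstruct_aline(cos(th), grid = g, mode = "standard")
  for (eps in c(1e-3, 5e-3, 1e-2)) {
    p <- reconstruct_aline(cos(th), s_II = (1 + eps) * sin(th), grid = g,
                           mode = "direct")
    r <- extinction_ratio(p, b * pi / N, reference = ref)
    expect_lt(abs(r$suppression_db -
                  analytic_extinction(quadrature_error(eps, 0))), 0.1)
  }
  for (dp in c(1e-3, 5e-3, 1e-2)) {
    p <- reconstruct_aline(cos(th), s_II = sin(th + dp), grid = g, mode = "direct")
    r <- extinction_ratio(p, b * pi / N)
    expect_lt(abs(r$extinction_db -
                  analytic_extinction(quadrature_error(0, dp))), 0.1)
  }
})

test_that("complex reconstruction gains 6 dB, keeps FWHM, books energy", {
  g <- make_kgrid(512)
  N <- 512; n <- 0:(N - 1); b <- 100; th <- 2 * pi * b * n / N
  imb <- imbalance_preset("realistic")
  raw <- simulate_mirror_measurement(imb, reflector_set(b * pi / N), g, M = 1)
  m <- coherent_average(raw)
  cs <- quiet_calibrate(simulate_mirror_sweep(imb, g, noise_jitter_spec(),
                                              calibration_depths(g, 31), M = 1))
  pc <- reconstruct_aline(m, cs, mode = "calibrated")
  ps <- reconstruct_aline(m, mode = "standard")
  met <- peak_shape_metrics(pc, ps, main_pos = b * pi / N)
  expect_lt(abs(met$height_gain_db - 20 * log10(2)), 0.05)
  expect_lt(abs(met$fwhm_delta_bins), 0.1)

  pd <- reconstruct_aline(m, mode = "direct")
  i0 <- N / 2 + 1
  zi <- i0 + b
  expect_gte(Mod(pd$values[zi]) + Mod(pd$values[i0 - b]),
             Mod(pc$values[zi]) - 1e-9)

  expect_equal(unlist(peak_shape_metrics(ps, ps, main_pos = b * pi / N)),
               c(height_gain_db = 0, fwhm_delta_bins = 0, floor_delta_db = 0))
})

test_that("two-channel noise raises the depth-domain floor by 3 dB", {
  g <- make_kgrid(512)
  N <- 512; n <- 0:(N - 1); b <- 100; th <- 2 * pi * b * n / N
  set.seed(12)
  deltas <- replicate(20, {
    n1 <- rnorm(N, sd = 0.02); n2 <- rnorm(N, sd = 0.02)
    pc <- reconstruct_aline(cos(th) + n1, s_II = sin(th) + n2, grid = g,
                            mode = "direct")
    ps <- reconstruct_aline(cos(th) + n1, grid = g, mode = "standard")
    peak_shape_metrics(pc, ps, main_pos = b * pi / N)$floor_delta_db
  })
  expect_lt(abs(mean(deltas) - 3.01), 0.3)
})

test_that("evaluate_sweep returns per-depth rows and an empty-safe table", {
  g <- make_kgrid(512)
  imb <- imbalance_preset("realistic")
  depths <- calibration_depths(g, 31)
  cs <- quiet_calibrate(simulate_mirror_sweep(imb, g, noise_jitter_spec(),
                                              depths, M = 1))
  hd <- heldout_depths(g, depths, 6)
  ev <- evaluate_sweep(simulate_mirror_sweep(imb, g, noise_jitter_spec(), hd, M = 1),
                       cs)
  expect_equal(nrow(ev), length(hd))
  expect_true(all(ev$extinction_db > 60))
  expect_equal(nrow(evaluate_sweep(list(), cs)), 0)
  expect_equal(nrow(evaluate_sweep(
    simulate_mirror_sweep(imb, g, noise_jitter_spec(), hd, M = 1), cs,
    heldout_depths = numeric(0))), 0)
})

test_that("calibrated B-scan reconstruction suppresses phantom ghosts", {
  g <- make_kgrid(512)
  imb <- imbalance_preset("realistic")
  cs <- quiet_calibrate(simulate_mirror_sweep(imb, g, noise_jitter_spec(),
                                              calibration_depths(g, 31), M = 1))
  layers <- phantom_layers(g, n_cols = 5, n_layers = 2, center = pi / 5,
                           spacing = pi / 20, sag = pi / 40)
  cols <- simulate_bscan_phantom(imb, g, noise_jitter_spec(), layers, M = 1)
  ghost <- function(p, depths) {
    i0 <- 257
    max(vapply(depths, function(d) {
      Mod(p$values[i0 - round(d * 512 / pi)])
    }, numeric(1))) / max(Mod(p$values))
  }
  m <- coherent_average(cols[[3]])
  d3 <- layers[[3]]$depths
  g_dir <- ghost(reconstruct_aline(m, mode = "direct"), d3)
  g_cal <- ghost(reconstruct_aline(m, cs, mode = "calibrated"), d3)
  expect_gt(g_dir, 1e-2)        # uncorrected ghosts clearly visible
  expect_lt(g_cal, 1e-4)        # calibrated ghosts suppressed > 40 dB further
})
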