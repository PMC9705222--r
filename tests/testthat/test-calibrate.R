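test_that("peak location is exact on-bin and sub-bin accurate off-bin", {
  g <- make_kgrid(1024)
  imb <- imbalance_preset("ideal")
  on <- extract_amplitude_phase(coherent_average(
    simulate_mirror_measurement(imb, reflector_set(128 * pi / 1024), g, M = 1)),
    "positive")
  pk <- locate_peak(on, g)
  expect_equal(pk$zbar_peak, pi / 8, tolerance = 1e-12)
  expect_equal(pk$side, 1)

  for (b in c(100.3, -200.45)) {
    side <- if (b > 0) "positive" else "negative"
    pair <- extract_amplitude_phase(coherent_average(
      simulate_mirror_measurement(imb, reflector_set(b * pi / 1024), g, M = 1)),
      side)
    pk <- locate_peak(pair, g)
    expect_lt(abs(pk$zbar_peak - b * pi / 1024) * 1024 / pi, 0.05)
  }

  two <- extract_amplitude_phase(coherent_average(
    simulate_mirror_measurement(imb, reflector_set(c(60, 140) * pi / 1024, c(1, 1)),
                                g, M = 1)), "positive")
  expect_error(locate_peak(two, g), class = "qc_ambiguous_peak")
})

test_that("beta/dphi extraction is exact for ideal pairs and label-antisymmetric", {
  g <- make_kgrid(256)
  pair <- extract_amplitude_phase(coherent_average(
    simulate_mirror_measurement(imbalance_preset("ideal"),
                                reflector_set(60 * pi / 256),
                                g, M = 1)), "positive")
  bd <- compute_beta_dphi(pair)
  expect_lt(max(abs(bd$beta - 1)), 1e-9)
  expect_lt(max(abs(bd$dphi - pi / 2)), 1e-9)

  swapped <- pair
  swapped$amp_I <- pair$amp_II; swapped$amp_II <- pair$amp_I
  swapped$ph_I <- pair$ph_II; swapped$ph_II <- pair$ph_I
  bs <- compute_beta_dphi(swapped)
  expect_equal(bs$beta, 1 / bd$beta, tolerance = 1e-12)
  expect_equal(quadcal:::wrap_pi(bs$dphi + bd$dphi), rep(0, 256), tolerance = 1e-9)

  dead <- pair
  dead$amp_II <- rep(0, 256)
  expect_error(compute_beta_dphi(dead), class = "qc_division_guard")
})

test_that("chromatic-only ground truth is recovered within 1e-3", {
  g <- make_kgrid(512)
  imb <- imbalance_preset("chromatic-only")
  tr <- true_beta_dphi(imb, g)
  pair <- extract_amplitude_phase(coherent_average(
    simulate_mirror_measurement(imb, reflector_set(150 * pi / 512), g, M = 1)),
    "positive")
  bd <- compute_beta_dphi(pair)
  core <- lit_mask(g)
  expect_lt(max(abs(bd$beta - tr$beta_k)[core]), 1e-3)
  expect_lt(max(abs(bd$dphi - tr$dphi_k)[core]), 1e-3)
})

test_that("fit_along_k reproduces polynomials, denoises, and honours exclusions", {
  N <- 400
  x <- seq(-1, 1, length.out = N)
  truth <- 1 + 0.2 * x - 0.4 * x^2 + 0.15 * x^3
  expect_lt(max(abs(fit_along_k(truth, method = "polynomial", degree = 3) - truth)),
            1e-9)

  set.seed(9)
  reduction <- replicate(10, {
    noisy <- truth + rnorm(N, sd = 0.01)
    fit <- fit_along_k(noisy, trusted_mask(N), degree = 3)
    sqrt(mean((noisy - truth)^2)) / sqrt(mean((fit - truth)^2))
  })
  expect_gt(stats::median(reduction), 3)

  spiked <- truth
  spiked[2] <- 50                       # inside the excluded edge margin
  tm <- trusted_mask(N, 0.05)
  expect_lt(max(abs(fit_along_k(spiked, tm, degree = 3) -
                    fit_along_k(truth, tm, degree = 3))), 1e-6)

  expect_error(fit_along_k(truth, c(rep(TRUE, 5), rep(FALSE, N - 5)), degree = 7),
               class = "qc_underdetermined")
})

test_that("spatial vectors are recovered, gauge-normalized and side-checked", {
  g <- make_kgrid(512)
  cfg <- calibration_config()
  imb <- imbalance_preset("rf-only")
  depths <- calibration_depths(g, 31)
  sweep <- simulate_mirror_sweep(imb, g, noise_jitter_spec(), depths, M = 1)
  samples <- lapply(sweep, function(b) depth_sample(coherent_average(b), cfg))
  sp <- fit_spatial_vectors(samples, g, cfg)
  tr <- gauged_truth(imb, g)
  expect_lt(max(abs(sp$beta_z - tr$beta_z)), 1e-3)
  expect_lt(max(abs(sp$dphi_z - tr$dphi_z)), 1e-3)
  i0 <- 257
  expect_equal(sp$beta_z[i0], 1)
  expect_equal(sp$dphi_z[i0], 0)

  # flat depth response: unity/zero everywhere
  flat <- simulate_mirror_sweep(imbalance_preset("chromatic-only"), g,
                                noise_jitter_spec(), depths, M = 1)
  sf <- fit_spatial_vectors(
    lapply(flat, function(b) depth_sample(coherent_average(b), cfg)), g, cfg)
  expect_lt(max(abs(sf$beta_z - 1)), 1e-6)
  expect_lt(max(abs(sf$dphi_z)), 1e-6)

  # a sample inside the zero-delay exclusion radius changes nothing
  near0 <- depth_sample(coherent_average(
    simulate_mirror_measurement(imb, reflector_set(2 * pi / 512), g, M = 1)),
    cfg, side = "positive")
  sp2 <- fit_spatial_vectors(c(samples, list(near0)), g, cfg)
  expect_equal(sp2$beta_z, sp$beta_z, tolerance = 1e-12)

  onesided <- samples[vapply(samples, function(s) s$zbar_peak > 0, logical(1))]
  expect_error(fit_spatial_vectors(onesided, g, cfg), class = "qc_coverage_error")
})

test_that("spatial correction is gauge-guarded and self-consistent", {
  g <- make_kgrid(512)
  cfg <- calibration_config()
  imb <- imbalance_preset("rf-only")
  m <- coherent_average(simulate_mirror_measurement(imb, reflector_set(98 * pi / 512),
                                                    g, M = 1))

  ident <- apply_spatial_correction(m, rep(1, 512), rep(0, 512), "positive")
  expect_equal(ident$s_II, m$s_II, tolerance = 1e-12)
  expect_error(apply_spatial_correction(m, rep(1.2, 512), rep(0, 512), "positive"),
               class = "qc_gauge_error")

  # after correction, dphi(k) agrees between two well-separated depths
  depths <- calibration_depths(g, 31)
  sweep <- simulate_mirror_sweep(imb, g, noise_jitter_spec(), depths, M = 1)
  samples <- lapply(sweep, function(b) depth_sample(coherent_average(b), cfg))
  sp <- fit_spatial_vectors(samples, g, cfg)
  core <- lit_mask(g)
  dp <- lapply(c(65, -179) * pi / 512, function(z) {
    mm <- coherent_average(simulate_mirror_measurement(imb, reflector_set(z), g, M = 1))
    side <- if (z > 0) "positive" else "negative"
    cm <- apply_spatial_correction(mm, sp$beta_z, sp$dphi_z, side)
    compute_beta_dphi(extract_amplitude_phase(cm, side))$dphi
  })
  expect_lt(stats::median(abs(dp[[1]] - dp[[2]])[core]), 1e-3)

  # an on-bin tone's depth-domain peak scales by beta_z at its position
  tr <- gauged_truth(imb, g)
  i0 <- 257
  bcorr <- apply_spatial_correction(m, tr$beta_z, rep(0, 512), "positive")
  pk <- function(x) max(Mod(fftshift(stats::fft(x + 0i))))
  zi <- i0 + 98
  expect_lt(abs(pk(bcorr$s_II) / pk(m$s_II) - tr$beta_z[zi]), 1e-3 * tr$beta_z[zi])
})

test_that("chromatic averaging matches truth and rejects outlier depths", {
  g <- make_kgrid(512)
  cfg <- calibration_config()
  imb <- imbalance_preset("chromatic-only")
  tr <- true_beta_dphi(imb, g)
  depths <- calibration_depths(g, 15)
  sweep <- simulate_mirror_sweep(imb, g, noise_jitter_spec(), depths, M = 1)
  meas <- lapply(sweep, coherent_average)
  sides <- vapply(meas, detect_side, character(1))
  ch <- compute_chromatic_vectors(meas, sides, g, cfg)
  core <- lit_mask(g)
  expect_lt(max(abs(ch$beta_k - tr$beta_k)[core]), 1e-3)
  expect_lt(max(abs(ch$dphi_k - tr$dphi_k)[core]), 1e-3)
  expect_true(all(ch$used))

  # corrupt one depth: flagged, and the average survives unharmed
  bad <- meas
  bad[[4]]$s_II <- bad[[4]]$s_II * 1.2
  ch2 <- compute_chromatic_vectors(bad, sides, g, cfg)
  expect_false(ch2$used[4])
  expect_lt(max(abs(ch2$beta_k - ch$beta_k)[core]), 1e-3)
})

test_that("the full calibration pipeline recovers identity and truth", {
  g <- make_kgrid(512)
  depths <- calibration_depths(g, 31)
  sweep <- simulate_mirror_sweep(imbalance_preset("ideal"), g,
                                 noise_jitter_spec(), depths, M = 1)
  cs <- quiet_calibrate(sweep)
  expect_lt(max(abs(cs$beta_k - 1)), 1e-6)
  expect_lt(max(abs(cs$dphi_k - pi / 2)), 1e-6)
  expect_lt(max(abs(cs$beta_z - 1)), 1e-6)
  expect_lt(max(abs(cs$dphi_z)), 1e-6)

  # parameter recovery: products/sums match the ground truth everywhere lit
  imb <- imbalance_preset("realistic")
  cs2 <- quiet_calibrate(simulate_mirror_sweep(imb, g, noise_jitter_spec(),
                                               depths, M = 1))
  tr <- true_beta_dphi(imb, g)
  core_k <- which(lit_mask(g))
  core_z <- which(abs(g$zbar) > 6 * pi / 512 & abs(g$zbar) < 1.35)
  for (iz in core_z[seq(1, length(core_z), by = 24)]) {
    expect_lt(max(abs(cs2$beta_k[core_k] * cs2$beta_z[iz] -
                      tr$beta_k[core_k] * tr$beta_z[iz])), 1e-3)
    expect_lt(max(abs(cs2$dphi_k[core_k] + cs2$dphi_z[iz] -
                      (tr$dphi_k[core_k] + tr$dphi_z[iz]))), 1e-3)
  }

  # a measurement parked at zero-delay is either dropped as degenerate or
  # excluded by the zero-delay radius; the result is unchanged either way
  at0 <- simulate_mirror_measurement(imb, reflector_set(0), g, M = 1)
  cs2b <- suppressWarnings(calibrate(c(
    simulate_mirror_sweep(imb, g, noise_jitter_spec(), depths, M = 1),
    list(at0))))
  expect_equal(cs2b$beta_z, cs2$beta_z, tolerance = 1e-9)
  expect_equal(cs2b$beta_k, cs2$beta_k, tolerance = 1e-9)
})

test_that("correction sets validate their invariants", {
  g <- make_kgrid(64)
  ones <- rep(1, 64); zeros <- rep(0, 64); quad <- rep(pi / 2, 64)
  cs <- correction_set(ones, quad, ones, zeros, g)
  expect_s3_class(cs, "correction_set")
  expect_error(correction_set(ones, quad, ones * 2, zeros, g),
               class = "qc_gauge_error")
  expect_error(correction_set(ones, rep(0.05, 64), ones, zeros, g),
               class = "qc_conditioning_error")
  expect_error(correction_set(-ones, quad, ones, zeros, g),
               class = "qc_range_error")
  # validate = FALSE admits deliberately un-gauged sets (gauge-invariance tests)
  expect_s3_class(correction_set(ones, quad, ones * 2, zeros, g, validate = FALSE),
                  "correction_set")
})
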