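# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small (N = 256..512) except where a criterion prescribes the
# acceptance scale.

tone_pair <- function(N, b, amp_II = 1, dphi = pi / 2) {
  # channel I = cos, channel II lagging by dphi with amplitude amp_II
  n <- 0:(N - 1)
  th <- 2 * pi * b * n / N
  list(s_I = cos(th), s_II = amp_II * cos(th - dphi), th = th)
}

quiet_calibrate <- function(...) suppressWarnings(calibrate(...))

# ground-truth vectors in the calibration gauge (beta_z(0) = 1, dphi_z(0) = 0)
gauged_truth <- function(imb, grid) {
  tr <- true_beta_dphi(imb, grid)
  i0 <- grid$N %/% 2L + 1L
  list(beta_z = tr$beta_z / tr$beta_z[i0],
       dphi_z = tr$dphi_z - tr$dphi_z[i0],
       beta_k = tr$beta_k * tr$beta_z[i0],
       dphi_k = tr$dphi_k + tr$dphi_z[i0])
}

new_raw_batch_for_test <- function(ch_I, ch_II, grid) {
  quadcal:::new_raw_batch(ch_I, ch_II, grid)
}

k_unit_for_test <- function(grid) quadcal:::k_unit(grid)

# mask of k-samples that are both trusted and carry light for a preset
lit_mask <- function(grid, edge_frac = 0.05, floor = 0.01) {
  u <- 2 * (seq_len(grid$N) - 1) / (grid$N - 1) - 1
  trusted_mask(grid$N, edge_frac) & exp(-9 * u^2) > floor
}
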