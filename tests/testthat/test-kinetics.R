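test_that("patch capacitance: sphere limit, oracle agreement, scaling law", {
  g <- patch_capacitance(10, 10)
  expect_equal(g$area_um2, pi * 100)
  expect_equal(g$capacitance_pf, pi, tolerance = 1e-9)
  # near-sphere continuity of the closed form
  eps <- patch_capacitance(10 - 1e-7, 10)
  expect_equal(eps$area_um2, pi * 100, tolerance = 1e-6)
  # numerical surface-of-revolution oracle
  g2 <- patch_capacitance(8, 12)
  expect_equal(g2$area_um2, spheroid_area_numeric(8, 12), tolerance = 1e-8)
  expect_equal(g2$area_um2, 270.7, tolerance = 1e-3)
  expect_equal(g2$capacitance_pf, 2.707, tolerance = 1e-3)
  # doubling both axes quadruples area
  g4 <- patch_capacitance(16, 24)
  expect_equal(g4$area_um2, 4 * g2$area_um2)
  expect_error(patch_capacitance(12, 8), "axis")
  # general-ellipsoid approximation stays within ~1% of the closed form
  gt <- patch_capacitance(8, 12, method = "thomsen")
  expect_equal(gt$area_um2, g2$area_um2, tolerance = 0.02)
})

test_that("current density divides the baseline-subtracted peak by capacitance", {
  cfg <- sim_config(1)
  geom <- patch_capacitance(10, 10)
  sw <- gen_asic_current(-471, 300, -20, cfg)
  m <- current_density(sw, geom)
  expect_equal(m$peak_pa, -471)
  expect_equal(m$density_pa_pf, 471 / pi)
  expect_equal(m$density_pa_pf, 150, tolerance = 1e-3)
  # flat sweep -> zero density
  flat <- sweep_recording(sw$time_s, rep(0, length(sw$time_s)), clamp = "vc",
                          sampling_khz = cfg$sampling_khz, pulse = sw$pulse)
  expect_equal(current_density(flat, geom)$density_pa_pf, 0)
  # whole-trace baseline offset cancels
  off <- sweep_recording(sw$time_s, sw$value - 40, clamp = "vc",
                         sampling_khz = cfg$sampling_khz, pulse = sw$pulse)
  expect_equal(current_density(off, geom)$density_pa_pf, m$density_pa_pf,
               tolerance = 1e-12)
})

test_that("desensitization fit recovers noiseless parameters to 1e-6", {
  cfg <- sim_config(1)
  sw <- gen_asic_current(-500, 300, -20, cfg)
  f <- fit_desensitization(sw)
  expect_true(f$converged)
  expect_equal(f$a_pa, -480, tolerance = 1e-6)
  expect_equal(f$tau_ms, 300, tolerance = 1e-6)
  expect_equal(f$c_pa, -20, tolerance = 1e-6)
  # with C = 0 the current at t = tau after the peak is peak/e
  sw0 <- gen_asic_current(-500, 250, 0, cfg)
  idx <- which.min(abs(sw0$time_s - (sw0$pulse$onset_s + 0.25)))
  expect_equal(sw0$value[idx], -500 / exp(1), tolerance = 1e-3)
  # non-decaying trace flagged, not fitted
  flat <- sweep_recording(sw$time_s, rep(-100, length(sw$time_s)), clamp = "vc",
                          sampling_khz = cfg$sampling_khz, pulse = sw$pulse)
  expect_false(fit_desensitization(flat)$converged)
})

test_that("desensitization tau is robust to 2% amplitude noise", {
  errs <- vapply(1:100, function(s) {
    cfg <- sim_config(s, i_noise_pa = 10)  # 2% of the 500 pA peak
    f <- fit_desensitization(gen_asic_current(-500, 300, -20, cfg))
    abs(f$tau_ms - 300) / 300
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("Hill fit recovers noiseless parameters and predicts correctly", {
  cfg <- sim_config(1)
  tab <- gen_ph_response(6.3, 1.8, c(7.4, 7.0, 6.8, 6.5, 6.3, 6.0, 5.5, 5.0), cfg)
  f <- fit_hill_ph(tab)
  expect_equal(f$ph50, 6.3, tolerance = 1e-6)
  expect_equal(f$hill_n, 1.8, tolerance = 1e-6)
  expect_equal(f$a_max, 1, tolerance = 1e-6)
  expect_false(f$flagged)
  expect_equal(hill_response(f, 6.3), 0.5, tolerance = 1e-6)
  expect_equal(hill_response(f, 5), 0.9954, tolerance = 1e-4)
  # molar EC50 parameterization predicts identically
  resp_molar <- f$a_max / (1 + (f$ec50_m / 10^(-tab$ph))^f$hill_n)
  expect_equal(resp_molar, hill_response(f, tab$ph), tolerance = 1e-12)
  expect_error(fit_hill_ph(data.frame(ph = c(7, 6), response = c(0.1, 0.9))),
               "4 distinct")
})

test_that("reversal interpolation finds the in-span polynomial root", {
  cfg <- sim_config(1)
  lin <- gen_iv_points(67.8, seq(-60, 90, 30), cfg, slope = 4, curvature = 0)
  expect_equal(fit_reversal(lin)$vrev_mv, 67.8, tolerance = 1e-9)
  # odd-symmetric data about zero
  odd <- data.frame(v_mv = seq(-80, 80, 20), i_pa = 2 * seq(-80, 80, 20))
  expect_equal(fit_reversal(odd)$vrev_mv, 0, tolerance = 1e-9)
  quad <- gen_iv_points(61, seq(-60, 90, 30), cfg, slope = 5, curvature = 0.02)
  expect_equal(fit_reversal(quad)$vrev_mv, 61, tolerance = 1e-6)
  allpos <- data.frame(v_mv = seq(0, 40, 10), i_pa = seq(5, 45, 10))
  expect_error(fit_reversal(allpos), "sign change")
})

test_that("Nernst potential: equilibrium, antisymmetry, printed magnitude", {
  expect_equal(nernst_potential(140, 140), 0)
  expect_equal(nernst_potential(14, 135, 310), -nernst_potential(135, 14, 310))
  # 135 mM out / 14 mM in at 310 K
  expect_equal(nernst_potential(135, 14, 310), 60.5, tolerance = 1e-2)
  # room-temperature default gives the ~58 mV value
  expect_equal(nernst_potential(135, 14), 58.2, tolerance = 0.1)
  expect_error(nernst_potential(-1, 14), "positive")
})

test_that("tachyphylaxis fit recovers both printed time constants exactly", {
  cfg <- sim_config(1)
  for (tau in c(37.5, 8.9)) {
    s <- gen_tachyphylaxis_series(tau, 0.2, cfg, interval_s = 20, n_pulses = 16)
    f <- fit_tachyphylaxis(s)
    expect_false(f$flagged)
    expect_equal(f$tau_s, tau, tolerance = 1e-6)
    expect_equal(f$plateau, 0.2, tolerance = 1e-6)
  }
  flat <- data.frame(time_s = seq(0, 100, 20), amplitude = rep(1, 6))
  expect_true(fit_tachyphylaxis(flat)$flagged)
})

test_that("density is invariant to matched gain/capacitance scaling", {
  cfg <- sim_config(1)
  sw <- gen_asic_current(-300, 200, -10, cfg)
  g1 <- patch_capacitance(8, 12)
  sw2 <- sweep_recording(sw$time_s, 4 * sw$value, clamp = "vc",
                         sampling_khz = cfg$sampling_khz, pulse = sw$pulse)
  g2 <- patch_capacitance(16, 24)   # area, hence capacitance, x4
  expect_equal(current_density(sw, g1)$density_pa_pf,
               current_density(sw2, g2)$density_pa_pf, tolerance = 1e-12)
})
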