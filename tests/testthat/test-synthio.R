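test_that("generators are deterministic under a fixed seed and config", {
  cfg <- sim_config(seed = 42, i_noise_pa = 5, vm_noise_mv = 0.5)
  s1 <- gen_asic_current(-500, 300, -20, cfg)
  s2 <- gen_asic_current(-500, 300, -20, cfg)
  expect_identical(s1$value, s2$value)
  f1 <- gen_step_family(phenotype_spec("stuttering"), cfg)
  f2 <- gen_step_family(phenotype_spec("stuttering"), cfg)
  expect_identical(lapply(f1, `[[`, "value"), lapply(f2, `[[`, "value"))
  pr <- protocol_day1()
  b1 <- gen_freezing_session(pr, rep(0.3, 6), cfg)
  b2 <- gen_freezing_session(pr, rep(0.3, 6), cfg)
  expect_identical(b1$bouts, b2$bouts)
  cfg2 <- sim_config(seed = 43, i_noise_pa = 5)
  expect_false(identical(gen_asic_current(-500, 300, -20, cfg2)$value, s1$value))
})

test_that("step families embed planted passive and spiking structure", {
  cfg <- sim_config(1)
  spec <- phenotype_spec("accommodating", accommodation = 2, rin_mohm = 150)
  fam <- gen_step_family(spec, cfg)
  # hyperpolarizing steps: steady-state deflection = Rin * I exactly
  expect_equal(input_resistance(fam[[1]]), 150)
  expect_equal(input_resistance(fam[[2]]), 150)
  # planted accommodating ratio recoverable through the feature module
  # (sample-grid snapping limits agreement to ~the grid resolution)
  expect_equal(accommodating_ratio(fam), 2, tolerance = 0.005)
  # planted spike times equal detected times on every sweep
  planted <- attr(fam, "spike_times_ms")
  for (i in seq_along(fam)) {
    det <- detect_spikes(fam[[i]])
    expect_equal(det$times_ms, planted[[i]], tolerance = 1e-9)
  }
})

test_that("late-spiking family plants the first-spike delay on a 2 s step", {
  cfg <- sim_config(3)
  fam <- gen_step_family(phenotype_spec("late_spiking", delay_ms = 1769), cfg)
  dr <- spike_delay_and_rheobase(fam)
  expect_equal(dr$delay_ms, 1769)
  expect_equal(dr$rheobase_pa, 60)
})

test_that("unknown phenotype is rejected with the list of valid names", {
  expect_error(phenotype_spec("bursty"), "accommodating.*fast_spiking")
})

test_that("proton-current generator follows the desensitization law", {
  cfg <- sim_config(1)
  sw <- gen_asic_current(-500, 300, -20, cfg)
  expect_equal(min(sw$value), -500)
  expect_equal(sw$time_s[which.min(sw$value)], sw$pulse$onset_s)
  expect_true(all(sw$value[sw$time_s < sw$pulse$onset_s] == 0))
  expect_error(gen_asic_current(-500, 300, -20, cfg, dur_s = -1), "duration")
  expect_error(gen_asic_current(-500, -5, 0, cfg), "tau")
})

test_that("pH-response generator evaluates the Hill law exactly", {
  cfg <- sim_config(1)
  tab <- gen_ph_response(6.3, 1.8, c(6.3, 5, 7.4), cfg)
  expect_equal(tab$response[1], 0.5)
  # direct-evaluation oracle: 1/(1 + (10^-6.3 / 10^-pH)^1.8)
  direct <- function(ph) 1 / (1 + (10^(-6.3) / 10^(-ph))^1.8)
  expect_equal(tab$response[2], direct(5))
  expect_equal(tab$response[2], 0.9954, tolerance = 1e-4)
  expect_equal(tab$response[3], direct(7.4))  # = 0.01036
  expect_error(gen_ph_response(6.3, 1.8, numeric(0), cfg), "non-empty")
})

test_that("I-V generator plants a unique in-span zero crossing", {
  cfg <- sim_config(1)
  iv <- gen_iv_points(67.8, seq(-60, 90, 30), cfg)
  expect_equal(stats::approx(iv$i_pa, iv$v_mv, xout = 0)$y, 67.8)
  # symmetric voltages about a zero reversal give odd-symmetric currents
  ivs <- gen_iv_points(0, seq(-60, 60, 20), cfg)
  expect_equal(ivs$i_pa, -rev(ivs$i_pa))
  expect_error(gen_iv_points(100, seq(-60, 90, 30), cfg), "outside")
})

test_that("tachyphylaxis series follows the planted exponential", {
  cfg <- sim_config(1)
  s <- gen_tachyphylaxis_series(8.9, 0.2, cfg, interval_s = 20, n_pulses = 10)
  expect_equal(s$amplitude[1], 1)
  expect_equal(s$amplitude[2], 0.2 + 0.8 * exp(-20 / 8.9))
  flat <- gen_tachyphylaxis_series(8.9, 1, cfg, n_pulses = 5)
  expect_true(all(flat$amplitude == 1))
  expect_error(gen_tachyphylaxis_series(8.9, 0.2, cfg, n_pulses = 2), "3 pulses")
})

test_that("LTP series generator plants plateau, drift and rejects bad input", {
  cfg <- sim_config(1)
  expect_equal(ltp_magnitude(gen_ltp_series(2.11, cfg))$magnitude_pct, 211)
  expect_equal(ltp_magnitude(gen_ltp_series(1, cfg))$magnitude_pct, 100)
  expect_false(qc_series(gen_ltp_series(2, cfg, rs_drift = 0.25))$pass)
  expect_error(gen_ltp_series(0, cfg), "plateau")
})

test_that("freezing generator hits target fractions at the extremes", {
  cfg <- sim_config(5)
  pr <- protocol_day1()
  none <- gen_freezing_session(pr, rep(0, 6), cfg)
  expect_true(all(session_summary(none)$freezing_pct == 0))
  full <- gen_freezing_session(pr, rep(1, 6), cfg)
  expect_true(all(session_summary(full)$freezing_pct == 100))
  expect_error(gen_freezing_session(pr, c(0.5, 0.5), cfg), "per epoch")
})

test_that("cohort generator retains ground truth and separates point masses", {
  cfg <- sim_config(11)
  a <- phenotype_spec("fast_spiking"); b <- phenotype_spec("delay_firing")
  co <- gen_cohort(list(list(spec = a, n = 10, sd = c(delay_ms = 1e-6)),
                        list(spec = b, n = 10, sd = c(delay_ms = 1e-6))), cfg)
  expect_equal(co$labels, rep(c("fast_spiking", "delay_firing"), each = 10))
  lab <- assign_labels(ward_cluster(minmax_normalize(
    co$features[, "delay_ms", drop = FALSE])), 2)
  expect_equal(label_agreement(lab, co$labels), 1)
  expect_error(gen_cohort(list(list(spec = a, n = 5, sd = c(delay_ms = -1))),
                          cfg), "positive")
})

test_that("sweep CSV + sidecar round-trips losslessly", {
  cfg <- sim_config(1)
  sw <- gen_asic_current(-471, 250, -15, cfg, ph = 5, holding_mv = -60)
  path <- file.path(withr::local_tempdir(), "sweep.csv")
  write_sweep(sw, path)
  back <- read_sweep(path)
  expect_equal(back$value, sw$value)
  expect_equal(back$pulse$ph, 5)
  expect_equal(back$holding_mv, -60)
  expect_equal(back$sampling_khz, sw$sampling_khz)
})
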