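test_that("spike detection finds planted crossings and rejects wrong input", {
  fs <- 10    # kHz
  t <- seq(0, 1.2, by = 1 / (fs * 1000))
  v <- rep(-65, length(t))
  planted <- c(0.2, 0.5, 0.9)
  for (tp in planted) v[round(tp * fs * 1000) + 1 + 0:5] <- 30
  sw <- sweep_recording(t, v, clamp = "cc", sampling_khz = fs,
                        step = list(amp_pa = 100, start_s = 0.1, end_s = 1.1))
  tr <- detect_spikes(sw)
  expect_equal(tr$times_ms, (planted - 0.1) * 1000, tolerance = 1e-9)

  flat <- sweep_recording(t, rep(-65, length(t)), clamp = "cc", sampling_khz = fs,
                          step = list(amp_pa = 100, start_s = 0.1, end_s = 1.1))
  expect_length(detect_spikes(flat)$times_ms, 0)

  vc <- sweep_recording(t, rep(0, length(t)), clamp = "vc", sampling_khz = fs)
  expect_error(detect_spikes(vc), "current-clamp")

  # 30 planted spikes -> count oracle feeds the rate feature
  v30 <- rep(-65, length(t))
  times30 <- 0.1 + (1:30) / 31
  for (tp in times30) v30[round(tp * fs * 1000) + 1 + 0:5] <- 30
  sw30 <- sweep_recording(t, v30, clamp = "cc", sampling_khz = fs,
                          step = list(amp_pa = 200, start_s = 0.1, end_s = 1.1))
  expect_equal(max_mean_firing_rate(list(sw30)), 30)
})

test_that("accommodating ratio follows its defining formula and max rule", {
  # ISIs: five of 10 ms then five of 20 ms -> ratio 20/10 = 2
  tr <- make_train(cumsum(c(5, rep(10, 5), rep(20, 5))), amp_pa = 75)
  expect_equal(accommodating_ratio(list(tr)), 2)
  # perfectly regular -> 1
  reg <- make_train(cumsum(c(5, rep(15, 11))), amp_pa = 75)
  expect_equal(accommodating_ratio(list(reg)), 1)
  # maximum over qualifying sweeps
  r12 <- make_train(cumsum(c(5, rep(10, 5), rep(12, 5))), amp_pa = 75)
  r18 <- make_train(cumsum(c(5, rep(10, 5), rep(18, 5))), amp_pa = 100)
  expect_equal(accommodating_ratio(list(r12, r18)), 1.8)
  # >= 400 pA sweeps never qualify; too few spikes never qualify
  hot <- make_train(cumsum(c(5, rep(10, 5), rep(30, 5))), amp_pa = 400)
  few <- make_train(cumsum(c(5, rep(10, 8))), amp_pa = 75)
  res <- accommodating_ratio(list(hot, few))
  expect_true(is.na(res))
  expect_match(attr(res, "reason"), "qualifying")
})

test_that("spike delay is read from the rheobase sweep only", {
  none <- make_train(numeric(0), amp_pa = 50)
  lo <- make_train(c(778, 900), amp_pa = 75)
  hi <- make_train(c(100, 200, 300), amp_pa = 125)
  dr <- spike_delay_and_rheobase(list(none, lo, hi))
  expect_equal(dr$delay_ms, 778)
  expect_equal(dr$rheobase_pa, 75)
  # first spike at step onset
  onset <- make_train(c(0, 50), amp_pa = 60)
  expect_equal(spike_delay_and_rheobase(list(onset))$delay_ms, 0)
  empty <- spike_delay_and_rheobase(list(none))
  expect_true(is.na(empty$delay_ms) && is.na(empty$rheobase_pa))
})

test_that("maximal CV of ISI ratios matches the direct arithmetic oracle", {
  reg <- make_train(cumsum(rep(20, 10)), amp_pa = 75)
  expect_equal(max_cv_isi_ratio(list(reg)), 0)
  # ISIs [10,10,100,10,10,100] -> ratios [1,10,0.1,1,10]
  tr <- make_train(cumsum(c(5, 10, 10, 100, 10, 10, 100)), amp_pa = 75)
  ratios <- c(1, 10, 0.1, 1, 10)
  oracle <- stats::sd(ratios) / mean(ratios)   # sample (n-1) SD
  expect_equal(max_cv_isi_ratio(list(tr)), oracle)
  expect_equal(oracle, 1.155442, tolerance = 1e-6)
  # max rule over sweeps
  mild <- make_train(cumsum(c(5, 10, 11, 10, 11, 10)), amp_pa = 75)
  expect_equal(max_cv_isi_ratio(list(mild, tr)), oracle)
  short <- make_train(c(10, 20, 30), amp_pa = 75)  # 2 ISIs, 1 ratio: no CV
  expect_true(is.na(max_cv_isi_ratio(list(short))))
})

test_that("maximal mean firing rate is the max spike count as Hz", {
  trains <- lapply(c(4, 12, 30, 28), function(n)
    make_train(seq(10, 990, length.out = n), amp_pa = 100))
  expect_equal(max_mean_firing_rate(trains), 30)
  expect_equal(max_mean_firing_rate(list(make_train(numeric(0)))), 0)
})

test_that("input resistance applies Ohm's law to the steady state", {
  fs <- 5
  t <- seq(0, 1.2, by = 1 / (fs * 1000))
  mk <- function(amp, dv) {
    v <- rep(-65, length(t))
    v[t >= 0.1 & t < 1.1] <- -65 + dv
    sweep_recording(t, v, clamp = "cc", sampling_khz = fs,
                    step = list(amp_pa = amp, start_s = 0.1, end_s = 1.1))
  }
  expect_equal(input_resistance(mk(-50, -5)), 100)
  expect_equal(input_resistance(mk(-25, -2.5)), 100)
  expect_error(input_resistance(mk(50, 5)), "hyperpolarizing")
})

test_that("feature extraction assembles all six features with honest missingness", {
  cfg <- sim_config(2)
  fam <- gen_step_family(phenotype_spec("accommodating"), cfg)
  f <- extract_features(fam)
  expect_s3_class(f, "ephys_features")
  vals <- unlist(f[c("accommodating_ratio", "delay_ms", "max_cv_isi_ratio",
                     "max_rate_hz", "rin_mohm", "rheobase_pa")])
  expect_true(all(is.finite(vals)))
  expect_length(f$missing, 0)
  # only hyperpolarizing sweeps -> only input resistance present
  hyper <- fam[1:2]
  fh <- extract_features(hyper)
  expect_true(is.finite(fh$rin_mohm))
  expect_true(is.na(fh$accommodating_ratio) && is.na(fh$delay_ms))
  expect_true("accommodating_ratio" %in% names(fh$missing))
  expect_error(extract_features(list()), "empty")
})

test_that("ISI scale invariance: time rescaling leaves ratios, divides rate", {
  base_isis <- c(8, 10, 12, 15, 20, 26, 30, 35, 40, 44, 50)
  for (k in c(0.5, 2, 3)) {
    t1 <- make_train(cumsum(base_isis), amp_pa = 80, step_dur_s = 1)
    tk <- make_train(cumsum(base_isis * k), amp_pa = 80, step_dur_s = k)
    expect_equal(accommodating_ratio(list(tk)), accommodating_ratio(list(t1)))
    expect_equal(max_cv_isi_ratio(list(tk)), max_cv_isi_ratio(list(t1)))
    expect_equal(max_mean_firing_rate(list(tk)),
                 max_mean_firing_rate(list(t1)) / k)
  }
})

test_that("zero-noise pipeline spike counts equal planted counts for all phenotypes", {
  cfg <- sim_config(7, sampling_khz = 5)
  for (ph in c("accommodating", "stuttering", "delay_firing", "fast_spiking",
               "late_spiking", "early_spiking", "low_threshold_bursting")) {
    fam <- gen_step_family(phenotype_spec(ph), cfg)
    planted <- attr(fam, "spike_times_ms")
    for (i in seq_along(fam))
      expect_length(detect_spikes(fam[[i]])$times_ms, length(planted[[i]]))
  }
})
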