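#' Simulation configuration
#'
#' Bundles the seed, sampling rate and per-signal-class noise levels used by
#' every generator. All randomness flows from `seed` through per-call
#' streams, so the same `(seed, config)` pair always yields bit-identical
#' output and adding one generator call never perturbs another's draws.
#'
#' @param seed integer master seed.
#' @param sampling_khz sampling rate for generated traces, kHz.
#' @param vm_noise_mv additive Gaussian noise SD on voltage samples, mV.
#' @param i_noise_pa additive Gaussian noise SD on current samples, pA.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, sampling_khz = 10, vm_noise_mv = 0,
                       i_noise_pa = 0) {
  if (!.is_number(sampling_khz) || sampling_khz <= 0)
    .stopf("sampling rate must be > 0")
  structure(list(seed = as.integer(seed), sampling_khz = sampling_khz,
                 vm_noise_mv = vm_noise_mv, i_noise_pa = i_noise_pa),
            class = "sim_config")
}

.PHENOTYPES <- c("accommodating", "stuttering", "delay_firing",
                 "fast_spiking", "late_spiking", "early_spiking",
                 "low_threshold_bursting")

# nominal per-phenotype parameters; delays for the late/early-spiking
# central-amygdala types follow the printed group means, the rest are
# representative slice-physiology values (no quantitative table is given
# for them) and are user-overridable.
.PHENO_DEFAULTS <- list(
  accommodating          = list(rheobase_pa = 75,  rin_mohm = 150, max_rate_hz = 40,
                                accommodation = 2.5, delay_ms = 25,  step_dur_s = 1),
  stuttering             = list(rheobase_pa = 100, rin_mohm = 200, max_rate_hz = 60,
                                accommodation = 1.2, delay_ms = 40,  step_dur_s = 1),
  delay_firing           = list(rheobase_pa = 120, rin_mohm = 120, max_rate_hz = 30,
                                accommodation = 1.1, delay_ms = 600, step_dur_s = 1),
  fast_spiking           = list(rheobase_pa = 150, rin_mohm = 100, max_rate_hz = 120,
                                accommodation = 1.05, delay_ms = 10, step_dur_s = 1),
  late_spiking           = list(rheobase_pa = 60,  rin_mohm = 250, max_rate_hz = 25,
                                accommodation = 1.1, delay_ms = 1769, step_dur_s = 2),
  early_spiking          = list(rheobase_pa = 70,  rin_mohm = 220, max_rate_hz = 30,
                                accommodation = 1.2, delay_ms = 778, step_dur_s = 2),
  low_threshold_bursting = list(rheobase_pa = 50,  rin_mohm = 180, max_rate_hz = 45,
                                accommodation = 3,  delay_ms = 5,   step_dur_s = 1)
)

#' Firing-phenotype specification
#'
#' Describes one of the seven firing phenotypes seen across basolateral and
#' central amygdala neurons, with the planted parameters that the feature
#' extractor must be able to recover: accommodation factor (ratio of late to
#' early interspike intervals), first-spike delay at rheobase, maximal mean
#' firing rate, input resistance and rheobase.
#'
#' @param name one of `"accommodating"`, `"stuttering"`, `"delay_firing"`,
#'   `"fast_spiking"`, `"late_spiking"`, `"early_spiking"`,
#'   `"low_threshold_bursting"`.
#' @param ... overrides for the named defaults: `rheobase_pa`, `rin_mohm`,
#'   `max_rate_hz`, `accommodation`, `delay_ms`, `step_dur_s`.
#' @return A list of class `phenotype_spec`.
#' @export
phenotype_spec <- function(name, ...) {
  if (!name %in% .PHENOTYPES)
    .stopf("unknown phenotype '%s'; valid names: %s", name,
           paste(.PHENOTYPES, collapse = ", "))
  spec <- .PHENO_DEFAULTS[[name]]
  dots <- list(...)
  bad <- setdiff(names(dots), names(spec))
  if (length(bad)) .stopf("unknown phenotype parameters: %s",
                          paste(bad, collapse = ", "))
  spec[names(dots)] <- dots
  spec$name <- name
  if (spec$delay_ms < 0 || spec$delay_ms > spec$step_dur_s * 1000)
    .stopf("delay must lie within [0, step duration]")
  if (spec$max_rate_hz < 0) .stopf("max rate must be >= 0")
  structure(spec, class = "phenotype_spec")
}

# ISI weight pattern for a train of n spikes; late/early mean ratio equals
# `accom` exactly whenever there are >= 10 ISIs
.isi_weights <- function(name, n_spikes, accom, cfg, stream_counter) {
  n_isi <- n_spikes - 1L
  if (n_isi < 1L) return(numeric(0))
  if (name == "stuttering") {
    # bursts of five spikes separated by long jittered gaps
    w <- numeric(0)
    k <- 0L
    jit <- .with_stream(cfg, "stutter_gaps",
                        stats::runif(ceiling(n_isi / 4), 0.7, 1.3),
                        counter = stream_counter)
    while (length(w) < n_isi) {
      k <- k + 1L
      w <- c(w, rep(1, 4), 12 * jit[k])
    }
    return(w[seq_len(n_isi)])
  }
  if (name == "low_threshold_bursting") {
    # onset burst then slow regular firing
    nb <- min(4L, n_isi)
    return(c(rep(0.15, nb), rep(1, n_isi - nb)))
  }
  if (n_isi >= 10L) {
    mid <- if (n_isi > 10L)
      exp(seq(log(1), log(accom), length.out = n_isi - 8L))[-c(1L, n_isi - 8L)]
    else numeric(0)
    c(rep(1, 5), mid, rep(accom, 5))
  } else if (n_isi >= 2L) {
    exp(seq(log(1), log(accom), length.out = n_isi))
  } else {
    1
  }
}

# planted spike times (ms from step onset) for one suprathreshold sweep;
# drive = 0 at rheobase, 1 at the largest step
.plan_spikes <- function(spec, drive, duration_ms, cfg, stream_counter) {
  delay_types <- c("delay_firing", "late_spiking", "early_spiking")
  n_max <- max(1, round(spec$max_rate_hz * duration_ms / 1000))
  n_min <- if (spec$name %in% delay_types) 1L else min(12L, n_max)
  n <- max(1L, round(n_min + (n_max - n_min) * drive))
  delay <- spec$delay_ms * (1 - 0.8 * drive)
  room <- duration_ms - delay
  if (room <= 0 || n == 1L) return(delay)
  w <- .isi_weights(spec$name, n, spec$accommodation, cfg, stream_counter)
  isis <- w * (0.95 * room / sum(w))
  delay + c(0, cumsum(isis))
}

#' Generate a current-step sweep family for one firing phenotype
#'
#' Builds the full current-clamp protocol for a synthetic cell: sweeps at
#' each requested step amplitude, with hyperpolarizing steps producing a
#' steady-state deflection of exactly `rin_mohm * amp` and suprathreshold
#' steps producing stereotyped spikes at generator-planned times. Spikes are
#' 2 ms triangular depolarizations to +30 mV; only their times carry
#' information downstream.
#'
#' @param spec a [phenotype_spec()].
#' @param cfg a [sim_config()].
#' @param amps_pa step amplitudes in pA, strictly increasing; defaults to
#'   -50, -25 then 6 depolarizing steps from rheobase upward.
#' @param duration_s step duration in s (default from the spec).
#' @param baseline_mv resting potential, mV.
#' @return A list of [sweep_recording()]s with attribute `spike_times_ms`
#'   (planted spike times per sweep, ms from step onset).
#' @export
gen_step_family <- function(spec, cfg, amps_pa = NULL,
                            duration_s = spec$step_dur_s,
                            baseline_mv = -65) {
  stopifnot(inherits(spec, "phenotype_spec"), inherits(cfg, "sim_config"))
  if (is.null(amps_pa))
    amps_pa <- c(-50, -25, round(spec$rheobase_pa + seq(0, 225, by = 45)))
  if (any(diff(amps_pa) <= 0)) .stopf("step amplitudes must be strictly increasing")
  fs <- cfg$sampling_khz * 1000
  pre_s <- 0.1; post_s <- 0.1
  n_total <- round((pre_s + duration_s + post_s) * fs)
  time_s <- seq(0, by = 1 / fs, length.out = n_total)
  step <- list(start_s = pre_s, end_s = pre_s + duration_s)
  supra <- which(amps_pa >= spec$rheobase_pa)
  sweeps <- vector("list", length(amps_pa))
  planted <- vector("list", length(amps_pa))
  for (i in seq_along(amps_pa)) {
    amp <- amps_pa[i]
    v <- rep(baseline_mv, n_total)
    in_step <- time_s >= step$start_s & time_s < step$end_s
    # passive deflection; depolarizing deflection capped below threshold
    dv <- amp * spec$rin_mohm / 1000
    if (amp > 0) dv <- min(dv, 20)
    v[in_step] <- v[in_step] + dv
    st_ms <- numeric(0)
    if (amp >= spec$rheobase_pa && spec$max_rate_hz > 0) {
      drive <- if (length(supra) > 1L)
        (match(i, supra) - 1) / (length(supra) - 1) else 0
      st_ms <- .plan_spikes(spec, drive, duration_s * 1000, cfg,
                            stream_counter = i)
      st_ms <- st_ms[st_ms <= duration_s * 1000]
      st_ms <- round(st_ms * fs / 1000) / (fs / 1000)  # snap to sample grid
      for (t0 in st_ms) {
        k <- round((pre_s + t0 / 1000) * fs) + 1L   # apex sample
        fall <- round(0.002 * fs)
        idx <- k:min(k + fall, n_total)
        v[idx] <- pmax(v[idx], seq(30, baseline_mv + dv, length.out = length(idx)))
      }
    }
    if (cfg$vm_noise_mv > 0)
      v <- v + .with_stream(cfg, "step_noise",
                            stats::rnorm(n_total, 0, cfg$vm_noise_mv),
                            counter = i)
    sweeps[[i]] <- sweep_recording(time_s, v, clamp = "cc",
                                   sampling_khz = cfg$sampling_khz,
                                   step = c(list(amp_pa = amp), step))
    planted[[i]] <- st_ms
  }
  attr(sweeps, "spike_times_ms") <- planted
  attr(sweeps, "phenotype") <- spec$name
  sweeps
}

#' Generate a proton-evoked current sweep with exponential desensitization
#'
#' Zero current before pulse onset; during the pulse the current follows
#' `(peak - steady) * exp(-t / tau) + steady` (inward currents negative),
#' returning to zero at pulse end.
#'
#' @param peak_pa peak current at pulse onset, pA (typically negative).
#' @param tau_ms desensitization time constant, ms (> 0).
#' @param steady_pa steady-state current, pA.
#' @param cfg a [sim_config()]; `i_noise_pa` sets additive Gaussian noise.
#' @param onset_s,dur_s pulse onset and duration, s.
#' @param total_s trace length, s.
#' @param ph test pH recorded in the pulse metadata.
#' @param holding_mv holding potential, mV.
#' @return A [sweep_recording()] (voltage clamp).
#' @export
gen_asic_current <- function(peak_pa, tau_ms, steady_pa = 0, cfg,
                             onset_s = 0.1, dur_s = 1,
                             total_s = onset_s + dur_s + 0.1,
                             ph = 5, holding_mv = -60) {
  stopifnot(inherits(cfg, "sim_config"))
  if (tau_ms <= 0) .stopf("tau must be > 0")
  if (dur_s <= 0) .stopf("pulse duration must be > 0")
  if (onset_s < 0 || onset_s + dur_s > total_s)
    .stopf("pulse must lie inside the trace")
  fs <- cfg$sampling_khz * 1000
  time_s <- seq(0, total_s, by = 1 / fs)
  i_pa <- numeric(length(time_s))
  in_pulse <- time_s >= onset_s & time_s < onset_s + dur_s
  t_ms <- (time_s[in_pulse] - onset_s) * 1000
  i_pa[in_pulse] <- (peak_pa - steady_pa) * exp(-t_ms / tau_ms) + steady_pa
  if (cfg$i_noise_pa > 0)
    i_pa <- i_pa + .with_stream(cfg, "asic_noise",
                                stats::rnorm(length(i_pa), 0, cfg$i_noise_pa))
  sweep_recording(time_s, i_pa, clamp = "vc", sampling_khz = cfg$sampling_khz,
                  pulse = list(onset_s = onset_s, dur_s = dur_s, ph = ph),
                  holding_mv = holding_mv)
}

#' Generate a normalized pH-response family under the Hill law
#'
#' Responses follow `a_max / (1 + (EC50 / c)^n)` with proton concentration
#' `c = 10^(-pH)` and `EC50 = 10^(-ph50)`, plus optional Gaussian noise.
#'
#' @param ph50 half-maximal pH.
#' @param hill_n Hill coefficient.
#' @param ph_values pH values to sample, each within [4, 8].
#' @param cfg a [sim_config()].
#' @param noise_sd Gaussian noise SD on the normalized response.
#' @param a_max maximal-effect constant (1 for normalized families).
#' @return A data frame with columns `ph`, `response`.
#' @export
gen_ph_response <- function(ph50, hill_n, ph_values, cfg, noise_sd = 0,
                            a_max = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(ph_values) == 0L) .stopf("ph_values must be non-empty")
  if (any(ph_values < 4 | ph_values > 8))
    .stopf("pH values must lie within [4, 8]")
  resp <- a_max / (1 + 10 ^ (hill_n * (ph_values - ph50)))
  if (noise_sd > 0)
    resp <- resp + .with_stream(cfg, "ph_noise",
                                stats::rnorm(length(resp), 0, noise_sd))
  data.frame(ph = ph_values, response = resp)
}

#' Generate a quadratic current-voltage point family
#'
#' `I(V) = slope * (V - vrev) + curvature * (V - vrev)^2`: a quadratic with
#' its (unique, in-span) zero crossing planted at `vrev`.
#'
#' @param vrev_mv planted reversal potential, mV; must lie inside the
#'   voltage span.
#' @param voltages_mv test potentials, mV.
#' @param cfg a [sim_config()].
#' @param slope conductance-like linear coefficient, pA/mV.
#' @param curvature quadratic coefficient, pA/mV^2.
#' @param noise_sd Gaussian noise SD on currents, pA.
#' @return A data frame with columns `v_mv`, `i_pa`.
#' @export
gen_iv_points <- function(vrev_mv, voltages_mv, cfg, slope = 5,
                          curvature = 0, noise_sd = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  if (vrev_mv < min(voltages_mv) || vrev_mv > max(voltages_mv))
    .stopf("planted reversal %g mV lies outside the voltage span [%g, %g]",
           vrev_mv, min(voltages_mv), max(voltages_mv))
  dv <- voltages_mv - vrev_mv
  i_pa <- slope * dv + curvature * dv^2
  if (noise_sd > 0)
    i_pa <- i_pa + .with_stream(cfg, "iv_noise",
                                stats::rnorm(length(i_pa), 0, noise_sd))
  data.frame(v_mv = voltages_mv, i_pa = i_pa)
}

#' Generate a tachyphylaxis (cumulative run-down) amplitude series
#'
#' Normalized peak amplitudes across repeated agonist pulses:
#' `amp(t) = (1 - plateau) * exp(-t / tau) + plateau`, `t = 0` at the first
#' pulse, so the first amplitude is 1 by construction.
#'
#' @param tau_s run-down time constant, s.
#' @param plateau asymptotic normalized amplitude, fraction in [0, 1].
#' @param cfg a [sim_config()].
#' @param interval_s inter-pulse interval, s (default 20 s, i.e. 0.05 Hz).
#' @param n_pulses number of pulses (>= 3).
#' @param noise_sd Gaussian noise SD on normalized amplitudes.
#' @return A data frame with columns `time_s`, `amplitude`.
#' @export
gen_tachyphylaxis_series <- function(tau_s, plateau = 0.2, cfg,
                                     interval_s = 20, n_pulses = 16,
                                     noise_sd = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  if (interval_s <= 0) .stopf("inter-pulse interval must be > 0")
  if (n_pulses < 3) .stopf("need at least 3 pulses for a fittable series")
  if (tau_s <= 0) .stopf("tau must be > 0")
  t <- (seq_len(n_pulses) - 1) * interval_s
  amp <- (1 - plateau) * exp(-t / tau_s) + plateau
  if (noise_sd > 0)
    amp <- amp + .with_stream(cfg, "tachy_noise",
                              stats::rnorm(n_pulses, 0, noise_sd))
  data.frame(time_s = t, amplitude = amp)
}

#' Generate a synaptic-response amplitude series around an HFS event
#'
#' Amplitudes are sampled every `isi_s` (default 20 s); pre-HFS points sit
#' at `baseline_mean`, post-HFS points at `baseline_mean * plateau_ratio`,
#' both with multiplicative noise of coefficient of variation `noise_cv`.
#' The series-resistance log drifts linearly by a fraction `rs_drift` of its
#' initial value over the session.
#'
#' @param plateau_ratio post/pre response ratio (> 0); 2.11 emulates robust
#'   potentiation, 1 no change.
#' @param cfg a [sim_config()].
#' @param baseline_mean mean pre-HFS amplitude (arbitrary response units).
#' @param hfs_time_min HFS time, minutes from series start.
#' @param duration_min total series duration, minutes.
#' @param isi_s inter-stimulus interval, s.
#' @param noise_cv coefficient of variation of amplitude noise.
#' @param rs_drift fractional series-resistance drift over the session.
#' @param rs0_mohm initial series resistance, MOhm.
#' @return An `ltp_series` object (see [ltp_series()]).
#' @export
gen_ltp_series <- function(plateau_ratio, cfg, baseline_mean = 1,
                           hfs_time_min = 5, duration_min = 35, isi_s = 20,
                           noise_cv = 0, rs_drift = 0, rs0_mohm = 15) {
  stopifnot(inherits(cfg, "sim_config"))
  if (plateau_ratio <= 0) .stopf("plateau ratio must be > 0")
  if (hfs_time_min >= duration_min) .stopf("HFS must precede series end")
  t <- seq(0, duration_min * 60, by = isi_s)
  hfs_s <- hfs_time_min * 60
  mu <- ifelse(t < hfs_s, baseline_mean, baseline_mean * plateau_ratio)
  amp <- if (noise_cv > 0)
    mu * (1 + .with_stream(cfg, "ltp_noise",
                           stats::rnorm(length(t), 0, noise_cv)))
  else mu
  rs <- rs0_mohm * (1 + rs_drift * t / max(t))
  ltp_series(time_s = t, amplitude = amp, rs_mohm = rs, hfs_time_s = hfs_s)
}

#' Generate a freezing session from per-epoch target fractions
#'
#' Draws immobility bouts inside each protocol epoch so that the total bout
#' time equals `fraction * epoch length`; individual bout durations are
#' exponential with scale `bout_scale_s` (renormalized to the target), so
#' short sub-2 s bouts occur when the scale is small.
#'
#' @param protocol a [protocol_spec()].
#' @param fractions per-epoch target freezing fractions in [0, 1]; length
#'   must equal the number of epochs.
#' @param cfg a [sim_config()].
#' @param bout_scale_s mean bout duration, s.
#' @return A `freezing_session` (see [freezing_session()]).
#' @export
gen_freezing_session <- function(protocol, fractions, cfg, bout_scale_s = 5) {
  stopifnot(inherits(protocol, "protocol_spec"), inherits(cfg, "sim_config"))
  ep <- protocol$epochs
  if (length(fractions) != nrow(ep))
    .stopf("need one fraction per epoch (%d epochs, %d fractions)",
           nrow(ep), length(fractions))
  if (any(fractions < 0 | fractions > 1))
    .stopf("fractions must lie in [0, 1]")
  bouts <- list()
  for (i in seq_len(nrow(ep))) {
    len <- ep$end_s[i] - ep$start_s[i]
    target <- fractions[i] * len
    if (target <= 0) next
    if (target >= len) {
      bouts[[length(bouts) + 1L]] <- data.frame(
        epoch = ep$label[i], start_s = ep$start_s[i], end_s = ep$end_s[i])
      next
    }
    nb <- max(1L, round(target / bout_scale_s))
    draws <- .with_stream(cfg, "freeze_bouts", {
      d <- stats::rexp(nb, 1 / bout_scale_s)
      g <- stats::rexp(nb + 1L, 1)
      list(d = d, g = g)
    }, counter = i)
    dur <- draws$d * target / sum(draws$d)          # exact total bout time
    gaps <- draws$g * (len - target) / sum(draws$g) # partition the free time
    starts <- ep$start_s[i] + cumsum(gaps)[seq_len(nb)] +
      c(0, cumsum(dur))[seq_len(nb)]
    bouts[[length(bouts) + 1L]] <- data.frame(
      epoch = ep$label[i], start_s = starts, end_s = starts + dur)
  }
  b <- if (length(bouts)) do.call(rbind, bouts) else
    data.frame(epoch = character(0), start_s = numeric(0), end_s = numeric(0))
  freezing_session(protocol, b[, c("start_s", "end_s")])
}

#' Generate a labeled cohort of synthetic cells
#'
#' Draws per-cell planted feature values from truncated normal laws around
#' each phenotype's target parameters, keeping the ground-truth labels so
#' classifier recovery can be scored. With `sweeps = TRUE` a full
#' current-step family is generated per cell from its individual parameters.
#'
#' @param types a list; each element a list with `spec` (a
#'   [phenotype_spec()]), `n` (cells of that type), and optionally `sd`, a
#'   named numeric vector of dispersions for any of `delay_ms`,
#'   `accommodation`, `max_rate_hz`, `rin_mohm`, `rheobase_pa` (default:
#'   15% of the type mean).
#' @param cfg a [sim_config()].
#' @param sweeps if `TRUE`, also generate each cell's step family.
#' @return A list with `features` (data frame: one row per cell with the
#'   planted parameter values plus `cell_id`), `labels` (character ground
#'   truth), and when requested `cells` (list of sweep families).
#' @export
gen_cohort <- function(types, cfg, sweeps = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  pars <- c("delay_ms", "accommodation", "max_rate_hz", "rin_mohm", "rheobase_pa")
  lower <- c(delay_ms = 0, accommodation = 0.2, max_rate_hz = 1,
             rin_mohm = 10, rheobase_pa = 10)
  rows <- list(); labels <- character(0); cells <- list()
  cell_id <- 0L
  for (ti in seq_along(types)) {
    ty <- types[[ti]]
    stopifnot(inherits(ty$spec, "phenotype_spec"))
    if (is.null(ty$n) || ty$n < 1) .stopf("each type needs n >= 1 cells")
    mu <- unlist(ty$spec[pars])
    sdv <- 0.15 * abs(mu)
    if (!is.null(ty$sd)) {
      if (any(ty$sd <= 0)) .stopf("dispersions must be positive")
      sdv[names(ty$sd)] <- ty$sd
    }
    upper <- c(delay_ms = ty$spec$step_dur_s * 1000, accommodation = Inf,
               max_rate_hz = Inf, rin_mohm = Inf, rheobase_pa = Inf)
    for (j in seq_len(ty$n)) {
      cell_id <- cell_id + 1L
      vals <- .with_stream(cfg, "cohort_cell",
                           stats::rnorm(length(mu), mu, sdv),
                           counter = cell_id)
      names(vals) <- pars
      vals <- pmin(pmax(vals, lower[pars]), upper[pars])
      rows[[cell_id]] <- c(cell_id = cell_id, vals)
      labels[cell_id] <- ty$spec$name
      if (sweeps) {
        cspec <- do.call(phenotype_spec,
                         c(list(name = ty$spec$name), as.list(vals),
                           list(step_dur_s = ty$spec$step_dur_s)))
        cells[[cell_id]] <- gen_step_family(
          cspec, sim_config(seed = .stream_seed(cfg$seed, "cohort_sweeps", cell_id),
                            sampling_khz = cfg$sampling_khz,
                            vm_noise_mv = cfg$vm_noise_mv))
      }
    }
  }
  out <- list(features = as.data.frame(do.call(rbind, rows)), labels = labels)
  if (sweeps) out$cells <- cells
  out
}
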