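#' Detect action potentials in a current-clamp sweep
#'
#' One spike per upward crossing of `threshold_mv`, with crossings closer
#' than `refractory_ms` to the previous accepted spike discarded. Spike
#' times are reported at the crossing sample, in ms relative to step onset.
#'
#' @param sweep a current-clamp [sweep_recording()].
#' @param threshold_mv detection threshold, mV (default 0).
#' @param refractory_ms minimum separation between spikes, ms.
#' @return A list of class `spike_train`: `times_ms` (relative to step
#'   onset), `amp_pa` (injected current), `step_dur_s`.
#' @export
detect_spikes <- function(sweep, threshold_mv = 0, refractory_ms = 1) {
  stopifnot(inherits(sweep, "sweep_recording"))
  if (sweep$clamp != "cc")
    .stopf("spike detection needs a current-clamp sweep, got voltage clamp")
  v <- sweep$value
  up <- which(v[-1] >= threshold_mv & v[-length(v)] < threshold_mv) + 1L
  times <- sweep$time_s[up]
  if (length(times) > 1L) {
    keep <- logical(length(times)); keep[1] <- TRUE
    last <- times[1]
    for (i in 2:length(times)) {
      if ((times[i] - last) * 1000 >= refractory_ms) {
        keep[i] <- TRUE; last <- times[i]
      }
    }
    times <- times[keep]
  }
  onset <- if (!is.null(sweep$step)) sweep$step$start_s else 0
  structure(list(times_ms = (times - onset) * 1000,
                 amp_pa = if (!is.null(sweep$step)) sweep$step$amp_pa else NA_real_,
                 step_dur_s = if (!is.null(sweep$step))
                   sweep$step$end_s - sweep$step$start_s else NA_real_),
            class = "spike_train")
}

.as_trains <- function(sweeps) {
  lapply(sweeps, function(s) if (inherits(s, "spike_train")) s else detect_spikes(s))
}

.missing_feature <- function(reason) structure(NA_real_, reason = reason)

#' Accommodating ratio
#'
#' Over sweeps qualifying under the defining rule — injected current below
#' `max_current_pa` (400 pA) and more than 10 spikes within the 1 s step —
#' computes mean(last five ISIs) / mean(first five ISIs) and returns the
#' maximum such ratio.
#'
#' @param sweeps a list of current-clamp [sweep_recording()]s or
#'   `spike_train`s.
#' @param max_current_pa qualification cap on injected current, pA.
#' @return The maximal ratio, or `NA` with a `reason` attribute when no
#'   sweep qualifies.
#' @export
accommodating_ratio <- function(sweeps, max_current_pa = 400) {
  trains <- .as_trains(sweeps)
  ratios <- vapply(trains, function(tr) {
    if (is.na(tr$amp_pa) || tr$amp_pa <= 0 || tr$amp_pa >= max_current_pa)
      return(NA_real_)
    st <- tr$times_ms[tr$times_ms >= 0 & tr$times_ms <= tr$step_dur_s * 1000]
    if (length(st) <= 10L) return(NA_real_)   # > 10 APs per second required
    isi <- diff(st)
    mean(utils::tail(isi, 5)) / mean(utils::head(isi, 5))
  }, numeric(1))
  if (all(is.na(ratios)))
    return(.missing_feature("no qualifying sweep (<400 pA with >10 spikes in the step)"))
  max(ratios, na.rm = TRUE)
}

#' Spike delay and rheobase
#'
#' Rheobase is the smallest depolarizing step amplitude eliciting at least
#' one spike; the spike delay is the latency of the first spike on that
#' (near-threshold) sweep.
#'
#' @inheritParams accommodating_ratio
#' @return A list `(delay_ms, rheobase_pa)`; both `NA` with reasons when no
#'   sweep spikes.
#' @export
spike_delay_and_rheobase <- function(sweeps) {
  trains <- .as_trains(sweeps)
  amps <- vapply(trains, function(tr) tr$amp_pa, numeric(1))
  spiking <- vapply(trains, function(tr) length(tr$times_ms) > 0, logical(1)) &
    !is.na(amps) & amps > 0
  if (!any(spiking))
    return(list(delay_ms = .missing_feature("no spiking sweep"),
                rheobase_pa = .missing_feature("no spiking sweep")))
  i <- which(spiking)[which.min(amps[spiking])]
  list(delay_ms = trains[[i]]$times_ms[1], rheobase_pa = amps[i])
}

#' Maximal coefficient of variation of ISI ratios
#'
#' Per sweep, successive-interval ratios `r_i = ISI_{i+1} / ISI_i`; the CV
#' (sample SD / mean) of those ratios is computed, and the maximum over
#' sweeps is returned. A sweep needs at least 4 spikes (2 ratios) to
#' contribute.
#'
#' @inheritParams accommodating_ratio
#' @return The maximal CV, or `NA` with a reason.
#' @export
max_cv_isi_ratio <- function(sweeps) {
  trains <- .as_trains(sweeps)
  cvs <- vapply(trains, function(tr) {
    if (length(tr$times_ms) < 4L) return(NA_real_)
    r <- diff(tr$times_ms)
    ratios <- r[-1] / r[-length(r)]
    .cv(ratios)
  }, numeric(1))
  if (all(is.na(cvs)))
    return(.missing_feature("no sweep with >= 2 ISI ratios"))
  max(cvs, na.rm = TRUE)
}

#' Maximal mean firing rate
#'
#' The maximal number of spikes generated within the 1 s current step over
#' all sweeps, expressed in Hz (counts scaled by step duration).
#'
#' @inheritParams accommodating_ratio
#' @return Rate in Hz (0 when no sweep spikes).
#' @export
max_mean_firing_rate <- function(sweeps) {
  trains <- .as_trains(sweeps)
  rates <- vapply(trains, function(tr) {
    if (is.na(tr$step_dur_s)) return(0)
    sum(tr$times_ms >= 0 & tr$times_ms <= tr$step_dur_s * 1000) / tr$step_dur_s
  }, numeric(1))
  if (!length(rates)) 0 else max(rates)
}

#' Input resistance from a hyperpolarizing step
#'
#' Steady-state voltage change (mean over the final `ss_window_ms` of the
#' step minus the pre-step baseline) divided by the injected current, for
#' -25 or -50 pA 1 s steps. Returned in MOhm, positive.
#'
#' @param sweep a current-clamp [sweep_recording()] with a hyperpolarizing
#'   step.
#' @param ss_window_ms steady-state averaging window at step end, ms.
#' @return Input resistance, MOhm.
#' @export
input_resistance <- function(sweep, ss_window_ms = 200) {
  stopifnot(inherits(sweep, "sweep_recording"))
  if (is.null(sweep$step) || sweep$step$amp_pa >= 0)
    .stopf("input resistance requires a hyperpolarizing (-25 or -50 pA) step")
  t <- sweep$time_s; v <- sweep$value
  base <- mean(v[t < sweep$step$start_s])
  ss <- mean(v[t >= sweep$step$end_s - ss_window_ms / 1000 & t < sweep$step$end_s])
  dv <- ss - base                       # mV
  dv / sweep$step$amp_pa * 1000         # mV / pA -> MOhm (positive: both negative)
}

#' Assemble the per-cell electrophysiological feature vector
#'
#' Runs all feature extractors over one cell's step family and assembles
#' the six-feature record: accommodating ratio, spike delay, maximal CV of
#' ISI ratios, maximal mean firing rate, input resistance, rheobase.
#' Features that cannot be computed are `NA` with the reason recorded in
#' the `missing` field — never silently defaulted.
#'
#' @param sweeps a list of current-clamp [sweep_recording()]s (one cell).
#' @return A list of class `ephys_features` with fields
#'   `accommodating_ratio`, `delay_ms`, `max_cv_isi_ratio`, `max_rate_hz`,
#'   `rin_mohm`, `rheobase_pa`, and `missing` (named character reasons).
#' @export
extract_features <- function(sweeps) {
  if (!length(sweeps)) .stopf("empty recording: no sweeps")
  trains <- .as_trains(sweeps)
  hyper <- Filter(function(s) inherits(s, "sweep_recording") &&
                    !is.null(s$step) && s$step$amp_pa < 0, sweeps)
  rin <- if (length(hyper))
    mean(vapply(hyper, input_resistance, numeric(1)))
  else .missing_feature("no hyperpolarizing sweep")
  acc <- accommodating_ratio(trains)
  dr <- spike_delay_and_rheobase(trains)
  cv <- max_cv_isi_ratio(trains)
  rate <- max_mean_firing_rate(trains)
  feats <- list(accommodating_ratio = acc, delay_ms = dr$delay_ms,
                max_cv_isi_ratio = cv, max_rate_hz = rate,
                rin_mohm = rin, rheobase_pa = dr$rheobase_pa)
  missing <- vapply(feats, function(f)
    if (is.na(f[1]) && !is.null(attr(f, "reason"))) attr(f, "reason") else NA_character_,
    character(1))
  feats <- lapply(feats, function(f) { attributes(f) <- NULL; f })
  feats$missing <- missing[!is.na(missing)]
  structure(feats, class = "ephys_features")
}

#' @export
print.ephys_features <- function(x, ...) {
  cat("<ephys_features>\n")
  for (nm in c("accommodating_ratio", "delay_ms", "max_cv_isi_ratio",
               "max_rate_hz", "rin_mohm", "rheobase_pa"))
    cat(sprintf("  %-20s %s\n", nm, format(x[[nm]], digits = 4)))
  if (length(x$missing))
    cat("  missing:", paste(names(x$missing), collapse = ", "), "\n")
  invisible(x)
}

#' Feature table for a cohort of cells
#'
#' @param cells a list; each element a list of sweeps for one cell.
#' @return A data frame, one row per cell, columns the six features.
#' @export
cohort_features <- function(cells) {
  rows <- lapply(cells, function(cs) {
    f <- extract_features(cs)
    data.frame(accommodating_ratio = f$accommodating_ratio,
               delay_ms = f$delay_ms, max_cv_isi_ratio = f$max_cv_isi_ratio,
               max_rate_hz = f$max_rate_hz, rin_mohm = f$rin_mohm,
               rheobase_pa = f$rheobase_pa)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
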