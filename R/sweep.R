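#' Stimulus-locked recording sweep
#'
#' The atom of all trace analysis: one uniformly sampled voltage
#' (current-clamp) or current (voltage-clamp) trace together with its
#' stimulus metadata.
#'
#' @param time_s numeric vector of sample times in seconds (uniform grid).
#' @param value numeric vector of samples; mV in current clamp, pA in
#'   voltage clamp.
#' @param clamp `"cc"` (current clamp) or `"vc"` (voltage clamp).
#' @param sampling_khz sampling rate in kHz.
#' @param step for current clamp: list with `amp_pa`, `start_s`, `end_s`
#'   describing the injected current step.
#' @param pulse for voltage clamp: list with `onset_s`, `dur_s`, and
#'   optionally `ph` (test pH) describing the agonist application.
#' @param holding_mv holding potential (voltage clamp), mV.
#' @param units unit string for `value` (`"mV"` or `"pA"`).
#'
#' @return An object of class `sweep_recording`.
#' @export
sweep_recording <- function(time_s, value, clamp = c("cc", "vc"),
                            sampling_khz, step = NULL, pulse = NULL,
                            holding_mv = NA_real_,
                            units = if (clamp == "cc") "mV" else "pA") {
  clamp <- match.arg(clamp)
  if (length(time_s) != length(value))
    .stopf("time and value vectors differ in length (%d vs %d)",
           length(time_s), length(value))
  if (!.is_number(sampling_khz) || sampling_khz <= 0)
    .stopf("sampling rate must be a positive number (kHz)")
  if (length(time_s) > 1L) {
    dt <- diff(time_s)
    if (max(abs(dt - dt[1])) > 1e-9)
      .stopf("sweep must be uniformly sampled")
  }
  if (!is.null(step)) {
    if (step$start_s < time_s[1] - 1e-12 || step$end_s > time_s[length(time_s)] + 1e-12)
      .stopf("step window [%g, %g] s lies outside the trace", step$start_s, step$end_s)
  }
  structure(
    list(time_s = as.numeric(time_s), value = as.numeric(value),
         clamp = clamp, sampling_khz = sampling_khz, step = step,
         pulse = pulse, holding_mv = holding_mv, units = units),
    class = "sweep_recording")
}

#' @export
print.sweep_recording <- function(x, ...) {
  cat(sprintf("<sweep_recording> %s, %d samples @ %g kHz (%s)\n",
              if (x$clamp == "cc") "current clamp" else "voltage clamp",
              length(x$value), x$sampling_khz, x$units))
  if (!is.null(x$step))
    cat(sprintf("  step: %g pA, %g-%g s\n", x$step$amp_pa,
                x$step$start_s, x$step$end_s))
  if (!is.null(x$pulse))
    cat(sprintf("  pulse: onset %g s, %g s%s\n", x$pulse$onset_s,
                x$pulse$dur_s,
                if (!is.null(x$pulse$ph)) sprintf(", pH %g", x$pulse$ph) else ""))
  invisible(x)
}

#' Write / read a sweep as CSV plus JSON sidecar
#'
#' Traces are stored as a two-column CSV (`time_s`, `value`); all stimulus
#' metadata (units, sampling rate, clamp mode, step or pulse description,
#' holding potential) goes into a JSON sidecar at `<path>.json`.
#'
#' @param sweep a [sweep_recording()].
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_sweep` returns `path` invisibly; `read_sweep` returns a
#'   [sweep_recording()].
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_recording"))
  utils::write.csv(data.frame(time_s = sweep$time_s, value = sweep$value),
                   path, row.names = FALSE)
  meta <- sweep[c("clamp", "sampling_khz", "step", "pulse", "holding_mv", "units")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  tab <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sweep_recording(tab$time_s, tab$value, clamp = meta$clamp,
                  sampling_khz = meta$sampling_khz,
                  step = meta$step, pulse = meta$pulse,
                  holding_mv = if (is.null(meta$holding_mv)) NA_real_ else meta$holding_mv,
                  units = meta$units)
}
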