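#' Synaptic-response amplitude series
#'
#' Container for an LTP experiment: response amplitudes sampled at the
#' stimulus times (nominally every 20 s), the series-resistance log, the
#' HFS time and the baseline window (default: the 5 min immediately
#' preceding HFS).
#'
#' @param time_s stimulus times, s, increasing.
#' @param amplitude response amplitudes (EPSP mV or EPSC pA).
#' @param rs_mohm series-resistance log, MOhm (may be `NULL` when not
#'   recorded; QC is then indeterminate).
#' @param hfs_time_s HFS time, s.
#' @param baseline_s baseline window `(start, end)`, s; must precede HFS.
#' @return An object of class `ltp_series`.
#' @export
ltp_series <- function(time_s, amplitude, rs_mohm = NULL, hfs_time_s,
                       baseline_s = c(max(0, hfs_time_s - 300), hfs_time_s)) {
  if (any(diff(time_s) <= 0)) .stopf("stimulus times must be increasing")
  if (length(amplitude) != length(time_s))
    .stopf("amplitude and time vectors differ in length")
  if (!is.null(rs_mohm) && length(rs_mohm) != length(time_s))
    .stopf("series-resistance log must align with stimulus times")
  if (baseline_s[2] > hfs_time_s + 1e-9)
    .stopf("baseline window must precede HFS")
  structure(list(time_s = time_s, amplitude = amplitude, rs_mohm = rs_mohm,
                 hfs_time_s = hfs_time_s, baseline_s = baseline_s),
            class = "ltp_series")
}

#' @export
print.ltp_series <- function(x, ...) {
  cat(sprintf("<ltp_series> %d responses over %.1f min, HFS at %.1f min\n",
              length(x$amplitude), max(x$time_s) / 60, x$hfs_time_s / 60))
  invisible(x)
}

#' Quality control of an LTP series
#'
#' Fails a series whose series resistance changes by more than
#' `max_rs_change` (default 20%, strict inequality) relative to its initial
#' value, and flags baseline instability when the linear trend over the
#' baseline window exceeds `max_baseline_slope` (fraction of the baseline
#' mean per minute). An absent series-resistance log leaves QC
#' indeterminate, not passed.
#'
#' @param series an [ltp_series()].
#' @param max_rs_change maximal tolerated fractional series-resistance
#'   change.
#' @param max_baseline_slope maximal tolerated baseline trend, fraction of
#'   baseline mean per minute.
#' @return A list of class `ltp_qc`: `pass` (TRUE/FALSE/NA), `rs_change`,
#'   `baseline_slope`, `reasons`.
#' @export
qc_series <- function(series, max_rs_change = 0.20, max_baseline_slope = 0.05) {
  stopifnot(inherits(series, "ltp_series"))
  reasons <- character(0)
  if (is.null(series$rs_mohm) || !length(series$rs_mohm)) {
    rs_change <- NA_real_
    reasons <- c(reasons, "no series-resistance log: QC indeterminate")
    pass <- NA
  } else {
    rs_change <- max(abs(series$rs_mohm - series$rs_mohm[1])) / series$rs_mohm[1]
    pass <- !(rs_change > max_rs_change)    # strict: exactly 20% passes
    if (!pass) reasons <- c(reasons,
      sprintf("series resistance changed %.1f%% (> %.0f%%)",
              100 * rs_change, 100 * max_rs_change))
  }
  bl <- series$time_s >= series$baseline_s[1] & series$time_s < series$baseline_s[2]
  baseline_slope <- NA_real_
  if (sum(bl) >= 3) {
    fit <- stats::lm(series$amplitude[bl] ~ I(series$time_s[bl] / 60))
    baseline_slope <- unname(stats::coef(fit)[2]) / mean(series$amplitude[bl])
    if (is.finite(baseline_slope) && abs(baseline_slope) > max_baseline_slope) {
      pass <- if (is.na(pass)) NA else FALSE
      reasons <- c(reasons, sprintf("unstable baseline (%.1f%%/min)",
                                    100 * baseline_slope))
    }
  }
  structure(list(pass = pass, rs_change = rs_change,
                 baseline_slope = baseline_slope, reasons = reasons),
            class = "ltp_qc")
}

#' LTP magnitude from a baseline-normalized series
#'
#' Divides all amplitudes by the baseline-window mean and reports
#' 100 x mean of normalized amplitudes whose post-HFS time lies within
#' `window_min` (default 25-30 min after HFS, endpoints inclusive).
#'
#' @param series an [ltp_series()].
#' @param window_min post-HFS measurement window, minutes, `c(from, to)`.
#' @return A list of class `ltp_result`: `magnitude_pct`, `normalized`
#'   (data frame time_s/normalized), `qc` (an `ltp_qc`), `window_min`.
#' @export
ltp_magnitude <- function(series, window_min = c(25, 30)) {
  stopifnot(inherits(series, "ltp_series"))
  qc <- qc_series(series)
  bl <- series$time_s >= series$baseline_s[1] & series$time_s < series$baseline_s[2]
  if (!any(bl)) .stopf("no points in the baseline window")
  norm <- series$amplitude / mean(series$amplitude[bl])
  post_min <- (series$time_s - series$hfs_time_s) / 60
  win <- post_min >= window_min[1] & post_min <= window_min[2]
  if (!any(win))
    .stopf("no points in the %g-%g min post-HFS window", window_min[1], window_min[2])
  structure(list(magnitude_pct = 100 * mean(norm[win]),
                 normalized = data.frame(time_s = series$time_s, normalized = norm),
                 qc = qc, window_min = window_min),
            class = "ltp_result")
}

#' @export
print.ltp_result <- function(x, ...) {
  cat(sprintf("<ltp_result> magnitude %.1f%% of baseline (%g-%g min post-HFS)\n",
              x$magnitude_pct, x$window_min[1], x$window_min[2]))
  if (isFALSE(x$qc$pass))
    cat("  QC FAILED:", paste(x$qc$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Percentage reduction of LTP between genotypes
#'
#' With magnitudes in percent of baseline, the potentiation above baseline
#' is `P = magnitude - 100`; the reduction is
#' `100 * (P_wt - P_ko) / P_wt`. Complete LTP abolition (KO at 100%) maps
#' to 100%; a KO exceeding WT gives a negative value. `method = "ratio"`
#' instead reports `100 * (1 - ko / wt)` on the raw magnitudes.
#'
#' @param wt,ko LTP magnitudes, percent of baseline.
#' @param method `"potentiation"` (default) or `"ratio"`.
#' @return Reduction in percent, or `NA` with a `reason` attribute when the
#'   WT shows no potentiation.
#' @export
delta_ltp <- function(wt, ko, method = c("potentiation", "ratio")) {
  method <- match.arg(method)
  if (method == "ratio") return(100 * (1 - ko / wt))
  if (wt <= 100)
    return(structure(NA_real_,
                     reason = "WT magnitude <= 100%: no potentiation to reduce"))
  100 * ((wt - 100) - (ko - 100)) / (wt - 100)
}

#' Correlation between ASIC current density and LTP reduction
#'
#' Pearson product-moment correlation with the regression F-test p value
#' (delegated to [pearson_regression()]).
#'
#' @param density postsynaptic ASIC current densities, pA/pF.
#' @param delta_ltp_pct LTP reductions, percent.
#' @return A list: `r`, `p`, `slope`, `intercept`, `f`, `n`.
#' @export
density_ltp_correlation <- function(density, delta_ltp_pct) {
  if (length(density) < 3) .stopf("need at least 3 points")
  reg <- pearson_regression(density, delta_ltp_pct)
  list(r = reg$r, p = reg$p, slope = reg$slope, intercept = reg$intercept,
       f = reg$f, n = length(density))
}
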