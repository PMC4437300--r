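#' Nucleated-patch geometry and capacitance
#'
#' Nucleated patches are approximately ellipsoid; the membrane surface area
#' is computed from the measured minor and major axes (full axes, not
#' semi-axes) and converted to capacitance with the standard specific
#' membrane capacitance of 1 uF/cm^2 (= 0.01 pF/um^2).
#'
#' The default surface model is the prolate spheroid closed form over
#' semi-axes `a = major/2`, `b = minor/2`:
#' `S = 2*pi*b^2 + 2*pi*a*b*asin(e)/e`, `e = sqrt(1 - b^2/a^2)`, with the
#' sphere limit handled analytically. `method = "thomsen"` switches to the
#' Knud Thomsen approximation for a general ellipsoid with the two equal
#' axes set to the minor axis.
#'
#' @param minor_um,major_um full minor and major axes, um; `0 < minor <=
#'   major`.
#' @param method `"prolate"` (closed form, default) or `"thomsen"`.
#' @return A list of class `patch_geometry`: `minor_um`, `major_um`,
#'   `area_um2`, `capacitance_pf`.
#' @export
patch_capacitance <- function(minor_um, major_um, method = c("prolate", "thomsen")) {
  method <- match.arg(method)
  if (!.is_number(minor_um) || !.is_number(major_um) || minor_um <= 0)
    .stopf("axes must be positive numbers")
  if (minor_um > major_um)
    .stopf("minor axis (%g) exceeds major axis (%g); check argument order",
           minor_um, major_um)
  a <- major_um / 2; b <- minor_um / 2
  if (method == "prolate") {
    if (abs(a - b) < 1e-12 * a) {
      area <- 4 * pi * a^2                       # sphere limit
    } else {
      e <- sqrt(1 - (b / a)^2)
      area <- 2 * pi * b^2 + 2 * pi * a * b * asin(e) / e
    }
  } else {
    p <- 1.6075
    area <- 4 * pi * ((a^p * b^p + a^p * b^p + b^p * b^p) / 3)^(1 / p)
  }
  structure(list(minor_um = minor_um, major_um = major_um, area_um2 = area,
                 capacitance_pf = area * 0.01),  # 1 uF/cm^2 = 0.01 pF/um^2
            class = "patch_geometry")
}

#' Peak current and current density of a proton-evoked sweep
#'
#' The peak is the signed extremum within the pulse window relative to the
#' pre-pulse baseline (inward currents at negative holding potentials are
#' negative; `direction` selects the expected sign). Density is
#' `|peak| / capacitance` in pA/pF.
#'
#' @param sweep a voltage-clamp [sweep_recording()] with pulse metadata.
#' @param geometry a [patch_capacitance()] result.
#' @param direction `"inward"` (default) or `"outward"` expected current
#'   direction.
#' @return A list of class `asic_metrics`: `peak_pa` (baseline-subtracted),
#'   `density_pa_pf`, `capacitance_pf`, `ph`, `holding_mv`.
#' @export
current_density <- function(sweep, geometry, direction = c("inward", "outward")) {
  direction <- match.arg(direction)
  stopifnot(inherits(sweep, "sweep_recording"), inherits(geometry, "patch_geometry"))
  if (sweep$clamp != "vc") .stopf("current density needs a voltage-clamp sweep")
  if (is.null(sweep$pulse)) .stopf("sweep carries no pulse metadata")
  if (geometry$capacitance_pf <= 0) .stopf("capacitance must be positive")
  t <- sweep$time_s; i <- sweep$value
  pre <- i[t < sweep$pulse$onset_s]
  base <- if (length(pre)) mean(pre) else 0
  inp <- i[t >= sweep$pulse$onset_s & t < sweep$pulse$onset_s + sweep$pulse$dur_s] - base
  peak <- if (direction == "inward") min(inp) else max(inp)
  if ((direction == "inward" && peak > 0) || (direction == "outward" && peak < 0))
    peak <- 0                                   # no deflection in expected direction
  structure(list(peak_pa = peak,
                 density_pa_pf = abs(peak) / geometry$capacitance_pf,
                 capacitance_pf = geometry$capacitance_pf,
                 ph = sweep$pulse$ph, holding_mv = sweep$holding_mv),
            class = "asic_metrics")
}

# bounded Levenberg-Marquardt wrapper; returns NULL on non-convergence
.nls_fit <- function(formula, data, start, lower, upper) {
  tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
}

#' Fit exponential desensitization to a proton-evoked current
#'
#' Least-squares fit of `A * exp(-t / tau) + C` over the window from the
#' current peak to the pulse end, where `A` is the decaying component
#' amplitude, `tau` the desensitization time constant and `C` the
#' steady-state current. `tau` is initialized from the 1/e crossing.
#'
#' @param sweep a voltage-clamp [sweep_recording()] with pulse metadata.
#' @return A list of class `desens_fit`: `a_pa`, `tau_ms`, `c_pa`,
#'   `rms_pa`, `converged`. Non-decaying traces return
#'   `converged = FALSE`.
#' @export
fit_desensitization <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_recording"))
  if (is.null(sweep$pulse)) .stopf("sweep carries no pulse metadata")
  t <- sweep$time_s; i <- sweep$value
  sel <- t >= sweep$pulse$onset_s & t < sweep$pulse$onset_s + sweep$pulse$dur_s
  tp <- t[sel]; ip <- i[sel]
  pk <- which.min(ip)                 # inward peak
  tp <- (tp[pk:length(tp)] - tp[pk]) * 1000   # ms from peak
  ip <- ip[pk:length(ip)]
  a0 <- ip[1] - ip[length(ip)]
  if (abs(a0) < .Machine$double.eps^0.5 || abs(ip[1]) <= abs(ip[length(ip)]))
    return(structure(list(a_pa = NA_real_, tau_ms = NA_real_, c_pa = NA_real_,
                          rms_pa = NA_real_, converged = FALSE),
                     class = "desens_fit"))
  # 1/e crossing of the decaying component
  crossing <- which(abs(ip - ip[length(ip)]) <= abs(a0) / exp(1))[1]
  tau0 <- if (!is.na(crossing) && crossing > 1) tp[crossing] else diff(range(tp)) / 3
  fit <- .nls_fit(ip ~ A * exp(-tp / tau) + C, data.frame(tp = tp, ip = ip),
                  start = list(A = a0, tau = tau0, C = ip[length(ip)]),
                  lower = c(-Inf, 1e-6, -Inf), upper = c(Inf, Inf, Inf))
  if (is.null(fit))
    return(structure(list(a_pa = NA_real_, tau_ms = NA_real_, c_pa = NA_real_,
                          rms_pa = NA_real_, converged = FALSE),
                     class = "desens_fit"))
  cf <- stats::coef(fit)
  structure(list(a_pa = unname(cf["A"]), tau_ms = unname(cf["tau"]),
                 c_pa = unname(cf["C"]),
                 rms_pa = sqrt(mean(stats::residuals(fit)^2)),
                 converged = TRUE),
            class = "desens_fit")
}

#' Fit the Hill equation to a pH-response family
#'
#' Fits `response = A / (1 + (EC50 / c)^n)` with proton concentration
#' `c = 10^(-pH)`; equivalently, in pH, `A / (1 + 10^(n * (pH - pH50)))`.
#' The maximal effect `A` is estimated rather than assumed equal to the
#' most acidic response. Reported are the half-maximal pH
#' (`-log10(EC50)`), the Hill coefficient and `A`.
#'
#' @param points data frame with columns `ph` and `response`.
#' @param residual_threshold RMS residual above which the fit is flagged
#'   (grossly non-monotone data).
#' @return A list of class `hill_fit`: `ph50`, `ec50_m`, `hill_n`, `a_max`,
#'   `rms`, `flagged`.
#' @export
fit_hill_ph <- function(points, residual_threshold = 0.15) {
  if (length(unique(points$ph)) < 4)
    .stopf("need responses at >= 4 distinct pH values spanning the transition")
  ph <- points$ph; y <- points$response
  ph50_0 <- ph[which.min(abs(y - (min(y) + max(y)) / 2))]
  fit <- .nls_fit(y ~ A / (1 + 10 ^ (n * (ph - ph50))),
                  data.frame(ph = ph, y = y),
                  start = list(A = max(y), ph50 = ph50_0, n = 1.5),
                  lower = c(1e-6, 4, 0.1), upper = c(Inf, 8, 10))
  if (is.null(fit)) .stopf("Hill fit failed to converge")
  cf <- stats::coef(fit)
  rms <- sqrt(mean(stats::residuals(fit)^2))
  structure(list(ph50 = unname(cf["ph50"]), ec50_m = 10 ^ (-unname(cf["ph50"])),
                 hill_n = unname(cf["n"]), a_max = unname(cf["A"]), rms = rms,
                 flagged = rms > residual_threshold),
            class = "hill_fit")
}

#' Predicted Hill response at given pH
#'
#' @param fit a [fit_hill_ph()] result (or a list with `ph50`, `hill_n`,
#'   `a_max`).
#' @param ph pH value(s).
#' @return Predicted normalized response(s).
#' @export
hill_response <- function(fit, ph) {
  a <- if (is.null(fit$a_max)) 1 else fit$a_max
  a / (1 + 10 ^ (fit$hill_n * (ph - fit$ph50)))
}

#' Interpolated reversal potential from a current-voltage family
#'
#' Least-squares second-order polynomial through the (V, I) points; the
#' reversal potential is the real root inside the data span (the root
#' nearest the observed sign change if both fall in span).
#'
#' @param points data frame with columns `v_mv` and `i_pa`.
#' @return A list of class `reversal_fit`: `coef` (c0, c1, c2),
#'   `vrev_mv`, `span_mv`.
#' @export
fit_reversal <- function(points) {
  v <- points$v_mv; i <- points$i_pa
  if (length(v) < 4) .stopf("need >= 4 current-voltage points")
  if (min(i) > 0 || max(i) < 0)
    .stopf("no sign change of current within the sampled voltages")
  cf <- stats::coef(stats::lm(i ~ v + I(v^2)))
  span <- range(v)
  if (abs(cf[3]) < 1e-12) {
    roots <- -cf[1] / cf[2]
  } else {
    disc <- cf[2]^2 - 4 * cf[3] * cf[1]
    if (disc < 0) .stopf("fitted polynomial has no real root")
    roots <- (-cf[2] + c(-1, 1) * sqrt(disc)) / (2 * cf[3])
  }
  inside <- roots >= span[1] - 1e-9 & roots <= span[2] + 1e-9
  if (!any(inside))
    .stopf("no fitted root inside the data span [%g, %g]; roots: %s",
           span[1], span[2], paste(signif(roots, 6), collapse = ", "))
  cand <- roots[inside]
  if (length(cand) > 1) {
    # nearest to the observed sign change
    below <- max(v[i <= 0]); cand <- cand[which.min(abs(cand - below))]
  }
  structure(list(coef = unname(cf), vrev_mv = unname(cand), span_mv = span),
            class = "reversal_fit")
}

#' Nernst equilibrium potential
#'
#' `E = (R * T / F) * ln([ion]_out / [ion]_in)`, in mV. The default
#' temperature corresponds to near-physiological conditions; recordings at
#' room temperature should pass `temp_k = 298`.
#'
#' @param out_mm,in_mm outer and inner ion concentrations, mM (> 0).
#' @param temp_k absolute temperature, K.
#' @return Equilibrium potential, mV.
#' @export
nernst_potential <- function(out_mm, in_mm, temp_k = 298.15) {
  if (out_mm <= 0 || in_mm <= 0) .stopf("concentrations must be positive")
  R <- 8.31446; FA <- 96485.33
  1000 * R * temp_k / FA * log(out_mm / in_mm)
}

#' Fit single-exponential tachyphylaxis decay
#'
#' Fits `a * exp(-t / tau) + c` to a normalized repeated-pulse amplitude
#' series (first amplitude 1, `t = 0` at the first pulse). Series with no
#' decaying trend are flagged rather than fitted.
#'
#' @param series data frame with columns `time_s` and `amplitude`.
#' @return A list of class `tachy_fit`: `a`, `tau_s`, `plateau`, `rms`,
#'   `flagged`.
#' @export
fit_tachyphylaxis <- function(series) {
  t <- series$time_s; y <- series$amplitude
  if (length(t) < 3) .stopf("need >= 3 pulses to fit tachyphylaxis")
  if (y[length(y)] >= y[1] - 1e-12)
    return(structure(list(a = NA_real_, tau_s = NA_real_, plateau = NA_real_,
                          rms = NA_real_, flagged = TRUE,
                          note = "no decay to fit"),
                     class = "tachy_fit"))
  a0 <- y[1] - y[length(y)]
  # first e-fold of the decaying component
  ef <- which(y - y[length(y)] <= a0 / exp(1))[1]
  tau0 <- if (!is.na(ef) && ef > 1) t[ef] else diff(range(t)) / 3
  fit <- .nls_fit(y ~ a * exp(-t / tau) + c, data.frame(t = t, y = y),
                  start = list(a = a0, tau = tau0, c = y[length(y)]),
                  lower = c(1e-9, 1e-9, -Inf), upper = c(Inf, Inf, Inf))
  if (is.null(fit))
    return(structure(list(a = NA_real_, tau_s = NA_real_, plateau = NA_real_,
                          rms = NA_real_, flagged = TRUE,
                          note = "fit did not converge"),
                     class = "tachy_fit"))
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["a"]), tau_s = unname(cf["tau"]),
                 plateau = unname(cf["c"]),
                 rms = sqrt(mean(stats::residuals(fit)^2)), flagged = FALSE),
            class = "tachy_fit")
}
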