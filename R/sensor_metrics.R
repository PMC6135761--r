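# Sensor characterization: sensitivity, noise, LOD, functionality rules,
# evoked-transient kinetics, and implant geometry/mechanics.

#' Fit dopamine sensitivity from a calibration series
#'
#' Ordinary least-squares fit of measured oxidation-peak current against
#' dopamine concentration. When the capacitive background current is
#' supplied, the normalized sensitivity -- the slope per nM divided by the
#' background current, which corrects for differences in exposed
#' carbon-fiber area across probes -- is also computed.
#'
#' @param concs_uM Dopamine concentrations (uM); at least two distinct
#'   values.
#' @param peak_currents_nA Measured oxidation currents (nA), one per
#'   concentration point.
#' @param background_current_nA Optional background current magnitude (nA)
#'   for sensitivity normalization.
#' @return An object of class \code{"fscv_sensitivity"}: list with
#'   \code{slope_nA_per_uM}, \code{intercept_nA}, \code{pearson_R}
#'   (\code{NA}, with a warning, when the currents are constant),
#'   \code{normalized_slope} (nA nM^-1 nA^-1, or \code{NA}) and
#'   \code{background_current_nA}.
#' @examples
#' fit_sensitivity(c(0.25, 0.5, 1), 51.96 * c(0.25, 0.5, 1),
#'                 background_current_nA = 904)
#' @export
fit_sensitivity <- function(concs_uM, peak_currents_nA,
                            background_current_nA = NULL) {
  if (length(concs_uM) != length(peak_currents_nA))
    stop("concentrations and currents differ in length")
  if (length(unique(concs_uM)) < 2)
    stop("at least two distinct concentrations are required")
  fit <- stats::lm(peak_currents_nA ~ concs_uM)
  slope <- unname(stats::coef(fit)[2])
  if (stats::sd(peak_currents_nA) == 0) {
    warning("constant currents: Pearson R undefined")
    r <- NA_real_
  } else {
    r <- stats::cor(concs_uM, peak_currents_nA)
  }
  normalized <- NA_real_
  if (!is.null(background_current_nA)) {
    if (background_current_nA <= 0)
      stop("background current must be positive for normalization")
    normalized <- (slope / 1000) / background_current_nA
  }
  structure(list(slope_nA_per_uM = slope,
                 intercept_nA = unname(stats::coef(fit)[1]),
                 pearson_R = r,
                 normalized_slope = normalized,
                 background_current_nA =
                   if (is.null(background_current_nA)) NA_real_
                   else background_current_nA),
            class = "fscv_sensitivity")
}

#' Root-mean-square noise of a signal over a window
#'
#' RMS of the mean-removed signal (current in nA, or PCR-projected
#' concentration in nM) over a window of at least 10 samples.
#'
#' @param signal Numeric trace.
#' @param window Indices over which to measure; default the whole trace.
#' @return RMS noise in the signal's units.
#' @export
noise_rms <- function(signal, window = seq_along(signal)) {
  x <- signal[window]
  if (length(x) < 10) stop("noise window must contain at least 10 samples")
  sqrt(mean((x - mean(x))^2))
}

#' Limit of detection from concentration noise
#'
#' The practical LOD of a voltammetric dopamine sensor under the standard
#' signal-to-noise >= 3 criterion: three times the concentration-equivalent
#' noise RMS.
#'
#' @param concentration_noise_nM Concentration noise RMS (nM, nonnegative).
#' @return LOD (nM).
#' @examples
#' compute_lod(1.9)  # 5.7 nM
#' @export
compute_lod <- function(concentration_noise_nM) {
  if (any(concentration_noise_nM < 0)) stop("noise must be nonnegative")
  3 * concentration_noise_nM
}

#' Classify sensor functionality from a session
#'
#' Applies the three nonfunctionality rules for implanted sensors, in
#' order: (1) saturation -- any sample at or beyond the +/-2000 nA
#' transducer rails (perforated or damaged insulation); (2) low
#' background -- background CV magnitude below 100 nA at every potential
#' (mechanical break of the carbon fiber); (3) high noise -- current noise
#' RMS above 1 nA (perforated insulation or increased circuit resistance).
#' The first violated rule is reported.
#'
#' @param session An \code{\link{fscv_session}}.
#' @param background_window Scan indices over which the background CV and
#'   current noise are measured; defaults to
#'   \code{\link{default_background_window}} with 20 scans.
#' @param noise_limit_nA,saturation_nA,min_background_nA Rule thresholds.
#' @return An object of class \code{"fscv_sensor_status"}: list with
#'   \code{functional}, \code{reason} (\code{"none"}, \code{"saturation"},
#'   \code{"low_background"} or \code{"high_noise"}) and \code{diagnostics}
#'   (measured noise, max |background|, current range).
#' @export
classify_sensor <- function(session, background_window = NULL,
                            noise_limit_nA = 1, saturation_nA = 2000,
                            min_background_nA = 100) {
  stopifnot(inherits(session, "fscv_session"))
  if (is.null(background_window))
    background_window <- default_background_window(session, n_scans = 20L)
  w <- session$currents[background_window, , drop = FALSE]
  bg_cv <- colMeans(w)
  resid <- sweep(w, 2L, bg_cv)
  diagnostics <- list(
    noise_nA = sqrt(mean(resid^2)),
    max_abs_background_nA = max(abs(bg_cv)),
    current_range_nA = range(session$currents))
  reason <- if (any(abs(session$currents) >= saturation_nA)) "saturation"
    else if (diagnostics$max_abs_background_nA < min_background_nA) "low_background"
    else if (diagnostics$noise_nA > noise_limit_nA) "high_noise"
    else "none"
  structure(list(functional = reason == "none", reason = reason,
                 diagnostics = diagnostics),
            class = "fscv_sensor_status")
}

#' @export
print.fscv_sensor_status <- function(x, ...) {
  cat(sprintf("Sensor %s%s (noise %.3g nA, max |background| %.4g nA)\n",
              if (x$functional) "functional" else "NONFUNCTIONAL",
              if (x$functional) "" else paste0(": ", x$reason),
              x$diagnostics$noise_nA, x$diagnostics$max_abs_background_nA))
  invisible(x)
}

#' Evoked-transient kinetics of a concentration trace
#'
#' Locates the peak evoked dopamine concentration within an analysis window
#' and measures the decay time from maximum to half-maximum, the standard
#' temporal-fidelity metric for stimulation-evoked transients. Because the
#' trace is sampled at the scan repetition period (100 ms at 10 Hz), the
#' half-maximum crossing is estimated by interpolating between the two
#' bracketing samples: log-linearly (exact for a single-exponential decay)
#' when both bracketing values are positive, linearly otherwise.
#'
#' @param trace An \code{\link{project_concentration}} trace, or a numeric
#'   vector of dDA (nM) with \code{scan_times} supplied.
#' @param analysis_window Scan indices to search; default the whole trace
#'   (from the stimulation onset when one is recorded).
#' @param scan_times Scan times (s), required when \code{trace} is a bare
#'   vector.
#' @param noise_nM Concentration noise RMS used for the peak-significance
#'   check; taken from the trace when available.
#' @return An object of class \code{"fscv_transient"}: list with
#'   \code{peak_dDA_nM}, \code{time_of_peak_s} and \code{decay_half_time_ms}
#'   (\code{NA}, with a warning, if the trace never falls to half-maximum
#'   inside the window).
#' @export
transient_metrics <- function(trace, analysis_window = NULL,
                              scan_times = NULL, noise_nM = NULL) {
  if (inherits(trace, "fscv_trace")) {
    dda <- trace$dDA_nM
    scan_times <- trace$scan_times
    if (is.null(noise_nM)) noise_nM <- trace$concentration_noise_nM
    if (is.null(analysis_window) && !is.null(trace$stim_window))
      analysis_window <- trace$stim_window[1]:length(dda)
  } else {
    dda <- as.numeric(trace)
    if (is.null(scan_times)) stop("scan_times required for a bare trace")
  }
  if (is.null(analysis_window)) analysis_window <- seq_along(dda)
  analysis_window <- as.integer(analysis_window)
  if (any(analysis_window < 1L) || any(analysis_window > length(dda)))
    stop("analysis window outside trace")
  y <- dda[analysis_window]
  t <- scan_times[analysis_window]
  ipk <- which.max(y)
  peak <- y[ipk]
  if (!is.null(noise_nM) && peak <= 3 * noise_nM)
    stop("no transient: peak does not exceed 3x the concentration noise")
  half <- peak / 2
  below <- which(y[-seq_len(ipk)] < half)
  if (length(below) == 0) {
    warning("trace never falls to half-maximum inside the window")
    t_half <- NA_real_
  } else {
    j <- ipk + below[1]          # first sample below half; j-1 is above
    frac <- if (y[j] > 0 && y[j - 1] > 0)
      (log(y[j - 1]) - log(half)) / (log(y[j - 1]) - log(y[j]))
    else
      (y[j - 1] - half) / (y[j - 1] - y[j])
    t_half <- (t[j - 1] + frac * (t[j] - t[j - 1])) - t[ipk]
  }
  structure(list(peak_dDA_nM = peak, time_of_peak_s = t[ipk],
                 decay_half_time_ms = 1000 * t_half),
            class = "fscv_transient")
}

#' Cross-sectional area of a cylindrical implant
#'
#' @param diameter_um Diameter (um, positive).
#' @return Area in um^2 (\code{pi d^2 / 4}).
#' @examples
#' cross_section_area(90)    # ~6362 um^2, a silica-shafted CFE
#' cross_section_area(125)   # ~12272 um^2, a stimulation electrode
#' @export
cross_section_area <- function(diameter_um) {
  if (any(diameter_um <= 0)) stop("diameter must be positive")
  pi * diameter_um^2 / 4
}

#' Flexural rigidity of a cylindrical implant
#'
#' \code{K = E I} with second moment \code{I = pi d^4 / 64}, in SI units.
#' Young's moduli are material properties supplied by the user; typical
#' values are 72 GPa for fused silica and 234 GPa for carbon fiber.
#'
#' @param diameter_um Diameter (um).
#' @param youngs_modulus_GPa Young's modulus (GPa).
#' @return Flexural rigidity (N m^2).
#' @examples
#' flexural_rigidity(90, 72)   # silica CFE shaft, ~2.3e-7 N m^2
#' flexural_rigidity(7, 234)   # bare carbon fiber, < 8e-11 N m^2
#' @export
flexural_rigidity <- function(diameter_um, youngs_modulus_GPa) {
  if (any(diameter_um <= 0) || any(youngs_modulus_GPa <= 0))
    stop("inputs must be positive")
  (youngs_modulus_GPa * 1e9) * pi * (diameter_um * 1e-6)^4 / 64
}

#' Axial stiffness of a cylindrical implant
#'
#' \code{k = E A / L} with \code{A = pi d^2 / 4}, in SI units.
#'
#' @param diameter_um Diameter (um).
#' @param youngs_modulus_GPa Young's modulus (GPa).
#' @param length_mm Implant length (mm).
#' @return Axial stiffness (N/m).
#' @export
axial_stiffness <- function(diameter_um, youngs_modulus_GPa, length_mm) {
  if (any(diameter_um <= 0) || any(youngs_modulus_GPa <= 0) ||
      any(length_mm <= 0))
    stop("inputs must be positive")
  (youngs_modulus_GPa * 1e9) * pi * (diameter_um * 1e-6)^2 / 4 /
    (length_mm * 1e-3)
}
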