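#' Construct an FSCV scan session
#'
#' A scan session is the unit of FSCV recording: a matrix of measured
#' current with one row per triangular scan and one column per in-scan
#' sample, together with the waveform and timing metadata.
#'
#' Currents are in nA. The transducer dynamic range is \eqn{\pm 2000} nA;
#' values at the rail are retained (they indicate saturation and are flagged
#' by \code{\link{classify_sensor}}, not rejected here).
#'
#' @param currents Numeric matrix, scans x samples (nA); the number of
#'   columns must equal \code{waveform$samples_per_scan}.
#' @param waveform An \code{\link{build_waveform}} object.
#' @param scan_times Numeric vector of scan start times (s from session
#'   start); defaults to a uniform grid at \code{1/rep_freq}. Must be
#'   strictly increasing at that spacing.
#' @param probe_id,day Optional probe identifier and day postimplant.
#' @param stim_window Optional integer range of scan indices during which
#'   electrical stimulation was applied.
#'
#' @return An object of class \code{"fscv_session"}.
#' @export
fscv_session <- function(currents, waveform, scan_times = NULL,
                         probe_id = NA_character_, day = NA_real_,
                         stim_window = NULL) {
  stopifnot(inherits(waveform, "fscv_waveform"))
  currents <- as.matrix(currents)
  if (ncol(currents) != waveform$samples_per_scan)
    stop(sprintf("currents has %d columns but the waveform has %d samples per scan",
                 ncol(currents), waveform$samples_per_scan))
  if (!all(is.finite(currents))) stop("currents must be finite")
  period <- 1 / waveform$rep_freq
  if (is.null(scan_times))
    scan_times <- (seq_len(nrow(currents)) - 1) * period
  if (length(scan_times) != nrow(currents))
    stop("scan_times length must match the number of scans")
  if (nrow(currents) > 1) {
    d <- diff(scan_times)
    if (any(d <= 0) || any(abs(d - period) > 1e-6 * period))
      stop("scan_times must be strictly increasing at spacing 1/rep_freq")
  }
  if (!is.null(stim_window)) {
    stim_window <- as.integer(range(stim_window))
    if (stim_window[1] < 1L || stim_window[2] > nrow(currents))
      stop("stim_window outside session")
  }
  structure(list(currents = currents, waveform = waveform,
                 scan_times = scan_times, probe_id = probe_id, day = day,
                 stim_window = stim_window),
            class = "fscv_session")
}

#' @export
print.fscv_session <- function(x, ...) {
  cat(sprintf("FSCV session: %d scans x %d samples, %.3g s, probe %s day %s\n",
              nrow(x$currents), ncol(x$currents),
              diff(range(x$scan_times)) + 1 / x$waveform$rep_freq,
              x$probe_id, format(x$day)))
  invisible(x)
}

#' Default pre-stimulus background window
#'
#' Ten scans ending one second before the stimulation window (when one is
#' recorded), or the first ten scans otherwise.
#'
#' @param session An \code{fscv_session}.
#' @param n_scans Number of background scans.
#' @return Integer vector of scan indices.
#' @export
default_background_window <- function(session, n_scans = 10L) {
  n <- nrow(session$currents)
  if (!is.null(session$stim_window)) {
    last <- session$stim_window[1] - 1L -
      as.integer(round(session$waveform$rep_freq))  # end 1 s before stimulus
    last <- max(last, 1L)
    first <- max(last - n_scans + 1L, 1L)
    first:last
  } else {
    seq_len(min(n_scans, n))
  }
}

#' Background-subtract an FSCV session into a color plot
#'
#' Removes the large capacitive background current by subtracting, from
#' every scan, the per-sample mean of the scans inside a background window.
#' The result is the standard FSCV "color plot": a matrix of current change
#' (nA) with potential along one axis and scan time along the other, in
#' which faradaic events such as dopamine release appear as localized
#' current changes at the redox potentials.
#'
#' @param session An \code{\link{fscv_session}}.
#' @param background_window Integer scan indices used as background;
#'   defaults to \code{\link{default_background_window}}. Must be nonempty
#'   and inside the session; a window overlapping the stimulation window
#'   triggers a warning.
#'
#' @return An object of class \code{"fscv_colorplot"}: list with
#'   \code{bg_subtracted} (scans x samples, nA), \code{background_window},
#'   plus the session's waveform, scan times and stimulation window.
#' @export
subtract_background <- function(session, background_window = NULL) {
  stopifnot(inherits(session, "fscv_session"))
  if (is.null(background_window))
    background_window <- default_background_window(session)
  background_window <- as.integer(background_window)
  n <- nrow(session$currents)
  if (length(background_window) == 0)
    stop("background window is empty")
  if (any(background_window < 1L) || any(background_window > n))
    stop("background window outside session")
  if (!is.null(session$stim_window) &&
      any(background_window >= session$stim_window[1] &
          background_window <= session$stim_window[2]))
    warning("background window overlaps the stimulation window")
  bg <- colMeans(session$currents[background_window, , drop = FALSE])
  structure(list(
    bg_subtracted = sweep(session$currents, 2L, bg),
    background_window = background_window,
    background_cv = bg,
    waveform = session$waveform,
    scan_times = session$scan_times,
    stim_window = session$stim_window
  ), class = "fscv_colorplot")
}

#' Extract one cyclic voltammogram from a color plot
#'
#' @param plot An \code{fscv_colorplot}.
#' @param scan_index Scan (row) index.
#' @return Numeric vector of background-subtracted current (nA), one value
#'   per in-scan sample.
#' @export
extract_cv <- function(plot, scan_index) {
  stopifnot(inherits(plot, "fscv_colorplot"))
  scan_index <- as.integer(scan_index)
  if (length(scan_index) != 1L || scan_index < 1L ||
      scan_index > nrow(plot$bg_subtracted))
    stop("scan index out of range")
  plot$bg_subtracted[scan_index, ]
}

#' Current at a given potential on one sweep
#'
#' Looks up the current of a cyclic voltammogram at the in-scan sample whose
#' (offset-corrected) potential is nearest the requested potential on the
#' requested sweep half. No interpolation is performed: the grid step
#' (about 16 mV for the default waveform) is small compared to the redox
#' peak widths.
#'
#' @param cv Numeric CV vector (length \code{samples_per_scan}).
#' @param waveform The waveform the CV was recorded with.
#' @param potential Query potential (V), on the offset-corrected axis.
#' @param sweep \code{"anodic"} or \code{"cathodic"}.
#' @return Current (nA) at the nearest grid sample.
#' @examples
#' wf <- build_waveform()
#' cv <- make_da_template(template_spec(), conc_uM = 1, waveform = wf)
#' current_at_potential(cv, wf, 0.6, "anodic")   # dopamine oxidation peak
#' @export
current_at_potential <- function(cv, waveform, potential,
                                 sweep = c("anodic", "cathodic")) {
  stopifnot(inherits(waveform, "fscv_waveform"))
  sweep <- match.arg(sweep)
  if (length(cv) != waveform$samples_per_scan)
    stop("cv length does not match the waveform")
  if (potential < waveform$v_hold || potential > waveform$v_peak)
    stop(sprintf("potential %.3g V outside the swept range [%.3g, %.3g] V",
                 potential, waveform$v_hold, waveform$v_peak))
  idx <- sweep_indices(waveform, sweep)
  i <- idx[which.min(abs(waveform$potential[idx] - potential))]
  cv[i]
}
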