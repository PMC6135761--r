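#' Construct an FSCV triangular waveform
#'
#' Builds the applied potential program for one fast-scan cyclic voltammetry
#' (FSCV) scan: a triangular ramp from a holding potential up to a peak
#' potential and back, digitized on a fixed per-scan sample grid. The
#' default parameters correspond to the standard dopamine waveform:
#' \eqn{-0.4} to \eqn{1.3} V at 400 V/s, repeated at 10 Hz, 214 samples per
#' scan.
#'
#' The first half of the grid is the anodic (oxidizing) sweep from
#' \code{v_hold} to \code{v_peak}; the second half is the cathodic (reducing)
#' return sweep. Between scans the electrode is held at \code{v_hold}; the
#' hold is not digitized, so sessions contain only in-scan samples.
#'
#' A constant \code{potential_offset} may be applied in vivo (typically
#' 0.1--0.3 V) to compensate for drift of the implanted Ag/AgCl reference
#' electrode. The offset shifts the applied program only; all potential
#' queries (e.g. \code{\link{current_at_potential}}) are interpreted on the
#' offset-corrected chemistry axis, i.e. relative to the nominal
#' \code{v_hold}--\code{v_peak} triangle.
#'
#' @param v_hold Holding (start/end) potential in volts.
#' @param v_peak Apex potential in volts; must exceed \code{v_hold}.
#' @param scan_rate Sweep rate in V/s.
#' @param rep_freq Scan repetition frequency in Hz.
#' @param samples_per_scan Number of digitized samples per scan; must be an
#'   even integer of at least 4.
#' @param potential_offset Constant offset (V) added to the applied program.
#'
#' @return An object of class \code{"fscv_waveform"}: a list with the input
#'   parameters plus \code{potential} (the offset-free per-sample grid, V),
#'   \code{applied_potential} (grid plus offset), \code{scan_duration} (s)
#'   and the sample index ranges of the anodic and cathodic halves.
#'
#' @examples
#' wf <- build_waveform()
#' wf$scan_duration          # 8.5 ms for the default waveform
#' range(wf$potential)       # -0.4 to 1.3 V
#' @export
build_waveform <- function(v_hold = -0.4, v_peak = 1.3, scan_rate = 400,
                           rep_freq = 10, samples_per_scan = 214,
                           potential_offset = 0) {
  if (!is.numeric(v_hold) || !is.numeric(v_peak) || v_peak <= v_hold)
    stop("invalid waveform: v_peak must exceed v_hold")
  if (scan_rate <= 0) stop("invalid waveform: scan_rate must be positive")
  if (rep_freq <= 0) stop("invalid waveform: rep_freq must be positive")
  n <- as.integer(samples_per_scan)
  if (n < 4L || n %% 2L != 0L)
    stop("invalid waveform: samples_per_scan must be an even integer >= 4")
  scan_duration <- 2 * (v_peak - v_hold) / scan_rate
  if (scan_duration >= 1 / rep_freq)
    stop(sprintf(
      "invalid waveform: scan duration %.4g s is not shorter than the scan period %.4g s",
      scan_duration, 1 / rep_freq))

  half <- n %/% 2L
  step <- (v_peak - v_hold) / half
  # anodic: samples 1..half+1 ascend v_hold -> v_peak; cathodic descends back
  potential <- c(v_hold + step * 0:half, v_peak - step * seq_len(half - 1L))

  structure(list(
    v_hold = v_hold, v_peak = v_peak, scan_rate = scan_rate,
    rep_freq = rep_freq, samples_per_scan = n,
    potential_offset = potential_offset,
    potential = potential,
    applied_potential = potential + potential_offset,
    scan_duration = scan_duration,
    anodic = 1L:(half + 1L),
    cathodic = (half + 1L):n
  ), class = "fscv_waveform")
}

#' @export
print.fscv_waveform <- function(x, ...) {
  cat(sprintf(
    "FSCV waveform: %.3g to %.3g V at %g V/s, %g Hz, %d samples/scan (%.3g ms), offset %+.3g V\n",
    x$v_hold, x$v_peak, x$scan_rate, x$rep_freq, x$samples_per_scan,
    1000 * x$scan_duration, x$potential_offset))
  invisible(x)
}

#' Sample indices of one sweep half
#'
#' @param waveform An \code{fscv_waveform}.
#' @param sweep \code{"anodic"} (rising) or \code{"cathodic"} (falling).
#' @return Integer sample indices of the requested half. The apex sample is
#'   shared by both halves.
#' @export
sweep_indices <- function(waveform, sweep = c("anodic", "cathodic")) {
  stopifnot(inherits(waveform, "fscv_waveform"))
  sweep <- match.arg(sweep)
  if (sweep == "anodic") waveform$anodic else waveform$cathodic
}
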