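# Synthetic FSCV session generators. All generators are deterministic given
# their seed and restore the caller's RNG state.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Capacitive background CV: current proportional to sweep direction
# (square-wave-like), positive on the anodic half.
background_shape <- function(waveform) {
  dir <- rep(-1, waveform$samples_per_scan)
  dir[waveform$anodic] <- 1
  dir
}

#' Flow-cell simulation parameters
#'
#' Configuration of a synthetic in vitro flow-cell calibration session:
#' dopamine boluses at known concentrations are driven past the sensor,
#' separated by blank buffer, on top of a capacitive background with
#' optional drift and white current noise.
#'
#' @param concentrations Bolus dopamine concentrations (uM); default the
#'   physiological calibration set 0.25, 0.5 and 1 uM.
#' @param replicates Number of boluses per concentration.
#' @param bolus_duration,gap_duration,baseline_duration Segment durations (s).
#' @param current_noise_rms White current-noise RMS (nA); default 0.1, the
#'   in vitro noise scale of the sensors.
#' @param background_amplitude Capacitive background amplitude (nA);
#'   default 900.
#' @param drift_rate Background drift (nA/s); default 0.
#' @param seed RNG seed.
#' @return An object of class \code{"fscv_flowcell_config"}.
#' @export
flowcell_config <- function(concentrations = c(0.25, 0.5, 1), replicates = 3,
                            bolus_duration = 5, gap_duration = 5,
                            baseline_duration = 5, current_noise_rms = 0.1,
                            background_amplitude = 900, drift_rate = 0,
                            seed = 1) {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (current_noise_rms < 0) stop("noise RMS must be nonnegative")
  structure(as.list(environment()), class = "fscv_flowcell_config")
}

#' Simulate a flow-cell calibration session
#'
#' Builds a full synthetic FSCV session: capacitive background (square-wave
#' CV of amplitude \code{background_amplitude} plus linear drift), a
#' dopamine template contribution during each bolus window, and white
#' Gaussian current noise. Bolus order is one full concentration series per
#' replicate.
#'
#' @param cfg A \code{\link{flowcell_config}}.
#' @param spec A \code{\link{template_spec}} defining the dopamine response.
#' @param waveform The acquisition waveform.
#' @return List with \code{session} (an \code{\link{fscv_session}}) and
#'   \code{truth}, a data frame logging each bolus (concentration and the
#'   scan window it occupies).
#' @export
simulate_flowcell_session <- function(cfg = flowcell_config(),
                                      spec = template_spec(),
                                      waveform = build_waveform()) {
  stopifnot(inherits(cfg, "fscv_flowcell_config"))
  f <- waveform$rep_freq
  n_boluses <- length(cfg$concentrations) * cfg$replicates
  total <- cfg$baseline_duration +
    n_boluses * (cfg$bolus_duration + cfg$gap_duration)
  n_scans <- as.integer(round(total * f))
  t <- (seq_len(n_scans) - 1) / f

  conc_at_scan <- numeric(n_scans)
  truth <- vector("list", n_boluses)
  b <- 0L
  for (r in seq_len(cfg$replicates)) {
    for (conc in cfg$concentrations) {
      b <- b + 1L
      t0 <- cfg$baseline_duration +
        (b - 1L) * (cfg$bolus_duration + cfg$gap_duration)
      in_bolus <- which(t >= t0 & t < t0 + cfg$bolus_duration)
      conc_at_scan[in_bolus] <- conc
      truth[[b]] <- data.frame(bolus = b, conc_uM = conc,
                               start_scan = min(in_bolus),
                               end_scan = max(in_bolus))
    }
  }
  truth <- do.call(rbind, truth)

  da <- make_da_template(spec, conc_uM = 1, waveform = waveform)
  bg <- background_shape(waveform)
  amp <- cfg$background_amplitude + cfg$drift_rate * t
  currents <- outer(amp, bg) + outer(conc_at_scan, da)
  if (cfg$current_noise_rms > 0)
    currents <- currents + with_seed(cfg$seed,
      matrix(stats::rnorm(length(currents), sd = cfg$current_noise_rms),
             nrow = n_scans))
  list(session = fscv_session(currents, waveform, scan_times = t,
                              probe_id = "flowcell"),
       truth = truth)
}

#' Evoked-transient simulation parameters
#'
#' Configuration of a synthetic stimulation-evoked dopamine recording.
#' The evoked concentration rises linearly from zero to
#' \code{true_peak_conc} over the stimulus train and then decays as a
#' single exponential with time constant \code{decay_tau}, so the
#' ground-truth decay from maximum to half-maximum is
#' \code{decay_tau * log(2)}.
#'
#' @param true_peak_conc Peak evoked concentration (nM).
#' @param stim_onset Stimulus onset (s from session start).
#' @param stim_duration Stimulus train duration (s); default 0.4 s (24
#'   biphasic pulses at 60 Hz).
#' @param decay_tau Exponential decay time constant (s).
#' @param duration Session duration (s).
#' @param current_noise_rms White current-noise RMS (nA); default 0.04, the
#'   chronic in vivo noise scale.
#' @param ph_transient_amplitude Peak pH change (pH units) of an optional
#'   interfering pH transient; 0 disables it.
#' @param ph_transient_tau Decay time constant of the pH transient (s);
#'   pH shifts relax more slowly than dopamine reuptake.
#' @param background_amplitude Capacitive background amplitude (nA).
#' @param drift_rate Background drift (nA/s).
#' @param seed RNG seed.
#' @return An object of class \code{"fscv_evoked_config"}.
#' @export
evoked_config <- function(true_peak_conc = 200, stim_onset = 5,
                          stim_duration = 0.4, decay_tau = 0.15,
                          duration = 10, current_noise_rms = 0.04,
                          ph_transient_amplitude = 0, ph_transient_tau = 2,
                          background_amplitude = 900, drift_rate = 0,
                          seed = 1) {
  if (true_peak_conc < 0) stop("true_peak_conc must be nonnegative")
  if (decay_tau <= 0) stop("decay_tau must be positive")
  if (current_noise_rms < 0) stop("noise RMS must be nonnegative")
  structure(as.list(environment()), class = "fscv_evoked_config")
}

# Linear rise over [onset, onset+dur], exponential decay afterwards.
rise_decay <- function(t, onset, dur, peak, tau) {
  y <- numeric(length(t))
  rising <- t >= onset & t < onset + dur
  after <- t >= onset + dur
  y[rising] <- peak * (t[rising] - onset) / dur
  y[after] <- peak * exp(-(t[after] - onset - dur) / tau)
  y
}

#' Simulate a stimulation-evoked dopamine session
#'
#' @param cfg An \code{\link{evoked_config}}.
#' @param spec A \code{\link{template_spec}}.
#' @param waveform The acquisition waveform.
#' @return List with \code{session} (stimulation window recorded in the
#'   session metadata) and \code{truth}: per-scan true dopamine (nM) and pH
#'   change, the true peak, its time, and the closed-form decay time from
#'   maximum to half-maximum in ms.
#' @export
simulate_evoked_session <- function(cfg = evoked_config(),
                                    spec = template_spec(),
                                    waveform = build_waveform()) {
  stopifnot(inherits(cfg, "fscv_evoked_config"))
  f <- waveform$rep_freq
  n_scans <- as.integer(round(cfg$duration * f))
  t <- (seq_len(n_scans) - 1) / f
  if (cfg$stim_onset < 0 || cfg$stim_onset + cfg$stim_duration > cfg$duration)
    stop("stimulation window outside session")

  dda <- rise_decay(t, cfg$stim_onset, cfg$stim_duration,
                    cfg$true_peak_conc, cfg$decay_tau)
  dph <- rise_decay(t, cfg$stim_onset, cfg$stim_duration,
                    cfg$ph_transient_amplitude, cfg$ph_transient_tau)

  da <- make_da_template(spec, conc_uM = 1, waveform = waveform)
  ph <- make_ph_template(0.1, waveform) / 0.1  # per unit pH change
  bg <- background_shape(waveform)
  amp <- cfg$background_amplitude + cfg$drift_rate * t
  currents <- outer(amp, bg) + outer(dda / 1000, da) + outer(dph, ph)
  if (cfg$current_noise_rms > 0)
    currents <- currents + with_seed(cfg$seed,
      matrix(stats::rnorm(length(currents), sd = cfg$current_noise_rms),
             nrow = n_scans))

  stim_scans <- which(t >= cfg$stim_onset &
                        t < cfg$stim_onset + cfg$stim_duration)
  list(session = fscv_session(currents, waveform, scan_times = t,
                              probe_id = "evoked",
                              stim_window = range(stim_scans)),
       truth = list(per_scan = data.frame(scan_time = t, dDA_nM = dda,
                                          dph = dph),
                    peak_dDA_nM = cfg$true_peak_conc,
                    time_of_peak = cfg$stim_onset + cfg$stim_duration,
                    half_decay_ms = 1000 * cfg$decay_tau * log(2)))
}

#' Simulate a sensor-fault session
#'
#' Generates sessions reproducing the three failure signatures used to
#' declare implanted sensors nonfunctional: \code{"perforated"} insulation
#' (current noise above 1 nA), a \code{"broken"} carbon fiber (background
#' current magnitude below 100 nA), and \code{"saturated"} input (samples
#' pinned at the +/-2000 nA transducer rails).
#'
#' @param mode One of \code{"perforated"}, \code{"broken"},
#'   \code{"saturated"}.
#' @param waveform The acquisition waveform.
#' @param n_scans Number of scans.
#' @param seed RNG seed.
#' @return An \code{\link{fscv_session}}.
#' @export
simulate_fault_session <- function(mode = c("perforated", "broken",
                                            "saturated"),
                                   waveform = build_waveform(),
                                   n_scans = 100, seed = 1) {
  mode <- match.arg(mode)
  bg <- background_shape(waveform)
  par <- switch(mode,
    perforated = list(amp = 900, noise = 2.5),
    broken     = list(amp = 50,  noise = 0.05),
    saturated  = list(amp = 2500, noise = 0.1))
  currents <- outer(rep(par$amp, n_scans), bg) + with_seed(seed,
    matrix(stats::rnorm(n_scans * waveform$samples_per_scan,
                        sd = par$noise), nrow = n_scans))
  currents <- pmin(pmax(currents, -2000), 2000)  # transducer rails
  fscv_session(currents, waveform, probe_id = paste0("fault_", mode))
}
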