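# Shared fixtures and independent oracles for the test suite.

default_wf <- build_waveform()
default_spec <- template_spec()

# Brute-force oracle for radial_profile: per-pixel annulus averages
# restricted to the same arc, no interpolation.
annulus_profile <- function(img, arc_start_deg, arc_span_deg,
                            bin_width_um = 2, r_max_um,
                            background_range_um) {
  ps <- img$pixel_size_um
  xs <- (seq_len(ncol(img$pixels)) - 0.5) * ps
  ys <- (seq_len(nrow(img$pixels)) - 0.5) * ps
  x <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE) -
    img$origin_um[1]
  y <- matrix(ys, nrow = length(ys), ncol = length(xs)) - img$origin_um[2]
  r <- sqrt(x^2 + y^2)
  theta <- (atan2(y, x) * 180 / pi) %% 360
  rel <- (theta - arc_start_deg) %% 360
  in_arc <- rel <= arc_span_deg
  centers <- seq(bin_width_um / 2, r_max_um - bin_width_um / 2,
                 by = bin_width_um)
  raw <- vapply(centers, function(c0) {
    sel <- in_arc & r >= c0 - bin_width_um / 2 & r < c0 + bin_width_um / 2
    mean(img$pixels[sel])
  }, numeric(1))
  bg_sel <- in_arc & r >= background_range_um[1] & r < background_range_um[2]
  list(bin_centers_um = centers, raw = raw,
       background = mean(img$pixels[bg_sel]))
}

# Exact sampled single-exponential evoked trace for kinetics oracles.
exp_trace <- function(tau_s, peak_nM = 500, rep_freq = 10, t_peak = 1,
                      duration = 8) {
  t <- seq(0, duration, by = 1 / rep_freq)
  y <- ifelse(t < t_peak, peak_nM * t / t_peak,
              peak_nM * exp(-(t - t_peak) / tau_s))
  list(t = t, y = y)
}
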