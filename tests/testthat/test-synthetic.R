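test_that("dopamine template peaks at the redox potentials and is linear in concentration", {
  cv1 <- make_da_template(default_spec, conc_uM = 1, waveform = default_wf)
  an <- sweep_indices(default_wf, "anodic")
  peak_pot <- default_wf$potential[an][which.max(cv1[an])]
  expect_lt(abs(peak_pot - 0.6), 2 * 1.7 / 214)  # within one grid step
  expect_equal(make_da_template(default_spec, 0, default_wf), numeric(214))
  cv2 <- make_da_template(default_spec, 2, default_wf)
  expect_identical(cv2, 2 * cv1)                 # exact linearity
  expect_equal(max(cv1), default_spec$sensitivity_slope, tolerance = 1e-4)
  expect_error(make_da_template(default_spec, -1), "nonnegative")
})

test_that("pH template is broad, linear and weakly correlated with dopamine", {
  expect_equal(make_ph_template(0, default_wf), numeric(214))
  up <- make_ph_template(0.05, default_wf)
  dn <- make_ph_template(-0.05, default_wf)
  expect_identical(up, -dn)
  da <- make_da_template(default_spec, 1, default_wf)
  expect_lt(abs(cor(up, da)), 0.5)
  expect_error(make_ph_template(0.5, default_wf), "0.4")
})

test_that("generators are bit-identical under a fixed seed", {
  a <- simulate_flowcell_session(flowcell_config(seed = 7))
  b <- simulate_flowcell_session(flowcell_config(seed = 7))
  expect_identical(a$session$currents, b$session$currents)
  c1 <- simulate_evoked_session(evoked_config(seed = 7))
  c2 <- simulate_evoked_session(evoked_config(seed = 7))
  expect_identical(c1$session$currents, c2$session$currents)
  h1 <- simulate_histology_image(histology_config(seed = 7, size_um = 650,
                                                  origin_um = c(10, 10)))
  h2 <- simulate_histology_image(histology_config(seed = 7, size_um = 650,
                                                  origin_um = c(10, 10)))
  expect_identical(h1$pixels, h2$pixels)
  # and the generators do not disturb the caller's RNG stream
  set.seed(99); x1 <- rnorm(3)
  set.seed(99); invisible(simulate_evoked_session(evoked_config(seed = 1)))
  expect_identical(rnorm(3), x1)
})

test_that("generated current noise matches the configured RMS within 5%", {
  cfg <- evoked_config(true_peak_conc = 0, current_noise_rms = 0.04,
                       duration = 10, seed = 3)
  s <- simulate_evoked_session(cfg)$session
  resid <- sweep(s$currents, 2L, colMeans(s$currents))
  expect_equal(sqrt(mean(resid^2)), 0.04, tolerance = 0.05)
})

test_that("noiseless flow-cell bolus reproduces the template amplitude exactly", {
  cfg <- flowcell_config(concentrations = 1, replicates = 1,
                         current_noise_rms = 0, drift_rate = 0)
  sim <- simulate_flowcell_session(cfg, default_spec, default_wf)
  plot <- subtract_background(sim$session, 1:40)
  mid <- with(sim$truth, floor((start_scan + end_scan) / 2))
  peak <- current_at_potential(extract_cv(plot, mid), default_wf, 0.6,
                               "anodic")
  expect_equal(peak, max(make_da_template(default_spec, 1, default_wf)),
               tolerance = 1e-10)
})

test_that("flow-cell ground truth logs one window per bolus", {
  sim <- simulate_flowcell_session(flowcell_config(
    concentrations = c(0.25, 0.5, 1), replicates = 1, seed = 5))
  expect_equal(nrow(sim$truth), 3)
  expect_equal(sort(unique(sim$truth$conc_uM)), c(0.25, 0.5, 1))
  expect_true(all(sim$truth$start_scan <= sim$truth$end_scan))
  # windows are disjoint
  o <- order(sim$truth$start_scan)
  expect_true(all(diff(sim$truth$start_scan[o]) >
                    (sim$truth$end_scan - sim$truth$start_scan)[o][-3]))
})

test_that("evoked ground truth has closed-form kinetics", {
  sim <- simulate_evoked_session(evoked_config(decay_tau = 0.150, seed = 1))
  expect_equal(sim$truth$half_decay_ms, 150 * log(2) * 1000 / 1000 * 1,
               tolerance = 1e-12)
  expect_equal(sim$truth$half_decay_ms, 103.9721, tolerance = 1e-4)
  # peak occurs at stimulus end: 24 pulses at 60 Hz = 0.4 s after onset
  per_scan <- sim$truth$per_scan
  ipk <- which.max(per_scan$dDA_nM)
  expect_equal(per_scan$scan_time[ipk], 5 + 0.4, tolerance = 0.1)
  # stimulated at scans 51-54 (onset 5 s at 10 Hz), peak within [52, 55]
  expect_true(ipk >= 52 && ipk <= 55)
})

test_that("a zero-amplitude evoked session projects to a near-zero trace", {
  cal <- make_standard_set(default_wf, default_spec)
  model <- fit_pcr(cal)
  sim <- simulate_evoked_session(evoked_config(true_peak_conc = 0, seed = 2))
  trace <- project_concentration(model, subtract_background(sim$session))
  sigma <- trace$concentration_noise_nM
  n <- length(trace$dDA_nM)
  # the trace is pure noise: zero mean, full-trace RMS at the background
  # level, and no excursion beyond a max-of-n Gaussian bound
  expect_lt(abs(mean(trace$dDA_nM)), 3 * sigma / sqrt(n))
  expect_equal(sqrt(mean(trace$dDA_nM^2)), sigma, tolerance = 0.2)
  expect_lt(max(abs(trace$dDA_nM)), 1.5 * sigma * sqrt(2 * log(n)))
})

test_that("fault sessions express their failure signatures", {
  perf <- simulate_fault_session("perforated")
  resid <- sweep(perf$currents, 2L, colMeans(perf$currents))
  expect_gt(sqrt(mean(resid^2)), 1)
  broken <- simulate_fault_session("broken")
  expect_lt(max(abs(colMeans(broken$currents))), 100)
  sat <- simulate_fault_session("saturated")
  expect_true(any(abs(sat$currents) >= 2000))
  expect_error(simulate_fault_session("melted"), "arg")
})

test_that("histology generator is rotationally symmetric and flat when degenerate", {
  flat <- simulate_histology_image(histology_config(
    hole_radius_um = 0, halo_peak = 1, noise_sd = 0, size_um = 650,
    origin_um = c(10, 10)))
  pr <- radial_profile(flat, arc_start_deg = 0, arc_span_deg = 90)
  expect_equal(max(abs(pr$normalized_intensity - 1)), 0, tolerance = 1e-9)
  expect_equal(pr$background_intensity, 1000, tolerance = 1e-6)
  # symmetric noiseless halo: profiles from different arcs agree
  img <- simulate_histology_image(histology_config(
    hole_radius_um = 20, halo_peak = 3, noise_sd = 0, seed = 1))
  p0 <- radial_profile(img, arc_start_deg = 0)
  p123 <- radial_profile(img, arc_start_deg = 123)
  expect_lt(max(abs(p0$normalized_intensity - p123$normalized_intensity)),
            0.02)
  # undersized image is rejected
  expect_error(simulate_histology_image(histology_config(
    size_um = 400, origin_um = c(200, 200))), "too small")
})
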