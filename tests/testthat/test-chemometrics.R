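da_tmpl <- make_da_template(default_spec, 1, default_wf)

test_that("pure dopamine standards collapse to one component and self-predict", {
  concs <- c(100, 250, 500, 1000)
  cvs <- do.call(rbind, lapply(concs / 1000, make_da_template,
                               spec = default_spec, waveform = default_wf))
  cal <- calibration_set(cvs, "DA", concs, default_wf)
  model <- fit_pcr(cal)
  expect_equal(model$k, 1L)
  rows <- rep(seq_along(concs), 3)
  pred <- project_concentration(
    model,
    structure(list(bg_subtracted = cvs[rows, ], background_window = 1:12,
                   scan_times = seq_along(rows) / 10),
              class = "fscv_colorplot"))
  expect_equal(unname(pred$dDA_nM[3]), 500, tolerance = 1e-6 / 500)
  expect_equal(unname(pred$dDA_nM), concs[rows], tolerance = 1e-9)
})

test_that("dopamine and pH standards need two components and separate cleanly", {
  cal <- make_standard_set(default_wf, default_spec)
  model <- fit_pcr(cal)
  expect_equal(model$k, 2L)
  expect_true(all(abs(crossprod(model$loadings) - diag(2)) < 1e-10))
  space <- score_space(model, cal$cvs, cal$label_type)
  # centroid separation is bounded by the concentration spread of each
  # group (the clusters are lines through score space, not blobs)
  expect_gt(cluster_separation(space, "DA", "pH"), 1)
  # the groups are perfectly classified by distance to each group's
  # principal line: dopamine and pH CVs never mix
  pts <- as.matrix(space[, c("PC1", "PC2")])
  ldist <- function(p, grp) {
    m <- pts[space$group == grp, ]
    v <- prcomp(m)$rotation[, 1]
    w <- p - colMeans(m)
    sqrt(max(sum(w^2) - sum(w * v)^2, 0))
  }
  for (i in seq_len(nrow(pts))) {
    own <- ldist(pts[i, ], space$group[i])
    other <- ldist(pts[i, ], setdiff(c("DA", "pH"), space$group[i]))
    expect_lt(own, other)
  }
})

test_that("variance threshold 1 retains the full PCA rank", {
  cal <- make_standard_set(default_wf, default_spec,
                           da_concs_nM = c(250, 500, 1000),
                           dph_values = c(-0.1, 0.1),
                           noise_rms = 0.5, seed = 4)
  model <- fit_pcr(cal, variance_threshold = 1)
  expect_equal(model$k, nrow(cal$cvs) - 1L)  # 5 noisy standards -> rank 4
})

test_that("degenerate calibrations are rejected", {
  cvs <- rbind(da_tmpl, da_tmpl)
  cal <- calibration_set(cvs, "DA", c(250, 500), default_wf)
  expect_error(fit_pcr(cal), "degenerate")
  expect_error(calibration_set(rbind(da_tmpl, da_tmpl), "DA", c(500, 500),
                               default_wf), "distinct")
})

test_that("PCR prediction equals minimum-norm least squares on tiny instances", {
  # oracle: labels regressed directly on centered CVs via the pseudoinverse
  wf8 <- build_waveform(samples_per_scan = 8)
  set.seed(31)
  X <- matrix(rnorm(3 * 8), nrow = 3)
  y <- c(100, 400, 250)
  cal <- calibration_set(X, "DA", y, wf8)
  model <- fit_pcr(cal, variance_threshold = 1)  # k = n - 1 = 2
  Xc <- sweep(X, 2L, colMeans(X))
  beta <- MASS::ginv(Xc) %*% (y - mean(y))
  queries <- rbind(X, 0.3 * X[1, ] + 0.7 * X[3, ])
  oracle <- mean(y) + sweep(queries, 2L, colMeans(X)) %*% beta
  pcr <- fscvr:::pcr_predict(model, queries)[, "dDA_nM"]
  expect_equal(unname(pcr), unname(drop(oracle)), tolerance = 1e-8)
})

test_that("evoked peak concentration is recovered within 10%", {
  model <- fit_pcr(make_standard_set(default_wf, default_spec))
  sim <- simulate_evoked_session(evoked_config(true_peak_conc = 200,
                                               seed = 17),
                                 default_spec, default_wf)
  trace <- project_concentration(model, subtract_background(sim$session))
  expect_equal(max(trace$dDA_nM), 200, tolerance = 0.10)
})

test_that("concentration estimates are linear in the CV and reject pure pH", {
  model <- fit_pcr(make_standard_set(default_wf, default_spec))
  cv <- make_da_template(default_spec, 0.3, default_wf)  # 300 nM
  base <- fscvr:::pcr_predict(model, cv)[, "dDA_nM"]
  for (alpha in c(0.5, 2, 10))
    expect_equal(fscvr:::pcr_predict(model, alpha * cv)[, "dDA_nM"],
                 alpha * base, tolerance = 1e-9)
  # noiseless pH CVs map to zero apparent dopamine
  for (dph in c(-0.2, 0.05, 0.3))
    expect_lt(abs(fscvr:::pcr_predict(
      model, make_ph_template(dph, default_wf))[, "dDA_nM"]), 1e-8)
})

test_that("cv_correlation behaves as a Pearson correlation and guards degeneracy", {
  expect_equal(cv_correlation(da_tmpl, da_tmpl), 1)
  expect_equal(cv_correlation(-da_tmpl, da_tmpl), -1)
  expect_error(cv_correlation(rep(1, 214), da_tmpl), "zero-variance")
  expect_error(cv_correlation(da_tmpl[1:10], da_tmpl), "differ")
})

test_that("score space is centered and dopamine standards are collinear", {
  cal <- make_standard_set(default_wf, default_spec)
  model <- fit_pcr(cal)
  origin <- score_space(model, model$mean_cv, "mean")
  expect_lt(max(abs(c(origin$PC1, origin$PC2))), 1e-9)
  da <- score_space(model, cal$cvs[cal$label_type == "DA", ], "DA")
  expect_gt(cor(da$PC1, da$PC2)^2 + (sd(da$PC2) == 0), 0.99)
  # in vivo style CVs overlay the dopamine standards: each sits on the DA
  # standards' principal line and off the pH line
  sims <- lapply(1:5, function(i) {
    s <- simulate_evoked_session(evoked_config(true_peak_conc = 100 * i,
                                               seed = i),
                                 default_spec, default_wf)
    plot <- subtract_background(s$session)
    extract_cv(plot, which.max(rowSums(plot$bg_subtracted^2)))
  })
  all_cvs <- rbind(cal$cvs, do.call(rbind, sims))
  labels <- c(cal$label_type, rep("invivo", 5))
  sp <- score_space(model, all_cvs, labels)
  pts <- as.matrix(sp[, c("PC1", "PC2")])
  ldist <- function(p, grp) {
    m <- pts[sp$group == grp, ]
    v <- prcomp(m)$rotation[, 1]
    w <- p - colMeans(m)
    sqrt(max(sum(w^2) - sum(w * v)^2, 0))
  }
  for (i in which(labels == "invivo"))
    expect_lt(ldist(pts[i, ], "DA"), ldist(pts[i, ], "pH"))
})

test_that("cluster separation matches the isotropic closed form", {
  set.seed(8)
  n <- 2000; d <- 3; s <- 0.8
  sp <- structure(data.frame(
    PC1 = c(rnorm(n, -d, s), rnorm(n, d, s)),
    PC2 = c(rnorm(n, 0, s), rnorm(n, 0, s)),
    group = rep(c("A", "B"), each = n)),
    class = c("fscv_scorespace", "data.frame"))
  expect_equal(cluster_separation(sp, "A", "B"), 2 * d / (s * sqrt(2)),
               tolerance = 0.1)
  # identical groups score zero
  sp2 <- sp; sp2$PC1 <- rep(sp$PC1[1:n], 2); sp2$PC2 <- rep(sp$PC2[1:n], 2)
  expect_equal(cluster_separation(sp2, "A", "B"), 0)
  sp3 <- sp[c(1, 2, 2001), ]
  expect_error(cluster_separation(sp3, "A", "B"), "at least 2")
})

test_that("PCR recovery is unbiased across many evoked simulations", {
  model <- fit_pcr(make_standard_set(default_wf, default_spec))
  seeds <- 1:40
  truths <- seq(50, 700, length.out = length(seeds))
  err <- vapply(seq_along(seeds), function(i) {
    sim <- simulate_evoked_session(
      evoked_config(true_peak_conc = truths[i], seed = seeds[i]),
      default_spec, default_wf)
    trace <- project_concentration(model, subtract_background(sim$session))
    (max(trace$dDA_nM) - truths[i]) / truths[i]
  }, numeric(1))
  expect_lt(median(abs(err)), 0.10)
  # no systematic sign bias
  expect_gt(binom.test(sum(err > 0), length(err))$p.value, 0.01)
})
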