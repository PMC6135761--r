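# Principal-component regression (PCR) calibration of dopamine against pH
# interference, and CV fidelity / score-space metrics.

#' Assemble a calibration set of labeled standard voltammograms
#'
#' @param cvs Matrix of background-subtracted standard CVs, one row per
#'   standard, or a list of equal-length vectors.
#' @param label_type Character vector, \code{"DA"} or \code{"pH"} per
#'   standard.
#' @param label_value Numeric labels: dopamine concentration in nM for DA
#'   standards, pH change in pH units for pH standards.
#' @param waveform The waveform the standards were recorded with.
#' @return An object of class \code{"fscv_calset"}.
#' @export
calibration_set <- function(cvs, label_type, label_value,
                            waveform = build_waveform()) {
  if (is.list(cvs)) cvs <- do.call(rbind, cvs)
  cvs <- as.matrix(cvs)
  label_type <- match.arg(label_type, c("DA", "pH"), several.ok = TRUE)
  if (length(label_type) == 1L) label_type <- rep(label_type, nrow(cvs))
  if (nrow(cvs) != length(label_type) || nrow(cvs) != length(label_value))
    stop("one label_type and label_value required per CV")
  if (ncol(cvs) != waveform$samples_per_scan)
    stop("CV length does not match the waveform")
  if (length(unique(label_value[label_type == "DA"])) < 2)
    stop("at least 2 distinct dopamine concentrations are required")
  structure(list(cvs = cvs, label_type = label_type,
                 label_value = label_value, waveform = waveform),
            class = "fscv_calset")
}

#' Default dopamine/pH standard set built from the synthetic templates
#'
#' Convenience constructor mirroring an in vitro flow-cell calibration:
#' dopamine standards over the physiological range and pH standards at
#' 0.05-unit steps around physiological pH.
#'
#' @param waveform Acquisition waveform.
#' @param spec Dopamine \code{\link{template_spec}}.
#' @param da_concs_nM Dopamine standard concentrations (nM).
#' @param dph_values pH-change standards (pH units).
#' @param noise_rms Optional white noise added to each standard CV (nA).
#' @param seed RNG seed used when \code{noise_rms > 0}.
#' @return An \code{\link{calibration_set}}.
#' @export
make_standard_set <- function(waveform = build_waveform(),
                              spec = template_spec(),
                              da_concs_nM = c(250, 500, 750, 1000),
                              dph_values = c(-0.2, -0.1, -0.05,
                                             0.05, 0.1, 0.2),
                              noise_rms = 0, seed = 1) {
  da <- lapply(da_concs_nM, function(c_nM)
    make_da_template(spec, conc_uM = c_nM / 1000, waveform = waveform))
  ph <- lapply(dph_values, make_ph_template, waveform = waveform)
  cvs <- do.call(rbind, c(da, ph))
  if (noise_rms > 0)
    cvs <- cvs + with_seed(seed,
      matrix(stats::rnorm(length(cvs), sd = noise_rms), nrow = nrow(cvs)))
  calibration_set(cvs,
                  label_type = rep(c("DA", "pH"),
                                   c(length(da_concs_nM), length(dph_values))),
                  label_value = c(da_concs_nM, dph_values),
                  waveform = waveform)
}

#' Fit a principal-component regression calibration
#'
#' Performs PCA on the mean-centered standard CVs, retains the smallest
#' number of components whose cumulative explained variance reaches
#' \code{variance_threshold} (with a floor of two components whenever pH
#' standards are present, so that both the dopamine and the pH subspaces
#' are spanned), and regresses the known labels on the component scores by
#' least squares. The fitted model maps any background-subtracted CV to an
#' apparent dopamine concentration change (nM) and pH change.
#'
#' @param cal A \code{\link{calibration_set}}.
#' @param variance_threshold Cumulative explained-variance fraction used to
#'   choose the number of retained components; default 0.995.
#' @return An object of class \code{"fscv_pcr"}: list with \code{mean_cv},
#'   \code{loadings} (samples x k, orthonormal columns), \code{k},
#'   regression \code{coef} (k x 2: dDA_nM, dph) and \code{intercept},
#'   and per-component \code{variance_explained} fractions.
#' @export
fit_pcr <- function(cal, variance_threshold = 0.995) {
  stopifnot(inherits(cal, "fscv_calset"))
  X <- cal$cvs
  if (max(apply(X, 2, stats::sd)) < 1e-12)
    stop("degenerate calibration: all standards identical")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  usable <- sum(pc$sdev > 1e-10 * pc$sdev[1])
  k <- which(cumsum(var_frac) >= variance_threshold - 1e-12)[1]
  if (is.na(k)) k <- usable
  if (any(cal$label_type == "pH")) k <- max(k, 2L)
  k <- min(k, usable, nrow(X) - 1L, ncol(X))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  Y <- cbind(dDA_nM = ifelse(cal$label_type == "DA", cal$label_value, 0),
             dph = ifelse(cal$label_type == "pH", cal$label_value, 0))
  fit <- stats::lsfit(scores, Y, intercept = TRUE)
  structure(list(mean_cv = pc$center,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 k = k,
                 intercept = fit$coefficients[1, ],
                 coef = fit$coefficients[-1, , drop = FALSE],
                 variance_explained = var_frac[seq_len(k)],
                 waveform = cal$waveform),
            class = "fscv_pcr")
}

#' @export
print.fscv_pcr <- function(x, ...) {
  cat(sprintf("PCR calibration: k = %d components, %.2f%% variance explained\n",
              x$k, 100 * sum(x$variance_explained)))
  invisible(x)
}

# Project CVs (rows) onto the model's retained components.
pcr_scores <- function(model, cvs) {
  cvs <- matrix(cvs, ncol = length(model$mean_cv))
  sweep(cvs, 2L, model$mean_cv) %*% model$loadings
}

# Predict (dDA_nM, dph) for CVs (rows).
pcr_predict <- function(model, cvs) {
  s <- pcr_scores(model, cvs)
  pred <- sweep(s %*% model$coef, 2L, model$intercept, "+")
  colnames(pred) <- c("dDA_nM", "dph")
  pred
}

#' Project a color plot to a dopamine concentration trace
#'
#' Applies a fitted PCR calibration scan by scan to a background-subtracted
#' session, yielding the apparent dopamine concentration change over time.
#' The concentration noise RMS is measured on the background window of the
#' projected trace.
#'
#' @param model A fitted \code{\link{fit_pcr}} calibration.
#' @param plot An \code{\link{subtract_background}} color plot.
#' @return An object of class \code{"fscv_trace"}: list with \code{dDA_nM}
#'   and \code{dph} per scan, \code{scan_times}, and
#'   \code{concentration_noise_nM} (RMS over the background window).
#' @export
project_concentration <- function(model, plot) {
  stopifnot(inherits(model, "fscv_pcr"), inherits(plot, "fscv_colorplot"))
  if (ncol(plot$bg_subtracted) != length(model$mean_cv))
    stop("CV length does not match the calibration model")
  pred <- pcr_predict(model, plot$bg_subtracted)
  noise <- noise_rms(pred[, "dDA_nM"], window = plot$background_window)
  structure(list(dDA_nM = pred[, "dDA_nM"], dph = pred[, "dph"],
                 scan_times = plot$scan_times,
                 concentration_noise_nM = noise,
                 background_window = plot$background_window,
                 stim_window = plot$stim_window),
            class = "fscv_trace")
}

#' Pearson correlation between a recorded CV and a standard template
#'
#' The standard chemical-fidelity metric for chronically recorded
#' voltammograms: the correlation, over all in-scan samples, of a
#' background-subtracted CV with an in vitro dopamine standard.
#'
#' @param cv,template Equal-length numeric CV vectors with nonzero variance.
#' @return Pearson R.
#' @export
cv_correlation <- function(cv, template) {
  if (length(cv) != length(template)) stop("CV lengths differ")
  if (stats::sd(cv) == 0 || stats::sd(template) == 0)
    stop("zero-variance input")
  stats::cor(cv, template)
}

#' Principal-component score space of a set of voltammograms
#'
#' Projects CVs onto the first two retained components of a fitted PCR
#' model, for score-space separation analysis of in vivo recordings against
#' dopamine and pH standards.
#'
#' @param model A fitted \code{\link{fit_pcr}} model with \code{k >= 2}.
#' @param cvs Matrix of CVs (rows) or a single CV vector.
#' @param labels Group label per CV (e.g. "invivo", "DA", "pH").
#' @return An object of class \code{"fscv_scorespace"}: data frame with
#'   columns \code{PC1}, \code{PC2}, \code{group}.
#' @export
score_space <- function(model, cvs, labels) {
  stopifnot(inherits(model, "fscv_pcr"))
  if (model$k < 2) stop("score-space analysis requires k >= 2 components")
  s <- pcr_scores(model, cvs)
  if (length(labels) == 1L) labels <- rep(labels, nrow(s))
  if (length(labels) != nrow(s)) stop("one label per CV required")
  structure(data.frame(PC1 = s[, 1], PC2 = s[, 2], group = labels,
                       stringsAsFactors = FALSE),
            class = c("fscv_scorespace", "data.frame"))
}

#' Separation score between two groups in PC score space
#'
#' Distance between group centroids divided by the pooled within-group RMS
#' distance to the own centroid. For two isotropic Gaussian clusters with
#' per-axis spread s at centroid distance 2d in the plane, the score is
#' approximately \code{2 d / (s sqrt(2))}. Scores above 2 indicate
#' well-separated clusters.
#'
#' @param space An \code{\link{score_space}} result.
#' @param groupA,groupB Group labels to compare; each must have at least
#'   two members.
#' @return Separation score (unitless, nonnegative).
#' @export
cluster_separation <- function(space, groupA, groupB) {
  stopifnot(inherits(space, "fscv_scorespace"))
  a <- as.matrix(space[space$group == groupA, c("PC1", "PC2")])
  b <- as.matrix(space[space$group == groupB, c("PC1", "PC2")])
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("each group needs at least 2 members to define a spread")
  ca <- colMeans(a); cb <- colMeans(b)
  d2 <- c(rowSums(sweep(a, 2L, ca)^2), rowSums(sweep(b, 2L, cb)^2))
  spread <- sqrt(mean(d2))
  dist <- sqrt(sum((ca - cb)^2))
  if (spread == 0) {
    if (dist == 0) return(0)
    return(Inf)
  }
  dist / spread
}
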