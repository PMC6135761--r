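# Longitudinal stability statistics across days and probes.

#' Assemble a per-probe longitudinal record table
#'
#' @param probe_id,rat_id Identifiers (recycled if length 1).
#' @param day Day postimplant (nonnegative, nondecreasing within probe).
#' @param dDA_nM Evoked dopamine amplitude (nM).
#' @param decay_ms Decay time from maximum to half-maximum (ms).
#' @param stim_id Stimulation-parameter identifier.
#' @return A data frame with one row per recording session.
#' @export
probe_records <- function(probe_id, rat_id = NA_character_, day, dDA_nM,
                          decay_ms = NA_real_, stim_id = NA_character_) {
  if (any(day < 0)) stop("days postimplant must be nonnegative")
  data.frame(probe_id = probe_id, rat_id = rat_id, day = day,
             dDA_nM = dDA_nM, decay_ms = decay_ms, stim_id = stim_id,
             stringsAsFactors = FALSE)
}

#' Longitudinal trend of a per-probe metric
#'
#' Fits an ordinary least-squares line to a metric (evoked dopamine or
#' decay time) as a function of days postimplant. Reports the slope, the
#' Pearson correlation between metric and day, and the two-sided p-value of
#' the correlation against zero (t statistic with n-2 degrees of freedom),
#' together with the metric's mean and standard deviation.
#'
#' @param records Data frame with columns \code{day} and the metric (see
#'   \code{\link{probe_records}}).
#' @param metric \code{"dDA"} (column \code{dDA_nM}) or \code{"decay"}
#'   (column \code{decay_ms}).
#' @return An object of class \code{"fscv_trend"}: list with \code{slope}
#'   (metric units per day), \code{pearson_R}, \code{p_value}, \code{mean},
#'   \code{sd} and \code{n}. A constant metric yields slope 0 and
#'   \code{NA} correlation, with a warning.
#' @export
fit_trend <- function(records, metric = c("dDA", "decay")) {
  metric <- match.arg(metric)
  col <- if (metric == "dDA") "dDA_nM" else "decay_ms"
  y <- records[[col]]
  x <- records$day
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(unique(x)) < 3)
    stop("trend fitting requires at least 3 observations on distinct days")
  if (stats::sd(y) == 0) {
    warning("constant metric: correlation undefined")
    return(structure(list(slope = 0, pearson_R = NA_real_,
                          p_value = NA_real_, mean = mean(y), sd = 0, n = n),
                     class = "fscv_trend"))
  }
  slope <- stats::cov(x, y) / stats::var(x)
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  structure(list(slope = slope, pearson_R = r, p_value = p,
                 mean = mean(y), sd = stats::sd(y), n = n),
            class = "fscv_trend")
}

#' @export
print.fscv_trend <- function(x, ...) {
  cat(sprintf("Trend: slope %.4g/day, R = %.4g, p = %.4g (n = %d, mean %.4g, SD %.4g)\n",
              x$slope, x$pearson_R, x$p_value, x$n, x$mean, x$sd))
  invisible(x)
}

#' Standard scores of a series
#'
#' Z-scores using the sample (n-1) standard deviation, to compare
#' fluctuations across probes whose absolute concentration scales differ
#' widely.
#'
#' @param values Numeric vector with at least two values and nonzero SD.
#' @return Z-scores: mean 0, sample SD 1.
#' @export
zscore_series <- function(values) {
  if (length(values) < 2) stop("at least two values required")
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation")
  (values - mean(values)) / s
}

#' Monthly summaries of longitudinal records
#'
#' Bins records by month postimplant (days 1-30, 31-60, 61-90, and >90 as
#' ">3") and summarizes the metric per bin: n, min, max, mean and the 95%
#' confidence half-width \code{1.96 * SEM} (undefined for single-record
#' bins). Empty bins are absent from the output.
#'
#' @param records Data frame with column \code{day} and the metric column.
#' @param metric Column name to summarize; default \code{"dDA_nM"}.
#' @return Data frame with one row per nonempty month bin.
#' @export
monthly_bins <- function(records, metric = "dDA_nM") {
  day <- records$day
  y <- records[[metric]]
  bin <- cut(day, breaks = c(-Inf, 30, 60, 90, Inf),
             labels = c("1", "2", "3", ">3"))
  out <- lapply(levels(bin), function(b) {
    yy <- y[bin == b & is.finite(y)]
    if (length(yy) == 0) return(NULL)
    data.frame(month = b, n = length(yy), min = min(yy), max = max(yy),
               mean = mean(yy),
               ci95_half = if (length(yy) > 1)
                 1.96 * stats::sd(yy) / sqrt(length(yy)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare metric values between groups
#'
#' Unpaired two-tailed t-test (equal variances) for two groups, or one-way
#' ANOVA for two or more groups, as used to compare recorded dopamine
#' between animals and across probes within an animal. No multiple-testing
#' correction is applied.
#'
#' @param groups List of numeric vectors, each with at least two values.
#' @param design \code{"two-sample"} or \code{"oneway"}.
#' @return List with \code{statistic} (t or F), \code{p_value}, \code{df}
#'   and \code{method}.
#' @export
compare_groups <- function(groups, design = c("two-sample", "oneway")) {
  design <- match.arg(design)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least two values")
  if (design == "two-sample") {
    if (length(groups) != 2) stop("two-sample design requires two groups")
    ht <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         df = unname(ht$parameter), method = "unpaired two-tailed t-test")
  } else {
    y <- unlist(groups)
    g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
    ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         df = unname(ht$parameter), method = "one-way ANOVA")
  }
}
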