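# Readers and writers for the pipeline's on-disk formats.
#
# Session CSV dialect: UTF-8, comma-separated, '.' decimal. Header lines
# start with '#' and carry key=value metadata; each data row is
# scan_time_s followed by samples_per_scan current values in nA.

fmt_num <- function(x) sprintf("%.17g", x)

write_kv_header <- function(con, kv) {
  for (k in names(kv)) {
    v <- kv[[k]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) next
    cat(sprintf("# %s=%s\n", k,
                paste(if (is.numeric(v)) fmt_num(v) else as.character(v),
                      collapse = ",")),
        file = con)
  }
}

read_kv_header <- function(path) {
  lines <- readLines(path, n = 64L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^=]+)=(.*)$", h))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  kv
}

kv_num <- function(kv, key, default = NA_real_) {
  if (is.null(kv[[key]])) default else as.numeric(strsplit(kv[[key]], ",")[[1]])
}

#' Write an FSCV session to CSV
#'
#' @param session An \code{\link{fscv_session}}.
#' @param path Output file.
#' @param extra Optional named list of extra metadata written into the
#'   header (e.g. seed, config hash).
#' @return \code{path}, invisibly.
#' @export
write_session_csv <- function(session, path, extra = NULL) {
  stopifnot(inherits(session, "fscv_session"))
  wf <- session$waveform
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write_kv_header(con, c(list(
    v_hold = wf$v_hold, v_peak = wf$v_peak, scan_rate = wf$scan_rate,
    rep_freq = wf$rep_freq, samples_per_scan = wf$samples_per_scan,
    potential_offset = wf$potential_offset,
    probe_id = session$probe_id, day = session$day,
    stim_window = session$stim_window), extra))
  m <- cbind(session$scan_times, session$currents)
  utils::write.table(matrix(fmt_num(m), nrow = nrow(m)), con, sep = ",",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an FSCV session from CSV
#'
#' @param path Session CSV written by \code{\link{write_session_csv}}.
#' @return An \code{\link{fscv_session}}.
#' @export
read_session_csv <- function(path) {
  kv <- read_kv_header(path)
  for (key in c("v_hold", "v_peak", "scan_rate", "rep_freq",
                "samples_per_scan"))
    if (is.null(kv[[key]]))
      stop(sprintf("parse error in %s: missing header key '%s'", path, key))
  wf <- build_waveform(kv_num(kv, "v_hold"), kv_num(kv, "v_peak"),
                       kv_num(kv, "scan_rate"), kv_num(kv, "rep_freq"),
                       kv_num(kv, "samples_per_scan"),
                       kv_num(kv, "potential_offset", 0))
  m <- as.matrix(utils::read.table(path, sep = ",", comment.char = "#",
                                   header = FALSE))
  if (ncol(m) != wf$samples_per_scan + 1L)
    stop(sprintf("parse error in %s: %d columns, expected %d",
                 path, ncol(m), wf$samples_per_scan + 1L))
  sw <- kv_num(kv, "stim_window", NA_real_)
  fscv_session(m[, -1, drop = FALSE], wf, scan_times = m[, 1],
               probe_id = if (is.null(kv$probe_id)) NA_character_ else kv$probe_id,
               day = kv_num(kv, "day"),
               stim_window = if (all(is.na(sw))) NULL else as.integer(sw))
}

#' Write a calibration set to CSV
#'
#' One row per standard: \code{label_type}, \code{label_value}, then the CV
#' samples.
#'
#' @param cal A \code{\link{calibration_set}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_calibration_csv <- function(cal, path) {
  stopifnot(inherits(cal, "fscv_calset"))
  wf <- cal$waveform
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write_kv_header(con, list(
    v_hold = wf$v_hold, v_peak = wf$v_peak, scan_rate = wf$scan_rate,
    rep_freq = wf$rep_freq, samples_per_scan = wf$samples_per_scan,
    potential_offset = wf$potential_offset))
  rows <- cbind(cal$label_type, fmt_num(cal$label_value),
                matrix(fmt_num(cal$cvs), nrow = nrow(cal$cvs)))
  utils::write.table(rows, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a calibration set from CSV
#'
#' @param path Calibration CSV written by \code{\link{write_calibration_csv}}.
#' @return A \code{\link{calibration_set}}.
#' @export
read_calibration_csv <- function(path) {
  kv <- read_kv_header(path)
  wf <- build_waveform(kv_num(kv, "v_hold"), kv_num(kv, "v_peak"),
                       kv_num(kv, "scan_rate"), kv_num(kv, "rep_freq"),
                       kv_num(kv, "samples_per_scan"),
                       kv_num(kv, "potential_offset", 0))
  d <- utils::read.table(path, sep = ",", comment.char = "#",
                         header = FALSE, stringsAsFactors = FALSE)
  calibration_set(as.matrix(d[, -(1:2)]), label_type = d[[1]],
                  label_value = as.numeric(d[[2]]), waveform = wf)
}

#' Write a concentration trace to CSV
#'
#' Columns \code{scan_time_s}, \code{dDA_nM} (and \code{dph} when present).
#'
#' @param trace An \code{\link{project_concentration}} trace.
#' @param path Output file.
#' @param extra Optional named header metadata.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path, extra = NULL) {
  stopifnot(inherits(trace, "fscv_trace"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write_kv_header(con, c(list(
    concentration_noise_nM = trace$concentration_noise_nM), extra))
  d <- data.frame(scan_time_s = fmt_num(trace$scan_times),
                  dDA_nM = fmt_num(trace$dDA_nM),
                  dph = fmt_num(trace$dph))
  utils::write.table(d, con, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Write a radial profile to CSV
#'
#' Columns \code{bin_center_um}, \code{normalized_intensity}.
#'
#' @param profile An \code{\link{radial_profile}} result.
#' @param path Output file.
#' @param extra Optional named header metadata.
#' @return \code{path}, invisibly.
#' @export
write_profile_csv <- function(profile, path, extra = NULL) {
  stopifnot(inherits(profile, "fscv_radial_profile"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write_kv_header(con, c(list(
    background_intensity = profile$background_intensity,
    arc_start_deg = profile$arc[["start"]],
    arc_span_deg = profile$arc[["span"]],
    n_rays = profile$n_rays, channel = profile$channel), extra))
  d <- data.frame(bin_center_um = fmt_num(profile$bin_centers_um),
                  normalized_intensity = fmt_num(profile$normalized_intensity))
  utils::write.table(d, con, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Write a metrics report as JSON
#'
#' @param report Named list of metrics.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a histology image as 16-bit grayscale TIFF
#'
#' Counts are stored as 16-bit unsigned integers (clamped to 0--65535).
#'
#' @param img An \code{\link{fscv_histimage}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_histology_tiff <- function(img, path) {
  stopifnot(inherits(img, "fscv_histimage"))
  counts <- round(pmin(pmax(img$pixels, 0), 65535))
  tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a 16-bit grayscale TIFF as a histology image
#'
#' @param path TIFF file.
#' @param pixel_size_um Pixel size (um/px).
#' @param origin_um Implant-track center (x, y) in um.
#' @param channel Marker label.
#' @return An \code{\link{fscv_histimage}} with intensities in counts.
#' @export
read_histology_tiff <- function(path, pixel_size_um = 1, origin_um,
                                channel = "other") {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  fscv_histimage(round(px * 65535), pixel_size_um = pixel_size_um,
                 origin_um = origin_um, channel = channel)
}
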