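#' Histology image simulation parameters
#'
#' Configuration of a synthetic single-channel fluorescence image of an
#' implant track: a circular displacement hole of zero intensity (tissue
#' pushed aside by the shaft), surrounded by a Gaussian halo of elevated
#' marker intensity that relaxes to a flat background, plus Gaussian count
#' noise. The pattern is exactly rotationally symmetric about the origin
#' before noise.
#'
#' @param size_um Image side length (um); the image is square.
#' @param pixel_size_um Pixel size (um/px).
#' @param hole_radius_um Radius of the central displacement hole (um).
#' @param halo_peak Peak halo intensity relative to background (1 = no
#'   halo).
#' @param halo_sigma_um Gaussian width of the halo (um).
#' @param background_intensity Background level (counts).
#' @param noise_sd Gaussian noise sigma (counts).
#' @param origin_um Implant-track center, (x, y) in um from the image's
#'   lower-left corner; the default sits at the image center so that rays
#'   at any angle reach the 620 um background annulus.
#' @param channel Marker label (GFAP, Iba1, IgG, DAPI, ...).
#' @param seed RNG seed.
#' @return An object of class \code{"fscv_histology_config"}.
#' @export
histology_config <- function(size_um = 1300, pixel_size_um = 1,
                             hole_radius_um = 5, halo_peak = 1.52,
                             halo_sigma_um = 20,
                             background_intensity = 1000, noise_sd = 20,
                             origin_um = c(650, 650), channel = "GFAP",
                             seed = 1) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (background_intensity <= 0) stop("background_intensity must be positive")
  if (halo_peak <= 0 || hole_radius_um < 0 || halo_sigma_um <= 0)
    stop("invalid halo parameters")
  structure(as.list(environment()), class = "fscv_histology_config")
}

#' Simulate an implant-track fluorescence image
#'
#' Radial ground-truth intensity: 0 inside the displacement hole, and
#' \code{background * (1 + (halo_peak - 1) * exp(-(r - hole)^2 / (2 sigma^2)))}
#' outside it, plus Gaussian noise (clamped at zero counts).
#'
#' @param cfg A \code{\link{histology_config}}.
#' @return An object of class \code{"fscv_histimage"}: list with
#'   \code{pixels} (matrix, rows indexed by y, columns by x),
#'   \code{pixel_size_um}, \code{origin_um}, \code{channel} and the
#'   generating \code{config}.
#' @export
simulate_histology_image <- function(cfg = histology_config()) {
  stopifnot(inherits(cfg, "fscv_histology_config"))
  n <- as.integer(round(cfg$size_um / cfg$pixel_size_um))
  centers <- (seq_len(n) - 0.5) * cfg$pixel_size_um
  # farthest image corner must lie beyond the 620 um background annulus
  corner <- max(sqrt(outer((c(0, cfg$size_um) - cfg$origin_um[1])^2,
                           (c(0, cfg$size_um) - cfg$origin_um[2])^2, "+")))
  if (corner < 620)
    stop("image too small: no pixel reaches 620 um from the origin")
  r <- sqrt(outer((centers - cfg$origin_um[2])^2,
                  (centers - cfg$origin_um[1])^2, "+"))  # rows = y, cols = x
  intensity <- cfg$background_intensity *
    (1 + (cfg$halo_peak - 1) * exp(-(r - cfg$hole_radius_um)^2 /
                                     (2 * cfg$halo_sigma_um^2)))
  intensity[r < cfg$hole_radius_um] <- 0
  if (cfg$noise_sd > 0)
    intensity <- intensity + with_seed(cfg$seed,
      matrix(stats::rnorm(length(intensity), sd = cfg$noise_sd), nrow = n))
  intensity <- pmax(intensity, 0)
  fscv_histimage(intensity, pixel_size_um = cfg$pixel_size_um,
                 origin_um = cfg$origin_um, channel = cfg$channel,
                 config = cfg)
}

#' Construct a histology image object
#'
#' @param pixels Intensity matrix (counts); rows index y (row 1 = y near 0),
#'   columns index x.
#' @param pixel_size_um Pixel size (um/px).
#' @param origin_um Implant-track center (x, y) in um.
#' @param channel Marker label.
#' @param config Optional generating configuration.
#' @return An object of class \code{"fscv_histimage"}.
#' @export
fscv_histimage <- function(pixels, pixel_size_um = 1, origin_um,
                           channel = "other", config = NULL) {
  pixels <- as.matrix(pixels)
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  ext <- dim(pixels)[c(2, 1)] * pixel_size_um
  if (origin_um[1] < 0 || origin_um[1] > ext[1] ||
      origin_um[2] < 0 || origin_um[2] > ext[2])
    stop("origin outside image")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 origin_um = origin_um, channel = channel, config = config),
            class = "fscv_histimage")
}
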