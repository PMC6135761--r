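# Radial quantification of tissue response around an implant track.

# Bilinear interpolation of image intensity at (x, y) um points.
# Pixel centers sit at (i - 0.5) * pixel_size; points beyond the outermost
# pixel centers are an error (the caller checks coverage first).
bilinear_sample <- function(img, x, y) {
  ps <- img$pixel_size_um
  px <- x / ps + 0.5  # fractional column index
  py <- y / ps + 0.5  # fractional row index
  nc <- ncol(img$pixels); nr <- nrow(img$pixels)
  if (any(px < 1 | px > nc | py < 1 | py > nr))
    stop("sample point outside image")
  x0 <- pmin(floor(px), nc - 1L); y0 <- pmin(floor(py), nr - 1L)
  fx <- px - x0; fy <- py - y0
  p <- img$pixels
  p[cbind(y0, x0)]           * (1 - fx) * (1 - fy) +
    p[cbind(y0, x0 + 1)]     * fx       * (1 - fy) +
    p[cbind(y0 + 1, x0)]     * (1 - fx) * fy +
    p[cbind(y0 + 1, x0 + 1)] * fx       * fy
}

#' Radial fluorescence-intensity profile around an implant track
#'
#' Averages image intensity in radial distance bins from a marked
#' implant-track origin, along rays cast at fixed angular steps within an
#' arc (chosen to avoid anatomical boundaries and neighboring probes), and
#' normalizes by the background intensity measured over a far annulus along
#' the same rays. Intensities are sampled by bilinear interpolation at each
#' bin-center radius on each ray, then averaged over rays per bin.
#'
#' Defaults follow standard implant-track quantification: 2 um bins from
#' the origin to 500 um, rays every 0.5 degrees over a 90 degree arc, and
#' background taken 600--620 um from the origin.
#'
#' @param img An \code{\link{fscv_histimage}}.
#' @param arc_start_deg Start angle of the arc (degrees, counterclockwise
#'   from the +x axis).
#' @param arc_span_deg Arc span (degrees); default 90.
#' @param bin_width_um Radial bin width (um); default 2.
#' @param r_max_um Outer profiling radius (um); default 500.
#' @param background_range_um Radii (um) of the background annulus;
#'   default c(600, 620).
#' @param ray_step_deg Angular ray spacing (degrees); default 0.5.
#' @return An object of class \code{"fscv_radial_profile"}: list with
#'   \code{bin_centers_um}, \code{normalized_intensity},
#'   \code{raw_intensity} (mean counts per bin),
#'   \code{background_intensity} (counts), \code{arc} (start, span) and
#'   \code{n_rays}.
#' @export
radial_profile <- function(img, arc_start_deg = 0, arc_span_deg = 90,
                           bin_width_um = 2, r_max_um = 500,
                           background_range_um = c(600, 620),
                           ray_step_deg = 0.5) {
  stopifnot(inherits(img, "fscv_histimage"))
  angles <- seq(arc_start_deg, arc_start_deg + arc_span_deg,
                by = ray_step_deg) * pi / 180
  bin_centers <- seq(bin_width_um / 2, r_max_um - bin_width_um / 2,
                     by = bin_width_um)
  bg_radii <- seq(background_range_um[1] + bin_width_um / 2,
                  background_range_um[2] - bin_width_um / 2,
                  by = bin_width_um)
  r_all <- c(bin_centers, bg_radii)
  ox <- img$origin_um[1]; oy <- img$origin_um[2]
  ps <- img$pixel_size_um
  ext_x <- ncol(img$pixels) * ps; ext_y <- nrow(img$pixels) * ps
  r_need <- max(background_range_um)
  end_x <- ox + r_need * cos(angles); end_y <- oy + r_need * sin(angles)
  # bilinear support requires points inside the outermost pixel centers
  if (any(end_x < 0.5 * ps | end_x > ext_x - 0.5 * ps |
          end_y < 0.5 * ps | end_y > ext_y - 0.5 * ps))
    stop(sprintf("arc leaves the image before %g um from the origin", r_need))

  x <- outer(cos(angles), r_all) + ox   # rays x radii
  y <- outer(sin(angles), r_all) + oy
  samples <- matrix(bilinear_sample(img, as.vector(x), as.vector(y)),
                    nrow = length(angles))
  nb <- length(bin_centers)
  raw <- colMeans(samples[, seq_len(nb), drop = FALSE])
  background <- mean(samples[, nb + seq_along(bg_radii), drop = FALSE])
  if (background <= 0) stop("background intensity is not positive")
  structure(list(bin_centers_um = bin_centers,
                 normalized_intensity = raw / background,
                 raw_intensity = raw,
                 background_intensity = background,
                 arc = c(start = arc_start_deg, span = arc_span_deg),
                 n_rays = length(angles),
                 channel = img$channel),
            class = "fscv_radial_profile")
}

#' Peak relative fluorescence intensity of a radial profile
#'
#' Maximum background-normalized intensity over profile bins, optionally
#' excluding bins inside the displacement hole (where intensity is near
#' zero and carries no marker signal).
#'
#' @param profile An \code{fscv_radial_profile}.
#' @param exclude_hole_um Bins with centers at or below this radius (um) are
#'   excluded; default 0 (use all bins).
#' @return Peak normalized intensity (unitless; 1 = background level).
#' @export
peak_relative_intensity <- function(profile, exclude_hole_um = 0) {
  stopifnot(inherits(profile, "fscv_radial_profile"))
  keep <- profile$bin_centers_um > exclude_hole_um
  if (!any(keep)) stop("all bins excluded")
  max(profile$normalized_intensity[keep])
}

#' Cell-displacement radius from a nuclear-stain profile
#'
#' Distance from the implant-track center at which stain intensity first
#' returns to background level, scanning outward: the smallest bin-center
#' radius whose normalized intensity is at least \code{1 - tolerance}.
#' Intended for nuclear (DAPI) profiles, where the implant shaft displaces
#' cell bodies and leaves a central intensity void. A flat profile (no
#' void) yields 0.
#'
#' @param profile An \code{fscv_radial_profile}.
#' @param tolerance Fraction of background within which intensity counts as
#'   "at background"; default 0.1.
#' @return Displacement radius (um), or \code{NA} (with a warning) if the
#'   profile never reaches background.
#' @export
displacement_radius <- function(profile, tolerance = 0.1) {
  stopifnot(inherits(profile, "fscv_radial_profile"))
  at_bg <- profile$normalized_intensity >= 1 - tolerance
  if (!any(at_bg)) {
    warning("intensity never reaches background; displacement radius undefined")
    return(NA_real_)
  }
  i <- which(at_bg)[1]
  if (i == 1L) 0 else profile$bin_centers_um[i]
}
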