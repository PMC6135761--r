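#' Dopamine voltammogram template parameters
#'
#' Parameters of the model dopamine cyclic voltammogram used by the
#' synthetic-data generators and as the in vitro standard shape. Dopamine
#' under the standard waveform produces an oxidation current peak near
#' +0.6 V on the anodic sweep and a reduction peak near -0.2 V on the
#' cathodic sweep; both peaks are modeled as Gaussians in potential, with
#' the reduction peak scaled by a negative ratio. The template is exactly
#' linear in concentration with the given sensitivity slope.
#'
#' @param ox_peak_potential Oxidation peak potential (V), default 0.6.
#' @param red_peak_potential Reduction peak potential (V), default -0.2.
#' @param ox_peak_width Gaussian sigma of the oxidation peak (V).
#' @param red_peak_width Gaussian sigma of the reduction peak (V).
#' @param red_to_ox_ratio Reduction/oxidation amplitude ratio (negative).
#' @param sensitivity_slope Oxidation peak current per unit concentration
#'   (nA per uM); default 50, the scale of chronically implantable
#'   carbon-fiber microsensors.
#' @return An object of class \code{"fscv_template_spec"}.
#' @export
template_spec <- function(ox_peak_potential = 0.6, red_peak_potential = -0.2,
                          ox_peak_width = 0.15, red_peak_width = 0.2,
                          red_to_ox_ratio = -0.4, sensitivity_slope = 50) {
  if (sensitivity_slope <= 0) stop("sensitivity_slope must be positive")
  structure(list(ox_peak_potential = ox_peak_potential,
                 red_peak_potential = red_peak_potential,
                 ox_peak_width = ox_peak_width,
                 red_peak_width = red_peak_width,
                 red_to_ox_ratio = red_to_ox_ratio,
                 sensitivity_slope = sensitivity_slope),
            class = "fscv_template_spec")
}

#' Synthetic dopamine cyclic voltammogram
#'
#' Background-free dopamine CV at a given concentration: a Gaussian
#' oxidation bump on the anodic half at \code{ox_peak_potential} plus a
#' scaled Gaussian reduction bump on the cathodic half at
#' \code{red_peak_potential}. The amplitude is
#' \code{conc_uM * sensitivity_slope} at the oxidation peak.
#'
#' @param spec A \code{\link{template_spec}}.
#' @param conc_uM Dopamine concentration in uM (nonnegative).
#' @param waveform The waveform defining the potential grid.
#' @return Numeric CV vector (nA), length \code{samples_per_scan}.
#' @export
make_da_template <- function(spec = template_spec(), conc_uM = 1,
                             waveform = build_waveform()) {
  stopifnot(inherits(spec, "fscv_template_spec"),
            inherits(waveform, "fscv_waveform"))
  if (conc_uM < 0) stop("concentration must be nonnegative")
  if (spec$ox_peak_potential < waveform$v_hold ||
      spec$ox_peak_potential > waveform$v_peak ||
      spec$red_peak_potential < waveform$v_hold ||
      spec$red_peak_potential > waveform$v_peak)
    stop("template peak potentials must lie inside the swept range")
  p <- waveform$potential
  n <- waveform$samples_per_scan
  cv <- numeric(n)
  an <- waveform$anodic
  ca <- setdiff(waveform$cathodic, an)  # apex sample assigned to the anodic half
  cv[an] <- exp(-(p[an] - spec$ox_peak_potential)^2 / (2 * spec$ox_peak_width^2))
  cv[ca] <- spec$red_to_ox_ratio *
    exp(-(p[ca] - spec$red_peak_potential)^2 / (2 * spec$red_peak_width^2))
  conc_uM * spec$sensitivity_slope * cv
}

#' Synthetic pH-change cyclic voltammogram
#'
#' pH shifts produce broad, low-frequency current changes spanning the whole
#' sweep rather than localized redox peaks. The template is a fixed
#' difference of two wide Gaussians in potential, scaled linearly by the pH
#' change. Its shape is weakly correlated with the dopamine template
#' (|Pearson r| < 0.5), which is what makes dopamine and pH separable in
#' principal-component score space.
#'
#' @param dph pH change in pH units; physiological calibrations span
#'   roughly -0.4 to +0.4.
#' @param waveform The waveform defining the potential grid.
#' @param amplitude_per_ph Current amplitude per unit pH change (nA);
#'   default 120.
#' @return Numeric CV vector (nA).
#' @export
make_ph_template <- function(dph, waveform = build_waveform(),
                             amplitude_per_ph = 120) {
  stopifnot(inherits(waveform, "fscv_waveform"))
  if (abs(dph) > 0.4) stop("|dph| must be at most 0.4")
  p <- waveform$potential
  shape <- exp(-(p - 1.0)^2 / (2 * 0.35^2)) -
    0.6 * exp(-(p + 0.1)^2 / (2 * 0.45^2))
  dph * amplitude_per_ph * shape
}
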