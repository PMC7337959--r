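# FRET readout of gRNA loading: the acceptor ratio (ratio_A) from paired
# emission spectra, and dye-labelling efficiency from absorbance readings.

#' Fluorescence emission spectrum
#'
#' Emission intensities on a wavelength grid for one excitation wavelength.
#' The standard acquisition excites the donor at 530 nm (emission collected
#' 550-800 nm) and the acceptor directly at 630 nm (emission 650-800 nm).
#'
#' @param emission_nm Strictly increasing wavelength grid, all above the
#'   excitation wavelength.
#' @param intensity Arbitrary-unit intensities, >= 0 (small negative values
#'   from baseline subtraction are clipped with a warning).
#' @param excitation_nm Excitation wavelength, typically 530 or 630.
#' @return Data frame of class `emission_spectrum` with columns
#'   `wavelength_nm`, `intensity`.
#' @export
emission_spectrum <- function(emission_nm, intensity, excitation_nm) {
  stopifnot(length(emission_nm) == length(intensity))
  if (is.unsorted(emission_nm, strictly = TRUE)) {
    stop("emission grid must be strictly increasing")
  }
  if (min(emission_nm) <= excitation_nm) {
    stop("emission wavelengths must exceed the excitation wavelength")
  }
  if (any(intensity < 0)) {
    warning("negative intensities clipped to 0")
    intensity <- pmax(intensity, 0)
  }
  out <- data.frame(wavelength_nm = emission_nm, intensity = intensity)
  attr(out, "excitation_nm") <- excitation_nm
  class(out) <- c("emission_spectrum", "data.frame")
  out
}

spectrum_window_mean <- function(spec, lo, hi) {
  sel <- spec$wavelength_nm >= lo & spec$wavelength_nm <= hi
  if (!any(sel)) stop("spectrum does not cover the requested window")
  mean(spec$intensity[sel])
}

#' Acceptor ratio (ratio_A) from paired emission spectra
#'
#' The acceptor emission peak as sensitised by donor excitation, relative to
#' the same peak under direct acceptor excitation: ratio_A =
#' sensitised / direct. High energy transfer (fluorophores close, as in apo
#' Cas9) gives a high ratio; gRNA loading moves the labelled residues apart
#' and lowers it, making ratio_A a proxy readout for RNP formation.
#'
#' Peak intensities are means over a +/- `window_halfwidth` nm window centred
#' on the acceptor emission maximum of the direct-excitation spectrum (more
#' robust than a single-pixel maximum). When a donor-only reference is
#' supplied, donor bleed-through into the acceptor window of the
#' donor-excitation spectrum is subtracted after scaling the reference to the
#' sample's donor peak.
#'
#' @param spec530 Emission spectrum under donor (530 nm) excitation.
#' @param spec630 Emission spectrum under direct acceptor (630 nm)
#'   excitation.
#' @param donor_only Optional donor-only reference spectrum under 530 nm
#'   excitation.
#' @param acceptor_window Optional c(lo, hi) nm; default is the acceptor
#'   peak of `spec630` +/- `window_halfwidth`.
#' @param window_halfwidth Half-width of the peak window in nm.
#' @param donor_window c(lo, hi) nm used to scale the donor-only reference.
#' @param noise_floor Direct acceptor peak intensities at or below this value
#'   raise an error (no measurable acceptor signal).
#' @return List of class `ratio_a` with `value`, `sensitized`, `direct`,
#'   `acceptor_window`, `bleedthrough` (subtracted amount).
#' @export
ratio_a <- function(spec530, spec630, donor_only = NULL,
                    acceptor_window = NULL, window_halfwidth = 10,
                    donor_window = c(555, 575), noise_floor = 0) {
  stopifnot(inherits(spec530, "emission_spectrum"),
            inherits(spec630, "emission_spectrum"))
  if (is.null(acceptor_window)) {
    peak_nm <- spec630$wavelength_nm[which.max(spec630$intensity)]
    acceptor_window <- c(peak_nm - window_halfwidth,
                         peak_nm + window_halfwidth)
  }
  direct <- spectrum_window_mean(spec630, acceptor_window[1],
                                 acceptor_window[2])
  if (direct <= noise_floor) {
    stop("acceptor peak below noise floor in the direct-excitation spectrum")
  }
  sensitized <- spectrum_window_mean(spec530, acceptor_window[1],
                                     acceptor_window[2])
  bleed <- 0
  if (!is.null(donor_only)) {
    ref_donor <- spectrum_window_mean(donor_only, donor_window[1],
                                      donor_window[2])
    sample_donor <- spectrum_window_mean(spec530, donor_window[1],
                                         donor_window[2])
    if (ref_donor > 0) {
      scale <- sample_donor / ref_donor
      bleed <- scale * spectrum_window_mean(donor_only, acceptor_window[1],
                                            acceptor_window[2])
      sensitized <- max(sensitized - bleed, 0)
    }
  }
  structure(list(value = sensitized / direct, sensitized = sensitized,
                 direct = direct, acceptor_window = acceptor_window,
                 bleedthrough = bleed),
            class = "ratio_a")
}

#' @export
print.ratio_a <- function(x, ...) {
  cat(sprintf("<ratio_a> %.3f (sensitised %.4g / direct %.4g, window %g-%g nm)\n",
              x$value, x$sensitized, x$direct, x$acceptor_window[1],
              x$acceptor_window[2]))
  invisible(x)
}

#' Dye labelling efficiency from absorbance readings
#'
#' Protein and dye concentrations from absorbances at 280 nm (protein),
#' 552 nm (Cy3) and 650 nm (Cy5) via their extinction coefficients; the
#' protein absorbance is corrected for the dyes' own 280 nm absorbance using
#' standard per-dye correction fractions. Labelling efficiency is the
#' dye:protein molar ratio.
#'
#' @param a280,a552,a650 Absorbances, >= 0.
#' @param eps_protein,eps_cy3,eps_cy5 Extinction coefficients in 1/(M cm).
#' @param correction_280 Named fractions of each dye's peak absorbance that
#'   appears at 280 nm (manufacturer values: about 8% for Cy3, 5% for Cy5).
#' @return List with `protein_M`, `cy3_M`, `cy5_M`, `cy3_per_protein`,
#'   `cy5_per_protein`.
#' @export
labelling_efficiency <- function(a280, a552, a650, eps_protein, eps_cy3,
                                 eps_cy5,
                                 correction_280 = c(cy3 = 0.08, cy5 = 0.05)) {
  stopifnot(a280 >= 0, a552 >= 0, a650 >= 0,
            eps_protein > 0, eps_cy3 > 0, eps_cy5 > 0)
  cy3 <- a552 / eps_cy3
  cy5 <- a650 / eps_cy5
  a280_corr <- a280 - correction_280[["cy3"]] * a552 -
    correction_280[["cy5"]] * a650
  if (a280_corr <= 0) {
    stop("corrected A280 is non-positive; dye correction exceeds the signal")
  }
  protein <- a280_corr / eps_protein
  list(protein_M = protein, cy3_M = cy3, cy5_M = cy5,
       cy3_per_protein = cy3 / protein, cy5_per_protein = cy5 / protein)
}
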