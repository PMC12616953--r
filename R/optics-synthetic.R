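#' Synthetic spectral curves
#'
#' Helpers for constructing smooth synthetic spectra: a Gaussian band and a
#' red-tailed emission shape (Gaussian rise with a mixed Gaussian/exponential
#' decay, mimicking the long red tails of biliverdin-binding fluorescent
#' proteins). These are used for the shipped synthetic optical models and in
#' tests; they are stand-ins, not vendor data.
#'
#' @param peak_nm Peak wavelength.
#' @param sigma_nm Gaussian width.
#' @param from_nm,to_nm,step_nm Tabulation range and spacing.
#' @return A [spectrum_table()].
#' @export
gaussian_band <- function(peak_nm, sigma_nm, from_nm = peak_nm - 5 * sigma_nm,
                          to_nm = peak_nm + 5 * sigma_nm, step_nm = 1) {
  wl <- seq(from_nm, to_nm, by = step_nm)
  spectrum_table(wl, exp(-0.5 * ((wl - peak_nm) / sigma_nm)^2))
}

#' @rdname gaussian_band
#' @param tail_scale_nm Decay length of the exponential red tail.
#' @param tail_weight Mixing weight of the tail at the peak, in \[0, 1).
#' @export
tailed_emission <- function(peak_nm, sigma_nm, tail_scale_nm = 60,
                            tail_weight = 0.4, from_nm = peak_nm - 4 * sigma_nm,
                            to_nm = peak_nm + 5 * tail_scale_nm, step_nm = 1) {
  wl <- seq(from_nm, to_nm, by = step_nm)
  gauss <- exp(-0.5 * ((wl - peak_nm) / sigma_nm)^2)
  tail <- ifelse(wl >= peak_nm, exp(-(wl - peak_nm) / tail_scale_nm), gauss)
  spectrum_table(wl, (1 - tail_weight) * gauss + tail_weight * tail)
}

# Super-Gaussian bandpass: flat top, steep but smooth edges (order 10).
bandpass_filter <- function(center_nm, fwhm_nm, step_nm = 1) {
  half <- fwhm_nm / 2
  wl <- seq(center_nm - 3 * fwhm_nm, center_nm + 3 * fwhm_nm, by = step_nm)
  spectrum_table(wl, 1 / (1 + ((wl - center_nm) / half)^10))
}

#' Synthetic optical model of the near-infrared (REKAR-like) configuration
#'
#' A self-consistent synthetic stand-in for the miRFP670nano3/miRFP720 imaging
#' configuration: a 635 nm excitation band shared by both channels, a donor
#' channel collecting around 667/30 nm and a FRET channel collecting around
#' 730/39 nm, and red-tailed synthetic fluorophore spectra. Because no
#' tabulated spectra for the real pair are published alongside the sensors,
#' these curves are synthetic: the calibration ratios they produce are
#' internally consistent (and exercised by every test) but are not the
#' original instrument's values — for those see [reference_calibration()].
#'
#' @param concentration_ratio_k Acceptor-to-donor concentration ratio.
#' @return A list with elements `sensor` ([sensor_optical_model()]),
#'   `donor_channel` and `fret_channel` ([channel_config()]s).
#' @export
synthetic_red_optics <- function(concentration_ratio_k = 1) {
  source_spec <- gaussian_band(635, 9)
  ex_filter <- bandpass_filter(635, 22)
  donor <- fluorophore(
    name = "synthetic-miRFP670-like",
    absorption = gaussian_band(645, 22),
    emission = tailed_emission(670, 12, tail_scale_nm = 70, tail_weight = 0.45),
    extinction_coefficient = 9.0,
    quantum_yield = 0.185
  )
  acceptor <- fluorophore(
    name = "synthetic-miRFP720-like",
    absorption = gaussian_band(702, 25),
    emission = tailed_emission(720, 15, tail_scale_nm = 60, tail_weight = 0.35),
    extinction_coefficient = 9.8,
    quantum_yield = 0.061
  )
  list(
    sensor = sensor_optical_model(donor, acceptor, source_spec,
                                  concentration_ratio_k = concentration_ratio_k),
    donor_channel = channel_config("RFP670", ex_filter,
                                   bandpass_filter(667, 30),
                                   relative_power = 1, exposure = 1),
    fret_channel = channel_config("FRET720", ex_filter,
                                  bandpass_filter(730, 39),
                                  relative_power = 1, exposure = 1)
  )
}

#' Synthetic optical model of the CFP/YFP (EKAREN4-like) configuration
#'
#' Synthetic stand-in spectra for the two-filter CFP/YFP configuration, used
#' to compute an internally consistent gain ratio \eqn{R_P}.
#'
#' @return A list with elements `sensor`, `donor_channel` (CFP filter set)
#'   and `fret_channel` (YFP filter set, i.e. the acceptor channel).
#' @export
synthetic_cfpyfp_optics <- function() {
  source_spec <- spectrum_table(380:560, rep(1, 181))
  donor <- fluorophore(
    name = "synthetic-CFP-like",
    absorption = gaussian_band(435, 20),
    emission = tailed_emission(475, 16, tail_scale_nm = 50, tail_weight = 0.3),
    extinction_coefficient = 3.0,
    quantum_yield = 0.93
  )
  acceptor <- fluorophore(
    name = "synthetic-YFP-like",
    absorption = gaussian_band(515, 15),
    emission = tailed_emission(530, 12, tail_scale_nm = 40, tail_weight = 0.25),
    extinction_coefficient = 13.3,
    quantum_yield = 0.77
  )
  list(
    sensor = sensor_optical_model(donor, acceptor, source_spec),
    donor_channel = channel_config("CFP", bandpass_filter(430, 24),
                                   bandpass_filter(470, 24)),
    fret_channel = channel_config("YFP", bandpass_filter(500, 20),
                                  bandpass_filter(535, 30))
  )
}
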