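#' Create a spectrum table
#'
#' A spectrum is a wavelength-indexed nonnegative curve: a fluorophore
#' absorption or emission spectrum, a filter transmissivity curve, or a light
#' source power spectrum. Units are arbitrary; every downstream quantity is a
#' ratio in which absolute units cancel.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nanometres, strictly
#'   increasing.
#' @param value Numeric vector of nonnegative spectral values, same length.
#' @return A tibble with columns `wavelength_nm` and `value`, of class
#'   `spectrum_tbl`. Values outside the tabulated range are treated as zero by
#'   every consumer.
#' @examples
#' spectrum_table(600:700, dnorm(600:700, 650, 15))
#' @export
spectrum_table <- function(wavelength_nm, value) {
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) == 0L) {
    stop("spectrum is empty: at least one (wavelength, value) pair is required",
         call. = FALSE)
  }
  if (length(wavelength_nm) != length(value)) {
    stop("`wavelength_nm` and `value` must have the same length", call. = FALSE)
  }
  if (anyNA(wavelength_nm) || anyNA(value)) {
    stop("spectrum contains missing values", call. = FALSE)
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop("`wavelength_nm` must be strictly increasing", call. = FALSE)
  }
  if (any(value < 0)) {
    stop("spectrum values must be nonnegative", call. = FALSE)
  }
  out <- tibble::tibble(wavelength_nm = wavelength_nm, value = value)
  class(out) <- c("spectrum_tbl", class(out))
  out
}

#' Read a spectrum from a two-column CSV file
#'
#' Expects columns `wavelength_nm` and `value` (extra columns are ignored).
#'
#' @param path Path to a CSV file.
#' @return A [spectrum_table()].
#' @export
read_spectrum_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("wavelength_nm", "value")) {
    if (!col %in% names(df)) {
      stop("spectrum file ", path, " is missing required column `", col, "`",
           call. = FALSE)
    }
  }
  spectrum_table(df$wavelength_nm, df$value)
}

#' Resample spectra onto a common wavelength grid
#'
#' All ratio computations integrate products of several curves, which requires
#' a shared grid. Spectra are linearly interpolated inside their own tabulated
#' support and set to zero outside it; the grid spans the union of supports.
#'
#' @param spectra A single [spectrum_table()] or a (possibly named) list of
#'   them.
#' @param step_nm Grid spacing in nanometres (default 1, the resolution at
#'   which vendor spectra are typically tabulated).
#' @return A list of spectrum tables sharing one strictly increasing grid.
#' @export
resample_to_grid <- function(spectra, step_nm = 1) {
  if (inherits(spectra, "spectrum_tbl")) spectra <- list(spectra)
  if (length(spectra) == 0L) stop("no spectra supplied", call. = FALSE)
  if (!is.numeric(step_nm) || length(step_nm) != 1L || step_nm <= 0) {
    stop("`step_nm` must be a single positive number", call. = FALSE)
  }
  spectra <- lapply(spectra, function(s) {
    if (!inherits(s, "spectrum_tbl")) s <- spectrum_table(s$wavelength_nm, s$value)
    s
  })
  lo <- min(vapply(spectra, function(s) min(s$wavelength_nm), numeric(1)))
  hi <- max(vapply(spectra, function(s) max(s$wavelength_nm), numeric(1)))
  grid <- seq(lo, hi, by = step_nm)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  lapply(spectra, function(s) {
    v <- interp_zero_outside(s$wavelength_nm, s$value, grid)
    spectrum_table(grid, v)
  })
}

# Linear interpolation inside the tabulated support, zero outside.
interp_zero_outside <- function(x, y, xout) {
  if (length(x) == 1L) {
    return(ifelse(xout == x, y, 0))
  }
  v <- stats::approx(x, y, xout = xout, method = "linear", rule = 1)$y
  v[is.na(v)] <- 0
  v
}

#' Describe a fluorophore's optical properties
#'
#' @param name Label, e.g. `"miRFP670nano3"`.
#' @param absorption,emission [spectrum_table()]s (arbitrary units; shape is
#'   what matters, the scale factors below carry the physics).
#' @param extinction_coefficient Molar extinction coefficient scale factor
#'   (> 0) applied to the absorption spectrum.
#' @param quantum_yield Fluorescence quantum yield in (0, 1].
#' @return A list of class `fluorophore`.
#' @export
fluorophore <- function(name, absorption, emission,
                        extinction_coefficient = 1, quantum_yield = 1) {
  stopifnot(inherits(absorption, "spectrum_tbl"), inherits(emission, "spectrum_tbl"))
  if (extinction_coefficient <= 0) {
    stop("`extinction_coefficient` must be > 0", call. = FALSE)
  }
  if (quantum_yield <= 0 || quantum_yield > 1) {
    stop("`quantum_yield` must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(name = name, absorption = absorption, emission = emission,
         extinction_coefficient = extinction_coefficient,
         quantum_yield = quantum_yield),
    class = "fluorophore"
  )
}

#' Describe an imaging channel
#'
#' A channel is an excitation filter, an emission filter, the relative
#' illumination power `P` delivered through it, and the exposure time `t`.
#'
#' @param name Channel label, e.g. `"RFP670"` (donor channel) or `"FRET720"`.
#' @param excitation_filter,emission_filter [spectrum_table()] transmissivity
#'   curves.
#' @param relative_power Dimensionless relative power delivered (> 0).
#' @param exposure Exposure time in seconds (> 0).
#' @return A list of class `channel_config`.
#' @export
channel_config <- function(name, excitation_filter, emission_filter,
                           relative_power = 1, exposure = 1) {
  stopifnot(inherits(excitation_filter, "spectrum_tbl"),
            inherits(emission_filter, "spectrum_tbl"))
  if (relative_power <= 0) stop("`relative_power` must be > 0", call. = FALSE)
  if (exposure <= 0) stop("`exposure` must be > 0", call. = FALSE)
  structure(
    list(name = name, excitation_filter = excitation_filter,
         emission_filter = emission_filter,
         relative_power = relative_power, exposure = exposure),
    class = "channel_config"
  )
}

#' Describe a FRET sensor's optical components
#'
#' @param donor,acceptor [fluorophore()] models for the FRET donor and
#'   acceptor.
#' @param light_source [spectrum_table()] of the excitation source power.
#' @param concentration_ratio_k Acceptor-to-donor concentration ratio
#'   \eqn{k = C^A/C^D}. Defaults to 1: a single-chain sensor carries exactly
#'   one donor and one acceptor per molecule. Exposed for photobleaching or
#'   chromophore-maturation asymmetry studies.
#' @return A list of class `sensor_optical_model`.
#' @export
sensor_optical_model <- function(donor, acceptor, light_source,
                                 concentration_ratio_k = 1) {
  stopifnot(inherits(donor, "fluorophore"), inherits(acceptor, "fluorophore"),
            inherits(light_source, "spectrum_tbl"))
  if (concentration_ratio_k <= 0) {
    stop("`concentration_ratio_k` must be > 0", call. = FALSE)
  }
  structure(
    list(donor = donor, acceptor = acceptor, light_source = light_source,
         concentration_ratio_k = concentration_ratio_k),
    class = "sensor_optical_model"
  )
}

#' Compute per-channel excitation and emission spectral products
#'
#' For channel \eqn{c} and fluorophore \eqn{f}, the excitation product is
#' \deqn{X_c^f(\lambda) = S(\lambda)\,T^{ex}_c(\lambda)\,\epsilon_f\,A_f(\lambda)}
#' (light source times excitation filter times extinction-scaled absorption),
#' and the emission product is
#' \deqn{M_c^f(\lambda) = QY_f\,E_f(\lambda)\,T^{em}_c(\lambda)}
#' (quantum yield times emission spectrum times emission-filter
#' transmissivity). All eight channel-by-fluorophore products are returned on
#' one common grid; these are the integrands of every calibration ratio.
#'
#' @param sensor A [sensor_optical_model()].
#' @param donor_channel,fret_channel [channel_config()]s for the donor
#'   (e.g. RFP670) and FRET (e.g. FRET720) imaging channels.
#' @param step_nm Common grid spacing in nm.
#' @return A tibble of class `spectral_products` with columns `wavelength_nm`,
#'   `channel` (`"D"`/`"F"`), `fluorophore` (`"D"`/`"A"`), `X`, `M`, carrying
#'   the channel configs and concentration ratio as attributes.
#' @export
spectral_products <- function(sensor, donor_channel, fret_channel, step_nm = 1) {
  stopifnot(inherits(sensor, "sensor_optical_model"),
            inherits(donor_channel, "channel_config"),
            inherits(fret_channel, "channel_config"))
  rs <- resample_to_grid(
    list(
      source = sensor$light_source,
      ex_D = donor_channel$excitation_filter,
      ex_F = fret_channel$excitation_filter,
      em_D = donor_channel$emission_filter,
      em_F = fret_channel$emission_filter,
      abs_D = sensor$donor$absorption,
      abs_A = sensor$acceptor$absorption,
      emi_D = sensor$donor$emission,
      emi_A = sensor$acceptor$emission
    ),
    step_nm = step_nm
  )
  grid <- rs$source$wavelength_nm
  v <- lapply(rs, function(s) s$value)

  ext <- c(D = sensor$donor$extinction_coefficient,
           A = sensor$acceptor$extinction_coefficient)
  qy <- c(D = sensor$donor$quantum_yield, A = sensor$acceptor$quantum_yield)
  absorb <- list(D = v$abs_D, A = v$abs_A)
  emit <- list(D = v$emi_D, A = v$emi_A)
  exf <- list(D = v$ex_D, F = v$ex_F)
  emf <- list(D = v$em_D, F = v$em_F)

  combos <- tidyr::expand_grid(channel = c("D", "F"), fluorophore = c("D", "A"))
  out <- purrr::pmap_dfr(combos, function(channel, fluorophore) {
    x_prod <- v$source * exf[[channel]] * ext[[fluorophore]] * absorb[[fluorophore]]
    m_prod <- qy[[fluorophore]] * emit[[fluorophore]] * emf[[channel]]
    tibble::tibble(
      wavelength_nm = grid,
      channel = channel,
      fluorophore = fluorophore,
      X = x_prod,
      M = m_prod
    )
  })

  if (all(product_col(out, "X", "D", "D") == 0) ||
      all(product_col(out, "M", "D", "D") == 0)) {
    stop(paste("calibration error: the donor-channel donor products",
               "X_D^D or M_D^D are identically zero (disjoint spectral",
               "supports); the donor channel would measure nothing"),
         call. = FALSE)
  }
  structure(
    out,
    step_nm = step_nm,
    donor_channel = donor_channel,
    fret_channel = fret_channel,
    concentration_ratio_k = sensor$concentration_ratio_k,
    class = c("spectral_products", class(out))
  )
}

# One X or M product curve on the common grid.
product_col <- function(products, which, channel, fluorophore) {
  sel <- products$channel == channel & products$fluorophore == fluorophore
  products[[which]][sel]
}

# Trapezoidal integral of one X or M product over the grid.
integrate_product <- function(products, which, channel, fluorophore) {
  grid <- unique(products$wavelength_nm)
  y <- product_col(products, which, channel, fluorophore)
  if (length(grid) == 1L) return(0)
  pracma::trapz(grid, y)
}

# Channel signal term for fluorophore excited as `f_ex` and emitting as
# `f_em`: excitation and emission happen at different wavelengths, so the
# detected intensity factorizes into the integrated excitation product times
# the integrated emission product.
signal_term <- function(products, channel, f_ex, f_em) {
  integrate_product(products, "X", channel, f_ex) *
    integrate_product(products, "M", channel, f_em)
}

#' Compute the calibration ratios of the crosstalk-corrected FRET model
#'
#' Trapezoidal integration of the spectral products yields the three
#' dimensionless ratios of the two-channel near-infrared model:
#' \deqn{R_{XT} = \frac{\int X_F^D\,d\lambda \int M_F^D\,d\lambda}{\int X_D^D\,d\lambda \int M_D^D\,d\lambda},\quad
#'       R_{Chan} = \frac{\int X_F^A\,d\lambda \int M_F^A\,d\lambda}{\int X_D^D\,d\lambda \int M_D^D\,d\lambda},\quad
#'       R_{FRET} = \frac{\int X_F^D\,d\lambda \int M_F^A\,d\lambda}{\int X_D^D\,d\lambda \int M_D^D\,d\lambda}.}
#' Excitation and emission occur at different wavelengths, so each channel
#' signal term factorizes into the integrated excitation product
#' \eqn{X_c^f} times the integrated emission product \eqn{M_c^f}; each ratio
#' is the corresponding pair of factorized signal terms.
#' \eqn{R_{XT}} is donor bleed-through into the FRET channel, \eqn{R_{Chan}}
#' is direct acceptor excitation read in the FRET channel, and \eqn{R_{FRET}}
#' is the sensitized-emission pathway (donor excited, acceptor emitting).
#'
#' Two auxiliary donor-channel ratios (`R_donor_DA`, `R_donor_AA`) carrying
#' the acceptor-emission bleed into the donor channel are also returned; they
#' are zero in the simplified model and only used by the full forward model
#' (see [forward_nir()]).
#'
#' @param products A [spectral_products()] tibble.
#' @return A one-row tibble of class `fret_ratios` with columns `R_XT`,
#'   `R_Chan`, `R_FRET`, `R_donor_DA`, `R_donor_AA`, `k`, `source`
#'   (`"computed"`).
#' @export
compute_ratios <- function(products) {
  stopifnot(inherits(products, "spectral_products"))
  den <- signal_term(products, "D", "D", "D")
  if (!is.finite(den) || den <= 0) {
    stop("calibration error: donor-channel signal term X_D^D * M_D^D is not positive",
         call. = FALSE)
  }
  out <- tibble::tibble(
    R_XT = signal_term(products, "F", "D", "D") / den,
    R_Chan = signal_term(products, "F", "A", "A") / den,
    R_FRET = signal_term(products, "F", "D", "A") / den,
    R_donor_DA = signal_term(products, "D", "D", "A") / den,
    R_donor_AA = signal_term(products, "D", "A", "A") / den,
    k = attr(products, "concentration_ratio_k"),
    source = "computed"
  )
  class(out) <- c("fret_ratios", class(out))
  out
}

#' Construct a ratio set directly from known values
#'
#' Convenience constructor for working with measured or published calibration
#' constants rather than spectra.
#'
#' @param R_XT,R_Chan,R_FRET Nonnegative dimensionless ratios.
#' @param R_donor_DA,R_donor_AA Donor-channel acceptor-emission bleed ratios
#'   (default 0, i.e. the simplified model).
#' @param k Acceptor-to-donor concentration ratio (default 1).
#' @param source `"computed"` or `"measured"`.
#' @return A `fret_ratios` tibble.
#' @export
fret_ratios <- function(R_XT, R_Chan, R_FRET, R_donor_DA = 0, R_donor_AA = 0,
                        k = 1, source = "computed") {
  vals <- c(R_XT, R_Chan, R_FRET, R_donor_DA, R_donor_AA, k)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals[1:5] < 0) || k <= 0) {
    stop("ratios must be finite and nonnegative, and k > 0", call. = FALSE)
  }
  out <- tibble::tibble(R_XT = R_XT, R_Chan = R_Chan, R_FRET = R_FRET,
                        R_donor_DA = R_donor_DA, R_donor_AA = R_donor_AA,
                        k = k, source = source)
  class(out) <- c("fret_ratios", class(out))
  out
}

#' Compute the two-filter gain ratio R_P of a CFP/YFP sensor
#'
#' In the classical configuration the donor (CFP) and acceptor (YFP) are each
#' imaged through their own filter set, and the response is
#' \eqn{EfA = 1 - (I_{CFP}/I_{YFP})/R_P} where \eqn{R_P} is the total
#' donor-channel gain divided by the acceptor-channel gain. Each gain is the
#' spectral product of relative excitation power, exposure time, extinction
#' coefficient, quantum yield, source spectrum, filter transmissivities, and
#' absorption/emission spectra, integrated over wavelength.
#'
#' @param products A [spectral_products()] object in which the `"D"` channel
#'   is the donor (CFP) filter set and the `"F"` channel is the acceptor
#'   (YFP) filter set.
#' @return The scalar ratio \eqn{R_P > 0}.
#' @export
compute_rp <- function(products) {
  stopifnot(inherits(products, "spectral_products"))
  dch <- attr(products, "donor_channel")
  ach <- attr(products, "fret_channel")
  donor_gain <- dch$relative_power * dch$exposure *
    signal_term(products, "D", "D", "D")
  acceptor_gain <- ach$relative_power * ach$exposure *
    signal_term(products, "F", "A", "A")
  if (!is.finite(donor_gain) || donor_gain <= 0 ||
      !is.finite(acceptor_gain) || acceptor_gain <= 0) {
    stop("calibration error: channel gains must both be positive", call. = FALSE)
  }
  donor_gain / acceptor_gain
}

#' Measure the crosstalk ratio from donor-only images
#'
#' The computed \eqn{R_{XT}} lives in the overlapping tails of the donor
#' emission spectrum and the FRET-channel emission filter, exactly where small
#' tabulation errors in vendor spectra stack; a direct calibration is
#' therefore preferred when available. Imaging a sample expressing the donor
#' fluorophore alone through both filter sets gives, per image pair, the
#' power/exposure-normalized intensity ratio, whose mean is the measured
#' \eqn{R_{XT}}.
#'
#' @param measurements A data frame with columns `i_fret` and `i_donor`
#'   (paired background-subtracted intensities of the same donor-only sample).
#' @param donor_channel,fret_channel [channel_config()]s used for the
#'   power/exposure normalization.
#' @param ratios Optional existing `fret_ratios` to update; the measured value
#'   overrides the computed one and `source` becomes `"measured"`.
#' @return A `fret_ratios` tibble with the measured `R_XT`.
#' @export
calibrate_rxt <- function(measurements, donor_channel, fret_channel,
                          ratios = NULL) {
  if (is.null(measurements) || nrow(measurements) == 0L) {
    stop("calibration error: no donor-only measurements supplied", call. = FALSE)
  }
  for (col in c("i_fret", "i_donor")) {
    if (!col %in% names(measurements)) {
      stop("`measurements` is missing required column `", col, "`", call. = FALSE)
    }
  }
  if (any(measurements$i_donor <= 0)) {
    stop("calibration error: all donor intensities must be > 0", call. = FALSE)
  }
  nir <- nir_from_intensities(measurements$i_fret, measurements$i_donor,
                              donor_channel, fret_channel)
  r_xt <- mean(nir)
  if (is.null(ratios)) {
    ratios <- fret_ratios(R_XT = r_xt, R_Chan = 0, R_FRET = 0,
                          source = "measured")
  } else {
    stopifnot(inherits(ratios, "fret_ratios"))
    ratios$R_XT <- r_xt
    ratios$source <- "measured"
  }
  ratios
}

#' Relative excess of a measured calibration value over a computed one
#'
#' Expressed in percent: `100 * (measured - computed) / computed`. Used to
#' judge the agreement between a directly measured crosstalk ratio and the one
#' predicted from tabulated spectra.
#'
#' @param measured,computed Positive scalars.
#' @return Percent excess (can be negative if the measurement is smaller).
#' @export
ratio_excess_pct <- function(measured, computed) {
  if (computed <= 0) stop("`computed` must be > 0", call. = FALSE)
  100 * (measured - computed) / computed
}

#' Reference crosstalk calibration of the original instrument
#'
#' The crosstalk ratio \eqn{R_{XT}} of the miRFP670nano3/miRFP720 imaging
#' configuration, as measured directly on the instrument the REKAR sensors
#' were characterized on (donor-only imaging through both filter sets) and as
#' computed from vendor spectral tables. The measured value is the one used
#' in quantification; the pair documents how closely a spectra-based
#' prediction approaches a direct measurement on real hardware.
#'
#' @return A one-row tibble with columns `quantity`, `measured`, `computed`.
#' @export
reference_calibration <- function() {
  tibble::tibble(quantity = "R_XT", measured = 0.578, computed = 0.551)
}
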