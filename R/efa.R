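#' Power/exposure-normalized intensity ratio (NIR)
#'
#' \deqn{NIR = \frac{I_{FRET}/I_{Donor}}{P_F t_F / (P_D t_D)}}
#' Normalizing the raw FRET-to-donor intensity ratio by each channel's
#' relative power times exposure makes the ratio comparable across
#' acquisition settings and is the quantity the crosstalk-corrected model
#' inverts.
#'
#' @param i_fret,i_donor Numeric vectors of channel intensities (recycled to
#'   a common length).
#' @param donor_channel,fret_channel [channel_config()]s carrying `P` and `t`.
#' @return Numeric vector of NIR values. Frames with `i_donor <= 0` become
#'   `NA` (a per-frame missing value, not an error).
#' @export
nir_from_intensities <- function(i_fret, i_donor, donor_channel, fret_channel) {
  stopifnot(inherits(donor_channel, "channel_config"),
            inherits(fret_channel, "channel_config"))
  norm <- (fret_channel$relative_power * fret_channel$exposure) /
    (donor_channel$relative_power * donor_channel$exposure)
  bad <- !is.na(i_donor) & i_donor <= 0
  nir <- (i_fret / i_donor) / norm
  nir[bad] <- NA_real_
  nir
}

#' Convert NIR to the FRET response EfA (crosstalk-corrected model)
#'
#' Inverts the simplified two-channel intensity model:
#' \deqn{EfA = \frac{NIR - R_{XT} - k\,R_{Chan}}{NIR - R_{XT} + R_{FRET}}}
#' where \eqn{k = C^A/C^D} is the acceptor-to-donor concentration ratio.
#' EfA is the product of the FRET efficiency of the associated (phosphorylated,
#' intramolecularly bound) configuration and the fraction of sensor molecules
#' in it; the two factors are not separately identifiable from this
#' measurement.
#'
#' Values outside \eqn{[0, 1]} are possible under noise and are returned
#' unchanged — never clipped, because clipping would bias the downstream
#' noise-variance estimate. Use [flag_efa_range()] to mark them.
#'
#' @param nir Numeric vector of normalized intensity ratios.
#' @param ratios A `fret_ratios` row (see [compute_ratios()], [fret_ratios()]).
#' @param k Concentration ratio \eqn{C^A/C^D}; defaults to the value stored in
#'   `ratios` (1 for a single-chain sensor).
#' @param denominator_tol Frames where
#'   `|NIR - R_XT + R_FRET| <= denominator_tol * (1 + |NIR|)` become `NA`
#'   rather than aborting the track.
#' @return Numeric vector of EfA values.
#' @export
efa_from_nir <- function(nir, ratios, k = NULL, denominator_tol = 1e-9) {
  stopifnot(inherits(ratios, "fret_ratios"))
  if (is.null(k)) k <- ratios$k
  num <- nir - ratios$R_XT - k * ratios$R_Chan
  den <- nir - ratios$R_XT + ratios$R_FRET
  efa <- num / den
  degenerate <- !is.na(den) & abs(den) <= denominator_tol * (1 + abs(nir))
  efa[degenerate] <- NA_real_
  efa
}

#' Flag EfA values outside the physical unit interval
#'
#' @param efa Numeric vector.
#' @return Logical vector, `TRUE` where `efa` is present and outside
#'   \eqn{[0, 1]}.
#' @export
flag_efa_range <- function(efa) {
  !is.na(efa) & (efa < 0 | efa > 1)
}

#' Forward model: NIR expected for a given EfA
#'
#' The simplified forward model (acceptor-emission bleed into the donor
#' channel neglected) is
#' \deqn{NIR = \frac{R_{XT}(1 - EfA) + R_{FRET}\,EfA + k\,R_{Chan}}{1 - EfA},}
#' the exact algebraic inverse of [efa_from_nir()]. With
#' `include_acceptor_bleed = TRUE` the donor-channel denominator additionally
#' carries the acceptor-emission terms
#' (\eqn{X_D^D M_D^A EfA} and \eqn{k X_D^A M_D^A}, supplied via the
#' `R_donor_DA`/`R_donor_AA` columns of `ratios`), which quantifies the error
#' of the simplification — the neglected emission-bleed term is on the order
#' of 0.1 or less for the miRFP pair.
#'
#' @param efa Numeric vector of EfA values, each `< 1` (an EfA of 1 means the
#'   donor-channel intensity vanishes).
#' @param ratios A `fret_ratios` row.
#' @param k Concentration ratio; defaults to the value stored in `ratios`.
#' @param include_acceptor_bleed Use the full donor-channel denominator.
#' @return Numeric vector of NIR values.
#' @export
forward_nir <- function(efa, ratios, k = NULL, include_acceptor_bleed = FALSE) {
  stopifnot(inherits(ratios, "fret_ratios"))
  if (is.null(k)) k <- ratios$k
  if (any(!is.na(efa) & efa >= 1)) {
    stop("domain error: EfA must be < 1 (the donor-channel intensity vanishes at 1)",
         call. = FALSE)
  }
  num <- ratios$R_XT * (1 - efa) + ratios$R_FRET * efa + k * ratios$R_Chan
  if (include_acceptor_bleed) {
    den <- (1 - efa) + ratios$R_donor_DA * efa + k * ratios$R_donor_AA
  } else {
    den <- 1 - efa
  }
  num / den
}

#' EfA from CFP/YFP intensities (two-filter configuration)
#'
#' \deqn{EfA = 1 - \frac{I_{CFP}/I_{YFP}}{R_P}}
#' where \eqn{R_P} is the donor-to-acceptor total channel gain ratio
#' ([compute_rp()]). Out-of-unit-interval values are returned unclipped.
#'
#' @param i_cfp,i_yfp Numeric intensity vectors.
#' @param r_p Positive gain ratio.
#' @return Numeric vector of EfA values; frames with `i_yfp <= 0` become `NA`.
#' @export
efa_cfp_yfp <- function(i_cfp, i_yfp, r_p) {
  if (!is.numeric(r_p) || length(r_p) != 1L || r_p <= 0) {
    stop("`r_p` must be a single positive number", call. = FALSE)
  }
  bad <- !is.na(i_yfp) & i_yfp <= 0
  efa <- 1 - (i_cfp / i_yfp) / r_p
  efa[bad] <- NA_real_
  efa
}
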