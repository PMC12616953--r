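#' Pipeline configuration
#'
#' Constants of the single-cell processing pipeline. The defaults are the
#' values used for the characterized sensors: tracks must span more than 85%
#' of the movie and stay within the sensor's expected EfA operating range
#' (EKAREN4 0.30–0.65; all REKAR variants 0.15–0.40); traces are smoothed
#' with a 3-point moving average; REKAR data are scaled onto the EKAREN4
#' scale with fixed factors (REKAR67 1.5679, REKAR76 3.0042) and all data are
#' multiplied by per-sensor normalizing values (REKAR67 5, REKAR76 3,
#' EKAREN4 4) to map the plotted signal onto 0–1.
#'
#' @param min_track_fraction Minimum fraction of movie frames a track must
#'   cover (exclusive bound: a track survives only if it covers *more* than
#'   this fraction).
#' @param expected_range Named list of `c(lower, upper)` EfA ranges per
#'   sensor label.
#' @param smoothing_window Odd moving-average window length.
#' @param scaling_factors Named vector of fixed sensor-to-reference scaling
#'   factors (reference sensors have factor 1).
#' @param normalizing_values Named vector of per-sensor plotting
#'   normalization multipliers.
#' @param range_rule `"any_frame"` rejects a track if any frame is outside
#'   the expected range (the strict reading); `"mean"` applies the range to
#'   the track mean instead.
#' @param ratio_floor_fraction Floor for the framewise scaling ratio,
#'   expressed as a fraction of the cell's reference-sensor maximum.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(
    min_track_fraction = 0.85,
    expected_range = list(
      "EKAREN4" = c(0.30, 0.65),
      "REKAR67" = c(0.15, 0.40), "REKAR76" = c(0.15, 0.40),
      "REKAR67-TA" = c(0.15, 0.40), "REKAR76-TA" = c(0.15, 0.40)
    ),
    smoothing_window = 3,
    scaling_factors = c("REKAR67" = 1.5679, "REKAR76" = 3.0042, "EKAREN4" = 1),
    normalizing_values = c("REKAR67" = 5, "REKAR76" = 3, "EKAREN4" = 4),
    range_rule = c("any_frame", "mean"),
    ratio_floor_fraction = 0.05) {
  range_rule <- match.arg(range_rule)
  if (min_track_fraction <= 0 || min_track_fraction > 1) {
    stop("`min_track_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (smoothing_window < 1 || smoothing_window %% 2 != 1) {
    stop("`smoothing_window` must be odd and >= 1", call. = FALSE)
  }
  for (r in expected_range) {
    if (length(r) != 2L || r[1] >= r[2]) {
      stop("each expected range must be c(lower, upper) with lower < upper",
           call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Quantify a raw track table: channel intensities to EfA
#'
#' Converts a long track table (one row per cell-frame-channel) into one row
#' per cell-frame with an `efa` column. Rows with `i_donor`/`i_fret` channels
#' go through the crosstalk-corrected model ([nir_from_intensities()] then
#' [efa_from_nir()]); rows with `i_cfp`/`i_yfp` channels through the
#' two-filter model ([efa_cfp_yfp()]). Tables already carrying an `efa`
#' column are validated and passed through. Out-of-unit-range EfA values are
#' flagged in `efa_out_of_range`, never clipped.
#'
#' @param tracks Long tibble with columns `cell_id`, `sensor`, `frame`,
#'   `time_min`, `channel`, `intensity` (plus any metadata columns, which are
#'   carried through), or a wide table already holding `efa`.
#' @param ratios `fret_ratios` for the red readout.
#' @param r_p Gain ratio for the CFP/YFP readout.
#' @param donor_channel,fret_channel [channel_config()]s for power/exposure
#'   normalization (defaults: unit power and exposure).
#' @return A tibble with one row per cell-frame: metadata columns plus `efa`
#'   and `efa_out_of_range`.
#' @export
quantify_tracks <- function(tracks, ratios = NULL, r_p = NULL,
                            donor_channel = NULL, fret_channel = NULL) {
  if ("efa" %in% names(tracks)) {
    out <- dplyr::as_tibble(tracks)
    out$efa_out_of_range <- flag_efa_range(out$efa)
    return(out)
  }
  for (col in c("cell_id", "sensor", "frame", "channel", "intensity")) {
    if (!col %in% names(tracks)) {
      stop("`tracks` is missing required column `", col, "`", call. = FALSE)
    }
  }
  wide <- tidyr::pivot_wider(tracks, names_from = "channel",
                             values_from = "intensity")
  red <- all(c("i_donor", "i_fret") %in% names(wide))
  cy <- all(c("i_cfp", "i_yfp") %in% names(wide))
  efa <- rep(NA_real_, nrow(wide))
  if (red) {
    if (is.null(ratios)) stop("`ratios` is required for the red readout", call. = FALSE)
    if (is.null(donor_channel)) donor_channel <- unit_channel("RFP670")
    if (is.null(fret_channel)) fret_channel <- unit_channel("FRET720")
    rows <- !is.na(wide$i_donor) | !is.na(wide$i_fret)
    nir <- nir_from_intensities(wide$i_fret[rows], wide$i_donor[rows],
                                donor_channel, fret_channel)
    efa[rows] <- efa_from_nir(nir, ratios)
  }
  if (cy) {
    if (is.null(r_p)) stop("`r_p` is required for the CFP/YFP readout", call. = FALSE)
    rows <- !is.na(wide$i_cfp) | !is.na(wide$i_yfp)
    efa[rows] <- efa_cfp_yfp(wide$i_cfp[rows], wide$i_yfp[rows], r_p)
  }
  if (!red && !cy) {
    stop("no recognized channel pair: need `i_donor`/`i_fret` or `i_cfp`/`i_yfp`",
         call. = FALSE)
  }
  wide$efa <- efa
  wide$efa_out_of_range <- flag_efa_range(efa)
  dplyr::select(wide, -dplyr::any_of(c("i_donor", "i_fret", "i_cfp", "i_yfp")))
}

#' Filter tracks by coverage and expected signal range
#'
#' A track survives only if (a) it is present in more than
#' `min_track_fraction` of the movie's frames and (b) its EfA values lie
#' within the sensor's expected operating range (by default every single
#' frame must — the strict reading; see `range_rule` in [pipeline_config()]).
#' Both bounds of the range are inclusive. A rejection log recording which
#' rule fired for each removed track is attached as the `"rejection_log"`
#' attribute (see [rejection_log()]).
#'
#' @param traces Quantified tibble (one row per cell-frame with `efa`).
#' @param config A [pipeline_config()].
#' @param movie_frames Total number of frames in the experiment; defaults to
#'   the number of distinct `frame` values in the table.
#' @return The filtered tibble, with attribute `rejection_log`.
#' @export
filter_tracks <- function(traces, config = pipeline_config(),
                          movie_frames = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(movie_frames)) movie_frames <- dplyr::n_distinct(traces$frame)
  unknown <- setdiff(unique(traces$sensor), names(config$expected_range))
  if (length(unknown) > 0) {
    stop("no expected range configured for sensor(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ranges <- config$expected_range
  per_track <- traces |>
    dplyr::group_by(.data$cell_id, .data$sensor) |>
    dplyr::summarise(
      n_present = sum(!is.na(.data$efa)),
      lo = min(.data$efa, na.rm = TRUE),
      hi = max(.data$efa, na.rm = TRUE),
      mean_efa = mean(.data$efa, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      range_lo = purrr::map_dbl(.data$sensor, ~ ranges[[.x]][1]),
      range_hi = purrr::map_dbl(.data$sensor, ~ ranges[[.x]][2]),
      fails_length = .data$n_present / movie_frames <= config$min_track_fraction,
      fails_range = if (config$range_rule == "any_frame") {
        .data$lo < .data$range_lo | .data$hi > .data$range_hi
      } else {
        .data$mean_efa < .data$range_lo | .data$mean_efa > .data$range_hi
      }
    )
  rejected <- per_track |>
    dplyr::filter(.data$fails_length | .data$fails_range) |>
    dplyr::mutate(rule = dplyr::case_when(
      .data$fails_length & .data$fails_range ~ "length+range",
      .data$fails_length ~ "length",
      TRUE ~ "range"
    )) |>
    dplyr::select("cell_id", "sensor", "rule")
  kept <- dplyr::anti_join(traces, rejected, by = c("cell_id", "sensor"))
  attr(kept, "rejection_log") <- rejected
  kept
}

#' Retrieve the rejection log attached by [filter_tracks()]
#'
#' @param traces A tibble returned by [filter_tracks()].
#' @return A tibble with columns `cell_id`, `sensor`, `rule` (`"length"`,
#'   `"range"`, or `"length+range"`); empty if nothing was removed.
#' @export
rejection_log <- function(traces) {
  log <- attr(traces, "rejection_log")
  if (is.null(log)) {
    tibble::tibble(cell_id = character(), sensor = character(),
                   rule = character())
  } else {
    log
  }
}

moving_average <- function(x, window) {
  zoo::rollapply(x, width = window, FUN = function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, partial = TRUE, align = "center")
}

#' Smooth traces with a centered moving average
#'
#' 3-point moving average by default; at the edges the window shrinks to the
#' available points, and missing frames are excluded from each window's mean.
#' Adds a column `efa_smooth` (the input column is untouched).
#'
#' @param traces Quantified tibble ordered or orderable by `time_min`.
#' @param window Odd window length.
#' @param col Column to smooth.
#' @return The input tibble with an added `efa_smooth` column.
#' @export
smooth_traces <- function(traces, window = 3, col = "efa") {
  if (window < 1 || window %% 2 != 1) {
    stop("`window` must be odd and >= 1", call. = FALSE)
  }
  if (nrow(traces) == 0L) {
    traces$efa_smooth <- numeric(0)
    return(traces)
  }
  traces |>
    dplyr::group_by(.data$cell_id, .data$sensor) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::mutate(efa_smooth = {
      x <- .data[[col]]
      if (all(is.na(x))) {
        stop("empty trace: all values missing for a cell", call. = FALSE)
      }
      moving_average(x, window)
    }) |>
    dplyr::ungroup()
}

#' Subtract each trace's minimum (zero-floor the signal)
#'
#' Subtracts the per-cell minimum of the smoothed signal so that every
#' trace's minimum becomes exactly zero. Adds a column `efa_rebased`.
#'
#' @param traces Tibble carrying the column named in `col` (default the
#'   smoothed signal).
#' @param col Column to rebase.
#' @return The input tibble with an added `efa_rebased` column.
#' @export
baseline_subtract <- function(traces, col = "efa_smooth") {
  if (!col %in% names(traces)) {
    stop("column `", col, "` not found; run smooth_traces() first or set `col`",
         call. = FALSE)
  }
  if (nrow(traces) == 0L) {
    traces$efa_rebased <- numeric(0)
    return(traces)
  }
  traces |>
    dplyr::group_by(.data$cell_id, .data$sensor) |>
    dplyr::mutate(efa_rebased = .data[[col]] - min(.data[[col]], na.rm = TRUE)) |>
    dplyr::ungroup()
}

#' Estimate sensor-to-reference scaling factors from dual-sensor cells
#'
#' For cells co-expressing a reference sensor (EKAREN4) and a second sensor,
#' computes per cell the framewise ratio of the reference signal to the
#' second sensor's signal — over frames where the second sensor's signal
#' exceeds a floor (a fraction of that cell's reference maximum, avoiding 0/0
#' near the rebased baseline) — averages it over frames, and then averages
#' the per-cell values over all cells pooled across replicates. Traces must
#' already be smoothed and baseline-subtracted.
#'
#' @param traces Tibble with `efa_rebased`, containing the reference sensor
#'   and at least one other sensor for the same `cell_id`s.
#' @param reference Reference sensor label.
#' @param config A [pipeline_config()] (supplies the ratio floor).
#' @return A tibble with one row per non-reference sensor: `sensor`,
#'   `scaling_factor`, `n_cells`.
#' @export
compute_scaling_factor <- function(traces, reference = "EKAREN4",
                                   config = pipeline_config()) {
  if (!"efa_rebased" %in% names(traces)) {
    stop("run smooth_traces() and baseline_subtract() before computing scaling factors",
         call. = FALSE)
  }
  ref <- traces |>
    dplyr::filter(.data$sensor == reference) |>
    dplyr::select("cell_id", "time_min", ref_signal = "efa_rebased")
  if (nrow(ref) == 0L) {
    stop("no cells carry the reference sensor `", reference, "`", call. = FALSE)
  }
  others <- traces |> dplyr::filter(.data$sensor != reference)
  if (nrow(others) == 0L) {
    stop("no dual-sensor cells: only the reference sensor is present", call. = FALSE)
  }
  per_cell <- others |>
    dplyr::inner_join(ref, by = c("cell_id", "time_min")) |>
    dplyr::group_by(.data$sensor, .data$cell_id) |>
    dplyr::summarise(
      cell_factor = {
        floor_eps <- config$ratio_floor_fraction *
          max(.data$ref_signal, na.rm = TRUE)
        use <- !is.na(.data$efa_rebased) & !is.na(.data$ref_signal) &
          .data$efa_rebased > floor_eps
        if (!any(use)) NA_real_ else {
          mean(.data$ref_signal[use] / .data$efa_rebased[use])
        }
      },
      .groups = "drop"
    )
  out <- per_cell |>
    dplyr::group_by(.data$sensor) |>
    dplyr::summarise(
      scaling_factor = mean(.data$cell_factor, na.rm = TRUE),
      n_cells = sum(!is.na(.data$cell_factor)),
      .groups = "drop"
    )
  if (any(out$n_cells == 0L)) {
    stop("estimation error: no frame above the ratio floor in any cell for sensor(s): ",
         paste(out$sensor[out$n_cells == 0L], collapse = ", "), call. = FALSE)
  }
  out
}

#' Scale and normalize traces for cross-sensor plotting
#'
#' Multiplies each rebased trace by its sensor's scaling factor (reference
#' sensors by 1) and then by the sensor's normalizing value so that the
#' plotted signal spans roughly 0–1. A pure monotone (order-preserving)
#' transform; nothing is clipped. Adds a column `efa_norm`.
#'
#' @param traces Tibble with `efa_rebased`.
#' @param scaling_factors Named vector of scaling factors; defaults to the
#'   fixed factors in `config`. Output of [compute_scaling_factor()] may be
#'   supplied as a tibble.
#' @param config A [pipeline_config()] (supplies the normalizing values and
#'   default factors).
#' @return The input tibble with an added `efa_norm` column.
#' @export
normalize_for_plotting <- function(traces, scaling_factors = NULL,
                                   config = pipeline_config()) {
  if (!"efa_rebased" %in% names(traces)) {
    stop("run smooth_traces() and baseline_subtract() first", call. = FALSE)
  }
  if (is.null(scaling_factors)) {
    scaling_factors <- config$scaling_factors
  } else if (is.data.frame(scaling_factors)) {
    scaling_factors <- stats::setNames(scaling_factors$scaling_factor,
                                       scaling_factors$sensor)
  }
  get_const <- function(tbl, sensor, what, default = NA_real_) {
    v <- tbl[sensor]
    unname(ifelse(is.na(v), default, v))
  }
  sens <- traces$sensor
  sf <- get_const(scaling_factors, sens, default = 1)
  nv <- get_const(config$normalizing_values, sens, default = 1)
  traces$efa_norm <- traces$efa_rebased * sf * nv
  traces
}
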