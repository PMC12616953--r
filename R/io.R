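#' Read a single-cell track table from CSV/TSV
#'
#' The canonical table is long/tidy: one row per cell-frame-channel (columns
#' `cell_id`, `sensor`, `frame`, `time_min`, `channel`, `intensity`), or one
#' row per cell-frame with an `efa` column for already-quantified data.
#' Replicate labels (`experimental_rep`, `technical_rep`) and treatment-time
#' metadata columns (`egf_time_min`, `inhibitor_time_min`) are carried
#' through when present. Malformed rows are reported with their line
#' numbers.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @return A validated tibble.
#' @export
read_track_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reader <- if (grepl("\\.tsv$|\\.txt$", path)) readr::read_tsv else readr::read_csv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop("malformed rows in ", path, " (rows ",
         paste(utils::head(unique(probs$row), 10), collapse = ", "),
         "): ", probs$expected[1], " expected, got ", probs$actual[1],
         call. = FALSE)
  }
  required <- c("cell_id", "frame", "time_min", "sensor")
  for (col in required) {
    if (!col %in% names(df)) {
      stop("track table is missing required column `", col, "`", call. = FALSE)
    }
  }
  for (col in intersect(c("frame", "time_min", "efa", "intensity"), names(df))) {
    if (!is.numeric(df[[col]])) {
      coerced <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(coerced) & !is.na(df[[col]]))
      stop("malformed rows in ", path, ": column `", col,
           "` is not numeric (rows ",
           paste(utils::head(bad, 10), collapse = ", "), ")", call. = FALSE)
    }
  }
  if (!("efa" %in% names(df)) &&
      !all(c("channel", "intensity") %in% names(df))) {
    stop("track table must contain either an `efa` column or `channel` and `intensity` columns",
         call. = FALSE)
  }
  dplyr::as_tibble(df)
}

#' Write a track table to CSV
#'
#' The canonical round-trip companion of [read_track_table()].
#'
#' @param tracks A tibble.
#' @param path Output path (`.csv`).
#' @return `path`, invisibly.
#' @export
write_track_table <- function(tracks, path) {
  readr::write_csv(tracks, path, progress = FALSE)
  invisible(path)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param tracks Path to a track table, or a `rekar_population` /
#'   track tibble already in memory, or `NULL` to simulate from
#'   `population`.
#' @param population A [population_spec()] used when `tracks` is `NULL`.
#' @param ratios `fret_ratios` for red-mode quantification (default:
#'   computed from [synthetic_red_optics()] when needed).
#' @param r_p CFP/YFP gain ratio (default: computed from
#'   [synthetic_cfpyfp_optics()] when needed).
#' @param pipeline A [pipeline_config()].
#' @param characterization A [characterization_config()].
#' @param seed Integer seed recorded in the run metadata and used for any
#'   simulation.
#' @param output_dir Directory for the output files, or `NULL` to skip
#'   writing.
#' @param apply_filter Apply the track length/range filter before
#'   processing (default `TRUE`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(tracks = NULL, population = NULL, ratios = NULL,
                       r_p = NULL, pipeline = pipeline_config(),
                       characterization = characterization_config(),
                       seed = 1L, output_dir = NULL, apply_filter = TRUE) {
  if (is.null(tracks) && is.null(population)) {
    stop("supply `tracks` (a path or table) or `population` (a population_spec)",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline: quantify, filter, process, characterize
#'
#' Composes the stages — quantification of channel intensities to EfA, track
#' filtering, smoothing/rebasing/normalization, and per-cell
#' characterization with replicate statistics — and optionally writes the
#' stage outputs (quantified tracks, per-cell and replicate-level
#' characterization, comparison statistics) plus a JSON run-metadata record
#' embedding the seed and a configuration hash. Deterministic under a fixed
#' seed; every stage is also exported individually.
#'
#' @param config A [run_config()].
#' @return A list of class `rekar_run`: `quantified` (filtered, processed
#'   traces), `rejections`, `scaling` (estimated factors, when dual-sensor
#'   cells are present), `characterization` (a `fret_characterization`),
#'   `metadata`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ratios <- config$ratios
  r_p <- config$r_p

  if (!is.null(config$tracks)) {
    tracks <- if (is.character(config$tracks)) {
      read_track_table(config$tracks)
    } else if (inherits(config$tracks, "rekar_population")) {
      config$tracks$tracks
    } else {
      dplyr::as_tibble(config$tracks)
    }
  } else {
    pop_spec <- config$population
    pop_spec$seed <- config$seed
    pop <- generate_population(pop_spec, ratios = ratios, r_p = r_p)
    ratios <- pop$ratios
    r_p <- pop$r_p
    tracks <- pop$tracks
  }
  if (is.null(ratios) && needs_red_quant(tracks)) {
    opt <- synthetic_red_optics()
    ratios <- compute_ratios(
      spectral_products(opt$sensor, opt$donor_channel, opt$fret_channel))
  }
  if (is.null(r_p) && needs_cy_quant(tracks)) {
    opt <- synthetic_cfpyfp_optics()
    r_p <- compute_rp(
      spectral_products(opt$sensor, opt$donor_channel, opt$fret_channel))
  }

  quantified <- quantify_tracks(tracks, ratios = ratios, r_p = r_p)
  if (isTRUE(config$apply_filter %||% TRUE)) {
    filtered <- filter_tracks(quantified, config$pipeline)
  } else {
    filtered <- quantified
  }
  rejections <- rejection_log(filtered)
  if (nrow(filtered) == 0L) {
    warning("no tracks survived filtering; downstream results are empty",
            call. = FALSE)
  }
  processed <- filtered |>
    smooth_traces(window = config$pipeline$smoothing_window) |>
    baseline_subtract()

  scaling <- NULL
  sensors <- unique(processed$sensor)
  if ("EKAREN4" %in% sensors && length(sensors) > 1) {
    dual_cells <- processed |>
      dplyr::distinct(.data$cell_id, .data$sensor) |>
      dplyr::count(.data$cell_id) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dual_cells) > 0) {
      scaling <- compute_scaling_factor(
        dplyr::semi_join(processed, dual_cells, by = "cell_id"),
        reference = "EKAREN4", config = config$pipeline
      )
    }
  }
  processed <- normalize_for_plotting(processed, scaling_factors = scaling,
                                      config = config$pipeline)
  characterization <- characterize(processed,
                                   config = config$characterization)

  metadata <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[c("pipeline", "characterization",
                                       "population", "seed")]),
    n_tracks_in = dplyr::n_distinct(quantified$cell_id, quantified$sensor),
    n_removed_length = sum(rejections$rule %in% c("length", "length+range")),
    n_removed_range = sum(rejections$rule %in% c("range", "length+range")),
    n_tracks_retained = dplyr::n_distinct(processed$cell_id, processed$sensor),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  out <- structure(
    list(quantified = processed, rejections = rejections, scaling = scaling,
         characterization = characterization, metadata = metadata),
    class = "rekar_run"
  )
  if (!is.null(config$output_dir)) write_run_outputs(out, config$output_dir)
  out
}

needs_red_quant <- function(tracks) {
  "channel" %in% names(tracks) &&
    any(c("i_donor", "i_fret") %in% unique(tracks$channel))
}
needs_cy_quant <- function(tracks) {
  "channel" %in% names(tracks) &&
    any(c("i_cfp", "i_yfp") %in% unique(tracks$channel))
}

write_run_outputs <- function(run, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$quantified, file.path(output_dir, "quantified_tracks.csv"),
                   progress = FALSE)
  readr::write_csv(run$rejections, file.path(output_dir, "rejection_log.csv"),
                   progress = FALSE)
  ch <- run$characterization
  readr::write_csv(ch$per_cell, file.path(output_dir, "characterization_cells.csv"),
                   progress = FALSE)
  readr::write_csv(ch$replicates,
                   file.path(output_dir, "characterization_replicates.csv"),
                   progress = FALSE)
  if (!is.null(ch$comparisons)) {
    readr::write_csv(tidy(ch), file.path(output_dir, "stats.csv"),
                     progress = FALSE)
  }
  if (!is.null(run$scaling)) {
    readr::write_csv(run$scaling, file.path(output_dir, "scaling_factors.csv"),
                     progress = FALSE)
  }
  jsonlite::write_json(run$metadata, file.path(output_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(output_dir)
}

#' Read a pipeline configuration from a YAML manifest
#'
#' The manifest may name spectra files (two-column CSVs) for a calibration
#' block, a track table path, and overrides for pipeline and
#' characterization constants. Recognised top-level keys: `tracks`,
#' `seed`, `output_dir`, `pipeline` (fields of [pipeline_config()]),
#' `characterization` (fields of [characterization_config()]), and `ratios`
#' (fields of [fret_ratios()]).
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pip <- do.call(pipeline_config, y$pipeline %||% list())
  ch <- do.call(characterization_config, y$characterization %||% list())
  ratios <- if (!is.null(y$ratios)) do.call(fret_ratios, y$ratios) else NULL
  run_config(
    tracks = y$tracks,
    ratios = ratios,
    r_p = y$r_p,
    pipeline = pip,
    characterization = ch,
    seed = y$seed %||% 1L,
    output_dir = y$output_dir
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rekar_run <- function(x, ...) {
  cat("Pipeline run:", x$metadata$n_tracks_in, "tracks in;",
      x$metadata$n_removed_length, "removed (length),",
      x$metadata$n_removed_range, "removed (range);",
      x$metadata$n_tracks_retained, "retained\n")
  print(x$characterization, ...)
  invisible(x)
}
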