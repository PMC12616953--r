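#' Characterization configuration
#'
#' The noise window is placed well after inhibitor addition, when true kinase
#' activity is fully suppressed and any residual variation is measurement
#' noise: by default hours 2 to 5 after treatment, both boundaries inclusive.
#'
#' @param noise_window_start_h,noise_window_end_h Window boundaries in hours
#'   after inhibitor addition.
#' @param min_frames_in_window Minimum frames required inside the window for
#'   a cell's noise estimate.
#' @param alpha Significance level for the multiple-comparison flags.
#' @return A list of class `characterization_config`.
#' @export
characterization_config <- function(noise_window_start_h = 2,
                                    noise_window_end_h = 5,
                                    min_frames_in_window = 10,
                                    alpha = 0.05) {
  if (!(noise_window_start_h >= 0 && noise_window_start_h < noise_window_end_h)) {
    stop("need 0 <= noise_window_start_h < noise_window_end_h", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  structure(as.list(environment()), class = "characterization_config")
}

#' Per-cell dynamic range (Signal)
#'
#' Maximum minus minimum of the cell's retained, unsmoothed signal: the
#' span from maximal activation (post-EGF peak) to maximal suppression
#' (post-inhibition minimum). Cells with fewer than two present frames give
#' `NA`.
#'
#' @param efa Numeric vector of one cell's EfA values.
#' @return Scalar dynamic range in the same (arbitrary) units as the signal.
#' @export
dynamic_range <- function(efa) {
  efa <- efa[!is.na(efa)]
  if (length(efa) < 2L) return(NA_real_)
  max(efa) - min(efa)
}

#' Per-cell noise variance (Noise)
#'
#' Unbiased sample variance of the signal over frames whose time lies in the
#' closed post-inhibition window (by default hours 2–5 after inhibitor
#' addition). Cells with too few frames in the window give `NA`.
#'
#' @param efa,time_min One cell's signal and frame times.
#' @param inhibitor_time_min Inhibitor addition time (same time base).
#' @param config A [characterization_config()].
#' @return Scalar variance (signal units squared).
#' @export
noise_variance <- function(efa, time_min, inhibitor_time_min,
                           config = characterization_config()) {
  lo <- inhibitor_time_min + 60 * config$noise_window_start_h
  hi <- inhibitor_time_min + 60 * config$noise_window_end_h
  inside <- !is.na(efa) & time_min >= lo & time_min <= hi
  if (sum(inside) < config$min_frames_in_window) return(NA_real_)
  stats::var(efa[inside])
}

#' Signal-to-noise ratio
#'
#' Per-cell dynamic range divided by that same cell's noise variance. Note
#' the population SNR reported for a sensor is the mean of per-cell ratios,
#' not the ratio of mean Signal to mean Noise.
#'
#' @param signal,noise Per-cell dynamic range and noise variance.
#' @return `signal / noise`; `NA` where noise is 0 (a noise-free measurement
#'   is outside the model; affected cells are excluded with a warning by
#'   [characterize_cells()]).
#' @export
snr <- function(signal, noise) {
  out <- signal / noise
  out[!is.na(noise) & noise == 0] <- NA_real_
  out
}

#' Per-cell characterization table
#'
#' Computes Signal ([dynamic_range()]), Noise ([noise_variance()]) and SNR
#' for every cell in a quantified trace table.
#'
#' @param traces Tibble with one row per cell-frame: `cell_id`, `sensor`,
#'   `time_min`, `efa`, replicate labels, and (unless supplied via
#'   `inhibitor_time_min`) an `inhibitor_time_min` column.
#' @param inhibitor_time_min Optional scalar overriding the per-track column.
#' @param config A [characterization_config()].
#' @param signal_col Column holding the signal (default `"efa"`).
#' @return A tibble with one row per cell: replicate labels, `signal`,
#'   `noise`, `snr`.
#' @export
characterize_cells <- function(traces, inhibitor_time_min = NULL,
                               config = characterization_config(),
                               signal_col = "efa") {
  stopifnot(inherits(config, "characterization_config"))
  if (is.null(inhibitor_time_min) && !"inhibitor_time_min" %in% names(traces)) {
    stop("supply `inhibitor_time_min` or include it as a column", call. = FALSE)
  }
  labels <- intersect(c("sensor", "experimental_rep", "technical_rep"),
                      names(traces))
  out <- traces |>
    dplyr::group_by(.data$cell_id, !!!rlang::syms(labels)) |>
    dplyr::summarise(
      signal = dynamic_range(.data[[signal_col]]),
      noise = noise_variance(
        .data[[signal_col]], .data$time_min,
        if (is.null(inhibitor_time_min)) .data$inhibitor_time_min[1]
        else inhibitor_time_min,
        config
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(snr = snr(.data$signal, .data$noise))
  zero_noise <- !is.na(out$noise) & out$noise == 0
  if (any(zero_noise)) {
    warning(sum(zero_noise),
            " cell(s) with zero noise variance excluded from SNR", call. = FALSE)
  }
  out
}

#' Aggregate per-cell metrics to replicate-level means
#'
#' The statistical sample is the technical replicate: each metric is averaged
#' over all cells within a technical replicate, and the per-replicate means
#' are pooled across experimental replicates. One row per nonempty
#' (experimental, technical) pair; empty replicates are dropped with a
#' warning.
#'
#' @param per_cell Output of [characterize_cells()].
#' @param metrics Metric columns to average.
#' @return A tibble with replicate labels, `n_cells`, and the mean of each
#'   metric.
#' @export
aggregate_replicates <- function(per_cell,
                                 metrics = c("signal", "noise", "snr")) {
  for (col in c("experimental_rep", "technical_rep")) {
    if (!col %in% names(per_cell)) {
      stop("`per_cell` is missing replicate label column `", col, "`",
           call. = FALSE)
    }
  }
  labels <- intersect(c("sensor", "experimental_rep", "technical_rep"),
                      names(per_cell))
  out <- per_cell |>
    dplyr::group_by(!!!rlang::syms(labels)) |>
    dplyr::summarise(
      n_cells = sum(!is.na(.data$signal)),
      dplyr::across(dplyr::all_of(metrics), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  empty <- out$n_cells == 0L
  if (any(empty)) {
    warning(sum(empty), " empty replicate(s) dropped", call. = FALSE)
    out <- out[!empty, , drop = FALSE]
  }
  out
}

#' Compare groups with one-way ANOVA and Tukey–Kramer post-hoc tests
#'
#' Fits a one-way ANOVA on replicate-level values and computes all pairwise
#' Tukey honest-significant-difference comparisons (the Tukey–Kramer
#' studentized-range procedure, which supports unequal group sizes).
#'
#' @param data Tibble of replicate-level values.
#' @param value Name of the value column.
#' @param group Name of the grouping column (e.g. `"sensor"`).
#' @param alpha Significance level for the `significant` flag.
#' @return An object of class `fret_comparison`: a list with `anova`
#'   (one-row tibble: `f_statistic`, `df_between`, `df_within`, `p_value`),
#'   `tukey` (one row per pair: `comparison`, `estimate`, `conf_low`,
#'   `conf_high`, `adj_p_value`, `significant`), `alpha`, and the group
#'   sizes. Supports [generics::tidy()] and [generics::glance()].
#' @export
compare_groups <- function(data, value, group = "sensor", alpha = 0.05) {
  for (col in c(value, group)) {
    if (!col %in% names(data)) {
      stop("`data` is missing column `", col, "`", call. = FALSE)
    }
  }
  df <- tibble::tibble(
    value = data[[value]],
    group = factor(data[[group]])
  )
  df <- df[!is.na(df$value), , drop = FALSE]
  sizes <- table(df$group)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("group(s) with < 2 values excluded: ",
            paste(small, collapse = ", "), call. = FALSE)
    df <- df[!df$group %in% small, , drop = FALSE]
    df$group <- droplevels(df$group)
    sizes <- table(df$group)
  }
  if (nlevels(df$group) < 2) {
    stop("need at least 2 groups with >= 2 values each", call. = FALSE)
  }
  fit <- stats::aov(value ~ group, data = df)
  an <- stats::anova(fit)
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  tukey <- tibble::tibble(
    comparison = rownames(tuk),
    estimate = tuk[, "diff"],
    conf_low = tuk[, "lwr"],
    conf_high = tuk[, "upr"],
    adj_p_value = tuk[, "p adj"],
    significant = tuk[, "p adj"] < alpha
  )
  structure(
    list(
      anova = tibble::tibble(
        f_statistic = an$`F value`[1],
        df_between = an$Df[1],
        df_within = an$Df[2],
        p_value = an$`Pr(>F)`[1]
      ),
      tukey = tukey,
      alpha = alpha,
      group_sizes = tibble::tibble(group = names(sizes),
                                   n = as.integer(sizes)),
      metric = value
    ),
    class = "fret_comparison"
  )
}

#' @export
print.fret_comparison <- function(x, ...) {
  cat("One-way ANOVA on `", x$metric, "`: F(", x$anova$df_between, ", ",
      x$anova$df_within, ") = ", signif(x$anova$f_statistic, 4),
      ", p = ", signif(x$anova$p_value, 3), "\n", sep = "")
  cat("Tukey-Kramer pairwise comparisons (alpha = ", x$alpha, "):\n", sep = "")
  print(x$tukey, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname compare_groups
#' @param x A `fret_comparison` object.
#' @param ... Unused.
#' @export
tidy.fret_comparison <- function(x, ...) x$tukey

#' @rdname compare_groups
#' @export
glance.fret_comparison <- function(x, ...) x$anova

#' Full characterization of a quantified population
#'
#' Runs [characterize_cells()], [aggregate_replicates()] and, when two or
#' more sensors are present, [compare_groups()] on each metric.
#'
#' @inheritParams characterize_cells
#' @return An object of class `fret_characterization`: a list with
#'   `per_cell`, `replicates`, `summary` (per-sensor means of the
#'   replicate-level values), and `comparisons` (a named list of
#'   `fret_comparison` objects for signal, noise and snr, or `NULL` with a
#'   single sensor).
#' @export
characterize <- function(traces, inhibitor_time_min = NULL,
                         config = characterization_config(),
                         signal_col = "efa") {
  per_cell <- characterize_cells(traces, inhibitor_time_min, config, signal_col)
  replicates <- aggregate_replicates(per_cell)
  summary <- replicates |>
    dplyr::group_by(dplyr::across(dplyr::any_of("sensor"))) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      dplyr::across(c("signal", "noise", "snr"), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  comparisons <- NULL
  if ("sensor" %in% names(replicates) &&
      dplyr::n_distinct(replicates$sensor) >= 2) {
    comparisons <- lapply(
      stats::setNames(c("signal", "noise", "snr"),
                      c("signal", "noise", "snr")),
      function(m) {
        tryCatch(compare_groups(replicates, m, "sensor", config$alpha),
                 error = function(e) NULL)
      }
    )
    comparisons <- purrr::compact(comparisons)
    if (length(comparisons) == 0L) comparisons <- NULL
  }
  structure(
    list(per_cell = per_cell, replicates = replicates, summary = summary,
         comparisons = comparisons, config = config),
    class = "fret_characterization"
  )
}

#' @export
print.fret_characterization <- function(x, ...) {
  cat("Biosensor characterization:", nrow(x$per_cell), "cells,",
      nrow(x$replicates), "replicate means\n")
  print(x$summary, ...)
  if (!is.null(x$comparisons)) {
    for (m in names(x$comparisons)) {
      cat("\n")
      print(x$comparisons[[m]])
    }
  }
  invisible(x)
}

#' @rdname characterize
#' @param x A `fret_characterization` object.
#' @param ... Unused.
#' @export
tidy.fret_characterization <- function(x, ...) {
  if (is.null(x$comparisons)) return(x$replicates)
  purrr::map_dfr(x$comparisons, tidy, .id = "metric")
}

#' @rdname characterize
#' @export
glance.fret_characterization <- function(x, ...) {
  if (is.null(x$comparisons)) {
    return(tibble::tibble(n_cells = nrow(x$per_cell),
                          n_replicates = nrow(x$replicates)))
  }
  purrr::map_dfr(x$comparisons, glance, .id = "metric")
}
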