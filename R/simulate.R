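#' Parameters of a single-cell ERK activity time course
#'
#' Describes the canonical growth-factor experiment the generator emulates:
#' cells at a serum-starved baseline are stimulated with EGF, ERK activity
#' rises sharply to a peak about 30 min later, relaxes toward an elevated
#' plateau, and is then abolished by combined MEK/EGFR inhibition, reaching
#' its minimum within 20 min. Sensors of the near-infrared class additionally
#' show a transient undershoot below baseline after inhibition that recovers
#' over about an hour; this readout artifact is housed here as a
#' sensor-specific profile term. A T/A mutant (phospho-acceptor threonine
#' replaced by alanine) yields a constant baseline trace regardless of
#' treatments.
#'
#' Activity is a dimensionless fraction in \[0, 1\] of the sensor's saturable
#' response; [activity_to_efa()] maps it onto a sensor's EfA range.
#'
#' @param baseline_activity Pre-stimulation activity fraction.
#' @param peak_activity Activity fraction reached at the EGF peak.
#' @param egf_time_min EGF addition time (minutes from movie start).
#' @param peak_time_offset_min Time from EGF to peak (default 30).
#' @param plateau_fraction Position of the post-peak plateau between baseline
#'   (0) and peak (1).
#' @param post_peak_decay_rate Per-minute exponential relaxation rate from
#'   peak toward the plateau.
#' @param inhibitor_time_min MEK/EGFR inhibitor addition time.
#' @param inhibition_tau_min Time constant of the post-inhibition decay.
#' @param inhibition_reach_min Time at which the decay reaches its floor
#'   (default 12 min, within the observed 20 min); the decay is a compressed
#'   exponential that attains the floor exactly rather than asymptotically.
#' @param undershoot_depth Depth (activity fraction) of the post-inhibition
#'   undershoot below baseline; 0 disables it.
#' @param undershoot_dip_min Time after inhibition at which the undershoot is
#'   deepest.
#' @param undershoot_recovery_min Recovery time scale; with the default dip
#'   shape the undershoot has decayed to ~1% of its depth 60 min after the
#'   dip.
#' @param frame_interval_min Imaging interval (default 6 min).
#' @param ta_mutant If `TRUE`, the trace is constant at baseline.
#' @return A list of class `activity_profile`.
#' @export
activity_profile <- function(baseline_activity = 0.2,
                             peak_activity = 0.8,
                             egf_time_min = 60,
                             peak_time_offset_min = 30,
                             plateau_fraction = 0.5,
                             post_peak_decay_rate = 0.03,
                             inhibitor_time_min = 240,
                             inhibition_tau_min = 4,
                             inhibition_reach_min = 12,
                             undershoot_depth = 0,
                             undershoot_dip_min = 16,
                             undershoot_recovery_min = 60,
                             frame_interval_min = 6,
                             ta_mutant = FALSE) {
  if (baseline_activity < 0 || peak_activity > 1 ||
      baseline_activity > peak_activity) {
    stop("need 0 <= baseline_activity <= peak_activity <= 1", call. = FALSE)
  }
  if (frame_interval_min <= 0) stop("`frame_interval_min` must be > 0", call. = FALSE)
  if (any(c(egf_time_min, inhibitor_time_min, peak_time_offset_min,
            undershoot_depth) < 0)) {
    stop("times and undershoot depth must be >= 0", call. = FALSE)
  }
  if (inhibitor_time_min <= egf_time_min + peak_time_offset_min) {
    stop("inconsistent treatment times: the inhibitor must be added after the EGF peak",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "activity_profile")
}

#' Simulate a noise-free single-cell activity trace
#'
#' Piecewise kinetics: baseline before EGF; a logistic rise reaching
#' `peak_activity` exactly at `egf_time + peak_time_offset`; exponential
#' relaxation toward an elevated plateau; after the inhibitor, a compressed
#' exponential decay that reaches the baseline floor within
#' `inhibition_reach_min`, minus an optional undershoot pulse dipping below
#' baseline and relaxing back over the recovery period. T/A-mutant profiles
#' are constant at baseline.
#'
#' @param profile An [activity_profile()].
#' @param duration_min Movie length in minutes; must cover both treatments.
#' @return A tibble with columns `time_min` and `activity` (in \[0, 1\]),
#'   one row per frame.
#' @export
simulate_activity <- function(profile, duration_min = 600) {
  stopifnot(inherits(profile, "activity_profile"))
  p <- profile
  if (duration_min < p$inhibitor_time_min) {
    stop("inconsistent treatment times: `duration_min` must cover the inhibitor time",
         call. = FALSE)
  }
  t <- seq(0, duration_min, by = p$frame_interval_min)
  tibble::tibble(time_min = t, activity = activity_at(p, t))
}

# Vectorized activity evaluation at arbitrary times.
activity_at <- function(p, t) {
  if (p$ta_mutant) return(rep(p$baseline_activity, length(t)))
  a <- rep(p$baseline_activity, length(t))
  t_peak <- p$egf_time_min + p$peak_time_offset_min
  plateau <- p$baseline_activity +
    p$plateau_fraction * (p$peak_activity - p$baseline_activity)

  # logistic rise normalized to hit baseline at EGF and peak at t_peak
  rise <- t >= p$egf_time_min & t <= t_peak
  if (any(rise)) {
    s <- p$peak_time_offset_min / 8
    mid <- p$egf_time_min + p$peak_time_offset_min / 2
    lg <- function(x) 1 / (1 + exp(-(x - mid) / s))
    g <- (lg(t[rise]) - lg(p$egf_time_min)) / (lg(t_peak) - lg(p$egf_time_min))
    a[rise] <- p$baseline_activity + (p$peak_activity - p$baseline_activity) * g
  }

  relax <- t > t_peak & t < p$inhibitor_time_min
  if (any(relax)) {
    a[relax] <- plateau + (p$peak_activity - plateau) *
      exp(-p$post_peak_decay_rate * (t[relax] - t_peak))
  }

  post <- t >= p$inhibitor_time_min
  if (any(post)) {
    a_inh <- plateau + (p$peak_activity - plateau) *
      exp(-p$post_peak_decay_rate * (p$inhibitor_time_min - t_peak))
    d <- t[post] - p$inhibitor_time_min
    tau <- p$inhibition_tau_min
    reach <- p$inhibition_reach_min
    decay <- pmax(0, exp(-d / tau) - exp(-reach / tau)) / (1 - exp(-reach / tau))
    dip <- if (p$undershoot_depth > 0) {
      r <- d / p$undershoot_dip_min
      p$undershoot_depth * r^2 * exp(2 * (1 - r))
    } else 0
    a[post] <- p$baseline_activity + (a_inh - p$baseline_activity) * decay - dip
  }
  pmin(pmax(a, 0), 1)
}

#' Sensor response parameters
#'
#' How a biosensor maps kinase activity onto measurable EfA, and the
#' measurement noise riding on it. The EfA endpoints are the sensor's
#' operating range (the same ranges used by the track range filter);
#' measurement noise can be placed on the channel intensities (the default
#' mechanism, reflecting that both channels of the near-infrared pair share
#' one excitation) or directly on EfA (a calibrated post-ratio mode in which
#' the generated traces have exactly the requested EfA noise s.d.).
#'
#' @param efa_min,efa_max Sensor EfA endpoints, `0 <= efa_min < efa_max <= 1`.
#' @param mode `"red"` (two-channel crosstalk-corrected readout) or
#'   `"cfpyfp"` (two-filter gain-ratio readout).
#' @param noise_mode `"intensity"` or `"efa"`.
#' @param noise_sd Intensity-scale Gaussian s.d. per channel per frame
#'   (counts), used when `noise_mode = "intensity"`.
#' @param noise_efa_sd EfA-scale Gaussian s.d. per frame, used when
#'   `noise_mode = "efa"`.
#' @param expression_lognormal_sigma Log-sd of the per-cell brightness
#'   multiplier (mean 1).
#' @param dropout_prob_per_frame Probability that a frame is missing from a
#'   track.
#' @param brightness Mean donor-channel brightness of a fully unquenched
#'   sensor (arbitrary counts).
#' @return A list of class `sensor_response`.
#' @export
sensor_response <- function(efa_min = 0.15, efa_max = 0.4,
                            mode = c("red", "cfpyfp"),
                            noise_mode = c("intensity", "efa"),
                            noise_sd = 0, noise_efa_sd = 0,
                            expression_lognormal_sigma = 0,
                            dropout_prob_per_frame = 0,
                            brightness = 1000) {
  mode <- match.arg(mode)
  noise_mode <- match.arg(noise_mode)
  if (!(efa_min >= 0 && efa_min < efa_max && efa_max <= 1)) {
    stop("need 0 <= efa_min < efa_max <= 1", call. = FALSE)
  }
  if (noise_sd < 0 || noise_efa_sd < 0) stop("noise s.d. must be >= 0", call. = FALSE)
  if (dropout_prob_per_frame < 0 || dropout_prob_per_frame >= 1) {
    stop("`dropout_prob_per_frame` must be in [0, 1)", call. = FALSE)
  }
  structure(as.list(environment()), class = "sensor_response")
}

#' Map an activity trace onto a sensor's EfA range
#'
#' Affine map: `efa = efa_min + activity * (efa_max - efa_min)`.
#'
#' @param activity Numeric vector in \[0, 1\].
#' @param response A [sensor_response()].
#' @return Numeric EfA vector.
#' @export
activity_to_efa <- function(activity, response) {
  stopifnot(inherits(response, "sensor_response"))
  if (any(!is.na(activity) & (activity < 0 | activity > 1))) {
    stop("activity must lie in [0, 1]", call. = FALSE)
  }
  response$efa_min + activity * (response$efa_max - response$efa_min)
}

#' Built-in sensor presets emulating the characterized biosensors
#'
#' Each preset bundles an activity profile and a sensor response whose
#' noise-free dynamic range and post-inhibition EfA noise variance equal the
#' values measured for the corresponding sensor on real cells
#' (EKAREN4: range 0.20, noise variance 0.0037; REKAR67: 0.13 and 0.009;
#' REKAR76: 0.10 and 0.007), with EfA operating ranges 0.30–0.65 (EKAREN4)
#' and 0.15–0.40 (REKAR variants). REKAR presets carry the post-inhibition
#' undershoot; `"REKAR67-TA"`/`"REKAR76-TA"` are the non-responsive
#' phospho-null controls (flat activity, same noise). Noise is placed on EfA
#' (the calibrated post-ratio mode) so that generated windows have exactly
#' the stated variances.
#'
#' @param name One of `"EKAREN4"`, `"REKAR67"`, `"REKAR76"`, `"REKAR67-TA"`,
#'   `"REKAR76-TA"`.
#' @return A list with elements `label`, `profile`, `response`.
#' @export
sensor_preset <- function(name = c("EKAREN4", "REKAR67", "REKAR76",
                                   "REKAR67-TA", "REKAR76-TA")) {
  name <- match.arg(name)
  base <- switch(
    name,
    "EKAREN4" = list(
      profile = activity_profile(baseline_activity = 0.12, peak_activity = 0.70,
                                 undershoot_depth = 0),
      response = sensor_response(efa_min = 0.30, efa_max = 0.65, mode = "cfpyfp",
                                 noise_mode = "efa", noise_efa_sd = 0.06108)
    ),
    "REKAR67" = ,
    "REKAR67-TA" = list(
      profile = activity_profile(baseline_activity = 0.20, peak_activity = 0.641,
                                 undershoot_depth = 0.08,
                                 ta_mutant = grepl("TA$", name)),
      response = sensor_response(efa_min = 0.15, efa_max = 0.40, mode = "red",
                                 noise_mode = "efa", noise_efa_sd = sqrt(0.009))
    ),
    "REKAR76" = ,
    "REKAR76-TA" = list(
      profile = activity_profile(baseline_activity = 0.20, peak_activity = 0.551,
                                 undershoot_depth = 0.05,
                                 ta_mutant = grepl("TA$", name)),
      response = sensor_response(efa_min = 0.15, efa_max = 0.40, mode = "red",
                                 noise_mode = "efa", noise_efa_sd = sqrt(0.007))
    )
  )
  c(list(label = name), base)
}

#' Convert an EfA trace to two channel-intensity traces
#'
#' Pushes a ground-truth EfA trace through the forward optical model. In the
#' `"red"` mode, the donor-channel intensity is proportional to
#' `expression * (1 - EfA)` and the FRET-channel intensity follows from the
#' forward NIR model; in the `"cfpyfp"` mode the CFP/YFP intensity ratio is
#' `R_P * (1 - EfA)`. Noise is then applied per the response's `noise_mode`:
#' additive Gaussian per channel per frame on intensities, or (post-ratio
#' mode) Gaussian on EfA before the forward mapping, in which case the
#' quantified EfA carries exactly that noise.
#'
#' @param efa Numeric EfA trace, all values `< 1`.
#' @param response A [sensor_response()].
#' @param ratios A `fret_ratios` row (`"red"` mode).
#' @param r_p Gain ratio (`"cfpyfp"` mode).
#' @param donor_channel,fret_channel [channel_config()]s; defaults have
#'   `P = t = 1`.
#' @param expression Per-cell brightness multiplier.
#' @param noise_multiplier Per-cell multiplier on the noise s.d.
#' @return A tibble with columns `frame`, `efa_true`, `efa_embedded` (the EfA
#'   actually encoded in the intensities, i.e. truth plus post-ratio noise if
#'   any), and one intensity column per channel (`i_donor`/`i_fret` or
#'   `i_cfp`/`i_yfp`).
#' @export
efa_to_intensities <- function(efa, response, ratios = NULL, r_p = NULL,
                               donor_channel = NULL, fret_channel = NULL,
                               expression = 1, noise_multiplier = 1) {
  stopifnot(inherits(response, "sensor_response"))
  if (any(!is.na(efa) & efa >= 1)) {
    stop("domain error: EfA must be < 1", call. = FALSE)
  }
  n <- length(efa)
  efa_emb <- efa
  if (response$noise_mode == "efa" && response$noise_efa_sd > 0) {
    efa_emb <- efa + stats::rnorm(n, 0, response$noise_efa_sd * noise_multiplier)
    efa_emb <- pmin(efa_emb, 0.999)  # forward model requires EfA < 1
  }
  bright <- response$brightness * expression
  if (response$mode == "red") {
    if (is.null(ratios)) stop("`ratios` is required in \"red\" mode", call. = FALSE)
    if (is.null(donor_channel)) donor_channel <- unit_channel("RFP670")
    if (is.null(fret_channel)) fret_channel <- unit_channel("FRET720")
    pt_d <- donor_channel$relative_power * donor_channel$exposure
    pt_f <- fret_channel$relative_power * fret_channel$exposure
    i_donor <- bright * (1 - efa_emb) * pt_d
    i_fret <- i_donor * forward_nir(efa_emb, ratios) * (pt_f / pt_d)
    out <- tibble::tibble(frame = seq_len(n) - 1L, efa_true = efa,
                          efa_embedded = efa_emb,
                          i_donor = i_donor, i_fret = i_fret)
  } else {
    if (is.null(r_p)) stop("`r_p` is required in \"cfpyfp\" mode", call. = FALSE)
    i_yfp <- rep(bright, n)
    i_cfp <- i_yfp * r_p * (1 - efa_emb)
    out <- tibble::tibble(frame = seq_len(n) - 1L, efa_true = efa,
                          efa_embedded = efa_emb,
                          i_cfp = i_cfp, i_yfp = i_yfp)
  }
  if (response$noise_mode == "intensity" && response$noise_sd > 0) {
    sd_i <- response$noise_sd * noise_multiplier
    ich <- setdiff(names(out), c("frame", "efa_true", "efa_embedded"))
    for (col in ich) out[[col]] <- out[[col]] + stats::rnorm(n, 0, sd_i)
  }
  out
}

unit_channel <- function(name) {
  flat <- spectrum_table(c(300, 900), c(1, 1))
  channel_config(name, flat, flat, relative_power = 1, exposure = 1)
}

#' Specify a synthetic single-cell population
#'
#' The replicate structure mirrors the characterization study design:
#' `n_experimental` independent experiments each containing `n_technical`
#' wells of `n_cells` tracked cells. With `dual = TRUE` every cell carries all
#' sensors in `sensors` (co-expression); otherwise each sensor gets its own
#' independent cells.
#'
#' @param n_cells Cells per technical replicate.
#' @param n_technical,n_experimental Replicate counts.
#' @param sensors A list of [sensor_preset()]-style lists (elements `label`,
#'   `profile`, `response`), or character names passed to [sensor_preset()].
#' @param dual Co-express all sensors in each cell.
#' @param amplitude_lognormal_sigma Log-sd of the per-cell multiplier on
#'   activity amplitude (peak minus baseline), mean 1.
#' @param duration_min Movie length.
#' @param seed Integer seed; all randomness in the generated population flows
#'   from it, and each cell draws from its own stream keyed by
#'   `(seed, cell index)` so that subsets of cells are reproducible.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_cells = 50, n_technical = 3, n_experimental = 3,
                            sensors = list(sensor_preset("REKAR67")),
                            dual = FALSE,
                            amplitude_lognormal_sigma = 0.15,
                            duration_min = 600, seed = 1L) {
  if (is.character(sensors)) sensors <- lapply(sensors, sensor_preset)
  if (n_cells < 0 || n_technical < 1 || n_experimental < 1) {
    stop("replicate counts must be >= 1 and `n_cells` >= 0", call. = FALSE)
  }
  labels <- vapply(sensors, function(s) s$label, character(1))
  if (anyDuplicated(labels)) stop("sensor labels must be unique", call. = FALSE)
  structure(as.list(environment()), class = "population_spec")
}

#' Generate a synthetic single-cell track table with ground truth
#'
#' Draws per-cell heterogeneity (lognormal multipliers on expression and on
#' activity amplitude), simulates each cell's activity, maps it through each
#' sensor's response and the forward optical model to channel intensities,
#' applies frame dropout, and returns both the observable track table and the
#' generating ground truth. Deterministic under a fixed spec seed.
#'
#' @param spec A [population_spec()].
#' @param ratios `fret_ratios` used by `"red"`-mode sensors (default: computed
#'   from [synthetic_red_optics()]).
#' @param r_p Gain ratio used by `"cfpyfp"`-mode sensors (default: computed
#'   from [synthetic_cfpyfp_optics()]).
#' @return A list of class `rekar_population` with elements `tracks` (long
#'   tibble: `cell_id`, `sensor`, `experimental_rep`, `technical_rep`,
#'   `frame`, `time_min`, `channel`, `intensity`, `egf_time_min`,
#'   `inhibitor_time_min`) and `truth` (`cell_id`, `sensor`, `frame`,
#'   `time_min`, `activity`, `efa_true`, `efa_embedded`).
#' @export
generate_population <- function(spec, ratios = NULL, r_p = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  needs_red <- any(vapply(spec$sensors, function(s) s$response$mode == "red",
                          logical(1)))
  needs_cy <- any(vapply(spec$sensors, function(s) s$response$mode == "cfpyfp",
                         logical(1)))
  if (needs_red && is.null(ratios)) {
    opt <- synthetic_red_optics()
    ratios <- compute_ratios(
      spectral_products(opt$sensor, opt$donor_channel, opt$fret_channel))
  }
  if (needs_cy && is.null(r_p)) {
    opt <- synthetic_cfpyfp_optics()
    r_p <- compute_rp(
      spectral_products(opt$sensor, opt$donor_channel, opt$fret_channel))
  }

  design <- tidyr::expand_grid(
    experimental_rep = seq_len(spec$n_experimental),
    technical_rep = seq_len(spec$n_technical),
    cell = seq_len(max(spec$n_cells, 0L))
  )
  if (spec$n_cells == 0L || nrow(design) == 0L) {
    return(empty_population())
  }
  design$cell_index <- seq_len(nrow(design))

  # noise-free base activity per sensor (shared across cells)
  base <- lapply(spec$sensors, function(s) {
    tr <- simulate_activity(s$profile, spec$duration_min)
    list(sensor = s, time = tr$time_min, act = tr$activity,
         baseline = s$profile$baseline_activity)
  })

  one_cell <- function(experimental_rep, technical_rep, cell, cell_index) {
    set.seed(cell_seed(spec$seed, cell_index))
    sig_a <- spec$amplitude_lognormal_sigma
    h_amp <- if (sig_a > 0) stats::rlnorm(1, -sig_a^2 / 2, sig_a) else 1
    cell_id <- sprintf("c%05d_e%d_t%d", cell_index, experimental_rep,
                       technical_rep)
    sensor_sets <- if (spec$dual) base else base[((cell_index - 1L) %% length(base)) + 1L]
    purrr::map(sensor_sets, function(b) {
      resp <- b$sensor$response
      sig_e <- resp$expression_lognormal_sigma
      h_expr <- if (sig_e > 0) stats::rlnorm(1, -sig_e^2 / 2, sig_e) else 1
      act <- pmin(pmax(b$baseline + h_amp * (b$act - b$baseline), 0), 1)
      efa <- activity_to_efa(act, resp)
      inten <- efa_to_intensities(efa, resp, ratios = ratios, r_p = r_p,
                                  expression = h_expr)
      keep <- rep(TRUE, length(act))
      if (resp$dropout_prob_per_frame > 0) {
        keep <- stats::runif(length(act)) >= resp$dropout_prob_per_frame
      }
      truth <- tibble::tibble(
        cell_id = cell_id, sensor = b$sensor$label,
        experimental_rep = experimental_rep, technical_rep = technical_rep,
        frame = inten$frame, time_min = b$time,
        activity = act, efa_true = inten$efa_true,
        efa_embedded = inten$efa_embedded
      )
      ich <- setdiff(names(inten), c("frame", "efa_true", "efa_embedded"))
      tracks <- tidyr::pivot_longer(
        dplyr::bind_cols(truth[keep, c("cell_id", "sensor", "experimental_rep",
                                       "technical_rep", "frame", "time_min")],
                         inten[keep, ich, drop = FALSE]),
        cols = dplyr::all_of(ich), names_to = "channel", values_to = "intensity"
      )
      tracks$egf_time_min <- b$sensor$profile$egf_time_min
      tracks$inhibitor_time_min <- b$sensor$profile$inhibitor_time_min
      list(tracks = tracks, truth = truth)
    })
  }

  parts <- purrr::pmap(design, one_cell)
  parts <- purrr::flatten(parts)
  out <- list(
    tracks = dplyr::bind_rows(purrr::map(parts, "tracks")),
    truth = dplyr::bind_rows(purrr::map(parts, "truth")),
    spec = spec, ratios = ratios, r_p = r_p
  )
  class(out) <- "rekar_population"
  out
}

cell_seed <- function(seed, cell_index) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(cell_index)) %% 2147483647
}

empty_population <- function() {
  structure(
    list(
      tracks = tibble::tibble(
        cell_id = character(), sensor = character(),
        experimental_rep = integer(), technical_rep = integer(),
        frame = integer(), time_min = numeric(), channel = character(),
        intensity = numeric(), egf_time_min = numeric(),
        inhibitor_time_min = numeric()
      ),
      truth = tibble::tibble(
        cell_id = character(), sensor = character(),
        experimental_rep = integer(), technical_rep = integer(),
        frame = integer(), time_min = numeric(), activity = numeric(),
        efa_true = numeric(), efa_embedded = numeric()
      )
    ),
    class = "rekar_population"
  )
}
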