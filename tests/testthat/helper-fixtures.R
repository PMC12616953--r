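# Shared fixtures, all built in code.

# A sensor preset with all randomness switched off.
quiet_preset <- function(name) {
  p <- sensor_preset(name)
  p$response$noise_efa_sd <- 0
  p$response$noise_sd <- 0
  p$response$expression_lognormal_sigma <- 0
  p
}

# Parameters of the Gaussian fixture optics, shared by the package path and
# the analytic oracle.
gaussian_optics_params <- function() {
  list(
    source = c(635, 10),
    ex_D = c(635, 12), em_D = c(670, 15),
    ex_F = c(635, 12), em_F = c(730, 18),
    abs_don = c(640, 20), emi_don = c(675, 18),
    abs_acc = c(700, 22), emi_acc = c(725, 20),
    ext_don = 2, qy_don = 0.5, ext_acc = 3, qy_acc = 0.25
  )
}

# Gaussian fixture spectra assembled into an optical model whose ratios are
# smooth and well-conditioned (used for convergence and oracle tests).
gaussian_optics <- function(step_nm = 1) {
  p <- gaussian_optics_params()
  mk <- function(ps) {
    wl <- seq(ps[1] - 5 * ps[2], ps[1] + 5 * ps[2], by = step_nm)
    spectrum_table(wl, exp(-0.5 * ((wl - ps[1]) / ps[2])^2))
  }
  donor <- fluorophore("gdonor", absorption = mk(p$abs_don),
                       emission = mk(p$emi_don),
                       extinction_coefficient = p$ext_don,
                       quantum_yield = p$qy_don)
  acceptor <- fluorophore("gacceptor", absorption = mk(p$abs_acc),
                          emission = mk(p$emi_acc),
                          extinction_coefficient = p$ext_acc,
                          quantum_yield = p$qy_acc)
  list(
    sensor = sensor_optical_model(donor, acceptor, mk(p$source)),
    donor_channel = channel_config("D", mk(p$ex_D), mk(p$em_D)),
    fret_channel = channel_config("F", mk(p$ex_F), mk(p$em_F))
  )
}

# Independent fine-grid integration oracle: plain Riemann sum at `step` nm of
# the factorized signal terms, evaluating the analytic Gaussian curves
# directly (independent of the package's tabulation and trapezoid path).
riemann_ratio_oracle <- function(step = 0.01) {
  p <- gaussian_optics_params()
  grid <- seq(450, 950, by = step)
  g <- function(ps) exp(-0.5 * ((grid - ps[1]) / ps[2])^2)
  ix <- function(exf, absn, ext) sum(g(p$source) * g(exf) * ext * g(absn)) * step
  im <- function(emf, emn, qy) sum(qy * g(emn) * g(emf)) * step
  den <- ix(p$ex_D, p$abs_don, p$ext_don) * im(p$em_D, p$emi_don, p$qy_don)
  list(
    R_XT = ix(p$ex_F, p$abs_don, p$ext_don) *
      im(p$em_F, p$emi_don, p$qy_don) / den,
    R_Chan = ix(p$ex_F, p$abs_acc, p$ext_acc) *
      im(p$em_F, p$emi_acc, p$qy_acc) / den,
    R_FRET = ix(p$ex_F, p$abs_don, p$ext_don) *
      im(p$em_F, p$emi_acc, p$qy_acc) / den
  )
}

# Random valid ratio set for inversion/monotonicity property tests.
random_ratios <- function() {
  fret_ratios(
    R_XT = stats::runif(1, 0, 2),
    R_Chan = stats::runif(1, 0.01, 1),
    R_FRET = stats::runif(1, 0.01, 1),
    k = stats::runif(1, 0.2, 3)
  )
}

# A compliant quantified trace table built directly from EfA values.
make_trace_table <- function(n_cells = 5, sensor = "REKAR67",
                             efa_fun = function(t) 0.25 + 0.05 * sin(t / 60),
                             n_frames = 101, frame_interval = 6,
                             inhibitor_time = 240) {
  purrr::map_dfr(seq_len(n_cells), function(i) {
    t <- (seq_len(n_frames) - 1) * frame_interval
    tibble::tibble(
      cell_id = sprintf("cell%03d", i), sensor = sensor,
      experimental_rep = 1L, technical_rep = 1L,
      frame = seq_len(n_frames) - 1L, time_min = t,
      efa = efa_fun(t), inhibitor_time_min = inhibitor_time
    )
  })
}
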