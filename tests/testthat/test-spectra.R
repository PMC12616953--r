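test_that("spectrum_table validates its invariants", {
  expect_error(spectrum_table(numeric(0), numeric(0)), "empty")
  expect_error(spectrum_table(c(600, 600), c(1, 1)), "strictly increasing")
  expect_error(spectrum_table(c(600, 610), c(1, -1)), "nonnegative")
  s <- spectrum_table(c(600, 610), c(0, 2))
  expect_s3_class(s, "spectrum_tbl")
})

test_that("resampling returns spectra unchanged on their own grid and zero outside support", {
  s <- spectrum_table(600:700, rep(1, 101))
  out <- resample_to_grid(s, step_nm = 1)[[1]]
  expect_equal(out$wavelength_nm, 600:700)
  expect_equal(out$value, rep(1, 101))

  # constant spectrum on [600, 700] seen from a wider union grid
  wide <- spectrum_table(c(550, 750), c(0, 0))
  both <- resample_to_grid(list(s, wide), step_nm = 1)
  v <- both[[1]]
  expect_equal(nrow(v), 201)
  expect_true(all(v$value[v$wavelength_nm >= 600 & v$wavelength_nm <= 700] == 1))
  expect_true(all(v$value[v$wavelength_nm < 600 | v$wavelength_nm > 700] == 0))
})

test_that("resampling matches a fine-grid interpolation oracle", {
  wl1 <- seq(600, 700, by = 2.5)
  wl2 <- seq(640, 760, by = 3)
  g1 <- spectrum_table(wl1, exp(-0.5 * ((wl1 - 650) / 15)^2))
  g2 <- spectrum_table(wl2, exp(-0.5 * ((wl2 - 700) / 20)^2))
  out <- resample_to_grid(list(g1, g2), step_nm = 1)
  # oracle: direct linear interpolation of each table at the output grid
  for (i in 1:2) {
    src <- list(g1, g2)[[i]]
    expect_grid <- out[[i]]$wavelength_nm
    oracle <- stats::approx(src$wavelength_nm, src$value, xout = expect_grid,
                            rule = 1)$y
    oracle[is.na(oracle)] <- 0
    expect_equal(out[[i]]$value, oracle, tolerance = 1e-9)
  }
})

test_that("spectral products reduce to raw spectra under unit filters and flat source", {
  flat <- spectrum_table(c(500, 900), c(1, 1))
  wl <- 600:700
  absn <- spectrum_table(wl, exp(-0.5 * ((wl - 650) / 15)^2))
  emn <- spectrum_table(wl, exp(-0.5 * ((wl - 680) / 15)^2))
  fl <- fluorophore("u", absn, emn, extinction_coefficient = 1, quantum_yield = 1)
  sens <- sensor_optical_model(fl, fl, flat)
  ch <- channel_config("c", flat, flat)
  pr <- spectral_products(sens, ch, ch)
  dd <- dplyr::filter(pr, channel == "D", fluorophore == "D")
  on_support <- dd$wavelength_nm %in% wl
  expect_equal(dd$X[on_support],
               stats::approx(absn$wavelength_nm, absn$value,
                             dd$wavelength_nm[on_support])$y)
  expect_equal(dd$M[on_support],
               stats::approx(emn$wavelength_nm, emn$value,
                             dd$wavelength_nm[on_support])$y)
  expect_true(all(dd$X[!on_support] == 0))
})

test_that("a zero emission filter zeroes that channel's M products", {
  opt <- gaussian_optics()
  dead <- spectrum_table(c(500, 900), c(0, 0))
  ch <- channel_config("dead-em", opt$fret_channel$excitation_filter, dead)
  pr <- spectral_products(opt$sensor, opt$donor_channel, ch)
  expect_true(all(pr$M[pr$channel == "F"] == 0))
  expect_true(any(pr$M[pr$channel == "D"] > 0))
})

test_that("products equal a pointwise multiplication oracle for boxcar filters", {
  wl <- seq(600, 780, by = 1)
  gauss <- function(mu, s) exp(-0.5 * ((wl - mu) / s)^2)
  box <- function(lo, hi) as.numeric(wl >= lo & wl <= hi)
  don <- fluorophore("d", spectrum_table(wl, gauss(640, 18)),
                     spectrum_table(wl, gauss(672, 14)),
                     extinction_coefficient = 2.5, quantum_yield = 0.4)
  acc <- fluorophore("a", spectrum_table(wl, gauss(700, 20)),
                     spectrum_table(wl, gauss(722, 16)),
                     extinction_coefficient = 1.5, quantum_yield = 0.2)
  src <- spectrum_table(wl, gauss(640, 10))
  sens <- sensor_optical_model(don, acc, src)
  chD <- channel_config("D", spectrum_table(wl, box(620, 650)),
                        spectrum_table(wl, box(660, 690)))
  chF <- channel_config("F", spectrum_table(wl, box(620, 650)),
                        spectrum_table(wl, box(705, 745)))
  pr <- spectral_products(sens, chD, chF)
  xfd <- dplyr::filter(pr, channel == "F", fluorophore == "D")
  expect_equal(xfd$X, gauss(640, 10) * box(620, 650) * 2.5 * gauss(640, 18))
  expect_equal(xfd$M, 0.4 * gauss(672, 14) * box(705, 745))
})

test_that("ratio trivial cases: zero crosstalk products and full symmetry", {
  opt <- gaussian_optics()
  # FRET channel with zero emission filter -> all FRET-channel terms zero
  dead <- spectrum_table(c(500, 900), c(0, 0))
  chF0 <- channel_config("F0", opt$fret_channel$excitation_filter, dead)
  r0 <- compute_ratios(spectral_products(opt$sensor, opt$donor_channel, chF0))
  expect_equal(r0$R_XT, 0)
  expect_equal(r0$R_Chan, 0)
  expect_equal(r0$R_FRET, 0)

  # identical fluorophores and identical channels -> all ratios exactly 1
  wl <- 600:700
  curve <- spectrum_table(wl, exp(-0.5 * ((wl - 650) / 12)^2))
  fl <- fluorophore("same", curve, curve)
  sens <- sensor_optical_model(fl, fl, curve)
  ch <- channel_config("same", curve, curve)
  r1 <- compute_ratios(spectral_products(sens, ch, ch))
  expect_equal(r1$R_XT, 1)
  expect_equal(r1$R_Chan, 1)
  expect_equal(r1$R_FRET, 1)
})

test_that("computed ratios match an independent fine-grid Riemann-sum oracle", {
  opt <- gaussian_optics()
  got <- compute_ratios(spectral_products(opt$sensor, opt$donor_channel,
                                          opt$fret_channel, step_nm = 1))
  want <- riemann_ratio_oracle(step = 0.01)
  expect_equal(got$R_XT, want$R_XT, tolerance = 1e-4)
  expect_equal(got$R_Chan, want$R_Chan, tolerance = 1e-4)
  expect_equal(got$R_FRET, want$R_FRET, tolerance = 1e-4)
})

test_that("ratios are invariant to a common rescaling of all spectra", {
  scale_spec <- function(s, f) spectrum_table(s$wavelength_nm, s$value * f)
  opt <- gaussian_optics()
  r1 <- compute_ratios(spectral_products(opt$sensor, opt$donor_channel,
                                         opt$fret_channel))
  f <- 37.5
  opt2 <- opt
  opt2$sensor$light_source <- scale_spec(opt$sensor$light_source, f)
  opt2$sensor$donor$absorption <- scale_spec(opt$sensor$donor$absorption, f)
  opt2$sensor$donor$emission <- scale_spec(opt$sensor$donor$emission, f)
  opt2$sensor$acceptor$absorption <- scale_spec(opt$sensor$acceptor$absorption, f)
  opt2$sensor$acceptor$emission <- scale_spec(opt$sensor$acceptor$emission, f)
  opt2$donor_channel$excitation_filter <- scale_spec(opt$donor_channel$excitation_filter, f)
  opt2$donor_channel$emission_filter <- scale_spec(opt$donor_channel$emission_filter, f)
  opt2$fret_channel$excitation_filter <- scale_spec(opt$fret_channel$excitation_filter, f)
  opt2$fret_channel$emission_filter <- scale_spec(opt$fret_channel$emission_filter, f)
  r2 <- compute_ratios(spectral_products(opt2$sensor, opt2$donor_channel,
                                         opt2$fret_channel))
  # every spectrum scaled by f: numerator and denominator terms pick up the
  # same power of f, so all ratios are unchanged
  expect_equal(r2$R_XT, r1$R_XT, tolerance = 1e-12)
  expect_equal(r2$R_Chan, r1$R_Chan, tolerance = 1e-12)
  expect_equal(r2$R_FRET, r1$R_FRET, tolerance = 1e-12)
})

test_that("disjoint donor supports raise a calibration error", {
  wl <- 600:650
  far <- 800:850
  don <- fluorophore("d", spectrum_table(wl, rep(1, 51)),
                     spectrum_table(wl, rep(1, 51)))
  acc <- fluorophore("a", spectrum_table(wl, rep(1, 51)),
                     spectrum_table(wl, rep(1, 51)))
  src <- spectrum_table(far, rep(1, 51))  # no overlap with absorption
  sens <- sensor_optical_model(don, acc, src)
  ch <- channel_config("c", spectrum_table(wl, rep(1, 51)),
                       spectrum_table(wl, rep(1, 51)))
  expect_error(spectral_products(sens, ch, ch), "calibration error")
})

test_that("gain ratio R_P behaves as a ratio of channel gains", {
  opt <- gaussian_optics()
  pr <- spectral_products(opt$sensor, opt$donor_channel, opt$fret_channel)
  rp <- compute_rp(pr)
  expect_gt(rp, 0)
  # doubling donor-channel power doubles R_P
  ch2 <- opt$donor_channel
  ch2$relative_power <- 2 * ch2$relative_power
  pr2 <- spectral_products(opt$sensor, ch2, opt$fret_channel)
  expect_equal(compute_rp(pr2), 2 * rp, tolerance = 1e-12)
  # symmetric configuration: identical gains -> R_P = 1
  wl <- 600:700
  curve <- spectrum_table(wl, exp(-0.5 * ((wl - 650) / 12)^2))
  fl <- fluorophore("same", curve, curve)
  sens <- sensor_optical_model(fl, fl, curve)
  ch <- channel_config("same", curve, curve)
  expect_equal(compute_rp(spectral_products(sens, ch, ch)), 1)
})

test_that("R_P matches the fine-grid oracle", {
  opt <- gaussian_optics()
  pr <- spectral_products(opt$sensor, opt$donor_channel, opt$fret_channel)
  want <- riemann_ratio_oracle(step = 0.01)
  # R_P = gain_D / gain_A; with unit P and t this is den / (IX_F^A IM_F^A),
  # i.e. 1 / R_Chan in oracle terms
  expect_equal(compute_rp(pr), 1 / want$R_Chan, tolerance = 1e-4)
})

test_that("crosstalk calibration from donor-only measurements", {
  dch <- channel_config("D", spectrum_table(c(500, 900), c(1, 1)),
                        spectrum_table(c(500, 900), c(1, 1)),
                        relative_power = 2, exposure = 0.5)
  fch <- channel_config("F", spectrum_table(c(500, 900), c(1, 1)),
                        spectrum_table(c(500, 900), c(1, 1)),
                        relative_power = 1, exposure = 1)
  # every normalized pair ratio identical -> that value exactly
  m <- tibble::tibble(i_donor = c(100, 200, 400))
  m$i_fret <- m$i_donor * 0.578  # P_F t_F / (P_D t_D) = 1 here
  r <- calibrate_rxt(m, dch, fch)
  expect_equal(r$R_XT, 0.578)
  expect_equal(r$source, "measured")

  # zero FRET-channel intensities -> zero crosstalk
  r0 <- calibrate_rxt(tibble::tibble(i_fret = c(0, 0), i_donor = c(10, 20)),
                      dch, fch)
  expect_equal(r0$R_XT, 0)

  # measured value overrides a computed ratio set
  base <- fret_ratios(R_XT = 0.3, R_Chan = 0.1, R_FRET = 0.2)
  upd <- calibrate_rxt(m, dch, fch, ratios = base)
  expect_equal(upd$R_XT, 0.578)
  expect_equal(upd$R_Chan, 0.1)
  expect_equal(upd$source, "measured")
  expect_error(calibrate_rxt(m[0, ], dch, fch), "calibration error")
})

test_that("noisy donor-only calibration recovers the true ratio", {
  dch <- channel_config("D", spectrum_table(c(500, 900), c(1, 1)),
                        spectrum_table(c(500, 900), c(1, 1)))
  set.seed(42)
  n <- 200
  true_rxt <- 0.578
  i_donor <- stats::runif(n, 100, 1000)
  i_fret <- i_donor * true_rxt * exp(stats::rnorm(n, 0, 0.05))
  r <- calibrate_rxt(tibble::tibble(i_fret = i_fret, i_donor = i_donor),
                     dch, dch)
  # multiplicative noise with log-sd 0.05: mean ratio within 3 SE
  se <- stats::sd(i_fret / i_donor) / sqrt(n)
  expect_lt(abs(r$R_XT - true_rxt * exp(0.05^2 / 2)), 3 * se)
})

test_that("spectrum CSV round trip and excess percentage arithmetic", {
  path <- withr::local_tempfile(fileext = ".csv")
  s <- gaussian_band(650, 15)
  readr::write_csv(s, path)
  s2 <- read_spectrum_csv(path)
  expect_equal(s2$value, s$value)
  expect_equal(ratio_excess_pct(1.1, 1.0), 10)
  expect_error(read_spectrum_csv(withr::local_tempfile(fileext = ".csv")))
  shipped <- system.file("extdata", "synthetic_mirfp670_emission.csv",
                         package = "rekar")
  expect_s3_class(read_spectrum_csv(shipped), "spectrum_tbl")
})
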