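test_that("dynamic range is max minus min of the retained trace", {
  expect_equal(dynamic_range(rep(0.3, 10)), 0)
  expect_equal(dynamic_range(c(0.20, 0.35, 0.25)), 0.15)
  expect_true(is.na(dynamic_range(c(0.3, NA))))
  # ground truth: a zero-noise synthetic cell returns exactly its amplitude
  p <- sensor_preset("REKAR67")
  tr <- simulate_activity(p$profile)
  efa <- activity_to_efa(tr$activity, p$response)
  expect_equal(dynamic_range(efa),
               (max(tr$activity) - min(tr$activity)) * (0.40 - 0.15))
})

test_that("noise variance is the unbiased variance inside the closed 2-5 h window", {
  t <- seq(0, 600, by = 6)
  inh <- 240
  efa <- rep(0.2, length(t))
  expect_equal(noise_variance(efa, t, inh), 0)
  # the window [inh+120, inh+300] holds 31 frames at 6-min spacing
  inside <- t >= inh + 120 & t <= inh + 300
  expect_equal(sum(inside), 31)
  # boundary frames are included: perturbing one changes the estimate
  efa2 <- efa; efa2[t == inh + 120] <- 0.5
  expect_gt(noise_variance(efa2, t, inh), 0)
  efa3 <- efa; efa3[t == inh + 300] <- 0.5
  expect_gt(noise_variance(efa3, t, inh), 0)
  # shifting the inhibitor time shifts the selected frames one-for-one
  efa4 <- efa; efa4[t == inh + 120] <- 0.5
  expect_equal(noise_variance(efa4, t, inh + 6), 0)
  # too few frames in the window is a per-cell missing result
  expect_true(is.na(noise_variance(efa[1:30], t[1:30], inh)))
})

test_that("windowed variance estimates recover a known i.i.d. noise level", {
  t <- seq(0, 600, by = 6)
  set.seed(33)
  n_cells <- 400
  ests <- vapply(seq_len(n_cells), function(i) {
    noise_variance(stats::rnorm(length(t), 0.2, 0.01), t, 240)
  }, numeric(1))
  # mean of the unbiased estimator is sigma^2 = 1e-4; chi-square(30) spread
  se <- sqrt(2 / 30) * 1e-4 / sqrt(n_cells)
  expect_lt(abs(mean(ests) - 1e-4), 3 * se)
})

test_that("SNR is signal over noise with the stated degenerate handling", {
  expect_equal(snr(0.13, 0.009), 14.444444, tolerance = 1e-6)
  expect_equal(snr(0, 0.009), 0)
  expect_equal(snr(0.13, 0.018), snr(0.13, 0.009) / 2)  # doubling noise halves SNR
  expect_true(is.na(snr(0.1, 0)))
})

test_that("SNR is invariant to adding a constant offset to the trace", {
  t <- seq(0, 600, by = 6)
  set.seed(7)
  efa <- 0.25 + 0.05 * sin(t / 60) + stats::rnorm(length(t), 0, 0.01)
  s1 <- dynamic_range(efa) / noise_variance(efa, t, 240)
  s2 <- dynamic_range(efa + 0.37) / noise_variance(efa + 0.37, t, 240)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("replicate aggregation pools technical means across experiments", {
  per_cell <- tibble::tibble(
    cell_id = paste0("c", 1:5),
    sensor = "s",
    experimental_rep = c(1L, 1L, 1L, 1L, 2L),
    technical_rep = c(1L, 1L, 2L, 2L, 1L),
    signal = c(1, 3, 1, 3, 5), noise = c(1, 1, 2, 2, 3),
    snr = c(1, 3, 0.5, 1.5, 5 / 3)
  )
  agg <- aggregate_replicates(per_cell)
  expect_equal(nrow(agg), 3)  # nonempty (experimental x technical) pairs
  expect_equal(sort(agg$signal), c(2, 2, 5))  # {1,3}->2, {1,3}->2, {5}->5
  # replicate means equal the mean of their member cells
  expect_equal(agg$n_cells, c(2L, 2L, 1L))
  # grand mean of replicate means equals the weighted per-cell mean with
  # weights 1 / (cells in replicate)
  w <- 1 / agg$n_cells[match(paste(per_cell$experimental_rep,
                                   per_cell$technical_rep),
                             paste(agg$experimental_rep, agg$technical_rep))]
  expect_equal(mean(agg$signal), sum(per_cell$signal * w) / sum(w))
})

test_that("per-cell characterization composes the three metrics over a table", {
  tab <- make_trace_table(n_cells = 3, efa_fun = function(t) {
    0.2 + 0.1 * (t > 100 & t < 200)
  })
  set.seed(12)
  tab$efa <- tab$efa + stats::rnorm(nrow(tab), 0, 0.005)
  pc <- characterize_cells(tab)
  expect_equal(nrow(pc), 3)
  expect_true(all(pc$signal > 0.09))
  expect_true(all(pc$noise > 0))
  expect_equal(pc$snr, pc$signal / pc$noise)
})

test_that("group comparison matches a hand-computed Tukey-Kramer oracle", {
  set.seed(88)
  dat <- tibble::tibble(
    sensor = rep(c("a", "b", "c"), times = c(8, 10, 6)),
    value = c(stats::rnorm(8, 0), stats::rnorm(10, 0.8), stats::rnorm(6, 0.3))
  )
  cmp <- compare_groups(dat, "value", "sensor")
  # independent oracle: studentized range statistic per pair
  mse <- {
    fit <- stats::lm(value ~ sensor, data = dat)
    sum(stats::resid(fit)^2) / fit$df.residual
  }
  means <- tapply(dat$value, dat$sensor, mean)
  ns <- tapply(dat$value, dat$sensor, length)
  df_w <- nrow(dat) - 3
  pairs <- utils::combn(names(means), 2, simplify = FALSE)
  oracle_p <- vapply(pairs, function(pr) {
    q <- abs(means[pr[2]] - means[pr[1]]) /
      sqrt((mse / 2) * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    stats::ptukey(q, nmeans = 3, df = df_w, lower.tail = FALSE)
  }, numeric(1))
  got <- cmp$tukey$adj_p_value[match(
    vapply(pairs, function(pr) paste(pr[2], pr[1], sep = "-"), character(1)),
    cmp$tukey$comparison)]
  expect_equal(unname(got), unname(oracle_p), tolerance = 1e-6)
  # glance/tidy surfaces
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_equal(nrow(tidy(cmp)), 3)
  expect_true(all(c("f_statistic", "p_value") %in% names(glance(cmp))))
})

test_that("extreme separation is detected and degenerate groups are excluded", {
  set.seed(4)
  dat <- tibble::tibble(
    sensor = rep(c("lo", "hi"), each = 3),
    value = c(0, 0, 0, 10, 10, 10) + stats::rnorm(6, 0, 1e-4)
  )
  cmp <- suppressWarnings(compare_groups(dat, "value", "sensor"))
  expect_lt(cmp$tukey$adj_p_value, 1e-6)
  expect_true(cmp$tukey$significant)
  # a group with fewer than 2 values is dropped with a warning
  dat2 <- dplyr::bind_rows(dat, tibble::tibble(sensor = "single", value = 1))
  warns <- testthat::capture_warnings(
    cmp2 <- compare_groups(dat2, "value", "sensor"))
  expect_true(any(grepl("excluded", warns)))
  expect_equal(nrow(cmp2$group_sizes), 2)
  expect_error(suppressWarnings(
    compare_groups(tibble::tibble(sensor = c("a", "b"), value = c(1, 2)),
                   "value", "sensor")), "at least 2 groups")
})

test_that("the comparison holds its type-I error rate under the null", {
  set.seed(1234)
  n_sim <- 100
  null_p <- vapply(seq_len(n_sim), function(i) {
    dat <- tibble::tibble(sensor = rep(c("a", "b"), each = 12),
                          value = stats::rnorm(24))
    compare_groups(dat, "value", "sensor")$tukey$adj_p_value
  }, numeric(1))
  expect_gte(sum(null_p > 0.05), 94)
})
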