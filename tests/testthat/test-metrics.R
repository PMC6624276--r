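test_that("time to a target dead fraction is the first crossing frame", {
  expect_equal(time_to_fraction_dead(c(0, 0.2, 0.5, 0.9), 0.5,
                                     time_grid = c(0, 30, 90, 120)), 90)
  expect_equal(time_to_fraction_dead(c(0, 0.4, 0.5, 1), 0.5,
                                     time_grid = c(0, 5, 10, 15)), 10)
  kc <- killing_curve(make_experiment(rep(NA_real_, 5), movie_length = 20))
  expect_true(is.na(time_to_fraction_dead(kc)))
  expect_error(time_to_fraction_dead(c(0, 1), 0, time_grid = c(0, 5)), "0, 1")
  expect_error(time_to_fraction_dead(c(0, 1), 1.2, time_grid = c(0, 5)), "0, 1")
})

test_that("crossing time is non-decreasing in the target fraction", {
  ex <- simulate_experiment(sim_config(seed = 71))
  kc <- killing_curve(ex)
  ts <- vapply(c(0.1, 0.25, 0.5, 0.75, 0.9), function(f) {
    time_to_fraction_dead(kc, f)
  }, numeric(1))
  expect_true(all(diff(ts) >= 0))
})

test_that("decile spread is zero for identical rows and validates parameters", {
  ex <- rank_order_experiment(100)
  fm <- fate_matrix(ex, rank_and_bin(ex, n_bins = 10))
  same <- fm
  same[] <- rep(fm[1, ], each = 10)           # every bin a copy of bin 1
  expect_equal(decile_spread(same)$spread, 0, tolerance = 1e-9)
  expect_equal(decile_spread(same, window = 1, polyorder = 0)$spread, 0)
  expect_error(decile_spread(fm, window = 4), "odd")
  expect_error(decile_spread(fm, window = 3, polyorder = 3), "polyorder")
})

test_that("smoothing shrinks the spread of an outlier-contaminated profile", {
  crossing <- c(100, 105, 110, 115, 120, 125, 130, 135, 200, 145)
  fm <- matrix(0, 10, 61, dimnames = list(bin = 1:10, time_min = seq(0, 300, 5)))
  for (i in 1:10) fm[i, ] <- as.numeric(seq(0, 300, 5) >= crossing[i])
  fm <- structure(fm, class = c("fate_matrix", "matrix"),
                  time_grid = seq(0, 300, 5), bin_sizes = rep(10L, 10),
                  covariate_name = "x")
  sp <- decile_spread(fm, window = 5, polyorder = 2)
  expect_equal(sp$time_to_half_by_bin, crossing)
  expect_lt(sp$spread, max(crossing) - min(crossing))
  expect_gte(sp$spread, 0)
})

test_that("noise-free link spread recovers the programmed death-time range", {
  strength <- 200
  ex <- simulate_experiment(sim_config(seed = 72, link_shape = "continuous_negative",
                                       link_strength = strength,
                                       death_time_center = 150,
                                       death_time_noise_sd = 0))
  fm <- fate_matrix(ex, rank_and_bin(ex, n_bins = 10))
  sp <- decile_spread(fm)
  # decile medians span ~ strength * (0.95 - 0.05) of the quantile range;
  # allow one frame interval of slack on either side after smoothing
  expect_gt(sp$spread, strength * 0.9 - 2 * 5)
  expect_lt(sp$spread, strength + 2 * 5)
})

test_that("bins that never reach the target are excluded with a warning", {
  # top bin entirely censored
  dt <- c(rep(50, 90), rep(NA_real_, 10))
  ex <- make_experiment(dt, movie_length = 100)
  fm <- fate_matrix(ex, rank_and_bin(ex, n_bins = 10))
  expect_warning(sp <- decile_spread(fm), "never reach")
  expect_true(is.na(sp$time_to_half_by_bin[10]))
  expect_equal(sp$spread, 0, tolerance = 1e-9)
})

test_that("promoter statistics return mean and population-sd CV", {
  const <- make_experiment(rep(50, 5), fluor = rep(7, 5))
  expect_equal(promoter_statistics(const), list(mean = 7, cv = 0))
  four <- make_experiment(rep(50, 4), fluor = c(1, 2, 3, 4))
  ps <- promoter_statistics(four)
  expect_equal(ps$mean, 2.5)
  expect_equal(ps$cv, 0.447213595499958, tolerance = 1e-12)
  expect_equal(promoter_statistics(four, population_sd = FALSE)$cv,
               sd(1:4) / 2.5)
})

test_that("log-normal CV matches its closed form at large N", {
  sigma <- 0.4
  ex <- simulate_experiment(sim_config(seed = 73, n_positions = 40,
                                       fluor_log_sd = sigma))
  expect_equal(promoter_statistics(ex)$cv, sqrt(exp(sigma^2) - 1),
               tolerance = 0.05)
})

test_that("cross-promoter correlations handle degenerate and aligned inputs", {
  expect_error(cross_promoter_correlation(c(1, 2), c(1, 2)), "at least 3")
  flat <- cross_promoter_correlation(c(0.1, 0.2, 0.3), c(5, 5, 5))
  expect_true(is.na(flat$pearson) && is.na(flat$spearman))
  aligned <- cross_promoter_correlation(c(0.1, 0.5, 0.2, 0.9),
                                        c(10, 30, 15, 80))
  expect_equal(aligned$spearman, 1)
})

test_that("a panel with unlinked strength shows no information-expression correlation", {
  # 15 simulated promoters: link strength assigned to expression ranks by a
  # permutation whose correlation with them is exactly zero by construction
  perm <- c(2, 10, 5, 15, 7, 3, 14, 6, 13, 8, 12, 9, 1, 11, 4)
  strengths <- seq(0, 140, by = 10)[perm]
  log_means <- seq(log(100), log(2000), length.out = 15)
  peaks <- numeric(15)
  means <- numeric(15)
  for (i in 1:15) {
    ex <- simulate_experiment(sim_config(seed = 740 + i, n_positions = 2,
                                         link_strength = strengths[i],
                                         fluor_log_mean = log_means[i]))
    peaks[i] <- fate_information(ex)$trace$peak_bits
    means[i] <- promoter_statistics(ex)$mean
  }
  cc <- cross_promoter_correlation(peaks, means)
  expect_lt(abs(cc$pearson), 0.3)
  expect_lt(abs(cc$spearman), 0.3)
})
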