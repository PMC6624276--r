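test_that("binary entropy matches the closed form and rejects bad input", {
  expect_identical(binary_entropy(0.5), 1)
  expect_identical(binary_entropy(0), 0)
  expect_identical(binary_entropy(1), 0)
  expect_equal(binary_entropy(0.25), 0.811278124459132864, tolerance = 1e-15)
  expect_equal(binary_entropy(0.25), binary_entropy(0.75))  # symmetry
  expect_error(binary_entropy(-0.1), "0, 1")
  expect_error(binary_entropy(1.1), "0, 1")
  expect_error(binary_entropy(NA_real_), "0, 1")
})

test_that("the information statistic reproduces its limiting cases", {
  b <- equal_bins(100, 10)
  # five bins fully dead, five fully alive: the theoretical 1-bit maximum
  expect_identical(mi_at_time(states_from_counts(c(rep(10, 5), rep(0, 5)), 10), b), 1)
  # all alive or all dead: zero information
  expect_identical(mi_at_time(rep(FALSE, 100), b), 0)
  expect_identical(mi_at_time(rep(TRUE, 100), b), 0)
  # identical dead fraction in every bin: fate unrelated to the covariate
  expect_equal(mi_at_time(states_from_counts(rep(3, 10), 10), b), 0,
               tolerance = 1e-15)
})

test_that("the statistic matches a hand-evaluated mixed configuration", {
  b <- equal_bins(100, 10)
  st <- states_from_counts(c(10, 10, 10, 10, 10, 5, 0, 0, 0, 0), 10)
  # H(0.55) - (1/10) H(0.5), evaluated independently at high precision
  expect_equal(mi_at_time(st, b), 0.892774453987808294, tolerance = 1e-14)
  expect_equal(mi_oracle(st, b), 0.892774453987808294, tolerance = 1e-14)
})

test_that("the statistic equals plug-in joint-table MI for equal bins", {
  set.seed(77)
  for (rep in 1:200) {
    n_bins <- sample(c(2, 4, 5, 10), 1)
    size <- sample(c(5, 10, 20), 1)
    b <- equal_bins(n_bins * size, n_bins)
    st <- states_from_counts(sample(0:size, n_bins, replace = TRUE), size)
    expect_lt(abs(mi_at_time(st, b) - mi_oracle(st, b)), 1e-12)
  }
})

test_that("unequal bins expose the unweighted-average definition", {
  # 2 cells in bin 1, 8 in bin 2: unweighted conditional entropy differs from
  # the count-weighted one, so the two estimators legitimately disagree
  bin <- c(1L, 1L, rep(2L, 8))
  names(bin) <- sprintf("c%04d", 1:10)
  b <- structure(list(n_bins = 2L, bin = bin, covariate_name = "x",
                      sizes = c(2L, 8L)),
                 class = "bin_assignment")
  st <- stats::setNames(c(TRUE, TRUE, rep(c(TRUE, FALSE), c(2, 6))), names(bin))
  unweighted <- binary_entropy(0.4) -
    mean(c(binary_entropy(1), binary_entropy(0.25)))
  expect_equal(mi_at_time(st, b), unweighted, tolerance = 1e-14)
  expect_false(isTRUE(all.equal(mi_at_time(st, b), mi_oracle(st, b),
                                tolerance = 1e-6)))
})

test_that("the statistic is symmetric under alive/dead relabeling", {
  set.seed(78)
  b <- equal_bins(100, 10)
  for (rep in 1:20) {
    st <- states_from_counts(sample(0:10, 10, replace = TRUE), 10)
    expect_equal(mi_at_time(st, b), mi_at_time(!st, b), tolerance = 1e-14)
    expect_equal(mi_oracle(st, b), mi_oracle(!st, b), tolerance = 1e-14)
  }
})

test_that("rank-order death yields the parabolic arc peaking at 1 bit at half-death", {
  ex <- rank_order_experiment(100)
  tr <- information_trace(ex, rank_and_bin(ex, n_bins = 10))
  expect_identical(tr$peak_bits, 1)
  expect_equal(tr$peak_time, 250)                  # 50 of 100 cells dead
  expect_identical(tr$info_bits[1], 0)             # all alive
  expect_identical(tr$info_bits[101], 0)           # all dead
  # at every frame where whole deciles have died (k*10 cells dead) the bins
  # are pure and the statistic equals the binary entropy of the dead fraction:
  # the arc rises to 1 bit at half-death and falls back symmetrically
  at_full <- 1 + 10 * (0:10)
  expect_equal(tr$info_bits[at_full], binary_entropy((0:10) / 10),
               tolerance = 1e-14)
  expect_true(all(diff(tr$info_bits[at_full][1:6]) > 0))       # rise
  expect_true(all(diff(tr$info_bits[at_full][6:11]) < 0))      # fall
  # between those frames the partially-dead bin subtracts conditional
  # entropy, so the trace carries a sawtooth on the arc but stays in bounds
  expect_true(all(tr$info_bits <= binary_entropy(seq(0, 1, 0.01)) + 1e-12))
  # symmetry of the arc: k dead mirrors N - k dead
  expect_equal(tr$info_bits, rev(tr$info_bits), tolerance = 1e-12)
})

test_that("the trace depends on fluorescence only through bin membership", {
  ex <- simulate_experiment(sim_config(seed = 51))
  tr1 <- information_trace(ex, rank_and_bin(ex, n_bins = 10))
  ex2 <- ex
  ex2$cells$initial_fluorescence <- sqrt(ex2$cells$initial_fluorescence)
  tr2 <- information_trace(ex2, rank_and_bin(ex2, n_bins = 10))
  expect_equal(tr1$info_bits, tr2$info_bits)
})

test_that("peak ties resolve to the earliest frame", {
  # two cells, one dies at t=5: trace is 0 at t=0 then constant; the peak
  # value recurs at every later frame and must be reported at its first frame
  ex <- make_experiment(c(5, NA), movie_length = 20)
  tr <- information_trace(ex, rank_and_bin(ex, n_bins = 2))
  expect_equal(tr$peak_time, 5)
})

test_that("information bounds hold across random simulated experiments", {
  for (seed in 52:54) {
    ex <- simulate_experiment(sim_config(seed = seed, death_time_noise_sd = 40))
    bins <- rank_and_bin(ex, n_bins = 10)
    tr <- information_trace(ex, bins)
    expect_true(all(tr$info_bits >= 0))
    kc <- killing_curve(ex)
    expect_true(all(tr$info_bits <= binary_entropy(kc$dead_fraction) + 1e-12))
    expect_true(all(tr$info_bits <= 1))
    expect_equal(tr$peak_bits, max(tr$info_bits))
  }
})

test_that("single-bin traces carry no information; per-cell bins recover 1 bit", {
  ex <- rank_order_experiment(100)
  tr1 <- information_trace(ex, rank_and_bin(ex, n_bins = 1))
  expect_equal(tr1$info_bits, rep(0, 101))
  trN <- information_trace(ex, rank_and_bin(ex, n_bins = 100))
  expect_identical(trN$peak_bits, 1)
  expect_equal(trN$peak_time, 250)
})

test_that("bin-count choice does not change strong-vs-null ordering", {
  strong <- simulate_experiment(sim_config(seed = 55))
  null_ex <- simulate_experiment(sim_config(seed = 55, link_shape = "none"))
  bs_strong <- bin_sensitivity(strong, c(5, 10, 20))
  bs_null <- bin_sensitivity(null_ex, c(5, 10, 20))
  expect_true(all(bs_strong$peak_bits > bs_null$peak_bits))
})

test_that("fluorescence-independent covariates carry signal only when coupled", {
  ex <- simulate_experiment(sim_config(seed = 56, link_shape = "none",
                                       growth_death_coupling = 120,
                                       size_death_coupling = 0,
                                       death_time_noise_sd = 20))
  pt_growth <- permutation_test(ex, covariate = "growth_rate", seed = 3)
  expect_true(pt_growth$exceeds_null)
  pt_size <- permutation_test(ex, covariate = "initial_size", seed = 3)
  expect_false(pt_size$exceeds_null)
  # fate_information on a covariate equals trace on that covariate's bins
  fit <- fate_information(ex, covariate = "growth_rate")
  expect_equal(fit$trace$info_bits,
               information_trace(ex, rank_and_bin(ex, "growth_rate"))$info_bits)
})
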