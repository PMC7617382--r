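test_that("metropolis acceptance follows min(1, exp(-dE/T))", {
  # single spin with h: flipping off->on has dE = -2h; with h = -0.5, the
  # uphill move (to +1) has dE = 1 and acceptance exp(-1)
  m <- independent_model(-0.5)
  w <- mcmc_walk(m, n_steps = 2e5, burn_in = 1000, seed = 4)
  # stationary occupancy of +1 is the two-state Boltzmann weight
  p_up <- exp(-0.5) / (exp(-0.5) + exp(0.5))
  frac <- mean(index_to_state(w$states, 1, "pm1") == 1)
  expect_lt(abs(frac - p_up), 4 * sqrt(p_up * (1 - p_up) / 2e4))
  # downhill (and flat) proposals always accepted: zero model accepts all
  w0 <- mcmc_walk(independent_model(rep(0, 4)), n_steps = 1e4, burn_in = 0,
                  seed = 1)
  expect_equal(w0$acceptance_rate, 1)
})

test_that("long walks reproduce the enumerated distribution", {
  gt <- make_ground_truth(6, coupling_scale = 0.4, seed = 5)
  w <- mcmc_walk(gt$model, n_steps = 3e5, burn_in = 10000, seed = 6)
  emp <- tabulate(w$states + 1L, nbins = 64) / length(w$states)
  p <- state_distribution(gt$model)
  expect_lt(max(abs(emp - p)), 0.01)
  # bit-reproducibility with the same seed
  w2 <- mcmc_walk(gt$model, n_steps = 1000, burn_in = 100, seed = 9)
  w3 <- mcmc_walk(gt$model, n_steps = 1000, burn_in = 100, seed = 9)
  expect_identical(w2$states, w3$states)
  expect_false(identical(w2$states,
                         mcmc_walk(gt$model, 1000, burn_in = 100,
                                   seed = 10)$states))
})

test_that("detailed balance holds empirically for hamming-1 pairs", {
  m <- random_model(4, seed = 44)
  w <- mcmc_walk(m, n_steps = 4e5, burn_in = 10000, seed = 3)
  p <- state_distribution(m)
  s <- w$states
  trans <- table(factor(s[-length(s)], levels = 0:15),
                 factor(s[-1], levels = 0:15))
  n_from <- rowSums(trans)
  viol <- 0; checked <- 0
  for (a in 0:15) for (j in 0:3) {
    b <- bitwXor(a, bitwShiftL(1L, j))
    if (b < a || n_from[a + 1] < 500 || n_from[b + 1] < 500) next
    flow_ab <- (n_from[a + 1] / length(s)) * (trans[a + 1, b + 1] / n_from[a + 1])
    flow_ba <- (n_from[b + 1] / length(s)) * (trans[b + 1, a + 1] / n_from[b + 1])
    se <- sqrt(flow_ab + flow_ba) / sqrt(length(s))
    checked <- checked + 1
    if (abs(flow_ab - flow_ba) > 5 * pmax(se, 1e-4)) viol <- viol + 1
  }
  expect_gt(checked, 10)
  expect_lte(viol / checked, 0.05)
})

test_that("basin trajectories and transition statistics count correctly", {
  # hand case: labels A A B B A
  st <- transition_stats(c("A", "A", "B", "B", "A"))
  expect_equal(st$freq["A", "B"], 1)
  expect_equal(st$freq["B", "A"], 1)
  expect_equal(st$dwell_times$A, c(2, 1))
  expect_equal(st$dwell_times$B, 2)
  expect_equal(unname(st$dwell_mean), c(1.5, 2))
  # total dwell equals series length
  expect_equal(sum(unlist(st$dwell_times)), 5)
  # constant series: no transitions, flagged normalizations
  st0 <- transition_stats(rep("A", 10))
  expect_equal(sum(st0$freq), 0)
  expect_true(all(is.na(st0$p_out)))
  # reversing time transposes the count matrix
  lab <- c(1, 1, 2, 3, 3, 2, 1, 2)
  expect_equal(transition_stats(rev(lab))$freq, t(transition_stats(lab)$freq))
  # p_out rows sum to one where defined
  expect_equal(unname(rowSums(transition_stats(lab)$p_out)), c(1, 1, 1))
})

test_that("raster time points map to the basins of their states", {
  m <- random_model(5, seed = 17)
  ls <- energy_landscape(m)
  # a raster pinned at a minimum state yields a constant label series
  s_min <- index_to_state(rep(ls$minima[1], 7), 5, "pm1")
  lab <- basin_trajectory(binary_raster(s_min, "pm1"), ls)
  expect_equal(lab, rep(ls$minima[1], 7))
  # generic: labels equal the landscape lookup of the state indices
  r <- simulate(m, 200, seed = 2)
  expect_equal(basin_trajectory(r, ls),
               ls$basin_of_state[state_index(r$states, "pm1") + 1L])
})

test_that("two independent chains agree on basin transition structure", {
  gt <- make_ground_truth(10, coupling_scale = 0.4, seed = 12)
  ls <- energy_landscape(gt$model)
  skip_if(length(ls$minima) < 2)  # needs a multi-basin landscape
  w1 <- mcmc_walk(gt$model, n_steps = 3e5, burn_in = 30000, seed = 21)
  w2 <- mcmc_walk(gt$model, n_steps = 3e5, burn_in = 30000, seed = 22)
  bs <- ls$minima
  s1 <- transition_stats(basin_trajectory(w1, ls), bs)
  s2 <- transition_stats(basin_trajectory(w2, ls), bs)
  cmp <- compare_transitions(s1, s2)
  expect_true(cmp$reliable)
  expect_gt(cmp$r_squared, 0.8)
  # identical inputs give the identity regression
  self <- compare_transitions(s1, s1)
  expect_equal(self$slope, 1)
  expect_equal(self$r_squared, 1)
})

test_that("dwell-size regression recovers planted exponential coefficients", {
  # fabricate stats/landscape with an exact exponential dwell-size law
  sizes <- c(0.1, 0.2, 0.3, 0.4)
  a <- 0.5; b <- 6
  fake_ls <- structure(list(minima = c(0L, 1L, 2L, 3L),
                            basin_sizes = stats::setNames(sizes, 0:3)),
                       class = "mem_landscape")
  fake_st <- structure(list(basin_set = c(0L, 1L, 2L, 3L),
                            visits = rep(5L, 4),
                            dwell_mean = exp(a + b * sizes)),
                       class = "transition_stats")
  fit <- dwell_size_relation(fake_st, fake_ls)
  expect_true(fit$reliable)
  expect_equal(fit$slope, b, tolerance = 1e-8)
  expect_equal(fit$intercept, a, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1)
  # on a real walk the dominant basin has the maximal mean dwell
  gt <- make_ground_truth(8, coupling_scale = 0.45, seed = 3)
  ls <- energy_landscape(gt$model)
  skip_if(length(ls$minima) < 2)
  w <- mcmc_walk(gt$model, n_steps = 2e5, burn_in = 10000, seed = 8)
  st <- transition_stats(basin_trajectory(w, ls), ls$minima)
  big <- which.max(ls$basin_sizes)
  expect_equal(which.max(st$dwell_mean), big)
})
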