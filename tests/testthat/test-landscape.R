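test_that("local minima match closed-form and brute-force expectations", {
  # independent negative fields: unique minimum = all-off
  m <- independent_model(rep(-1, 6))
  ls <- energy_landscape(m)
  expect_equal(ls$minima, 0L)
  expect_equal(unname(ls$basin_sizes), 1)
  expect_true(all(ls$basin_of_state == 0L))
  # all-pair ferromagnet: exactly two minima, all-off and all-on
  f <- ferromagnet(6, 0.4)
  lf <- energy_landscape(f)
  expect_setequal(lf$minima, c(0L, 63L))
  # flat landscape: no strict minima, flagged
  expect_warning(l0 <- energy_landscape(independent_model(rep(0, 4))),
                 "flat")
  expect_true(l0$flat)
  expect_length(l0$minima, 0)
})

test_that("basins partition the state space deterministically", {
  for (seed in c(3, 14, 15)) {
    m <- random_model(7, seed = seed)
    ls <- energy_landscape(m)
    expect_false(ls$flat)
    # every state labeled, labels are minima, each minimum maps to itself
    expect_false(anyNA(ls$basin_of_state))
    expect_true(all(ls$basin_of_state %in% ls$minima))
    expect_equal(ls$basin_of_state[ls$minima + 1L], ls$minima)
    expect_equal(sum(ls$basin_sizes), 1)
    # descending by steepest descent: every non-minimum state's basin equals
    # its steepest neighbor's basin
    expect_identical(energy_landscape(m)$basin_of_state, ls$basin_of_state)
  }
  # odd-N ferromagnet: no ties, perfectly symmetric halves
  lf <- energy_landscape(ferromagnet(7, 0.4))
  expect_equal(unname(lf$basin_sizes), c(0.5, 0.5))
  # even-N ferromagnet: every state off the zero-magnetization ridge falls
  # to the minimum on its own side; ridge states are still all assigned
  lf6 <- energy_landscape(ferromagnet(6, 0.4))
  expect_setequal(lf6$minima, c(0L, 63L))
  M <- rowSums(all_states(6, "pm1"))
  expect_true(all(lf6$basin_of_state[M < 0] == 0L))
  expect_true(all(lf6$basin_of_state[M > 0] == 63L))
  expect_true(all(lf6$basin_of_state[M == 0] %in% c(0L, 63L)))
  expect_equal(sum(lf6$basin_sizes), 1)
})

test_that("two-spin double well has the hand-computed saddle and barriers", {
  m <- mem_model(c(0, 0), matrix(c(0, 1, 1, 0), 2), "pm1")
  ls <- energy_landscape(m)
  expect_setequal(ls$minima, c(0L, 3L))   # (-1,-1) and (+1,+1), E = -1
  expect_equal(unname(ls$minima_energies), c(-1, -1))
  dg <- disconnectivity(ls)
  expect_equal(dg$saddle_energy[1, 2], 1)  # mixed states at E = +1
  expect_equal(dg$barrier_sym[1, 2], 2)
  expect_equal(dg$barrier_asym[1, 2], dg$barrier_asym[2, 1])
})

test_that("saddle energies equal the independent minimax-path oracle", {
  skip_if_not_installed("igraph")
  n_checked <- 0
  for (seed in 1:20) {
    n <- sample(c(5, 6, 7, 8), 1)
    m <- random_model(n, seed = 1000 + seed)
    ls <- energy_landscape(m)
    if (length(ls$minima) < 2) next
    dg <- disconnectivity(ls)
    or <- saddle_oracle(m)
    expect_equal(or$minima, dg$minima)
    expect_equal(unname(dg$saddle_energy), unname(or$saddle),
                 tolerance = 1e-12)
    # saddles never below either minimum; deeper side has the larger barrier
    k <- length(dg$minima)
    for (x in 1:(k - 1)) for (y in (x + 1):k) {
      expect_gte(dg$saddle_energy[x, y],
                 max(dg$minima_energies[c(x, y)]))
      expect_equal(dg$barrier_sym[x, y],
                   min(dg$barrier_asym[x, y], dg$barrier_asym[y, x]))
      # the barrier out of the deeper minimum is the larger of the two
      d <- if (dg$minima_energies[x] <= dg$minima_energies[y]) c(x, y) else c(y, x)
      expect_gte(dg$barrier_asym[d[1], d[2]] + 1e-12,
                 dg$barrier_asym[d[2], d[1]])
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 10)
})

test_that("disconnectivity handles the single-minimum case and builds a tree", {
  ls <- energy_landscape(independent_model(rep(-1, 4)))
  dg <- disconnectivity(ls)
  expect_true(all(is.na(dg$saddle_energy)))
  expect_equal(dg$merge_tree$minimum, 0L)
  # ferromagnet tree: one merge node joining the two leaves at the saddle
  lf <- energy_landscape(ferromagnet(5, 0.4))
  df <- disconnectivity(lf)
  expect_named(df$merge_tree, c("energy", "children"))
  expect_equal(df$merge_tree$energy, df$saddle_energy[1, 2])
  leaves <- sapply(df$merge_tree$children, function(ch) ch$minimum)
  expect_setequal(leaves, lf$minima)
})

test_that("landscape summary table is consistent with its inputs", {
  m <- random_model(6, seed = 33)
  ls <- energy_landscape(m)
  dg <- disconnectivity(ls)
  tab <- landscape_summary(ls, dg)
  expect_equal(nrow(tab), length(ls$minima))
  expect_equal(sum(tab$basin_size), 1)
  S <- index_to_state(tab$minimum, 6, m$convention)
  expect_equal(tab$energy, energy(m, S))
})
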