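test_that("exact observables match independent-spin closed forms", {
  # J = 0: C(T) = sum (h_i/T)^2 sech^2(h_i/T)
  h <- c(-0.5, 0.3, -0.8, 0.6)
  m <- independent_model(h)
  for (Tt in c(0.3, 0.7, 1, 1.9)) {
    ob <- observables_exact(m, Tt)
    expect_equal(ob$C, sum((h / Tt)^2 / cosh(h / Tt)^2), tolerance = 1e-10)
  }
  # h = 0, J = 0 in pm1: chi = N/T exactly, C = 0
  z <- independent_model(rep(0, 5))
  ob <- observables_exact(z, 0.5)
  expect_equal(ob$chi, 5 / 0.5, tolerance = 1e-12)
  expect_equal(ob$C, 0, tolerance = 1e-12)
  expect_error(observables_exact(z, -1), "positive")
})

test_that("fluctuation-dissipation: C equals the temperature derivative of <E>", {
  m <- random_model(6, seed = 41)
  Ts <- seq(0.4, 2, by = 0.002)
  mE <- vapply(Ts, function(Tt) observables_exact(m, Tt)$mean_E, 0.0)
  dEdT <- diff(mE) / diff(Ts)
  Tm <- (Ts[-1] + Ts[-length(Ts)]) / 2
  C <- vapply(Tm, function(Tt) observables_exact(m, Tt)$C, 0.0)
  expect_lt(max(abs(dEdT - C) / pmax(C, 0.05)), 0.01)
})

test_that("specific heat is convention-invariant; susceptibility rescales by 4", {
  m <- random_model(5, seed = 42)
  m01 <- convert_convention(m, "01")
  for (Tt in c(0.5, 1, 1.5)) {
    a <- observables_exact(m, Tt)
    b <- observables_exact(m01, Tt)
    expect_equal(a$C, b$C, tolerance = 1e-10)
    # M_01 = (M_pm + N)/2, so var shrinks by 4
    expect_equal(b$chi, a$chi / 4, tolerance = 1e-10)
  }
})

test_that("annealed sweeps converge to the exact curves", {
  gt <- make_ground_truth(8, coupling_scale = 0.4, seed = 31,
                          convention = "01")
  grid <- seq(2, 0.2, by = -0.1)
  ex <- thermo_exact(gt$model, grid)
  sw <- annealed_sweep(gt$model, grid, n_steps = 1.5e5, burn_in = 5000,
                       thin = 15, seed = 32)
  keep <- grid >= 0.4
  dev_C <- abs(sw$C - ex$C)[keep] / pmax(sw$C_se[keep], 1e-6)
  dev_chi <- abs(sw$chi - ex$chi)[keep] / pmax(sw$chi_se[keep], 1e-6)
  expect_true(all(dev_C < 3))
  expect_true(all(dev_chi < 3))
  # fixed seed reproducibility
  sw2 <- annealed_sweep(gt$model, grid, n_steps = 1e4, burn_in = 1000,
                        thin = 5, seed = 33)
  sw3 <- annealed_sweep(gt$model, grid, n_steps = 1e4, burn_in = 1000,
                        thin = 5, seed = 33)
  expect_identical(sw2$C, sw3$C)
  # T = 0 is excluded with a warning
  expect_warning(thermo_exact(gt$model, c(1, 0.5, 0)), "excluded")
})

test_that("uniform 0/1 ferromagnet shows bistable brainwide on/off at low T", {
  f <- convert_convention(ferromagnet(8, 0.25), "01")
  w_hot <- mcmc_walk(f, n_steps = 4e4, burn_in = 5000, temperature = 3,
                     seed = 1)
  w_cold <- mcmc_walk(f, n_steps = 4e4, burn_in = 5000, temperature = 0.4,
                      seed = 2)
  act_hot <- w_hot$magnetization / 8
  act_cold <- w_cold$magnetization / 8
  # high T: activation hovers at intermediate levels; low T: episodes of
  # near-complete activation or silence dominate
  expect_gt(mean(act_hot > 0.2 & act_hot < 0.8), 0.55)
  expect_gt(mean(act_cold < 0.1 | act_cold > 0.9), 0.9)
})

test_that("transition location handles triangular, flat and parabolic curves", {
  mk_curve <- function(Tv, Cv) {
    memland:::new_thermo_curve(Tv, Cv, chi = Cv, M_mean = Cv,
                               method = "exact", convention = "pm1",
                               n_units = 2)
  }
  # symmetric triangle peaking at T = 1, half-max crossings at 0.5, 1.5
  Tv <- seq(0, 2, by = 0.05)
  Cv <- pmax(1 - abs(Tv - 1), 0)
  suppressWarnings(tr <- locate_transition(mk_curve(Tv[Tv > 0], Cv[Tv > 0]),
                                           refine = FALSE))
  expect_equal(tr$Tc, 1)
  expect_equal(tr$fwhm, 1, tolerance = 1e-10)
  # constant curve flagged as boundary
  flat <- locate_transition(mk_curve(seq(0.1, 2, 0.1), rep(1, 20)))
  expect_true(flat$boundary)
  expect_true(is.na(flat$fwhm))
  # quadratic refinement recovers an off-grid parabola vertex
  Tv <- seq(0.1, 2, by = 0.1)
  Cv <- 2 - (Tv - 1.03)^2
  tr2 <- locate_transition(mk_curve(Tv, Cv))
  expect_equal(tr2$Tc, 1.03, tolerance = 1e-3)
})

test_that("virtual resection removes a region's couplings and observables", {
  # null resection: J = 0 model, removing any region leaves Tc unchanged
  m0 <- independent_model(rep(-0.6, 6))
  grid <- seq(2, 0.05, by = -0.05)
  r <- virtual_resection(m0, 3, grid)
  expect_equal(r$delta_Tc, 0, tolerance = 1e-10)
  expect_equal(r$strength, 0)
  # the resected curve equals the reduced model's curve exactly
  red <- independent_model(rep(-0.6, 5))
  expect_equal(r$curve$C, thermo_exact(red, grid)$C, tolerance = 1e-12)
  # uniform 0/1 ferromagnet: identical delta_Tc for every region, and
  # removing couplings shifts the peak to lower temperature
  n <- 8
  Jf <- matrix(0.5, n, n); diag(Jf) <- 0
  f <- mem_model(rep(-1, n), Jf, "01")
  scan <- resection_scan(f, grid)
  expect_equal(length(scan$results), 8)
  expect_lt(diff(range(scan$table$delta_Tc)), 1e-10)
  expect_lt(scan$table$delta_Tc[1], 0)
})

test_that("a planted hub dominates the resection ranking", {
  # region 1 strongly coupled to all others; the rest weakly coupled
  n <- 8
  J <- matrix(0.3, n, n)
  J[1, ] <- J[, 1] <- 0.8
  diag(J) <- 0
  m <- mem_model(rep(-1.5, n), J, "01")
  grid <- seq(2, 0.1, by = -0.05)
  scan <- resection_scan(m, grid)
  expect_equal(which.max(abs(scan$table$delta_Tc)), 1)
  expect_equal(which.max(scan$table$strength), 1)
  # strength ranking is mirrored by the resection effect ranking
  expect_gt(abs(scan$table$delta_Tc[1]), max(abs(scan$table$delta_Tc[-1])))
})
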