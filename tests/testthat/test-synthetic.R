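test_that("ground truth generation honors its invariants and determinism", {
  gt <- make_ground_truth(12, coupling_scale = 0.3, structure_noise = 0,
                          seed = 1)
  J <- gt$model$J
  expect_equal(J, t(J))
  expect_equal(unname(diag(J)), rep(0, 12))
  expect_true(any(J[upper.tri(J)] > 0) && any(J[upper.tri(J)] < 0))
  s <- gt$structural
  expect_equal(s, t(s))
  expect_true(all(s >= 0))
  expect_equal(unname(diag(s)), rep(0, 12))
  # zero noise: structural exactly proportional to |J| (Spearman 1 on edges)
  ut <- upper.tri(J)
  nz <- abs(J[ut]) > 0
  expect_equal(s[ut], gt$structural_scale * abs(J[ut]))
  expect_equal(cor(s[ut][nz], abs(J[ut][nz]), method = "spearman"), 1)
  # determinism contract
  expect_identical(make_ground_truth(12, seed = 5),
                   make_ground_truth(12, seed = 5))
  expect_false(identical(make_ground_truth(12, seed = 5)$model$J,
                         make_ground_truth(12, seed = 6)$model$J))
  # two regions leave exactly one free coupling
  g2 <- make_ground_truth(2, seed = 1, density = 1)
  expect_equal(g2$model$J[1, 2], g2$model$J[2, 1])
  expect_error(make_ground_truth(1), "at least 2")
})

test_that("exact sampling reproduces closed-form and enumerated moments", {
  # fair independent spins: means ~ 0 within 3/sqrt(n)
  z <- independent_model(rep(0, 6))
  n <- 4e4
  r <- sample_states(z, n, seed = 2)
  expect_true(all(abs(colMeans(r$states)) < 3 / sqrt(n)))
  # single spin, h = 1: fraction of +1 ~ e/(e + 1/e) within 3 binomial SE
  m1 <- independent_model(1)
  p <- exp(1) / (exp(1) + exp(-1))
  r1 <- sample_states(m1, n, seed = 3)
  expect_lt(abs(mean(r1$states == 1) - p), 3 * sqrt(p * (1 - p) / n))
  # empty request
  expect_equal(dim(sample_states(z, 0, seed = 1)), c(0L, 6L))
  # moment consistency vs enumeration: >= 99% of entries within 4 SE
  within <- total <- 0
  for (seed in 1:3) {
    gt <- make_ground_truth(8, coupling_scale = 0.35, seed = seed)
    mm <- model_moments(gt$model)
    n <- 2e4
    r <- sample_states(gt, n, seed = seed + 100)
    em <- empirical_moments(r)
    se_m <- sqrt(pmax(1 - mm$means^2, 1e-12) / n)
    ut <- upper.tri(mm$second_moments)
    se_s <- sqrt(pmax(1 - mm$second_moments[ut]^2, 1e-12) / n)
    dev <- c(abs(em$means - mm$means) / se_m,
             abs(em$second_moments[ut] - mm$second_moments[ut]) / se_s)
    within <- within + sum(dev < 4)
    total <- total + length(dev)
  }
  expect_gte(within / total, 0.99)
})

test_that("metropolis sampling agrees with exact sampling on the same model", {
  gt <- make_ground_truth(8, coupling_scale = 0.35, seed = 7)
  n <- 2e4
  re <- sample_states(gt, n, method = "exact_enumeration", seed = 1)
  rm_ <- sample_states(gt, n, method = "metropolis", seed = 2, thin = 20)
  me <- empirical_moments(re)$means
  mm <- empirical_moments(rm_)$means
  # combined Monte-Carlo error; metropolis samples thinned to near-independence
  se <- sqrt((1 - me^2) / n) + sqrt((1 - mm^2) / n)
  expect_true(all(abs(me - mm) < 5 * pmax(se, 1e-3)))
  expect_error(sample_states(make_ground_truth(21, seed = 1), 5,
                             method = "exact_enumeration"), "N <= 20")
})

test_that("trace emulation round-trips states at high SNR", {
  gt <- make_ground_truth(6, coupling_scale = 0.4, seed = 2)
  states <- sample_states(gt, 500, seed = 4)
  rec <- states_to_traces(states, neurons_per_region = 5, snr = 100,
                          seed = 9, ground_truth = gt)
  expect_equal(length(rec$region_of_neuron), 30)
  expect_true(all(table(rec$region_of_neuron) == 5))
  # region-average trace, z-scored, thresholded at 0 recovers the states
  avg <- rowsum(rec$traces, rec$region_of_neuron) / 5
  raster <- binarize(avg, threshold_z = 0, convention = states$convention)
  expect_gte(mean(raster$states == states$states), 0.99)
  # one neuron per region: region average equals the single trace
  rec1 <- states_to_traces(states, neurons_per_region = 1, snr = 10, seed = 9)
  expect_equal(rowsum(rec1$traces, rec1$region_of_neuron), rec1$traces,
               ignore_attr = TRUE)
  # determinism
  expect_identical(states_to_traces(states, 5, snr = 10, seed = 3)$traces,
                   states_to_traces(states, 5, snr = 10, seed = 3)$traces)
})

test_that("recordings round-trip exactly through plain-text files", {
  gt <- make_ground_truth(4, coupling_scale = 0.5, structure_noise = 0.1,
                          seed = 3)
  states <- sample_states(gt, 40, seed = 1)
  rec <- states_to_traces(states, neurons_per_region = 3, snr = 5, seed = 2,
                          ground_truth = gt)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rec")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$traces, rec$traces)
  expect_identical(back$neuron_positions, rec$neuron_positions)
  expect_identical(back$region_of_neuron, rec$region_of_neuron)
  expect_identical(back$states_true$states, rec$states_true$states)
  # JSON parameters preserve full float precision
  expect_identical(back$ground_truth$model$h, rec$ground_truth$model$h)
  expect_identical(back$ground_truth$model$J, rec$ground_truth$model$J)
  expect_identical(back$ground_truth$structural, rec$ground_truth$structural)
  # missing parent directory is an I/O error
  expect_error(write_recording(rec, file.path(dir, "no", "such", "dir")),
               "does not exist")
})

test_that("noiseless structural matrix is perfectly detectable from |J|", {
  gt <- make_ground_truth(10, coupling_scale = 0.3, structure_noise = 0,
                          seed = 4)
  sf <- structure_function(abs(gt$model$J), gt$structural,
                           thresholds = c(0.01, 0.3))
  expect_equal(unname(sf$auc_by_threshold), c(1, 1))
  # added structural noise lowers the AUC below 1
  gtn <- make_ground_truth(10, coupling_scale = 0.3, structure_noise = 0.3,
                           seed = 4)
  sfn <- structure_function(abs(gtn$model$J), gtn$structural,
                            thresholds = 0.3)
  expect_lt(unname(sfn$auc_by_threshold[1]), 1)
})
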