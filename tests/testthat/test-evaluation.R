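test_that("state probability comparison is normalized and self-consistent", {
  gt <- make_ground_truth(8, coupling_scale = 0.4, seed = 6)
  r <- sample_states(gt, 5e4, seed = 7)
  tab <- state_probability_comparison(r, gt$model)
  expect_equal(sum(tab$empirical_p), 1, tolerance = 1e-12)
  expect_equal(sum(tab$model_p), 1, tolerance = 1e-12)
  # log-log agreement on observed states: slope ~ 1, high R^2
  obs <- tab$empirical_p > 5 / nrow(r$states)
  fit <- lm(log(empirical_p) ~ log(model_p), data = tab[obs, ])
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)
  expect_gt(summary(fit)$r.squared, 0.95)
  # single repeated state
  one <- binary_raster(matrix(1, 5, 8), "pm1")
  t1 <- state_probability_comparison(one, gt$model)
  expect_equal(t1$empirical_p[t1$state == 2^8 - 1], 1)
  expect_equal(sum(t1$empirical_p), 1)
  expect_equal(t1$n_active[t1$state == 2^8 - 1], 8)
})

test_that("multi-information approaches 1 for data from a pairwise model", {
  gt <- make_ground_truth(8, coupling_scale = 0.5, seed = 9)
  r <- sample_states(gt, 5e4, seed = 10)
  fit <- fit_mem(r, method = "exact")
  mi <- multi_information(r, fit)
  expect_true(mi$r_defined)
  expect_gt(mi$r, 0.93)
  expect_gte(mi$IN, 0)
  # maximum-entropy ordering: the pairwise model entropy never exceeds the
  # independent model entropy
  expect_lte(mi$S2, mi$S1 + 1e-12)
})

test_that("independent data flags the multi-information fraction undefined", {
  m0 <- independent_model(runif(8, -1, 0))
  r <- simulate(m0, nsim = 2e4, seed = 11)
  fit <- fit_mem(r, method = "exact")
  mi <- multi_information(r, fit)
  expect_false(mi$r_defined)
  expect_true(is.na(mi$r))
  # small-sample warning fires below 10 * 2^N samples
  expect_warning(multi_information(simulate(m0, 100, seed = 1), fit),
                 "biased")
})

test_that("structure-function AUC behaves at its extremes and under scaling", {
  gt <- make_ground_truth(10, coupling_scale = 0.3, structure_noise = 0,
                          seed = 13)
  sf <- structure_function(abs(gt$model$J), gt$structural)
  expect_equal(unname(sf$auc_by_threshold), c(1, 1))
  # scaling the structural matrix leaves ranks, hence AUC, unchanged
  sf10 <- structure_function(abs(gt$model$J), gt$structural * 10)
  expect_equal(sf$auc_by_threshold, sf10$auc_by_threshold)
  # ROC curves are monotone nondecreasing
  roc <- sf$roc_curves[[1]]
  expect_true(all(diff(roc$FPR) >= 0))
  expect_true(all(diff(roc$TPR) >= 0))
  # permuted structural gives chance-level AUC (permutation interval)
  set.seed(14)
  J <- abs(gt$model$J)
  ut <- upper.tri(J)
  aucs <- replicate(200, {
    sp <- matrix(0, 10, 10)
    sp[ut] <- sample(gt$structural[ut])
    sp <- sp + t(sp)
    unname(structure_function(J, sp, thresholds = 0.3)$auc_by_threshold)
  })
  expect_gt(mean(aucs), quantile(aucs, 0.025))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # degenerate threshold: all edges one class -> flagged NA
  flat <- matrix(1, 10, 10); diag(flat) <- 0
  expect_true(is.na(structure_function(J, flat,
                                       thresholds = 2)$auc_by_threshold[1]))
})

test_that("rank-sum AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  scores <- rnorm(60)
  labels <- runif(60) < plogis(scores)
  skip_if(all(labels) || !any(labels))
  ours <- memland:::auc_rank(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("split-half fits are strongly correlated on large synthetic data", {
  gt <- make_ground_truth(8, coupling_scale = 0.4, seed = 16)
  r <- sample_states(gt, 4e4, seed = 17)
  sh <- split_half(r, seed = 18)
  expect_gt(sh$corr_J, 0.9)
  expect_gt(sh$corr_h, 0.9)
  expect_gt(sh$corr_state_p, 0.95)
  # duplicated halves, split so A = B by construction: correlations = 1
  dup <- binary_raster(rbind(r$states[1:500, ], r$states[1:500, ]), "pm1")
  shd <- split_half(dup, index_a = 1:500)
  expect_equal(shd$corr_J, 1, tolerance = 1e-6)
  expect_equal(shd$corr_h, 1, tolerance = 1e-6)
  expect_equal(shd$corr_state_p, 1, tolerance = 1e-6)
  # seed-reproducible split
  expect_identical(split_half(r, seed = 20)$index_A,
                   split_half(r, seed = 20)$index_A)
  expect_error(split_half(binary_raster(matrix(1, 2, 2), "pm1")), "at least 4")
})

test_that("resolution scan peaks at the planted cluster number", {
  gt <- make_ground_truth(8, coupling_scale = 0.5, structure_noise = 0.02,
                          seed = 23)
  states <- sample_states(gt, 3000, seed = 24)
  rec <- states_to_traces(states, neurons_per_region = 8, snr = 20, seed = 25,
                          ground_truth = gt)
  scan <- scan_resolutions(rec, cluster_numbers = c(4, 8, 12),
                           thresholds_z = c(0, 0.5), n_rois = 24, seed = 26)
  expect_equal(nrow(scan$grid), 6)
  expect_true(all(c("pearson", "auc_mean") %in% names(scan$grid)))
  # the best AUC sits at (or adjacent to) the generating resolution N = 8
  expect_true(scan$best$n_clusters %in% c(8, 12))
  # single-point grid reduces to one structure-function evaluation
  one <- scan_resolutions(rec, cluster_numbers = 8, thresholds_z = 0,
                          n_rois = 24, seed = 26)
  expect_equal(nrow(one$grid), 1)
})
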