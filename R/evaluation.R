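#' Empirical versus model state probabilities
#'
#' Tabulates, for every one of the `2^N` states, its empirical frequency in
#' the raster and its probability under the fitted model.  Both columns sum
#' to one; plotting them against each other (log-log) is the classic visual
#' goodness-of-fit check for a pairwise model.
#'
#' @param raster A [binary_raster()].
#' @param model A `"mem"` with the raster's convention, N <= 20.
#' @return data.frame: `state` (0-based index), `empirical_p`, `model_p`,
#'   `n_active` (number of "on" units in the state).
#' @export
state_probability_comparison <- function(raster, model) {
  stopifnot(inherits(model, "mem"))
  r <- as_raster_matrix(raster, model$convention)
  n <- model$n_units
  check_enumerable(n)
  idx <- state_index(r$states, model$convention)
  emp <- tabulate(idx + 1L, nbins = 2^n) / length(idx)
  bits <- index_to_state(0:(2^n - 1), n, "01")
  data.frame(state = 0:(2^n - 1), empirical_p = emp,
             model_p = state_distribution(model), n_active = rowSums(bits))
}

#' Multi-information captured by the pairwise model
#'
#' Quantifies goodness of fit by entropy accounting.  With `S1` the entropy
#' of the independent (first-order) model built from the empirical
#' marginals, `S2` the entropy of the fitted pairwise model, and `SN` the
#' plug-in entropy of the empirical state frequencies, the multi-information
#' is `IN = S1 - SN` (total correlation) and the pairwise model captures
#' `I2 = S1 - S2` of it; the reported fraction is \eqn{r = I_2 / I_N}.
#'
#' `SN` is the uncorrected maximum-likelihood estimator (biased downward at
#' small T; a warning is issued when `T < 10 * 2^N`).  Because the plug-in
#' `SN` never exceeds the plug-in `S1`, sampling noise alone produces a
#' small positive `IN` even for genuinely independent data; its expected
#' magnitude is the Miller-Madow bias `(K - 1 - N) / (2T)` nats, with `K`
#' the number of observed distinct states.  `r` is therefore flagged
#' undefined (rather than fabricated) whenever `IN` does not exceed twice
#' that floor — i.e. when the measured multi-information is
#' indistinguishable from sampling bias.
#'
#' @param raster A [binary_raster()].
#' @param model The fitted `"mem"` (N <= 20).
#' @return Object of class `"fit_quality"`: `S1`, `S2`, `SN`, `I2`, `IN`,
#'   `r`, `r_defined`, all entropies in nats (`units = "nats"`; printed in
#'   bits).
#' @export
multi_information <- function(raster, model) {
  stopifnot(inherits(model, "mem"))
  r <- as_raster_matrix(raster, model$convention)
  n <- model$n_units
  check_enumerable(n)
  X <- r$states
  tt <- nrow(X)
  if (tt < 10 * 2^n) {
    warning("T = ", tt, " < 10 * 2^N: plug-in empirical entropy is biased ",
            "downward; treat IN and r with caution")
  }
  on <- convention_values(r$convention)[["on"]]
  p_on <- colMeans(X == on)
  S1 <- sum(vapply(p_on, function(p) entropy_nats(c(p, 1 - p)), 0.0))
  idx <- state_index(X, r$convention)
  emp <- tabulate(idx + 1L, nbins = 2^n) / tt
  SN <- entropy_nats(emp)
  S2 <- entropy_nats(state_distribution(model))
  I2 <- S1 - S2
  IN <- S1 - SN
  k_obs <- sum(emp > 0)
  bias_floor <- max(k_obs - 1 - n, 0) / (2 * tt)
  r_defined <- IN > max(1e-12, 2 * bias_floor)
  structure(list(S1 = S1, S2 = S2, SN = SN, I2 = I2, IN = IN,
                 r = if (r_defined) I2 / IN else NA_real_,
                 r_defined = r_defined, n_samples = tt, units = "nats"),
            class = "fit_quality")
}

#' @export
print.fit_quality <- function(x, ...) {
  b <- nats_to_bits
  cat("Pairwise-model fit quality (entropies in bits):\n")
  cat(sprintf("  S1 = %.4f, S2 = %.4f, SN = %.4f\n", b(x$S1), b(x$S2),
              b(x$SN)))
  cat(sprintf("  I2 = %.4f, IN = %.4f\n", b(x$I2), b(x$IN)))
  if (x$r_defined) {
    cat(sprintf("  multi-information fraction r = I2/IN = %.4f\n", x$r))
  } else {
    cat("  r undefined (no detectable correlation beyond sampling bias)\n")
  }
  invisible(x)
}

# Mann-Whitney rank-sum AUC: exact, tie-robust (midranks).
auc_rank <- function(scores, labels) {
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o]); fp <- cumsum(!labels[o])
  # collapse score ties so the curve is well-defined
  keep <- c(diff(scores[o]) != 0, TRUE)
  data.frame(FPR = c(0, fp[keep] / max(sum(!labels), 1)),
             TPR = c(0, tp[keep] / max(sum(labels), 1)))
}

#' Structure-function coupling of fitted couplings
#'
#' Compares the fitted couplings `J` with a structural connectivity matrix
#' (e.g. fiber counts) over the off-diagonal upper triangle: Pearson and
#' Spearman correlations, and — treating `J_ij` as a classifier score for
#' the presence of a structural edge — ROC/AUC at each binarization
#' threshold, where structural edges are defined as entries above
#' `f * max(structural)` for each threshold fraction `f`.
#'
#' AUC is computed by the Mann-Whitney rank-sum identity (exact and robust
#' to ties).  A threshold at which all edges fall in one class yields a
#' flagged `NA` AUC.
#'
#' @param x A `"mem"` object or a coupling matrix `J`.
#' @param structural Symmetric nonnegative matrix, same dimension as `J`.
#' @param thresholds Fractions of the maximum structural weight (default
#'   the 1% and 30% operating points).
#' @param score `"J"` (signed couplings) or `"absJ"`.
#' @return List: `pearson`, `spearman`, `auc_by_threshold` (named vector),
#'   `roc_curves` (list of FPR/TPR data.frames), `thresholds`, `n_pairs`.
#' @export
structure_function <- function(x, structural, thresholds = c(0.01, 0.3),
                               score = c("J", "absJ")) {
  score <- match.arg(score)
  J <- if (inherits(x, "mem")) x$J else as.matrix(x)
  structural <- as.matrix(structural)
  stopifnot(all(dim(structural) == dim(J)))
  if (max(abs(structural - t(structural))) > 1e-8) {
    stop("structural matrix must be symmetric")
  }
  jv <- upper_tri_vec(J)
  if (score == "absJ") jv <- abs(jv)
  sv <- upper_tri_vec(structural)
  pearson <- if (stats::sd(jv) > 0 && stats::sd(sv) > 0) {
    stats::cor(jv, sv)
  } else NA_real_
  spearman <- if (stats::sd(jv) > 0 && stats::sd(sv) > 0) {
    stats::cor(jv, sv, method = "spearman")
  } else NA_real_
  aucs <- numeric(length(thresholds))
  rocs <- vector("list", length(thresholds))
  names(aucs) <- names(rocs) <- paste0("f=", thresholds)
  for (i in seq_along(thresholds)) {
    lab <- sv > thresholds[i] * max(sv)
    aucs[i] <- auc_rank(jv, lab)
    rocs[[i]] <- if (is.na(aucs[i])) NULL else roc_points(jv, lab)
  }
  list(pearson = pearson, spearman = spearman, auc_by_threshold = aucs,
       roc_curves = rocs, thresholds = thresholds, n_pairs = length(jv))
}

#' Split-half robustness of the fit
#'
#' Randomly splits the time samples into two equal halves, fits each half
#' independently, and correlates the fitted couplings, fields, and
#' all-state model probabilities between halves.
#'
#' @param raster A [binary_raster()] with T >= 4.
#' @param seed Integer seed for the split.
#' @param method,tolerance,max_iter,learning_rate Passed to [fit_mem()].
#' @param index_a Optional explicit time indices for half A (overrides the
#'   random split; the complement becomes half B).
#' @return List: `corr_J`, `corr_h`, `corr_state_p`, `fit_A`, `fit_B`,
#'   `index_A` (the time indices of half A).
#' @export
split_half <- function(raster, seed = 1, method = "auto", tolerance = 1e-4,
                       max_iter = 20000, learning_rate = 0.1,
                       index_a = NULL) {
  stopifnot(inherits(raster, "binary_raster"))
  tt <- nrow(raster$states)
  if (tt < 4) stop("need at least 4 time samples to split")
  half <- floor(tt / 2)
  iA <- if (is.null(index_a)) {
    with_seed(seed, sort(sample.int(tt, half)))
  } else {
    sort(as.integer(index_a))
  }
  iB <- setdiff(seq_len(tt), iA)
  rA <- binary_raster(raster$states[iA, , drop = FALSE], raster$convention,
                      raster$threshold_z)
  rB <- binary_raster(raster$states[iB, , drop = FALSE], raster$convention,
                      raster$threshold_z)
  fA <- fit_mem(rA, method = method, tolerance = tolerance,
                max_iter = max_iter, learning_rate = learning_rate)
  fB <- fit_mem(rB, method = method, tolerance = tolerance,
                max_iter = max_iter, learning_rate = learning_rate)
  corr_state_p <- if (fA$n_units <= 20) {
    stats::cor(state_distribution(fA), state_distribution(fB))
  } else NA_real_
  list(corr_J = stats::cor(upper_tri_vec(fA$J), upper_tri_vec(fB$J)),
       corr_h = stats::cor(fA$h, fB$h),
       corr_state_p = corr_state_p,
       fit_A = fA, fit_B = fB, index_A = iA)
}

# Majority ground-truth region of each ROI, then cluster-level structural
# connectivity: total fiber count between the member ROIs' regions.
aggregate_structural <- function(structural, roi_region, cluster_of_roi,
                                 n_clusters) {
  counts <- matrix(0, n_clusters, nrow(structural))
  for (a in seq_along(cluster_of_roi)) {
    counts[cluster_of_roi[a], roi_region[a]] <-
      counts[cluster_of_roi[a], roi_region[a]] + 1
  }
  agg <- counts %*% structural %*% t(counts)
  diag(agg) <- 0
  agg
}

majority_label <- function(labels) as.integer(names(which.max(table(labels))))

#' Scan cluster numbers and binarization thresholds
#'
#' Runs the full preprocessing + fitting + structure-function evaluation
#' over a grid of cluster counts and z-score thresholds, reporting the
#' correlation and AUC between fitted couplings and the structural matrix
#' at each grid point.  The structural matrix (defined between ground-truth
#' regions) is aggregated to each cluster resolution by summing fiber
#' counts between the member ROIs' (majority) regions.
#'
#' @param recording A `"synthetic_recording"` (or compatible list with
#'   `neuron_positions`, `traces`, `ground_truth`).
#' @param cluster_numbers Vector of functional cluster counts N to scan.
#' @param thresholds_z Vector of binarization thresholds.
#' @param structural Region-level structural matrix (default: the
#'   recording's ground truth).
#' @param n_rois Spatial ROIs for the k-means stage (default
#'   `min(4 * max(cluster_numbers), n_neurons)`).
#' @param convention Fitting convention.
#' @param seed Seed for the k-means stage.
#' @param tolerance,max_iter Fit controls.
#' @return List: `grid` (data.frame with one row per (N, z): correlations,
#'   per-threshold AUCs, `auc_mean`, convergence flag, error message if the
#'   fit failed), `best` (the maximizing row), `roi_set`.
#' @export
scan_resolutions <- function(recording, cluster_numbers, thresholds_z,
                             structural = NULL, n_rois = NULL,
                             convention = "pm1", seed = 1,
                             tolerance = 1e-4, max_iter = 20000) {
  if (is.null(structural)) {
    if (is.null(recording$ground_truth)) {
      stop("no structural matrix given and the recording has no ground truth")
    }
    structural <- recording$ground_truth$structural
  }
  n_neurons <- nrow(recording$traces)
  if (is.null(n_rois)) n_rois <- min(4 * max(cluster_numbers), n_neurons)
  rois <- spatial_kmeans(recording$neuron_positions, recording$traces,
                         n_rois = n_rois, seed = seed)
  roi_region <- vapply(seq_len(rois$n_rois), function(a) {
    majority_label(recording$region_of_neuron[rois$roi_of_neuron == a])
  }, 0L)
  rows <- list()
  for (nc in cluster_numbers) {
    cl <- functional_clusters(rois, n_clusters = nc)
    agg <- aggregate_structural(structural, roi_region, cl$cluster_of_roi, nc)
    for (z in thresholds_z) {
      rec <- tryCatch({
        raster <- binarize(cl, threshold_z = z, convention = convention)
        fit <- fit_mem(raster, tolerance = tolerance, max_iter = max_iter)
        sf <- structure_function(fit, agg, score = "absJ")
        c(list(n_clusters = nc, threshold_z = z, pearson = sf$pearson,
               spearman = sf$spearman, converged = fit$converged,
               error = NA_character_),
          as.list(stats::setNames(sf$auc_by_threshold,
                                  paste0("auc_", names(sf$auc_by_threshold)))),
          list(auc_mean = mean(sf$auc_by_threshold, na.rm = TRUE)))
      }, error = function(e) {
        list(n_clusters = nc, threshold_z = z, pearson = NA_real_,
             spearman = NA_real_, converged = FALSE,
             error = conditionMessage(e), auc_mean = NA_real_)
      })
      rows[[length(rows) + 1]] <- rec
    }
  }
  cols <- unique(unlist(lapply(rows, names)))
  grid <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    as.data.frame(r[cols], stringsAsFactors = FALSE)
  }))
  best <- grid[which.max(grid$auc_mean), , drop = FALSE]
  list(grid = grid, best = best, roi_set = rois)
}
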