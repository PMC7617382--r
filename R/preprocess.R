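#' Binary activity raster
#'
#' A T x N matrix of binarized cluster activity in a declared state
#' convention, the common currency between preprocessing, model fitting and
#' dynamics.
#'
#' @param states T x N matrix whose values match `convention`.
#' @param convention `"pm1"` or `"01"`.
#' @param threshold_z The z-score threshold the raster was produced at
#'   (`NA` if not applicable, e.g. simulated states).
#' @return Object of class `"binary_raster"` with elements `states`,
#'   `convention`, `threshold_z`.
#' @export
binary_raster <- function(states, convention = c("pm1", "01"),
                          threshold_z = NA_real_) {
  convention <- match.arg(convention)
  states <- as.matrix(states)
  check_state_values(states, convention)
  structure(list(states = states, convention = convention,
                 threshold_z = threshold_z),
            class = "binary_raster")
}

#' @export
print.binary_raster <- function(x, ...) {
  on <- convention_values(x$convention)[["on"]]
  cat("Binary raster: ", nrow(x$states), " time points x ", ncol(x$states),
      " clusters (", x$convention, ")\n", sep = "")
  if (nrow(x$states) > 0) {
    cat("  on-rates: ", paste(sprintf("%.2f",
        utils::head(colMeans(x$states == on), 8)), collapse = " "),
        if (ncol(x$states) > 8) " ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.binary_raster <- function(x) dim(x$states)

as_raster_matrix <- function(x, convention = NULL) {
  if (inherits(x, "binary_raster")) {
    if (!is.null(convention) && x$convention != convention) {
      stop("raster convention '", x$convention, "' does not match '",
           convention, "'")
    }
    list(states = x$states, convention = x$convention)
  } else {
    if (is.null(convention)) stop("convention must be given for plain matrices")
    check_state_values(as.matrix(x), convention)
    list(states = as.matrix(x), convention = convention)
  }
}

#' Concatenate rasters along the time axis
#'
#' Used to pool recordings (e.g. several fish) that share a cluster
#' definition.  Each raster is expected to have been z-scored and binarized
#' per recording before concatenation.
#'
#' @param ... `binary_raster` objects with identical column counts and
#'   conventions.
#' @return A single `binary_raster`.
#' @export
concat_rasters <- function(...) {
  rs <- list(...)
  stopifnot(length(rs) >= 1, all(vapply(rs, inherits, TRUE, "binary_raster")))
  conv <- unique(vapply(rs, function(r) r$convention, ""))
  ncols <- unique(vapply(rs, function(r) ncol(r$states), 0L))
  if (length(conv) != 1 || length(ncols) != 1) {
    stop("rasters must share convention and cluster count")
  }
  binary_raster(do.call(rbind, lapply(rs, function(r) r$states)), conv,
                threshold_z = rs[[1]]$threshold_z)
}

#' Spatial k-means parcellation of neurons into ROIs
#'
#' Clusters neurons into `n_rois` regions of interest by their 3D positions
#' (k-means, 10 random restarts, best within-cluster sum of squares).  ROI
#' traces are unweighted means of member neuron traces.
#'
#' @param positions n_neurons x 3 coordinate matrix.
#' @param traces n_neurons x T matrix of continuous activity traces.
#' @param n_rois Number of ROIs (<= n_neurons).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of random restarts.
#' @return Object of class `"roi_set"`: `roi_of_neuron`, `centroids`
#'   (n_rois x 3), `traces` (n_rois x T), `n_rois`.
#' @export
spatial_kmeans <- function(positions, traces, n_rois, seed = 1, nstart = 10) {
  positions <- as.matrix(positions)
  traces <- as.matrix(traces)
  stopifnot(nrow(positions) == nrow(traces))
  if (nrow(positions) < n_rois) {
    stop("n_rois (", n_rois, ") exceeds number of neurons (",
         nrow(positions), ")")
  }
  if (n_rois == nrow(positions)) {
    km <- list(cluster = seq_len(n_rois), centers = positions)
  } else {
    km <- with_seed(seed,
      stats::kmeans(positions, centers = n_rois, nstart = nstart,
                    iter.max = 100))
  }
  assign <- as.integer(km$cluster)
  counts <- tabulate(assign, nbins = n_rois)
  roi_traces <- rowsum(traces, assign) / counts
  centroids <- rowsum(positions, assign) / counts
  structure(list(roi_of_neuron = assign, centroids = centroids,
                 traces = roi_traces, n_rois = n_rois),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("ROI set: ", x$n_rois, " ROIs, ", length(x$roi_of_neuron),
      " neurons, T = ", ncol(x$traces), "\n", sep = "")
  invisible(x)
}

#' Functional clustering of ROIs by trace covariance structure
#'
#' Groups ROIs into `n_clusters` functional clusters by agglomerative
#' hierarchical clustering with distance `1 - Pearson correlation` between
#' ROI average traces (correlation rather than raw covariance so that ROI
#' scale does not dominate the grouping).  Cluster traces are unweighted
#' means of member-ROI traces.
#'
#' @param rois A `"roi_set"` from [spatial_kmeans()], or a plain
#'   n_rois x T trace matrix.
#' @param n_clusters Number of functional clusters (2 .. n_rois).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return Object of class `"cluster_set"`: `cluster_of_roi`, `traces`
#'   (N x T), `n_clusters`, `linkage`.
#' @export
functional_clusters <- function(rois, n_clusters, linkage = "average") {
  tr <- if (inherits(rois, "roi_set")) rois$traces else as.matrix(rois)
  n_rois <- nrow(tr)
  if (n_clusters < 2 || n_clusters > n_rois) {
    stop("n_clusters must be in [2, ", n_rois, "]")
  }
  sds <- apply(tr, 1, stats::sd)
  if (any(sds == 0)) {
    stop("ROI(s) with constant trace (zero variance): ",
         paste(which(sds == 0), collapse = ", "))
  }
  if (n_clusters == n_rois) {
    cl <- seq_len(n_rois)
  } else {
    d <- stats::as.dist(1 - stats::cor(t(tr)))
    cl <- stats::cutree(stats::hclust(d, method = linkage), k = n_clusters)
  }
  counts <- tabulate(cl, nbins = n_clusters)
  ctr <- rowsum(tr, cl) / counts
  structure(list(cluster_of_roi = as.integer(cl), traces = ctr,
                 n_clusters = n_clusters, linkage = linkage),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("Cluster set: ", x$n_clusters, " functional clusters (",
      x$linkage, " linkage), T = ", ncol(x$traces), "\n", sep = "")
  invisible(x)
}

#' Binarize cluster traces at a z-score threshold
#'
#' Each cluster trace is z-scored over time; samples strictly above
#' `threshold_z` are "on", samples at or below are "off" (the strict
#' comparison makes the `z = 0` case unambiguous).
#'
#' @param clusters A `"cluster_set"` or an N x T trace matrix.
#' @param threshold_z Z-score threshold (typical scan: 0, 0.5, 1, 1.5, 2).
#' @param convention Output encoding of on/off.
#' @return A [binary_raster()] (T x N).
#' @export
binarize <- function(clusters, threshold_z = 0, convention = c("pm1", "01")) {
  convention <- match.arg(convention)
  tr <- if (inherits(clusters, "cluster_set")) clusters$traces else as.matrix(clusters)
  sds <- apply(tr, 1, stats::sd)
  if (any(sds == 0)) {
    stop("cluster trace(s) with zero variance cannot be z-scored: ",
         paste(which(sds == 0), collapse = ", "))
  }
  z <- t(scale(t(tr)))  # z-score each cluster over time
  on <- t(z) > threshold_z  # T x N
  vals <- convention_values(convention)
  states <- matrix(vals[["off"]], nrow = nrow(on), ncol = ncol(on))
  states[on] <- vals[["on"]]
  binary_raster(states, convention, threshold_z = threshold_z)
}

#' Empirical means and second moments of a binary raster
#'
#' \eqn{\langle\sigma_i\rangle = T^{-1}\sum_t \sigma_i^t} and
#' \eqn{\langle\sigma_i\sigma_j\rangle = T^{-1}\sum_t \sigma_i^t\sigma_j^t}
#' (the diagonal equals 1 in `"pm1"` and the means in `"01"`).
#'
#' @param raster A [binary_raster()] (or state matrix plus `convention`).
#' @param convention Needed only when `raster` is a plain matrix.
#' @return A [moment_set()].
#' @export
empirical_moments <- function(raster, convention = NULL) {
  r <- as_raster_matrix(raster, convention)
  X <- r$states
  stopifnot(nrow(X) >= 1)
  means <- colMeans(X)
  second <- crossprod(X) / nrow(X)
  moment_set(means, second, n_samples = nrow(X), convention = r$convention,
             labels = colnames(X))
}
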