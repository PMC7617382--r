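#' Ground-truth model and structural matrix for synthetic recordings
#'
#' Draws a known pairwise model to generate data from, plus a structural
#' "fiber count" matrix correlated with the coupling magnitudes, so that
#' parameter recovery and structure-function evaluation can be tested
#' without external recordings.
#'
#' Couplings are Gaussian weights on an Erdos-Renyi support (edge density
#' `density`), scaled by `coupling_scale` — this produces a mixture of
#' positive and negative couplings and both strongly and weakly connected
#' regions, giving resection analyses contrast.  Fields are drawn uniform
#' in `h_range` (negative-biased by default so the all-off state dominates,
#' mirroring sparse activation).  The structural matrix is
#' `structural_scale * (|J| + noise)` clipped at zero, with symmetric
#' Gaussian noise of standard deviation `structure_noise` (in coupling
#' units): at `structure_noise = 0` it is exactly proportional to `|J|`.
#'
#' @param n_regions Number of regions (>= 2).
#' @param coupling_scale Standard deviation of nonzero couplings.
#' @param structure_noise Noise level of the structural matrix, in coupling
#'   units (0 = noiseless).
#' @param seed Integer seed; the whole object is deterministic given it.
#' @param density Erdos-Renyi edge density of the coupling support.
#' @param h_range Range the fields are drawn from (uniform).
#' @param convention State convention of the ground-truth model.
#' @param structural_scale Multiplier taking couplings to fiber-count units.
#' @return Object of class `"mem_ground_truth"`: `model` (a `"mem"`),
#'   `structural` (symmetric nonnegative, zero diagonal), `n_regions`,
#'   `seed`, and the generation parameters.
#' @export
make_ground_truth <- function(n_regions, coupling_scale = 0.3,
                              structure_noise = 0, seed = 1,
                              density = 0.4, h_range = c(-1, 0),
                              convention = c("pm1", "01"),
                              structural_scale = 100) {
  convention <- match.arg(convention)
  if (n_regions < 2) stop("n_regions must be at least 2")
  stopifnot(coupling_scale > 0, structure_noise >= 0)
  out <- with_seed(seed, {
    n <- n_regions
    J <- matrix(0, n, n)
    ut <- upper.tri(J)
    support <- stats::runif(sum(ut)) < density
    w <- stats::rnorm(sum(ut), sd = coupling_scale) * support
    J[ut] <- w
    J <- J + t(J)
    h <- stats::runif(n, h_range[1], h_range[2])
    noise <- matrix(0, n, n)
    noise[ut] <- stats::rnorm(sum(ut), sd = structure_noise)
    noise <- noise + t(noise)
    structural <- pmax(structural_scale * (abs(J) + noise), 0)
    diag(structural) <- 0
    list(h = h, J = J, structural = structural)
  })
  model <- mem_model(out$h, out$J, convention = convention)
  dimnames(out$structural) <- dimnames(model$J)
  structure(list(model = model, structural = out$structural,
                 n_regions = n_regions, seed = seed,
                 coupling_scale = coupling_scale,
                 structure_noise = structure_noise, density = density,
                 h_range = h_range, structural_scale = structural_scale),
            class = "mem_ground_truth")
}

#' @export
print.mem_ground_truth <- function(x, ...) {
  cat("Synthetic ground truth: ", x$n_regions, " regions (seed ", x$seed,
      ")\n", sep = "")
  print(x$model)
  invisible(x)
}

#' Sample binary states from a ground-truth or fitted model
#'
#' Draws `n_samples` states from the Boltzmann distribution, either i.i.d.
#' by exact enumeration (N <= 20) or as a thinned Metropolis chain.
#'
#' @param x A `"mem_ground_truth"` or `"mem"` object.
#' @param n_samples Number of samples (0 gives an empty raster with N
#'   columns).
#' @param temperature Sampling temperature.
#' @param method `"exact_enumeration"` or `"metropolis"`.
#' @param seed Integer seed.
#' @param burn_in,thin Metropolis controls.
#' @return A [binary_raster()] of dimension `n_samples x N`.
#' @export
sample_states <- function(x, n_samples, temperature = 1,
                          method = c("exact_enumeration", "metropolis"),
                          seed = 1, burn_in = 10000, thin = 10) {
  method <- match.arg(method)
  model <- if (inherits(x, "mem_ground_truth")) x$model else x
  stopifnot(inherits(model, "mem"))
  simulate(model, nsim = n_samples, seed = seed,
           method = if (method == "exact_enumeration") "exact" else "metropolis",
           temperature = temperature, burn_in = burn_in, thin = thin)
}

#' Calcium-like traces from binary region states
#'
#' Emulates a recording: each region gets `neurons_per_region` neurons in a
#' Gaussian spatial blob around a region center (centers on a jittered 3D
#' lattice, well separated), and each neuron's trace is a two-level step
#' signal (region off = 0, on = 1) plus white Gaussian noise of standard
#' deviation `1 / snr`.  The region-average trace, z-scored and thresholded
#' at z = 0, recovers the generating states with error rate vanishing as
#' `snr` grows (the z-scored off level is always below 0 and the on level
#' above it, for any on-rate).  No calcium-indicator kinetics are modeled:
#' the downstream pipeline only consumes z-scored thresholded traces.
#'
#' @param states A [binary_raster()] (T x N) of region states, e.g. from
#'   [sample_states()].
#' @param neurons_per_region Neurons per region blob.
#' @param snr Signal-to-noise ratio (signal amplitude 1, noise sd `1/snr`).
#' @param seed Integer seed.
#' @param ground_truth Optional `"mem_ground_truth"` to carry along.
#' @param blob_sd Spatial spread of each blob (lattice spacing is 5).
#' @return Object of class `"synthetic_recording"`: `neuron_positions`
#'   (n_neurons x 3), `traces` (n_neurons x T), `region_of_neuron`,
#'   `states_true` (the input raster), `ground_truth`, `snr`, `seed`,
#'   `n_regions`.
#' @export
states_to_traces <- function(states, neurons_per_region = 20, snr = 10,
                             seed = 1, ground_truth = NULL, blob_sd = 0.5) {
  stopifnot(inherits(states, "binary_raster"), snr > 0,
            neurons_per_region >= 1)
  X <- states$states
  n_regions <- ncol(X)
  tt <- nrow(X)
  on <- convention_values(states$convention)[["on"]]
  level <- (X == on) * 1.0  # T x N step signal in {0, 1}
  n_neurons <- n_regions * neurons_per_region
  side <- ceiling(n_regions^(1 / 3))
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(side)))[seq_len(n_regions), , drop = FALSE] * 5
  out <- with_seed(seed, {
    centers <- grid + matrix(stats::runif(n_regions * 3, -0.5, 0.5),
                             n_regions, 3)
    region <- rep(seq_len(n_regions), each = neurons_per_region)
    pos <- centers[region, , drop = FALSE] +
      matrix(stats::rnorm(n_neurons * 3, sd = blob_sd), n_neurons, 3)
    traces <- t(level[, region, drop = FALSE]) +
      matrix(stats::rnorm(n_neurons * tt, sd = 1 / snr), n_neurons, tt)
    list(pos = pos, region = region, traces = traces)
  })
  dimnames(out$pos) <- list(NULL, c("x", "y", "z"))
  dimnames(out$traces) <- NULL
  structure(list(neuron_positions = out$pos, traces = out$traces,
                 region_of_neuron = out$region, states_true = states,
                 ground_truth = ground_truth, snr = snr, seed = seed,
                 n_regions = n_regions),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat("Synthetic recording: ", nrow(x$traces), " neurons, ", x$n_regions,
      " regions, T = ", ncol(x$traces), ", SNR = ", x$snr, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic recording to plain-text files
#'
#' Layout under `path` (created if its parent exists):
#' * `neurons.csv` — id, x, y, z, region, then `t_0 ... t_{T-1}` trace
#'   columns;
#' * `states_true.csv` — T x N region states;
#' * `structural.csv` — region-labeled structural matrix (when ground truth
#'   is present);
#' * `ground_truth.json` — `{convention, h, J, ...}` at full double
#'   precision;
#' * `meta.json` — convention, snr, seeds.
#'
#' Numerics are written as `%.17g`, so [read_recording()] reproduces every
#' array exactly.
#'
#' @param rec A `"synthetic_recording"`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "synthetic_recording"))
  if (!dir.exists(dirname(path))) {
    stop("cannot write recording: directory '", dirname(path),
         "' does not exist")
  }
  if (!dir.exists(path)) dir.create(path)
  tt <- ncol(rec$traces)
  neuron_tab <- cbind(rec$neuron_positions, region = rec$region_of_neuron,
                      rec$traces)
  write_matrix_csv(cbind(id = seq_len(nrow(neuron_tab)), neuron_tab),
                   file.path(path, "neurons.csv"),
                   col_names = c("id", "x", "y", "z", "region",
                                 paste0("t_", seq_len(tt) - 1)))
  write_matrix_csv(rec$states_true$states, file.path(path, "states_true.csv"),
                   col_names = paste0("c", seq_len(ncol(rec$states_true$states))))
  meta <- list(convention = rec$states_true$convention,
               threshold_z = rec$states_true$threshold_z,
               snr = rec$snr, seed = rec$seed, n_regions = rec$n_regions)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = I(17))
  gt <- rec$ground_truth
  if (!is.null(gt)) {
    labels <- gt$model$labels
    write_matrix_csv(gt$structural, file.path(path, "structural.csv"),
                     col_names = labels)
    jsonlite::write_json(
      list(convention = gt$model$convention, h = gt$model$h,
           J = gt$model$J, seed = gt$seed,
           coupling_scale = gt$coupling_scale,
           structure_noise = gt$structure_noise, density = gt$density,
           h_range = gt$h_range, structural_scale = gt$structural_scale),
      file.path(path, "ground_truth.json"), auto_unbox = TRUE, digits = I(17),
      matrix = "rowmajor")
  }
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Directory containing the recording files.
#' @return A `"synthetic_recording"` equal (exactly, for all arrays) to the
#'   one written.
#' @export
read_recording <- function(path) {
  if (!dir.exists(path)) stop("no recording at '", path, "'")
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  nt <- utils::read.csv(file.path(path, "neurons.csv"),
                        check.names = FALSE)
  pos <- as.matrix(nt[, c("x", "y", "z")])
  region <- as.integer(nt$region)
  traces <- as.matrix(nt[, grepl("^t_", names(nt)), drop = FALSE])
  dimnames(traces) <- NULL
  st <- read_matrix_csv(file.path(path, "states_true.csv"), has_header = TRUE)
  gt <- NULL
  gt_file <- file.path(path, "ground_truth.json")
  if (file.exists(gt_file)) {
    g <- jsonlite::read_json(gt_file, simplifyVector = TRUE)
    model <- mem_model(g$h, g$J, convention = g$convention)
    structural <- read_matrix_csv(file.path(path, "structural.csv"),
                                  has_header = TRUE)
    dimnames(structural) <- dimnames(model$J)
    gt <- structure(list(model = model, structural = structural,
                         n_regions = length(g$h), seed = g$seed,
                         coupling_scale = g$coupling_scale,
                         structure_noise = g$structure_noise,
                         density = g$density, h_range = g$h_range,
                         structural_scale = g$structural_scale),
                    class = "mem_ground_truth")
  }
  structure(list(neuron_positions = pos, traces = traces,
                 region_of_neuron = region,
                 states_true = binary_raster(
                   st, meta$convention,
                   if (is.null(meta$threshold_z)) NA_real_ else meta$threshold_z),
                 ground_truth = gt, snr = meta$snr, seed = meta$seed,
                 n_regions = meta$n_regions),
            class = "synthetic_recording")
}
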