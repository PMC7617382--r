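#' Pairwise maximum-entropy (Ising) model
#'
#' Constructs a pairwise maximum-entropy model over `N` binary units.  The
#' model assigns every activity pattern \eqn{\sigma} the energy
#' \deqn{E(\sigma) = -\sum_i h_i \sigma_i
#'   - \tfrac{1}{2}\sum_{i \ne j} J_{ij} \sigma_i \sigma_j,}
#' and the Boltzmann probability \eqn{P(\sigma) = e^{-E(\sigma)/T}/Z}.
#' `h` is the activation bias of each unit (region/cluster) and `J` the
#' symmetric pairwise functional coupling.  This is the least-structured
#' distribution matching a set of unit means and pairwise coactivation
#' rates, i.e. the Ising model of statistical physics.
#'
#' @param h Numeric vector of activation biases, length N.
#' @param J Symmetric numeric N x N coupling matrix with zero diagonal.
#' @param convention State encoding the parameters refer to: `"pm1"`
#'   (states in -1/+1) or `"01"` (states in 0/1).  The same distribution has
#'   different `(h, J)` in the two encodings; see [convert_convention()].
#' @param labels Optional unit labels (default `"c1" ... "cN"`).
#' @return An object of class `"mem"`: a list with elements `h`, `J`,
#'   `convention`, `labels`, `n_units`.
#' @seealso [fit_mem()], [energy()], [state_distribution()],
#'   [model_moments()], [energy_landscape()]
#' @examples
#' m <- mem_model(h = c(0, 0), J = matrix(c(0, 1, 1, 0), 2), convention = "pm1")
#' model_moments(m)$second_moments[1, 2]  # tanh(1) for the 2-spin ferromagnet
#' @export
mem_model <- function(h, J, convention = c("pm1", "01"), labels = NULL) {
  convention <- match.arg(convention)
  h <- as.numeric(h)
  J <- as.matrix(J)
  n <- length(h)
  if (!is.numeric(J) || nrow(J) != n || ncol(J) != n) {
    stop("J must be a numeric ", n, " x ", n, " matrix matching length(h)")
  }
  if (any(!is.finite(h)) || any(!is.finite(J))) {
    stop("model parameters must be finite")
  }
  if (max(abs(J - t(J))) > 1e-10) stop("J must be symmetric")
  if (max(abs(diag(J))) > 1e-12) stop("J must have zero diagonal")
  J <- (J + t(J)) / 2
  diag(J) <- 0
  if (is.null(labels)) labels <- paste0("c", seq_len(n))
  dimnames(J) <- list(labels, labels)
  names(h) <- labels
  structure(list(h = h, J = J, convention = convention, labels = labels,
                 n_units = n),
            class = "mem")
}

#' @export
print.mem <- function(x, ...) {
  cat("Pairwise maximum-entropy model (", x$n_units, " units, convention ",
      x$convention, ")\n", sep = "")
  cat("  h: ", paste(sprintf("%.3f", utils::head(x$h, 8)), collapse = " "),
      if (x$n_units > 8) " ..." else "", "\n", sep = "")
  ut <- upper_tri_vec(x$J)
  cat(sprintf("  J: %d couplings, range [%.3f, %.3f], mean |J| = %.3f\n",
              length(ut), min(ut), max(ut), mean(abs(ut))))
  invisible(x)
}

#' @export
coef.mem <- function(object, ...) {
  n <- object$n_units
  jv <- upper_tri_vec(object$J)
  pairs <- which(upper.tri(object$J), arr.ind = TRUE)
  names(jv) <- paste0("J[", object$labels[pairs[, 1]], ",",
                      object$labels[pairs[, 2]], "]")
  hv <- object$h
  names(hv) <- paste0("h[", object$labels, "]")
  c(hv, jv)
}

#' Energy of binary activity states
#'
#' Evaluates \eqn{E(\sigma) = -\sum_i h_i\sigma_i - \frac{1}{2}\sum_{i\ne j}
#' J_{ij}\sigma_i\sigma_j} for one or more states.
#'
#' @param model A `"mem"` object.
#' @param states A state vector of length N, or a matrix with states in rows.
#'   Values must match `model$convention`.
#' @return Numeric vector of energies, one per state row.
#' @export
energy <- function(model, states) {
  stopifnot(inherits(model, "mem"))
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  states <- as.matrix(states)
  if (ncol(states) != model$n_units) {
    stop("states must have ", model$n_units, " columns")
  }
  check_state_values(states, model$convention)
  as.numeric(-states %*% model$h - 0.5 * rowSums((states %*% model$J) * states))
}

#' Exact Boltzmann distribution over all states
#'
#' Enumerates all `2^N` states and returns their probabilities
#' \eqn{P(\sigma) = e^{-E(\sigma)/T} / Z} with a log-sum-exp-stable
#' normalization.  State `s` (0-based index) places cluster 1 in the least
#' significant bit; see [all_states()].
#'
#' @param model A `"mem"` object with `n_units <= 20`.
#' @param temperature Positive temperature `T` scaling the energies.
#' @return Numeric vector of length `2^N` summing to one; element `s + 1`
#'   is the probability of state index `s`.
#' @export
state_distribution <- function(model, temperature = 1) {
  stopifnot(inherits(model, "mem"), temperature > 0)
  check_enumerable(model$n_units)
  S <- all_states(model$n_units, model$convention)
  logw <- -energy(model, S) / temperature
  logw <- logw - max(logw)
  w <- exp(logw)
  w / sum(w)
}

#' Exact model moments by enumeration
#'
#' Means \eqn{\langle\sigma_i\rangle} and second moments
#' \eqn{\langle\sigma_i\sigma_j\rangle} under the Boltzmann distribution.
#'
#' @inheritParams state_distribution
#' @return A `"moment_set"`: list with `means`, `second_moments`,
#'   `n_samples` (`Inf` for exact moments) and `convention`.
#' @export
model_moments <- function(model, temperature = 1) {
  p <- state_distribution(model, temperature)
  S <- all_states(model$n_units, model$convention)
  means <- as.numeric(crossprod(S, p))
  second <- crossprod(S, S * p)
  second <- (second + t(second)) / 2
  moment_set(means, second, n_samples = Inf, convention = model$convention,
             labels = model$labels)
}

#' Construct a moment set
#'
#' Container for unit means and pairwise second moments, the sufficient
#' statistics of the pairwise model.
#'
#' @param means Length-N vector of means.
#' @param second_moments Symmetric N x N matrix of second moments (diagonal
#'   equals 1 in `"pm1"` and equals the means in `"01"`).
#' @param n_samples Number of samples the moments came from (`Inf` = exact).
#' @param convention State encoding.
#' @param labels Optional unit labels.
#' @return An object of class `"moment_set"`.
#' @export
moment_set <- function(means, second_moments, n_samples, convention,
                       labels = NULL) {
  convention <- match_convention(convention)
  means <- as.numeric(means)
  second_moments <- as.matrix(second_moments)
  n <- length(means)
  stopifnot(nrow(second_moments) == n, ncol(second_moments) == n)
  if (max(abs(second_moments - t(second_moments))) > 1e-8) {
    stop("second_moments must be symmetric")
  }
  if (is.null(labels)) labels <- paste0("c", seq_len(n))
  names(means) <- labels
  dimnames(second_moments) <- list(labels, labels)
  structure(list(means = means, second_moments = second_moments,
                 n_samples = n_samples, convention = convention,
                 labels = labels),
            class = "moment_set")
}

#' @export
print.moment_set <- function(x, ...) {
  cat("Moment set: ", length(x$means), " units, convention ", x$convention,
      ", n = ", x$n_samples, "\n", sep = "")
  cat("  means in [", sprintf("%.3f", min(x$means)), ", ",
      sprintf("%.3f", max(x$means)), "]\n", sep = "")
  invisible(x)
}

#' Convert model parameters between state conventions
#'
#' The affine map \eqn{s = 2\sigma - 1} between 0/1 occupations and -1/+1
#' spins induces an exact reparameterization under which the distribution is
#' unchanged (the additive energy constant is absorbed by the partition
#' function):
#' \deqn{J^{01} = 4 J^{\pm},\qquad h^{01}_i = 2h^{\pm}_i - 2\sum_j J^{\pm}_{ij}.}
#'
#' @param model A `"mem"` object.
#' @param to Target convention.
#' @return A `"mem"` object in the target convention defining the identical
#'   distribution (a no-op if already there).
#' @export
convert_convention <- function(model, to = c("pm1", "01")) {
  stopifnot(inherits(model, "mem"))
  to <- match.arg(to)
  if (model$convention == to) return(model)
  r <- rowSums(model$J)
  if (to == "01") {
    # pm1 -> 01
    J <- 4 * model$J
    h <- 2 * model$h - 2 * r
  } else {
    # 01 -> pm1
    J <- model$J / 4
    h <- model$h / 2 + r / 4
  }
  out <- mem_model(h, J, convention = to, labels = model$labels)
  extra <- setdiff(names(model), names(out))
  out[extra] <- model[extra]
  class(out) <- class(model)
  out
}

#' Simulate binary states from a fitted or constructed model
#'
#' Draws samples from the model's Boltzmann distribution, either i.i.d. via
#' exact enumeration (N <= 20) or as a thinned Metropolis chain.
#'
#' @param object A `"mem"` object.
#' @param nsim Number of samples (rows) to draw.
#' @param seed Integer seed; required for reproducibility.
#' @param method `"exact"` (i.i.d., enumeration) or `"metropolis"`.
#' @param temperature Sampling temperature.
#' @param burn_in,thin Metropolis chain controls (ignored for exact).
#' @param ... Unused.
#' @return A [binary_raster()] with `nsim` rows (possibly zero).
#' @export
simulate.mem <- function(object, nsim = 1, seed = NULL,
                         method = c("exact", "metropolis"),
                         temperature = 1, burn_in = 1000, thin = 10, ...) {
  method <- match.arg(method)
  if (is.null(seed)) stop("simulate.mem requires an explicit integer seed")
  n <- object$n_units
  if (nsim == 0) {
    return(binary_raster(matrix(convention_values(object$convention)[["off"]],
                                0, n), object$convention))
  }
  if (method == "exact") {
    check_enumerable(n)
    p <- state_distribution(object, temperature)
    idx <- with_seed(seed, sample.int(length(p), nsim, replace = TRUE, prob = p)) - 1L
    states <- index_to_state(idx, n, object$convention)
  } else {
    walk <- mcmc_walk(object, n_steps = nsim * thin, burn_in = burn_in,
                      thin = thin, temperature = temperature, seed = seed)
    states <- index_to_state(walk$states[seq_len(nsim)], n, object$convention)
  }
  colnames(states) <- object$labels
  binary_raster(states, object$convention)
}

#' Predict state probabilities or energies
#'
#' @param object A `"mem"` object.
#' @param newdata State matrix (rows) or a [binary_raster()]; defaults to all
#'   `2^N` states.
#' @param type `"probability"` (requires N <= 20) or `"energy"`.
#' @param temperature Temperature for probabilities.
#' @param ... Unused.
#' @return Numeric vector, one value per state row.
#' @export
predict.mem <- function(object, newdata = NULL,
                        type = c("probability", "energy"),
                        temperature = 1, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "binary_raster")) {
    if (newdata$convention != object$convention) {
      stop("raster convention '", newdata$convention,
           "' does not match model convention '", object$convention, "'")
    }
    newdata <- newdata$states
  }
  if (is.null(newdata)) newdata <- all_states(object$n_units, object$convention)
  if (type == "energy") return(energy(object, newdata))
  p <- state_distribution(object, temperature)
  p[state_index(newdata, object$convention) + 1L]
}
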