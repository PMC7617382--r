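#' Fit a pairwise maximum-entropy model to binarized activity
#'
#' Calibrates fields `h` and couplings `J` so the model's means and pairwise
#' second moments match the data.  Two estimators are available:
#'
#' * `"exact"` — likelihood gradient ascent using exact model moments from
#'   enumeration of all `2^N` states:
#'   \eqn{h_i \leftarrow h_i + \epsilon(\langle\sigma_i\rangle_{data} -
#'   \langle\sigma_i\rangle_{model})}, similarly for `J`.  Exact but costs
#'   `O(2^N)` per iteration.
#' * `"pseudolikelihood"` — maximizes the product of single-unit conditional
#'   likelihoods \eqn{\tilde P(\sigma_i \mid \sigma_{\setminus i})} by
#'   gradient ascent; consistent as the number of time samples grows, and
#'   tractable for large N.  The two directed estimates of each coupling are
#'   kept symmetric by averaging the corresponding gradients.
#'
#' `method = "auto"` switches from exact to pseudo-likelihood above
#' `exact_limit` units (default 15, where full enumeration starts to become
#' expensive).
#'
#' @param x A [binary_raster()], a plain state matrix (with `convention`),
#'   or — for the exact method only — a [moment_set()].
#' @param method `"auto"`, `"exact"` or `"pseudolikelihood"`.
#' @param convention Needed when `x` is a plain matrix.
#' @param learning_rate Initial gradient step size \eqn{\epsilon}.  Adapted
#'   during the run: grown gently while the error decreases, geometrically
#'   cut on oscillation.
#' @param tolerance Convergence threshold on the maximum absolute moment
#'   discrepancy (exact) or pseudo-likelihood gradient entry.
#' @param max_iter Iteration cap; exceeding it returns `converged = FALSE`.
#' @param init Optional `"mem"` object used as starting point.
#' @param exact_limit N above which `"auto"` uses pseudo-likelihood.
#' @return An object of class `c("mem_fit", "mem")`: the fitted model plus
#'   `method`, `iterations`, `max_moment_error`, `converged`, `tolerance`,
#'   `data_moments` and the per-iteration `error_trace`.
#' @seealso [mem_model()], [model_moments()], [multi_information()]
#' @export
fit_mem <- function(x, method = c("auto", "exact", "pseudolikelihood"),
                    convention = NULL, learning_rate = 0.1,
                    tolerance = 1e-4, max_iter = 20000, init = NULL,
                    exact_limit = 15) {
  method <- match.arg(method)
  if (inherits(x, "moment_set")) {
    if (method == "pseudolikelihood") {
      stop("pseudo-likelihood fitting needs the raster, not just moments")
    }
    return(fit_exact_moments(x, learning_rate, tolerance, max_iter, init))
  }
  r <- as_raster_matrix(x, convention)
  n <- ncol(r$states)
  if (nrow(r$states) < 2) stop("need at least 2 time samples to fit")
  if (method == "auto") {
    method <- if (n <= exact_limit) "exact" else "pseudolikelihood"
  }
  if (method == "exact") {
    fit_exact_moments(empirical_moments(binary_raster(r$states, r$convention)),
                      learning_rate, tolerance, max_iter, init)
  } else {
    fit_pseudolikelihood(binary_raster(r$states, r$convention),
                         learning_rate, tolerance, max_iter, init)
  }
}

# Reject moments on the boundary of the attainable polytope (a unit always
# on/off, or a perfectly correlated pair): the maximum-entropy parameters
# diverge there.
check_moment_interior <- function(target) {
  m <- target$means
  s <- target$second_moments
  if (target$convention == "pm1") v <- 1 - m^2 else v <- m * (1 - m)
  bad <- which(v <= 1e-12)
  if (length(bad)) {
    stop("cluster(s) ", paste(target$labels[bad], collapse = ", "),
         " are constant (boundary moments); lower the binarization ",
         "threshold or merge clusters", call. = FALSE)
  }
  cv <- s - outer(m, m)
  denom <- sqrt(outer(v, v))
  rho <- cv / denom
  diag(rho) <- 0
  bad <- which(abs(rho) >= 1 - 1e-12, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop("clusters ", target$labels[i], " and ", target$labels[j],
         " are perfectly correlated (boundary moments); merge them or ",
         "lower the binarization threshold", call. = FALSE)
  }
  invisible(TRUE)
}

fit_exact_moments <- function(target, learning_rate = 0.1, tolerance = 1e-4,
                              max_iter = 20000, init = NULL) {
  stopifnot(inherits(target, "moment_set"))
  n <- length(target$means)
  check_enumerable(n)
  check_moment_interior(target)
  conv <- target$convention
  if (is.null(init)) {
    h <- rep(0, n); J <- matrix(0, n, n)
  } else {
    stopifnot(inherits(init, "mem"), init$convention == conv,
              init$n_units == n)
    h <- as.numeric(init$h); J <- init$J
  }
  S <- all_states(n, conv)
  tm <- target$means
  ts <- target$second_moments
  lr <- learning_rate
  prev_err <- Inf
  err_trace <- numeric(0)
  err <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    logw <- S %*% h + 0.5 * rowSums((S %*% J) * S)
    logw <- logw - max(logw)
    p <- exp(logw); p <- p / sum(p)
    mm <- as.numeric(crossprod(S, p))
    ms <- crossprod(S, S * as.numeric(p))
    gh <- tm - mm
    gJ <- ts - ms
    gJ <- (gJ + t(gJ)) / 2
    diag(gJ) <- 0
    err <- max(abs(c(gh, upper_tri_vec(gJ))))
    err_trace[iter] <- err
    if (err <= tolerance) break
    if (err > prev_err) lr <- lr * 0.7 else lr <- min(lr * 1.02, learning_rate * 10)
    prev_err <- err
    h <- h + lr * gh
    J <- J + lr * gJ
  }
  new_mem_fit(h, J, conv, target$labels, method = "exact_gradient",
              iterations = iter, max_moment_error = err,
              converged = err <= tolerance, tolerance = tolerance,
              data_moments = target, error_trace = err_trace)
}

fit_pseudolikelihood <- function(raster, learning_rate = 0.1,
                                 tolerance = 1e-4, max_iter = 20000,
                                 init = NULL) {
  stopifnot(inherits(raster, "binary_raster"))
  X <- raster$states
  n <- ncol(X)
  conv <- raster$convention
  target <- empirical_moments(raster)
  check_moment_interior(target)
  # Collapse to unique states with weights: the conditional statistics of
  # Eqs. (10)-(11)-type updates depend on the data only through state counts.
  if (n <= 24) {
    idx <- state_index(X, conv)
    tab <- table(idx)
    uidx <- as.integer(names(tab))
    w <- as.numeric(tab) / length(idx)
    U <- index_to_state(uidx, n, conv)
  } else {
    U <- X
    w <- rep(1 / nrow(X), nrow(X))
  }
  tm <- target$means
  ts <- target$second_moments
  if (is.null(init)) {
    h <- rep(0, n); J <- matrix(0, n, n)
  } else {
    stopifnot(inherits(init, "mem"), init$convention == conv,
              init$n_units == n)
    h <- as.numeric(init$h); J <- init$J
  }
  Uw <- U * w
  lr <- learning_rate
  prev_err <- Inf
  err_trace <- numeric(0)
  err <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    FF <- sweep(U %*% J, 2, h, "+")
    # conditional mean of sigma_i given the rest, per convention:
    # tanh(f) for spins in {-1,+1}, logistic(f) for occupations in {0,1}
    M <- if (conv == "pm1") tanh(FF) else stats::plogis(FF)
    gh <- tm - as.numeric(crossprod(M, w))
    cross <- crossprod(M, Uw)
    gJ <- ts - (cross + t(cross)) / 2
    diag(gJ) <- 0
    err <- max(abs(c(gh, upper_tri_vec(gJ))))
    err_trace[iter] <- err
    if (!is.finite(err)) {
      stop("pseudo-likelihood ascent diverged (non-finite parameters); ",
           "retry with a smaller learning_rate")
    }
    if (err <= tolerance) break
    if (err > prev_err) lr <- lr * 0.7 else lr <- min(lr * 1.05, learning_rate * 20)
    prev_err <- err
    h <- h + lr * gh
    J <- J + lr * gJ
  }
  new_mem_fit(h, J, conv, colnames(X), method = "pseudo_likelihood",
              iterations = iter, max_moment_error = err,
              converged = err <= tolerance, tolerance = tolerance,
              data_moments = target, error_trace = err_trace)
}

new_mem_fit <- function(h, J, convention, labels, ...) {
  m <- mem_model(h, J, convention, labels)
  extras <- list(...)
  m[names(extras)] <- extras
  class(m) <- c("mem_fit", "mem")
  m
}

#' @export
print.mem_fit <- function(x, ...) {
  cat("Fitted pairwise maximum-entropy model (", x$n_units, " units, ",
      x$method, ")\n", sep = "")
  cat(sprintf("  %s after %d iterations; max moment/gradient error %.2e (tol %.0e)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$max_moment_error, x$tolerance))
  invisible(x)
}

#' @export
summary.mem_fit <- function(object, ...) {
  out <- list(
    n_units = object$n_units,
    convention = object$convention,
    method = object$method,
    iterations = object$iterations,
    converged = object$converged,
    max_moment_error = object$max_moment_error,
    h_range = range(object$h),
    J_range = range(upper_tri_vec(object$J)),
    n_samples = object$data_moments$n_samples
  )
  class(out) <- "summary.mem_fit"
  out
}

#' @export
print.summary.mem_fit <- function(x, ...) {
  cat("Pairwise MEM fit summary\n")
  cat(sprintf("  units: %d (%s), samples: %s, method: %s\n", x$n_units,
              x$convention, format(x$n_samples), x$method))
  cat(sprintf("  iterations: %d, converged: %s, max error: %.3e\n",
              x$iterations, x$converged, x$max_moment_error))
  cat(sprintf("  h in [%.3f, %.3f]; J in [%.3f, %.3f]\n",
              x$h_range[1], x$h_range[2], x$J_range[1], x$J_range[2]))
  invisible(x)
}

#' Moment residuals of a fitted model
#'
#' Data moments minus exact model moments; for a converged exact fit every
#' entry is within the fit tolerance.
#'
#' @param object A `"mem_fit"` (requires N <= 20 for enumeration).
#' @param ... Unused.
#' @return List with `means` (length N) and `second_moments` (N x N).
#' @export
residuals.mem_fit <- function(object, ...) {
  mm <- model_moments(object)
  list(means = object$data_moments$means - mm$means,
       second_moments = object$data_moments$second_moments - mm$second_moments)
}

#' Diagnostic plot of a fitted model
#'
#' Scatter of data moments against exact model moments (means and pairwise
#' second moments); a converged fit lies on the identity line.
#'
#' @param x A `"mem_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mem_fit <- function(x, ...) {
  mm <- model_moments(x)
  dm <- x$data_moments
  xs <- c(mm$means, upper_tri_vec(mm$second_moments))
  ys <- c(dm$means, upper_tri_vec(dm$second_moments))
  graphics::plot(xs, ys, xlab = "model moment", ylab = "data moment",
                 pch = c(rep(1, length(mm$means)),
                         rep(3, length(xs) - length(mm$means))), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
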