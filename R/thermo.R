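#' Exact thermodynamic observables by enumeration
#'
#' Under the temperature-scaled Boltzmann distribution
#' \eqn{P(\sigma) \propto e^{-E(\sigma)/T}}, computes the mean and variance
#' of the energy E and of the magnetization \eqn{M = \sum_i \sigma_i}, and
#' the fluctuation-dissipation quantities
#' \deqn{C = \frac{\langle E^2\rangle - \langle E\rangle^2}{T^2}, \qquad
#'       \chi = \frac{\langle M^2\rangle - \langle M\rangle^2}{T}.}
#' The specific heat C measures the sensitivity of the mean energy to
#' temperature; its peak locates the critical temperature.  The
#' susceptibility \eqn{\chi} measures the sensitivity of global activation
#' to a uniform field perturbation.  M is the raw (unnormalized) sum of unit
#' values; divide \eqn{\chi} by N (or M by N) for a per-region version.
#'
#' @param model A `"mem"` object with N <= 20.
#' @param temperature Positive temperature.
#' @return Named list: `mean_E`, `var_E`, `mean_M`, `var_M`, `C`, `chi`.
#' @export
observables_exact <- function(model, temperature = 1) {
  stopifnot(inherits(model, "mem"))
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("temperature must be a positive number")
  }
  p <- state_distribution(model, temperature)
  S <- all_states(model$n_units, model$convention)
  E <- energy(model, S)
  M <- rowSums(S)
  mE <- sum(p * E); vE <- sum(p * E^2) - mE^2
  mM <- sum(p * M); vM <- sum(p * M^2) - mM^2
  list(mean_E = mE, var_E = max(vE, 0), mean_M = mM, var_M = max(vM, 0),
       C = max(vE, 0) / temperature^2, chi = max(vM, 0) / temperature)
}

new_thermo_curve <- function(temperatures, C, chi, M_mean, method,
                             convention, n_units, C_se = NULL,
                             chi_se = NULL, n_samples = NA) {
  structure(list(temperatures = temperatures, C = C, chi = chi,
                 M_mean = M_mean,
                 C_se = if (is.null(C_se)) rep(NA_real_, length(C)) else C_se,
                 chi_se = if (is.null(chi_se)) rep(NA_real_, length(chi)) else chi_se,
                 method = method, convention = convention, n_units = n_units,
                 n_samples = n_samples),
            class = "thermo_curve")
}

#' Exact specific-heat and susceptibility curves
#'
#' @param model A `"mem"` object with N <= 20.
#' @param T_grid Temperature grid (any order; stored as given).  Default
#'   2.0 down to 0.05 in steps of 0.05 (T = 0 is excluded: the Boltzmann
#'   weights degenerate).
#' @return A `"thermo_curve"` with `method = "exact"`.
#' @export
thermo_exact <- function(model, T_grid = seq(2, 0.05, by = -0.05)) {
  T_grid <- check_t_grid(T_grid, require_descending = FALSE)
  obs <- lapply(T_grid, function(Tt) observables_exact(model, Tt))
  new_thermo_curve(T_grid,
                   C = vapply(obs, `[[`, 0.0, "C"),
                   chi = vapply(obs, `[[`, 0.0, "chi"),
                   M_mean = vapply(obs, `[[`, 0.0, "mean_M"),
                   method = "exact", convention = model$convention,
                   n_units = model$n_units)
}

check_t_grid <- function(T_grid, require_descending = TRUE) {
  T_grid <- as.numeric(T_grid)
  if (any(T_grid == 0)) {
    warning("T = 0 excluded from the grid (acceptance degenerates)")
    T_grid <- T_grid[T_grid != 0]
  }
  if (any(T_grid <= 0)) stop("temperatures must be positive")
  if (require_descending && is.unsorted(rev(T_grid), strictly = TRUE)) {
    stop("T_grid must be strictly descending for an annealed sweep")
  }
  T_grid
}

#' Annealed Metropolis sweep over a temperature grid
#'
#' Runs a Metropolis chain at each temperature of a descending grid,
#' seeding each chain with the final state of the previous (warmer)
#' temperature — an annealing schedule that keeps the chain equilibrated as
#' the landscape sharpens.  C and \eqn{\chi} are estimated from the sample
#' variances of energy and magnetization via the fluctuation-dissipation
#' formulas, with Monte-Carlo standard errors from the fourth moment and an
#' AR(1) effective-sample-size correction of the thinned series.
#'
#' Defaults mirror a long production schedule (10^6 steps per temperature
#' after 30000 thermalization steps, retaining every 500th); `scale` shrinks
#' all three proportionally for quick runs (`scale = 0.1` keeps the same
#' number of retained samples at a tenth of the cost).
#'
#' @param model A `"mem"` object (any N; no enumeration involved).
#' @param T_grid Strictly descending positive temperatures (default 2.0 to
#'   0.05 by 0.05).
#' @param n_steps Post-burn-in Metropolis steps per temperature.
#' @param burn_in Thermalization steps per temperature.
#' @param thin Keep every `thin`-th step.
#' @param seed Integer seed (one stream per temperature, derived).
#' @param scale Multiplier applied to `n_steps`, `burn_in` and `thin`.
#' @return A `"thermo_curve"` with `method = "mcmc"` and per-T standard
#'   errors `C_se`, `chi_se`.
#' @export
annealed_sweep <- function(model, T_grid = seq(2, 0.05, by = -0.05),
                           n_steps = 1e6, burn_in = 30000, thin = 500,
                           seed = 1, scale = 1) {
  stopifnot(inherits(model, "mem"))
  T_grid <- check_t_grid(T_grid, require_descending = TRUE)
  n_steps <- max(1, round(n_steps * scale))
  burn_in <- max(0, round(burn_in * scale))
  thin <- max(1, round(thin * scale))
  vals <- convention_values(model$convention)
  state <- with_seed(child_seed(seed, 0),
                     ifelse(stats::runif(model$n_units) < 0.5,
                            vals[["on"]], vals[["off"]]))
  k <- length(T_grid)
  C <- chi <- Mm <- C_se <- chi_se <- numeric(k)
  for (i in seq_len(k)) {
    w <- mcmc_walk(model, n_steps = n_steps, burn_in = burn_in, thin = thin,
                   temperature = T_grid[i], seed = child_seed(seed, i),
                   init = state)
    state <- w$final_state
    eE <- fluct_stat(w$energy)
    eM <- fluct_stat(w$magnetization)
    C[i] <- eE$var / T_grid[i]^2
    C_se[i] <- eE$se_var / T_grid[i]^2
    chi[i] <- eM$var / T_grid[i]
    chi_se[i] <- eM$se_var / T_grid[i]
    Mm[i] <- eM$mean
  }
  new_thermo_curve(T_grid, C, chi, Mm, method = "mcmc",
                   convention = model$convention, n_units = model$n_units,
                   C_se = C_se, chi_se = chi_se,
                   n_samples = length(T_grid) * floor(n_steps / thin))
}

# Population variance of a (possibly autocorrelated) sample plus a
# delta-method standard error: var(v_hat) ~ (m4 - v^2) / n_eff, with n_eff
# from the lag-1 autocorrelation under an AR(1) approximation.
fluct_stat <- function(x) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  v <- mean(d^2)
  m4 <- mean(d^4)
  rho1 <- if (n > 2 && v > 0) {
    sum(d[-1] * d[-n]) / (n - 1) / v
  } else 0
  rho1 <- min(max(rho1, 0), 0.99)
  n_eff <- max(n * (1 - rho1) / (1 + rho1), 2)
  se_var <- sqrt(max(m4 - v^2, 0) / n_eff)
  list(mean = m, var = v, se_var = se_var)
}

#' @export
print.thermo_curve <- function(x, ...) {
  cat("Thermodynamic curve (", x$method, ", ", length(x$temperatures),
      " temperatures, N = ", x$n_units, ", ", x$convention, ")\n", sep = "")
  tr <- locate_transition(x)
  if (!is.na(tr$Tc)) {
    cat(sprintf("  Tc = %.3f, C_peak = %.3f, FWHM = %s\n", tr$Tc, tr$C_peak,
                if (is.na(tr$fwhm)) "undefined" else sprintf("%.3f", tr$fwhm)))
  } else {
    cat("  no interior specific-heat peak on this grid\n")
  }
  invisible(x)
}

#' @export
plot.thermo_curve <- function(x, ...) {
  o <- order(x$temperatures)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$temperatures[o], x$C[o], type = "b", xlab = "T",
                 ylab = "specific heat C", ...)
  graphics::plot(x$temperatures[o], x$chi[o], type = "b", xlab = "T",
                 ylab = expression(chi), ...)
  invisible(x)
}

#' Critical temperature and width of the specific-heat peak
#'
#' The critical temperature is the grid argmax of C, optionally refined by
#' a 3-point quadratic fit through the peak and its neighbors.  The full
#' width at half maximum is found by linear interpolation of the two
#' crossings of `C_peak / 2`; a crossing falling outside the grid is
#' flagged and leaves the FWHM undefined.
#'
#' @param curve A `"thermo_curve"` with at least 5 grid points.
#' @param refine Quadratic peak refinement (default TRUE).
#' @return List: `Tc`, `C_peak`, `fwhm`, `boundary` (TRUE when the argmax
#'   sits on a grid edge; `Tc`/`fwhm` are then NA), `left_crossing`,
#'   `right_crossing` (NA when outside the grid).
#' @export
locate_transition <- function(curve, refine = TRUE) {
  stopifnot(inherits(curve, "thermo_curve"))
  o <- order(curve$temperatures)
  Tv <- curve$temperatures[o]
  Cv <- curve$C[o]
  if (length(Tv) < 5) stop("need at least 5 grid points")
  i <- which.max(Cv)
  if (i == 1L || i == length(Cv) || diff(range(Cv)) == 0) {
    return(list(Tc = NA_real_, C_peak = max(Cv), fwhm = NA_real_,
                boundary = TRUE, left_crossing = NA_real_,
                right_crossing = NA_real_))
  }
  Tc <- Tv[i]; C_peak <- Cv[i]
  if (refine) {
    tt <- Tv[(i - 1):(i + 1)]; cc <- Cv[(i - 1):(i + 1)]
    co <- stats::coef(stats::lm(cc ~ tt + I(tt^2)))
    if (is.finite(co[3]) && co[3] < 0) {
      vx <- -co[2] / (2 * co[3])
      if (vx >= tt[1] && vx <= tt[3]) {
        Tc <- unname(vx)
        C_peak <- unname(co[1] + co[2] * vx + co[3] * vx^2)
      }
    }
  }
  half <- C_peak / 2
  cross <- function(side) {
    idx <- if (side == "left") seq(i, 2) else seq(i, length(Cv) - 1)
    for (j in idx) {
      jj <- if (side == "left") j - 1 else j + 1
      if ((Cv[j] >= half) != (Cv[jj] >= half)) {
        return(Tv[j] + (half - Cv[j]) * (Tv[jj] - Tv[j]) / (Cv[jj] - Cv[j]))
      }
    }
    NA_real_
  }
  lc <- cross("left"); rc <- cross("right")
  list(Tc = Tc, C_peak = C_peak,
       fwhm = if (is.na(lc) || is.na(rc)) NA_real_ else rc - lc,
       boundary = FALSE, left_crossing = lc, right_crossing = rc)
}

#' Virtual resection of one region
#'
#' Removes all couplings of a region (its J row and column set to zero) and
#' recomputes the thermodynamic curves.  The resected region — now a fully
#' decoupled unit — is excluded from the energy and magnetization
#' observables, since an independent spin with a nonzero field would only
#' add a Schottky background term to C that biases between-region
#' comparisons.  (Equivalently, the curves are those of the reduced (N-1)-
#' unit model with the region dropped.)
#'
#' @param model A `"mem"` object.
#' @param region Unit index (1-based) or label.
#' @param T_grid Temperature grid.
#' @param engine `"exact"` (enumeration, N-1 <= 20) or `"mcmc"`
#'   ([annealed_sweep()]).
#' @param intact Optional precomputed intact-model `"thermo_curve"` on the
#'   same grid/engine (avoids recomputation in scans).
#' @param seed,scale,n_steps,burn_in,thin Passed to [annealed_sweep()] for
#'   the mcmc engine.
#' @return Object of class `"mem_resection"`: `region` (label), `strength`
#'   (intact row sum of J for the region), `curve` (resected),
#'   `intact_curve`, `delta_Tc`, `delta_C_peak`, `delta_fwhm`.
#' @export
virtual_resection <- function(model, region, T_grid = seq(2, 0.05, by = -0.05),
                              engine = c("exact", "mcmc"), intact = NULL,
                              seed = 1, scale = 1, n_steps = 1e6,
                              burn_in = 30000, thin = 500) {
  stopifnot(inherits(model, "mem"))
  engine <- match.arg(engine)
  r <- if (is.character(region)) match(region, model$labels) else as.integer(region)
  if (is.na(r) || r < 1 || r > model$n_units) stop("invalid region: ", region)
  reduced <- mem_model(model$h[-r], model$J[-r, -r, drop = FALSE],
                       convention = model$convention,
                       labels = model$labels[-r])
  run <- function(m, k) {
    if (engine == "exact") thermo_exact(m, T_grid)
    else annealed_sweep(m, T_grid, n_steps = n_steps, burn_in = burn_in,
                        thin = thin, seed = child_seed(seed, k), scale = scale)
  }
  if (is.null(intact)) intact <- run(model, 0)
  curve <- run(reduced, r)
  t0 <- locate_transition(intact)
  t1 <- locate_transition(curve)
  structure(list(region = model$labels[r], region_index = r,
                 strength = sum(model$J[r, ]),
                 curve = curve, intact_curve = intact,
                 Tc = t1$Tc, delta_Tc = t1$Tc - t0$Tc,
                 delta_C_peak = t1$C_peak - t0$C_peak,
                 delta_fwhm = t1$fwhm - t0$fwhm),
            class = "mem_resection")
}

#' @export
print.mem_resection <- function(x, ...) {
  cat(sprintf("Virtual resection of %s (strength %.3f):\n", x$region,
              x$strength))
  cat(sprintf("  delta Tc = %s, delta C_peak = %s, delta FWHM = %s\n",
              format(round(x$delta_Tc, 4)), format(round(x$delta_C_peak, 4)),
              format(round(x$delta_fwhm, 4))))
  invisible(x)
}

#' Resect every region in turn
#'
#' One [virtual_resection()] per region against a shared intact curve, plus
#' the summary relation between a region's functional coupling strength
#' (sum of its J row) and its post-resection shift of the critical
#' temperature.
#'
#' @inheritParams virtual_resection
#' @return List: `results` (one `"mem_resection"` per region), `table`
#'   (region, strength, Tc, delta_Tc, delta_C_peak, delta_fwhm),
#'   `cor_strength_dTc` (Pearson) and `cor_strength_dTc_spearman`.
#' @export
resection_scan <- function(model, T_grid = seq(2, 0.05, by = -0.05),
                           engine = c("exact", "mcmc"), seed = 1, scale = 1,
                           n_steps = 1e6, burn_in = 30000, thin = 500) {
  engine <- match.arg(engine)
  intact <- if (engine == "exact") thermo_exact(model, T_grid)
            else annealed_sweep(model, T_grid, n_steps = n_steps,
                                burn_in = burn_in, thin = thin,
                                seed = child_seed(seed, 0), scale = scale)
  results <- lapply(seq_len(model$n_units), function(r) {
    virtual_resection(model, r, T_grid, engine = engine, intact = intact,
                      seed = seed, scale = scale, n_steps = n_steps,
                      burn_in = burn_in, thin = thin)
  })
  tab <- data.frame(
    region = vapply(results, `[[`, "", "region"),
    strength = vapply(results, `[[`, 0.0, "strength"),
    Tc = vapply(results, `[[`, 0.0, "Tc"),
    delta_Tc = vapply(results, `[[`, 0.0, "delta_Tc"),
    delta_C_peak = vapply(results, `[[`, 0.0, "delta_C_peak"),
    delta_fwhm = vapply(results, `[[`, 0.0, "delta_fwhm"),
    stringsAsFactors = FALSE)
  ok <- is.finite(tab$strength) & is.finite(tab$delta_Tc)
  cp <- if (sum(ok) >= 3 && stats::sd(tab$strength[ok]) > 0 &&
            stats::sd(tab$delta_Tc[ok]) > 0) {
    stats::cor(tab$strength[ok], tab$delta_Tc[ok])
  } else NA_real_
  cs <- if (sum(ok) >= 3 && stats::sd(tab$strength[ok]) > 0 &&
            stats::sd(tab$delta_Tc[ok]) > 0) {
    stats::cor(tab$strength[ok], tab$delta_Tc[ok], method = "spearman")
  } else NA_real_
  list(results = results, table = tab, intact_curve = intact,
       cor_strength_dTc = cp, cor_strength_dTc_spearman = cs)
}
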