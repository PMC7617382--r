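#' Metropolis-Hastings random walk on the energy landscape
#'
#' Simulates state dynamics as a single-flip Metropolis chain: from state
#' \eqn{\sigma}, one of the N Hamming-1 neighbors \eqn{\sigma'} is proposed
#' uniformly and accepted with probability
#' \eqn{\min[1, e^{(E(\sigma)-E(\sigma'))/T}]}.  The chain's stationary
#' distribution is the model's Boltzmann distribution at temperature `T`.
#'
#' The RNG draw order (proposal site, then acceptance uniform, always both)
#' is fixed, so walks are bit-reproducible for a given seed.
#'
#' @param model A `"mem"` object.
#' @param n_steps Number of post-burn-in steps.
#' @param burn_in Initial steps discarded as thermalization (default 30000).
#' @param thin Record every `thin`-th post-burn-in step (1 = record all;
#'   transition counting should not thin, as thinning distorts dwell times).
#' @param temperature Positive temperature.
#' @param seed Integer seed.
#' @param init Optional initial state (vector in the model's convention);
#'   default a uniformly random state.
#' @return Object of class `"mem_walk"`: `states` (0-based state indices of
#'   recorded steps), `energy`, `magnetization`, `final_state`,
#'   `acceptance_rate`, and the configuration.
#' @export
mcmc_walk <- function(model, n_steps, burn_in = 30000, thin = 1,
                      temperature = 1, seed = 1, init = NULL) {
  stopifnot(inherits(model, "mem"), n_steps > 0, burn_in >= 0, thin >= 1,
            temperature > 0)
  vals <- convention_values(model$convention)
  n <- model$n_units
  res <- with_seed(seed, {
    if (is.null(init)) {
      init_state <- ifelse(stats::runif(n) < 0.5, vals[["on"]], vals[["off"]])
    } else {
      check_state_values(matrix(init, nrow = 1), model$convention)
      init_state <- as.numeric(init)
    }
    metropolis_walk_cpp(model$h, model$J, init_state,
                        vals[["off"]], vals[["on"]], temperature,
                        n_steps, burn_in, thin)
  })
  structure(list(states = res$states, energy = res$energy,
                 magnetization = res$magnetization,
                 final_state = res$final_state,
                 acceptance_rate = res$acceptance_rate,
                 n_units = n, convention = model$convention,
                 n_steps = n_steps, burn_in = burn_in, thin = thin,
                 temperature = temperature, seed = seed),
            class = "mem_walk")
}

#' @export
print.mem_walk <- function(x, ...) {
  cat("Metropolis walk: ", length(x$states), " recorded steps (",
      x$n_units, " units, T = ", x$temperature, ", thin ", x$thin, ")\n",
      sep = "")
  cat(sprintf("  acceptance rate %.3f\n", x$acceptance_rate))
  invisible(x)
}

#' Map an activity time series to basin labels
#'
#' Each time point's state is looked up in the landscape's steepest-descent
#' basin assignment, giving the basin-level trajectory of the recording.
#'
#' @param x A [binary_raster()], a `"mem_walk"`, or a vector of 0-based
#'   state indices.
#' @param landscape A `"mem_landscape"` from [energy_landscape()].
#' @return Integer vector of basin labels (the minima's 0-based state
#'   indices), one per time point.
#' @export
basin_trajectory <- function(x, landscape) {
  stopifnot(inherits(landscape, "mem_landscape"))
  if (inherits(x, "binary_raster")) {
    if (x$convention != landscape$convention) {
      stop("raster convention does not match the landscape's model")
    }
    idx <- state_index(x$states, x$convention)
  } else if (inherits(x, "mem_walk")) {
    idx <- x$states
  } else {
    idx <- as.integer(x)
  }
  landscape$basin_of_state[idx + 1L]
}

#' Basin dwell times and transition statistics
#'
#' A transition is counted at each time step where the basin label changes;
#' dwell times are run lengths of constant label.  Row-normalized
#' (`p_out`) and column-normalized (`p_in`) transition probabilities follow
#' the convention: transitions out of (into) basin X divided by the total
#' number of transitions out of (into) X.
#'
#' @param labels Basin label series (from [basin_trajectory()]).
#' @param basin_set Optional vector of all basin labels to index the
#'   matrices by (default: the labels observed in the series).
#' @return Object of class `"transition_stats"`: `freq` (counts, zero
#'   diagonal), `p_out`, `p_in`, `dwell_mean`, `dwell_times` (list),
#'   `visits`, `n_time`.
#' @export
transition_stats <- function(labels, basin_set = NULL) {
  stopifnot(length(labels) >= 2)
  if (is.null(basin_set)) basin_set <- sort(unique(labels))
  k <- length(basin_set)
  lab <- factor(labels, levels = basin_set)
  if (anyNA(lab)) stop("series contains basins outside basin_set")
  r <- rle(as.integer(lab))
  freq <- matrix(0, k, k, dimnames = list(basin_set, basin_set))
  if (length(r$values) > 1) {
    from <- r$values[-length(r$values)]
    to <- r$values[-1]
    for (t in seq_along(from)) freq[from[t], to[t]] <- freq[from[t], to[t]] + 1
  }
  dwell <- split(r$lengths, factor(r$values, levels = seq_len(k)))
  names(dwell) <- basin_set
  dwell_mean <- vapply(dwell, function(d) if (length(d)) mean(d) else NA_real_,
                       0.0)
  visits <- vapply(dwell, length, 0L)
  out_tot <- rowSums(freq)
  in_tot <- colSums(freq)
  p_out <- sweep(freq, 1, ifelse(out_tot > 0, out_tot, NA), "/")
  p_in <- sweep(freq, 2, ifelse(in_tot > 0, in_tot, NA), "/")
  structure(list(freq = freq, p_out = p_out, p_in = p_in,
                 dwell_mean = dwell_mean, dwell_times = dwell,
                 visits = visits, n_time = length(labels),
                 basin_set = basin_set),
            class = "transition_stats")
}

#' @export
print.transition_stats <- function(x, ...) {
  cat("Transition statistics over ", length(x$basin_set), " basins, ",
      x$n_time, " time points, ", sum(x$freq), " transitions\n", sep = "")
  invisible(x)
}

#' Compare empirical and simulated basin transition frequencies
#'
#' Rescales the simulated counts to the empirical total and regresses the
#' empirical off-diagonal counts on the simulated ones; a good landscape
#' model of the dynamics gives slope near 1 and high R-squared.
#'
#' @param empirical,simulated `"transition_stats"` over the same basin set.
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n_pairs`,
#'   `reliable` (FALSE when fewer than 3 pairs are nonzero in either),
#'   `table` (per-pair scatter data).
#' @export
compare_transitions <- function(empirical, simulated) {
  stopifnot(inherits(empirical, "transition_stats"),
            inherits(simulated, "transition_stats"))
  if (!identical(empirical$basin_set, simulated$basin_set)) {
    stop("transition statistics must share the same basin set")
  }
  od <- row(empirical$freq) != col(empirical$freq)
  emp <- empirical$freq[od]
  sim <- simulated$freq[od]
  scale <- if (sum(sim) > 0) sum(emp) / sum(sim) else NA_real_
  sim_scaled <- sim * scale
  tab <- data.frame(
    from = rep(empirical$basin_set, times = length(empirical$basin_set))[od],
    to = rep(empirical$basin_set, each = length(empirical$basin_set))[od],
    empirical = emp, simulated = sim, simulated_scaled = sim_scaled)
  reliable <- sum(emp > 0 | sim > 0) >= 3 && stats::var(sim_scaled) > 0 &&
    stats::var(emp) > 0
  if (reliable) {
    fit <- stats::lm(emp ~ sim_scaled)
    slope <- stats::coef(fit)[2]
    icpt <- stats::coef(fit)[1]
    rho <- stats::cor(emp, sim_scaled)
    r2 <- rho^2
    # slope test in simple regression = correlation test
    df <- length(emp) - 2
    tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
    pv <- 2 * stats::pt(-abs(tstat), df)
  } else {
    slope <- icpt <- r2 <- pv <- NA_real_
  }
  list(slope = unname(slope), intercept = unname(icpt),
       r_squared = unname(r2), p_value = unname(pv),
       n_pairs = sum(od), reliable = reliable, table = tab)
}

#' Basin size versus dwell time
#'
#' Fits the exponential relation dwell ~ exp(a + b * size) by regressing
#' log mean dwell time on basin size (fraction of state space), over basins
#' actually visited.
#'
#' @param stats A `"transition_stats"`.
#' @param landscape The `"mem_landscape"` the basins came from.
#' @return List: `intercept`, `slope`, `r_squared`, `n_basins`, `reliable`
#'   (FALSE with fewer than 3 usable basins), `table`.
#' @export
dwell_size_relation <- function(stats, landscape) {
  stopifnot(inherits(stats, "transition_stats"),
            inherits(landscape, "mem_landscape"))
  sizes <- landscape$basin_sizes[match(stats$basin_set,
                                       landscape$minima)]
  usable <- which(stats$visits > 0 & !is.na(sizes) & stats$dwell_mean > 0)
  tab <- data.frame(basin = stats$basin_set[usable],
                    size = sizes[usable],
                    dwell_mean = stats$dwell_mean[usable])
  if (length(usable) < 3) {
    return(list(intercept = NA_real_, slope = NA_real_, r_squared = NA_real_,
                n_basins = length(usable), reliable = FALSE, table = tab))
  }
  fit <- stats::lm(log(dwell_mean) ~ size, data = tab)
  r2 <- if (stats::var(tab$size) > 0 && stats::var(log(tab$dwell_mean)) > 0) {
    stats::cor(tab$size, log(tab$dwell_mean))^2
  } else NA_real_
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r_squared = r2,
       n_basins = length(usable), reliable = TRUE, table = tab)
}
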