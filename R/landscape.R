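#' Exhaustive energy-landscape decomposition
#'
#' Builds the full landscape over all `2^N` activity states: per-state
#' energies, local minima (attractor states), and basins of attraction.
#' Two states are neighbors when they differ in exactly one unit (Hamming
#' distance 1).  A state is a local minimum iff its energy is strictly lower
#' than all N neighbors'.  Basins are found by steepest descent: from each
#' state, repeatedly move to the lowest-energy neighbor (ties broken toward
#' the smallest state index) until a minimum is reached.
#'
#' Energies are evaluated at the fitted scale (T = 1); temperature only
#' rescales probabilities, not the landscape itself.
#'
#' Degenerate ties are handled deterministically and reported: a state with
#' an equal-energy neighbor and no strictly lower one is not a minimum; such
#' "plateau" states are assigned to the basin of the smallest-index
#' equal-energy neighbor already assigned, falling back to the deepest
#' minimum.  They are listed in the `plateau_states` element.
#'
#' @param model A `"mem"` object with `n_units <= 20`.
#' @return Object of class `"mem_landscape"`: `energies` (length `2^N`,
#'   element `s + 1` for state index `s`), `minima` (0-based indices,
#'   ordered by energy), `minima_energies`, `basin_of_state` (label = the
#'   minimum's state index, per state), `basin_sizes` (fractions, named by
#'   minimum, summing to 1), `plateau_states`, `flat` (TRUE when no strict
#'   minimum exists), `convention`, `n_units`.
#' @seealso [disconnectivity()], [basin_trajectory()]
#' @export
energy_landscape <- function(model) {
  stopifnot(inherits(model, "mem"))
  n <- model$n_units
  check_enumerable(n)
  ns <- 2L^n
  E <- energy(model, all_states(n, model$convention))
  idx0 <- 0:(ns - 1L)
  nbr <- vapply(seq_len(n),
                function(j) bitwXor(idx0, bitwShiftL(1L, j - 1L)),
                integer(ns))
  nbr <- matrix(nbr, ncol = n)
  En <- matrix(E[nbr + 1L], ns, n)
  minE <- do.call(pmin, as.data.frame(En))
  is_min <- E < minE
  minima <- idx0[is_min]
  if (length(minima) == 0L) {
    warning("flat landscape: no strict local minimum exists")
    return(structure(list(energies = E, minima = integer(0),
                          minima_energies = numeric(0),
                          basin_of_state = rep(NA_integer_, ns),
                          basin_sizes = numeric(0),
                          plateau_states = integer(0), flat = TRUE,
                          convention = model$convention, n_units = n),
                     class = "mem_landscape"))
  }
  # steepest neighbor, ties toward smallest state index
  cand <- En == minE
  nbr_masked <- nbr
  nbr_masked[!cand] <- NA_integer_
  ptr <- do.call(pmin, c(as.data.frame(nbr_masked), list(na.rm = TRUE)))
  plateau <- !is_min & !(minE < E)  # tied with best neighbor, none lower
  ord <- order(E, idx0)
  basin <- rep(NA_integer_, ns)
  deepest <- minima[which.min(E[minima + 1L])]
  for (pos in ord) {
    s <- pos - 1L
    if (is_min[pos]) {
      basin[pos] <- s
    } else if (!plateau[pos]) {
      basin[pos] <- basin[ptr[pos] + 1L]  # strictly lower, already assigned
    } else {
      eq <- nbr[pos, ][En[pos, ] == E[pos]]
      eq <- eq[!is.na(basin[eq + 1L])]
      basin[pos] <- if (length(eq)) basin[min(eq) + 1L] else deepest
    }
  }
  minima <- minima[order(E[minima + 1L], minima)]
  sizes <- as.numeric(table(factor(basin, levels = minima))) / ns
  names(sizes) <- minima
  structure(list(energies = E, minima = minima,
                 minima_energies = E[minima + 1L],
                 basin_of_state = basin, basin_sizes = sizes,
                 plateau_states = idx0[plateau], flat = FALSE,
                 convention = model$convention, n_units = n),
            class = "mem_landscape")
}

#' @export
print.mem_landscape <- function(x, ...) {
  cat("Energy landscape over ", 2^x$n_units, " states (N = ", x$n_units,
      ")\n", sep = "")
  if (x$flat) {
    cat("  flat: no strict local minima\n")
  } else {
    cat("  ", length(x$minima), " local minima; basin sizes ",
        paste(sprintf("%.3f", utils::head(x$basin_sizes, 8)), collapse = " "),
        if (length(x$minima) > 8) " ..." else "", "\n", sep = "")
    if (length(x$plateau_states)) {
      cat("  ", length(x$plateau_states),
          " plateau state(s) assigned by tie rule\n", sep = "")
    }
  }
  invisible(x)
}

#' Saddle states, energy barriers and disconnectivity structure
#'
#' Finds, for every pair of local minima, the saddle energy: the energy of
#' the state whose removal first disconnects the pair when states are
#' deleted from the landscape graph in order of decreasing energy (ties
#' deleted larger-index first).  This is computed by the equivalent reverse
#' process — adding states in order of increasing energy under union-find
#' and recording the energy at which two minima's components merge — which
#' yields the minimax connection energy over all Hamming paths.
#'
#' The asymmetric barrier from minimum a toward b is
#' `saddle(a, b) - E(a)`; the symmetric barrier is the smaller of the two
#' asymmetric barriers.
#'
#' @param landscape A `"mem_landscape"` with at least one minimum.
#' @return Object of class `"mem_disconnectivity"`: `saddle_energy`
#'   (symmetric K x K, NA diagonal), `barrier_asym` (`[a, b]` = barrier from
#'   a toward b), `barrier_sym`, `minima`, `minima_energies`, and
#'   `merge_tree`, a nested list (leaves = minima, internal nodes = merge
#'   energies) suitable for JSON export and dendrogram plotting.  With a
#'   single minimum the matrices are empty 1 x 1 NA and the tree is the
#'   single leaf.
#' @export
disconnectivity <- function(landscape) {
  stopifnot(inherits(landscape, "mem_landscape"))
  if (landscape$flat) stop("flat landscape has no minima")
  minima <- landscape$minima
  k <- length(minima)
  E <- landscape$energies
  n <- landscape$n_units
  ns <- 2L^n
  lab <- as.character(minima)
  saddle <- matrix(NA_real_, k, k, dimnames = list(lab, lab))
  trees <- vector("list", ns)
  for (m in seq_len(k)) {
    trees[[minima[m] + 1L]] <- list(minimum = minima[m],
                                    energy = landscape$minima_energies[m])
  }
  if (k == 1L) {
    return(structure(list(saddle_energy = saddle, barrier_asym = saddle,
                          barrier_sym = saddle, minima = minima,
                          minima_energies = landscape$minima_energies,
                          merge_tree = trees[[minima[1] + 1L]]),
                     class = "mem_disconnectivity"))
  }
  idx0 <- 0:(ns - 1L)
  nbr <- vapply(seq_len(n),
                function(j) bitwXor(idx0, bitwShiftL(1L, j - 1L)),
                integer(ns))
  nbr <- matrix(nbr, ncol = n)
  # union-find over 1-based state positions
  parent <- seq_len(ns)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  minset <- vector("list", ns)  # minima positions carried by each root
  pos_of_min <- match(minima, idx0)
  for (m in seq_len(k)) minset[[pos_of_min[m]]] <- m
  active <- logical(ns)
  add_order <- order(E, idx0)  # increasing energy, ties smaller index first
  for (pos in add_order) {
    active[pos] <- TRUE
    for (q in nbr[pos, ] + 1L) {
      if (!active[q]) next
      ra <- find_root(pos); rb <- find_root(q)
      if (ra == rb) next
      ma <- minset[[ra]]; mb <- minset[[rb]]
      if (length(ma) && length(mb)) {
        for (a in ma) for (b in mb) {
          saddle[a, b] <- saddle[b, a] <- E[pos]
        }
        node <- list(energy = E[pos],
                     children = list(trees[[ra]], trees[[rb]]))
      } else if (length(ma)) {
        node <- trees[[ra]]
      } else {
        node <- trees[[rb]]
      }
      parent[ra] <- rb
      minset[rb] <- list(c(ma, mb))
      minset[ra] <- list(integer(0))
      trees[rb] <- list(node)
    }
  }
  emin <- landscape$minima_energies
  basym <- saddle - matrix(emin, k, k)            # [a, b]: saddle - E(a)
  bsym <- pmin(basym, t(basym))
  dimnames(basym) <- dimnames(bsym) <- list(lab, lab)
  root <- find_root(pos_of_min[1])
  structure(list(saddle_energy = saddle, barrier_asym = basym,
                 barrier_sym = bsym, minima = minima,
                 minima_energies = emin,
                 merge_tree = trees[[root]]),
            class = "mem_disconnectivity")
}

#' @export
print.mem_disconnectivity <- function(x, ...) {
  k <- length(x$minima)
  cat("Disconnectivity structure over ", k, " minima\n", sep = "")
  if (k > 1) {
    ut <- x$barrier_sym[upper.tri(x$barrier_sym)]
    cat(sprintf("  symmetric barriers in [%.3f, %.3f]\n", min(ut), max(ut)))
  }
  invisible(x)
}

#' Per-minimum landscape summary table
#'
#' @param landscape A `"mem_landscape"`.
#' @param dg Optional `"mem_disconnectivity"`; adds symmetric-barrier
#'   columns (one per other minimum).
#' @return A data.frame with one row per local minimum: `minimum` (state
#'   index), `state` (bit string, cluster 1 first), `energy`, `basin_size`,
#'   and barrier columns when `dg` is given.
#' @export
landscape_summary <- function(landscape, dg = NULL) {
  stopifnot(inherits(landscape, "mem_landscape"))
  minima <- landscape$minima
  bits <- index_to_state(minima, landscape$n_units, "01")
  tab <- data.frame(
    minimum = minima,
    state = apply(bits, 1, paste, collapse = ""),
    energy = landscape$minima_energies,
    basin_size = as.numeric(landscape$basin_sizes),
    stringsAsFactors = FALSE)
  if (!is.null(dg)) {
    stopifnot(identical(dg$minima, minima))
    bs <- dg$barrier_sym
    colnames(bs) <- paste0("barrier_", dg$minima)
    tab <- cbind(tab, as.data.frame(bs, row.names = NULL))
  }
  tab
}
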