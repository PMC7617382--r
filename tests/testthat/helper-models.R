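# Shared fixtures: small hand-built models and independent oracles.

# uniform ferromagnet, h = 0, J_ij = j0 for all pairs
ferromagnet <- function(n, j0 = 0.4, convention = "pm1") {
  J <- matrix(j0, n, n)
  diag(J) <- 0
  mem_model(rep(0, n), J, convention)
}

# independent spins (J = 0)
independent_model <- function(h, convention = "pm1") {
  mem_model(h, matrix(0, length(h), length(h)), convention)
}

# random small model with bounded parameters, deterministic in seed
random_model <- function(n, seed, h_max = 1, j_max = 0.5,
                         convention = "pm1") {
  set.seed(seed)
  J <- matrix(0, n, n)
  J[upper.tri(J)] <- stats::runif(n * (n - 1) / 2, -j_max, j_max)
  J <- J + t(J)
  mem_model(stats::runif(n, -h_max, h_max), J, convention)
}

# Independent minimax-path oracle for saddle energies: on the Hamming graph
# with edge weight max(E_u, E_v), the minimax connection value between two
# minima equals the maximum edge weight on their path in a minimum spanning
# tree.  This is a different route than the package's union-find sweep.
saddle_oracle <- function(model) {
  skip_if_not_installed("igraph")
  n <- model$n_units
  ns <- 2L^n
  E <- energy(model, all_states(n, model$convention))
  a_all <- integer(0); b_all <- integer(0)
  for (j in seq_len(n)) {
    a <- 0:(ns - 1L)
    b <- bitwXor(a, bitwShiftL(1L, j - 1L))
    keep <- a < b
    a_all <- c(a_all, a[keep]); b_all <- c(b_all, b[keep])
  }
  g <- igraph::graph_from_edgelist(cbind(a_all + 1L, b_all + 1L),
                                   directed = FALSE)
  igraph::E(g)$weight <- pmax(E[a_all + 1L], E[b_all + 1L])
  mst <- igraph::mst(g)
  ls <- energy_landscape(model)
  k <- length(ls$minima)
  saddle <- matrix(NA_real_, k, k)
  if (k >= 2) {
    for (x in 1:(k - 1)) for (y in (x + 1):k) {
      ep <- igraph::shortest_paths(mst, from = ls$minima[x] + 1L,
                                   to = ls$minima[y] + 1L, weights = NA,
                                   output = "epath")$epath[[1]]
      saddle[x, y] <- saddle[y, x] <- max(igraph::E(mst)$weight[ep])
    }
  }
  list(minima = ls$minima, saddle = saddle)
}
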