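#' @useDynLib memland, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run code under a fixed seed without disturbing the caller's RNG stream.
# All stochastic operations in the package route through this, so no function
# mutates global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a user seed, kept inside 32-bit
# integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 7919) %% 2147483647)
}

#' Conventions for binary states
#'
#' Two encodings of an on/off state are supported throughout the package:
#' `"pm1"` (spins in \{-1, +1\}) and `"01"` (occupation numbers in \{0, 1\}).
#' The two parameterizations of the same distribution are interconvertible
#' with [convert_convention()].
#'
#' @param convention Character, `"pm1"` or `"01"`.
#' @return The matched convention string.
#' @keywords internal
match_convention <- function(convention) {
  match.arg(convention, c("pm1", "01"))
}

convention_values <- function(convention) {
  if (convention == "pm1") c(off = -1, on = 1) else c(off = 0, on = 1)
}

# Check a state matrix uses exactly the values of its declared convention.
check_state_values <- function(states, convention) {
  vals <- convention_values(convention)
  u <- unique(as.vector(states))
  if (!all(u %in% vals)) {
    stop("states contain values ", paste(setdiff(u, vals), collapse = ", "),
         " not allowed in convention '", convention, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Enumerate all binary states of an N-unit system
#'
#' State index `s` (0-based, `0 .. 2^N - 1`) encodes cluster `j` in bit
#' `j - 1`: cluster 1 is the least significant bit.  This ordering is fixed
#' so state indices are reproducible across functions and exports.
#'
#' @param n_units Number of binary units (N <= 20).
#' @param convention State encoding, see [match_convention()].
#' @return A `2^N x N` matrix; row `s + 1` is state `s`.
#' @examples
#' all_states(2, "01")
#' @export
all_states <- function(n_units, convention = "pm1") {
  convention <- match_convention(convention)
  check_enumerable(n_units)
  idx <- 0:(2^n_units - 1)
  bits <- vapply(seq_len(n_units),
                 function(j) bitwAnd(bitwShiftR(idx, j - 1L), 1L),
                 integer(length(idx)))
  bits <- matrix(bits, ncol = n_units)
  vals <- convention_values(convention)
  out <- matrix(vals[["off"]], nrow = nrow(bits), ncol = n_units)
  out[bits == 1L] <- vals[["on"]]
  out
}

check_enumerable <- function(n_units) {
  if (n_units > 20) {
    stop("exhaustive enumeration over 2^N states is limited to N <= 20 (got N = ",
         n_units, "); use Metropolis sampling instead", call. = FALSE)
  }
  invisible(TRUE)
}

#' Map state rows to state indices
#'
#' @param states Matrix of states (rows) in either convention.
#' @param convention State encoding of `states`.
#' @return Integer vector of 0-based state indices (cluster 1 = least
#'   significant bit).
#' @export
state_index <- function(states, convention = "pm1") {
  convention <- match_convention(convention)
  states <- as.matrix(states)
  on <- convention_values(convention)[["on"]]
  bits <- states == on
  pow <- 2^(seq_len(ncol(states)) - 1)
  as.integer(bits %*% pow)
}

#' Decode state indices into state rows
#'
#' @param idx 0-based state indices.
#' @param n_units Number of units.
#' @param convention Target encoding.
#' @return Matrix with one decoded state per row.
#' @export
index_to_state <- function(idx, n_units, convention = "pm1") {
  convention <- match_convention(convention)
  bits <- vapply(seq_len(n_units),
                 function(j) bitwAnd(bitwShiftR(as.integer(idx), j - 1L), 1L),
                 integer(length(idx)))
  bits <- matrix(bits, ncol = n_units)
  vals <- convention_values(convention)
  out <- matrix(vals[["off"]], nrow = nrow(bits), ncol = n_units)
  out[bits == 1L] <- vals[["on"]]
  out
}

upper_tri_vec <- function(m) m[upper.tri(m)]

off_diag_vec <- function(m) m[row(m) != col(m)]

# Entropy (nats) of a probability vector; 0 log 0 = 0.
entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

nats_to_bits <- function(x) x / log(2)

# %.17g round-trips doubles exactly through text.
format_full <- function(x) sprintf("%.17g", x)

write_matrix_csv <- function(m, path, col_names = NULL, row_names = NULL) {
  m <- as.matrix(m)
  ch <- matrix(format_full(m), nrow = nrow(m))
  df <- as.data.frame(ch, stringsAsFactors = FALSE)
  if (!is.null(col_names)) names(df) <- col_names
  if (!is.null(row_names)) df <- cbind(label = row_names, df)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = !is.null(col_names) || !is.null(row_names))
  invisible(path)
}

read_matrix_csv <- function(path, has_header = FALSE, has_labels = FALSE) {
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (has_labels) {
    labs <- df[[1]]
    df <- df[, -1, drop = FALSE]
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    rownames(m) <- labs
  } else {
    m <- as.matrix(df)
    storage.mode(m) <- "double"
  }
  m
}
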