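#' @importFrom rlang abort warn inform %||%
#' @importFrom stats cor var sd quantile rnorm runif rbinom rbeta pf pt qnorm
#' @importFrom utils head
NULL

# Canonical upper-triangle edge order: column-major over i < j (1-based matrix
# indices), i.e. (1,2), (1,3), (2,3), (1,4), ... Exposed node ids are 0-based.
edge_index <- function(n_nodes) {
  idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  ord <- order(idx[, 2L], idx[, 1L])
  tibble::tibble(
    edge = seq_len(nrow(idx)),
    node_i = idx[ord, 1L] - 1L,
    node_j = idx[ord, 2L] - 1L
  )
}

# rows of `pairs` are 0-based (i, j) with i < j; returns positions in the
# canonical upper-triangle vectorization of an n_nodes x n_nodes matrix
edge_positions <- function(pairs, n_nodes) {
  i <- pairs[, 1L] + 1L
  j <- pairs[, 2L] + 1L
  stopifnot(all(i < j), all(j <= n_nodes))
  # column-major count of upper-triangle cells before column j is (j-1)(j-2)/2
  as.integer((j - 1L) * (j - 2L) / 2L + i)
}

upper_tri_values <- function(m) m[upper.tri(m)]

# rebuild a symmetric zero-diagonal matrix from its upper-triangle vector
matrix_from_upper <- function(v, n_nodes) {
  m <- matrix(0, n_nodes, n_nodes)
  m[upper.tri(m)] <- v
  m + t(m)
}

check_positive_int <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x)) {
    abort(sprintf("`%s` must be a single positive integer, got %s",
                  name, paste(format(x), collapse = ", ")))
  }
  as.integer(x)
}

# derive a stream-specific 32-bit seed from a base seed
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + stream * 1009L) %% 2147483647L
}
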