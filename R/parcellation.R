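#' Generate a synthetic brain parcellation
#'
#' Creates a node table emulating a whole-brain parcellation in which every
#' region of interest (ROI) is pre-assigned to one of a fixed set of
#' large-scale networks (default 13, as in the 264-node scheme the pipeline
#' targets). Coordinates are placed on a sphere of roughly head size and are
#' used only for reports.
#'
#' @param n_nodes Number of ROIs (nodes). Must be at least `n_networks`.
#' @param n_networks Number of large-scale networks; every network is
#'   guaranteed at least one node.
#' @param seed Integer seed; the assignment is reproducible.
#'
#' @return A tibble of class `parcellation` with columns `node_id` (0-based),
#'   `label`, `network`, and MNI-like coordinates `x`, `y`, `z` (mm).
#' @export
#' @examples
#' p <- make_parcellation(60, 13, seed = 1)
#' dplyr::count(p, network)
make_parcellation <- function(n_nodes, n_networks, seed = 1L) {
  n_nodes <- check_positive_int(n_nodes, "n_nodes")
  n_networks <- check_positive_int(n_networks, "n_networks")
  if (n_networks > n_nodes) {
    abort("`n_networks` must not exceed `n_nodes`")
  }
  networks <- network_names(n_networks)
  withr::with_seed(seed, {
    # one node per network first, remainder assigned at random
    assignment <- c(
      seq_len(n_networks),
      sample(n_networks, n_nodes - n_networks, replace = TRUE)
    )
    assignment <- assignment[sample.int(n_nodes)]
    # points on a sphere of radius ~70 mm (cosmetic, report-only)
    u <- rnorm(n_nodes); v <- rnorm(n_nodes); w <- rnorm(n_nodes)
    r <- sqrt(u^2 + v^2 + w^2)
    out <- tibble::tibble(
      node_id = seq_len(n_nodes) - 1L,
      label = sprintf("ROI_%03d", seq_len(n_nodes) - 1L),
      network = networks[assignment],
      x = 70 * u / r, y = 70 * v / r, z = 70 * w / r
    )
  })
  class(out) <- c("parcellation", class(out))
  out
}

network_names <- function(n_networks) {
  pool <- c(
    "default_mode", "frontoparietal", "dorsal_attention", "ventral_attention",
    "salience", "cingulo_opercular", "visual", "auditory", "somatomotor_hand",
    "somatomotor_mouth", "subcortical", "memory_retrieval", "cerebellum",
    "uncertain"
  )
  if (n_networks <= length(pool)) pool[seq_len(n_networks)]
  else c(pool, sprintf("network_%02d", seq_len(n_networks - length(pool))))
}
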