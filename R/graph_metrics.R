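#' Node strengths of a masked signed connectome
#'
#' For every node of the annotated component: positive strength (sum of
#' positive incident weights), negative strength (magnitude of the sum of
#' negative incident weights), and total strength (their sum).
#'
#' @param masked A [mask_connectome()] result (or any [connectome()] with a
#'   `component_nodes` attribute; absent that, all nodes are used).
#' @return A tibble: `node_id` (0-based), `pos_strength`, `neg_strength`,
#'   `total_strength`.
#' @export
node_strengths <- function(masked) {
  m <- unclass(masked)
  nodes <- attr(masked, "component_nodes") %||% (seq_len(nrow(m)) - 1L)
  sub <- m[nodes + 1L, nodes + 1L, drop = FALSE]
  pos <- rowSums(pmax(sub, 0))
  neg <- rowSums(-pmin(sub, 0))
  tibble::tibble(node_id = as.integer(nodes), pos_strength = pos,
                 neg_strength = neg, total_strength = pos + neg)
}

#' Fractional strength
#'
#' The ratio of the sum of positive to negative link weights, at node or
#' whole-graph level; the balance metric carried into the regression and
#' mediation stages on the natural-log scale. When the negative sum is zero
#' the ratio is undefined and returned as `NA` with a warning, so affected
#' subjects propagate as missing (never as zero) downstream.
#'
#' @param masked A masked [connectome()].
#' @param level `"graph"` (default) or `"node"`.
#' @return For `"graph"`: a list with `fractional_strength`,
#'   `log_fractional_strength`, `pos_sum`, `neg_sum`. For `"node"`: a
#'   tibble with `node_id`, `fractional_strength`, `log_fractional_strength`.
#' @export
fractional_strength <- function(masked, level = c("graph", "node")) {
  level <- match.arg(level)
  ns <- node_strengths(masked)
  if (level == "node") {
    undef <- ns$neg_strength == 0
    if (any(undef)) {
      warn(sprintf("fractional strength undefined (no negative links) at %d node(s)",
                   sum(undef)))
    }
    fs <- ifelse(undef, NA_real_, ns$pos_strength / ns$neg_strength)
    return(tibble::tibble(node_id = ns$node_id, fractional_strength = fs,
                          log_fractional_strength = log(fs)))
  }
  pos_sum <- sum(ns$pos_strength) / 2
  neg_sum <- sum(ns$neg_strength) / 2
  if (neg_sum == 0) {
    warn("graph fractional strength undefined: no negative links in mask")
    return(list(fractional_strength = NA_real_,
                log_fractional_strength = NA_real_,
                pos_sum = pos_sum, neg_sum = neg_sum))
  }
  fs <- pos_sum / neg_sum
  list(fractional_strength = fs, log_fractional_strength = log(fs),
       pos_sum = pos_sum, neg_sum = neg_sum)
}

#' Weighted betweenness centrality
#'
#' The fraction of all shortest paths in the component that pass through a
#' node. Edge lengths are `1 / |w|` on absolute weights (signed shortest
#' path semantics are ill-defined, so the sign carries no meaning here);
#' ties among equally short paths are split fractionally. Values are
#' normalized by `(n - 1)(n - 2)` over ordered node pairs, so the middle
#' node of a 3-node path scores exactly 1. Components with fewer than 3
#' nodes score 0 everywhere.
#'
#' @param masked A masked [connectome()].
#' @return A tibble: `node_id` (0-based), `betweenness`.
#' @export
betweenness_centrality <- function(masked) {
  m <- unclass(masked)
  nodes <- attr(masked, "component_nodes") %||% (seq_len(nrow(m)) - 1L)
  n <- length(nodes)
  if (n < 3L) {
    return(tibble::tibble(node_id = as.integer(nodes), betweenness = 0))
  }
  sub <- abs(m[nodes + 1L, nodes + 1L, drop = FALSE])
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                           weighted = TRUE)
  bc <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                            directed = FALSE, normalized = FALSE)
  tibble::tibble(node_id = as.integer(nodes),
                 betweenness = 2 * as.numeric(bc) / ((n - 1) * (n - 2)))
}

#' All graph metrics of a masked connectome, tidily
#'
#' Combines node strengths, node and graph fractional strength, and
#' betweenness centrality into one long table matching the pipeline's
#' metrics output format: graph-level rows use `node_id = "GRAPH"`.
#'
#' @param masked A masked [connectome()].
#' @param component_id Identifier recorded in the output (default the
#'   mask's `component_index` or 1).
#' @return A tibble: `subject_id`, `component_id`, `node_id` (character;
#'   `"GRAPH"` for graph-level rows), `metric`, `value`.
#' @export
graph_metrics <- function(masked, component_id = NULL) {
  component_id <- component_id %||% attr(masked, "component_index") %||% 1L
  subject_id <- attr(masked, "subject_id") %||% NA_character_
  ns <- node_strengths(masked)
  fs_node <- withCallingHandlers(
    fractional_strength(masked, "node"),
    warning = function(w) invokeRestart("muffleWarning")
  )
  fs_graph <- withCallingHandlers(
    fractional_strength(masked, "graph"),
    warning = function(w) invokeRestart("muffleWarning")
  )
  bc <- betweenness_centrality(masked)
  node_long <- dplyr::bind_rows(
    tidyr::pivot_longer(ns, -"node_id", names_to = "metric", values_to = "value"),
    tidyr::pivot_longer(fs_node, -"node_id", names_to = "metric", values_to = "value"),
    tidyr::pivot_longer(bc, -"node_id", names_to = "metric", values_to = "value")
  )
  node_long$node_id <- as.character(node_long$node_id)
  graph_long <- tibble::tibble(
    node_id = "GRAPH",
    metric = c("pos_sum", "neg_sum", "total_sum", "fractional_strength",
               "log_fractional_strength"),
    value = c(fs_graph$pos_sum, fs_graph$neg_sum,
              fs_graph$pos_sum + fs_graph$neg_sum,
              fs_graph$fractional_strength, fs_graph$log_fractional_strength)
  )
  dplyr::bind_cols(
    tibble::tibble(subject_id = subject_id, component_id = component_id),
    dplyr::bind_rows(node_long, graph_long)
  )
}
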