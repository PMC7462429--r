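#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline
#'   geom_tile geom_col labs facet_wrap scale_fill_gradient2 theme_minimal
#' @export
ggplot2::autoplot

#' Plot an NBS permutation null distribution
#'
#' Histogram of the null maximal component sizes with the observed
#' component sizes overlaid as vertical lines (dashed when not
#' FWE-significant).
#'
#' @param object An [nbs_test()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nbs_result
#' @export
autoplot.nbs_result <- function(object, ...) {
  null_df <- tibble::tibble(max_size = object$null_max_sizes)
  p <- ggplot(null_df, aes(x = .data$max_size)) +
    geom_histogram(binwidth = 1, fill = "grey60", colour = "white") +
    labs(x = "null maximal component size (edges)", y = "permutations",
         title = sprintf("NBS null, contrast %s (T = %.2f)",
                         object$contrast, object$T)) +
    theme_minimal()
  if (length(object$components)) {
    obs <- tidy(object)
    p <- p + geom_vline(data = obs,
                        aes(xintercept = .data$size,
                            linetype = .data$significant),
                        colour = "firebrick") +
      ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                                `FALSE` = "dashed"),
                                     name = "FWE significant")
  }
  p
}

#' Heatmap of varimax-rotated loadings
#'
#' @param object A [fit_pca_varimax()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot component_model
#' @export
autoplot.component_model <- function(object, ...) {
  long <- tidy(object)
  ggplot(long, aes(x = .data$component, y = .data$item,
                   fill = .data$loading)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white",
                         high = "firebrick", limits = c(-1, 1)) +
    facet_wrap(~cluster, scales = "free") +
    labs(x = NULL, y = NULL, title = "Varimax-rotated component loadings") +
    theme_minimal()
}

#' Bar chart of mediation path coefficients
#'
#' @param object A [mediate()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mediation_result
#' @export
autoplot.mediation_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$term, y = .data$estimate)) +
    geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.2, na.rm = TRUE) +
    labs(x = "path", y = "standardized estimate",
         title = sprintf("Mediation paths (indirect = %.3f)", object$indirect)) +
    theme_minimal()
}

#' Node strength profile of a masked component
#'
#' @param metrics A [graph_metrics()] tibble (one or many subjects).
#' @return A ggplot of subject-averaged node strengths.
#' @export
plot_strength_profile <- function(metrics) {
  node_rows <- dplyr::filter(metrics, .data$node_id != "GRAPH",
                             .data$metric %in% c("pos_strength", "neg_strength",
                                                 "total_strength"))
  avg <- dplyr::summarise(
    dplyr::group_by(node_rows, .data$node_id, .data$metric),
    value = mean(.data$value), .groups = "drop"
  )
  ggplot(avg, aes(x = .data$node_id, y = .data$value, fill = .data$metric)) +
    geom_col(position = "dodge") +
    labs(x = "node", y = "strength (|r| units)",
         title = "Subject-averaged node strengths") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
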