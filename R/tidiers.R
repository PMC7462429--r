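#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a component model
#'
#' @param x A [fit_pca_varimax()] result.
#' @param ... Unused.
#' @return A long tibble of varimax-rotated loadings: `cluster`, `item`,
#'   `component`, `loading`.
#' @method tidy component_model
#' @export
tidy.component_model <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$clusters, function(fit, nm) {
    l <- fit$loadings
    tibble::tibble(
      cluster = nm,
      item = rep(rownames(l), ncol(l)),
      component = rep(paste0("cluster", nm, "_", colnames(l)),
                      each = nrow(l)),
      loading = as.vector(l)
    )
  }))
}

#' @rdname tidy.component_model
#' @return `glance()`: one row per cluster with `n_items`, `n_components`,
#'   `variance_explained`.
#' @method glance component_model
#' @export
glance.component_model <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$clusters, function(fit, nm) {
    tibble::tibble(cluster = nm, n_items = length(fit$items),
                   n_components = x$n_components,
                   variance_explained = fit$variance_explained)
  }))
}

#' Tidy an NBS result
#'
#' @param x An [nbs_test()] result.
#' @param ... Unused.
#' @return One row per suprathreshold component: `component`, `size`
#'   (edge count), `n_nodes`, `fwe_p`, `significant`.
#' @method tidy nbs_result
#' @export
tidy.nbs_result <- function(x, ...) {
  if (!length(x$components)) {
    return(tibble::tibble(component = integer(), size = integer(),
                          n_nodes = integer(), fwe_p = numeric(),
                          significant = logical()))
  }
  dplyr::bind_rows(purrr::imap(x$components, function(comp, i) {
    tibble::tibble(component = i, size = comp$size,
                   n_nodes = length(comp$nodes), fwe_p = comp$fwe_p,
                   significant = comp$significant)
  }))
}

#' @rdname tidy.nbs_result
#' @return `glance()`: one row with the test settings and the null
#'   distribution's upper quantiles.
#' @method glance nbs_result
#' @export
glance.nbs_result <- function(x, ...) {
  tibble::tibble(
    contrast = x$contrast, T_threshold = x$T, n_perm = x$n_perm,
    df = x$df, n_components = length(x$components),
    n_significant = sum(purrr::map_lgl(x$components, "significant")),
    null_max_q95 = unname(quantile(x$null_max_sizes, 0.95)),
    null_max_max = max(x$null_max_sizes)
  )
}

#' Tidy an ICC result
#'
#' @param x An [icc()] result.
#' @param ... Unused.
#' @return A one-row tibble: `icc`, `ci_low`, `ci_high`, `p`, `form`, `n`.
#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 p = x$p, form = x$form, n = x$n)
}

#' Tidy a mediation result
#'
#' @param x A [mediate()] result.
#' @param ... Unused.
#' @return One row per path (`a`, `b`, `c`, `c_prime`, `indirect`) with the
#'   estimate; the indirect row carries the bootstrap SE and percentile CI.
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c", "c_prime", "indirect"),
    estimate = c(x$a, x$b, x$c, x$c_prime, x$indirect),
    se = c(NA, NA, NA, NA, x$se_indirect),
    ci_low = c(NA, NA, NA, NA, x$ci_low),
    ci_high = c(NA, NA, NA, NA, x$ci_high)
  )
}

#' @rdname tidy.mediation_result
#' @return `glance()`: one row with the indirect effect, its CI,
#'   significance, and sample sizes.
#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(indirect = x$indirect, se_indirect = x$se_indirect,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 significant = x$significant, n = x$n,
                 n_dropped = x$n_dropped, n_boot = x$n_boot)
}

#' Tidy a linear fit
#'
#' @param x A [fit_linear()] result.
#' @param ... Unused.
#' @return The coefficient tibble (`term`, `estimate`, `se`, `statistic`,
#'   `p.value`).
#' @method tidy linear_fit
#' @export
tidy.linear_fit <- function(x, ...) x$coefficients

#' @rdname tidy.linear_fit
#' @method glance linear_fit
#' @export
glance.linear_fit <- function(x, ...) {
  tibble::tibble(n = x$n, df = x$df, n_dropped = x$n_dropped,
                 sigma = sqrt(sum(x$residuals^2) / x$df))
}
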