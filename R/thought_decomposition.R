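#' Extract the item matrix from a ratings table
#'
#' @param ratings Tibble with a `subject_id` column and one column per Likert
#'   item (values 1-4).
#' @return Numeric matrix, subjects x items, with item column names.
#' @keywords internal
ratings_values <- function(ratings) {
  if (!"subject_id" %in% names(ratings)) {
    abort("ratings table must have a `subject_id` column")
  }
  m <- as.matrix(ratings[setdiff(names(ratings), "subject_id")])
  if (any(!is.finite(m))) abort("ratings contain missing or non-finite cells")
  storage.mode(m) <- "double"
  m
}

#' Cluster rating items into two groups
#'
#' Items are hierarchically clustered by the similarity of their response
#' profiles across subjects (items as observations, subjects as features)
#' using Ward linkage on squared Euclidean distances, and the tree is cut
#' into exactly two clusters. This partitions the questionnaire before the
#' per-cluster principal component decomposition.
#'
#' @param ratings Ratings tibble (`subject_id` + item columns, values 1-4).
#' @return A list of class `item_linkage` with the `hclust` merge history
#'   (`hclust`), `cluster_of_item` (named vector of `"A"`/`"B"`), and the
#'   item order.
#' @export
#' @examples
#' cohort <- simulate_cohort(desk_cohort_config(seed = 1))
#' linkage <- cluster_items(cohort$ratings)
#' table(linkage$cluster_of_item)
cluster_items <- function(ratings) {
  x <- ratings_values(ratings)
  if (ncol(x) < 4L) abort("at least 4 items are required for clustering")
  if (nrow(x) < 2L) abort("at least 2 subjects are required for clustering")
  constant <- apply(x, 2L, sd) == 0
  if (any(constant)) {
    inform(sprintf("constant (zero-variance) item(s): %s",
                   paste(colnames(x)[constant], collapse = ", ")))
  }
  d <- stats::dist(t(x))^2
  hc <- stats::hclust(d, method = "ward.D")
  members <- stats::cutree(hc, k = 2L)
  # deterministic naming: the cluster containing the first item is "A"
  first <- members[1L]
  cluster_of_item <- ifelse(members == first, "A", "B")
  names(cluster_of_item) <- colnames(x)
  structure(
    list(hclust = hc, cluster_of_item = cluster_of_item,
         items = colnames(x)),
    class = "item_linkage"
  )
}

#' Choose the number of retained components
#'
#' @param eigenvalues Eigenvalues of a correlation-matrix PCA, sorted in
#'   decreasing order.
#' @param rule `"fixed"` (default; retain `k` components, the pipeline
#'   default of 3 per cluster) or `"eigenvalue_gt_1"` (Kaiser rule, strict
#'   `> 1`).
#' @param k Number of components under the fixed rule.
#' @return An integer count.
#' @export
#' @examples
#' select_n_components(c(2.4, 1.3, 1.1, 0.6), rule = "eigenvalue_gt_1")
select_n_components <- function(eigenvalues,
                                rule = c("fixed", "eigenvalue_gt_1"),
                                k = 3L) {
  rule <- match.arg(rule)
  if (is.unsorted(rev(eigenvalues))) {
    abort("`eigenvalues` must be sorted in decreasing order")
  }
  if (rule == "eigenvalue_gt_1") {
    return(sum(eigenvalues > 1))
  }
  k <- check_positive_int(k, "k")
  if (k > length(eigenvalues)) {
    abort("`k` cannot exceed the number of eigenvalues (items)")
  }
  k
}

#' Fit per-cluster PCA with varimax rotation
#'
#' For each of the two item clusters: items are standardized, a PCA is run on
#' the item correlation matrix, the leading `n_components` are retained and
#' varimax-rotated (Kaiser row normalization, tolerance 1e-8), and component
#' score weights are computed by the regression method
#' (`W = R^{-1} L_rotated`). Component signs follow a fixed convention: the
#' loading with the largest absolute value in each component is made
#' positive, which removes rotation sign indeterminacy.
#'
#' @param ratings Ratings tibble.
#' @param linkage An [cluster_items()] result.
#' @param n_components Components retained per cluster (default 3).
#' @return A list of class `component_model`; per cluster it stores item
#'   names, standardization parameters, eigenvalues, unrotated and rotated
#'   loadings, score weights, and the proportion of variance explained by
#'   the retained set. `component_names` gives the 6 score column names
#'   (`clusterA_pc1` ... `clusterB_pc3`).
#' @export
fit_pca_varimax <- function(ratings, linkage, n_components = 3L) {
  n_components <- check_positive_int(n_components, "n_components")
  x <- ratings_values(ratings)
  clusters <- list(A = names(which(linkage$cluster_of_item == "A")),
                   B = names(which(linkage$cluster_of_item == "B")))
  fits <- purrr::imap(clusters, function(items, nm) {
    if (length(items) < n_components) {
      abort(sprintf("cluster %s has %d items, fewer than n_components = %d",
                    nm, length(items), n_components))
    }
    xc <- x[, items, drop = FALSE]
    center <- colMeans(xc)
    scale_ <- apply(xc, 2L, sd)
    if (any(scale_ == 0)) {
      abort(sprintf("cannot standardize constant item(s): %s",
                    paste(items[scale_ == 0], collapse = ", ")))
    }
    z <- sweep(sweep(xc, 2L, center), 2L, scale_, `/`)
    r <- cor(z)
    ev <- eigen(r, symmetric = TRUE)
    if (min(ev$values) < 1e-10) {
      collinear <- items[which.max(abs(ev$vectors[, length(items)]))]
      abort(sprintf(
        "singular item correlation matrix in cluster %s (collinearity involving '%s')",
        nm, collinear))
    }
    lambda <- ev$values
    loadings <- ev$vectors[, seq_len(n_components), drop = FALSE] %*%
      diag(sqrt(lambda[seq_len(n_components)]), n_components)
    rot <- stats::varimax(loadings, normalize = TRUE, eps = 1e-8)
    rotated <- loadings %*% rot$rotmat
    # sign convention: dominant loading positive in each component
    flip <- vapply(seq_len(n_components), function(j) {
      sign(rotated[which.max(abs(rotated[, j])), j])
    }, numeric(1))
    rotated <- sweep(rotated, 2L, flip, `*`)
    dimnames(rotated) <- list(items, paste0("pc", seq_len(n_components)))
    dimnames(loadings) <- dimnames(rotated)
    weights <- solve(r, rotated)
    list(items = items, center = center, scale = scale_,
         eigenvalues = lambda, loadings_unrotated = loadings,
         loadings = rotated, weights = weights,
         variance_explained = sum(lambda[seq_len(n_components)]) / length(items))
  })
  structure(
    list(clusters = fits, n_components = n_components,
         component_names = unlist(purrr::imap(fits, function(f, nm) {
           paste0("cluster", nm, "_pc", seq_len(n_components))
         }), use.names = FALSE)),
    class = "component_model"
  )
}

#' Score subjects on fitted thought components
#'
#' Standardizes the ratings with the model's stored item means and standard
#' deviations and applies the stored regression-method weights. In-sample
#' scores therefore have mean zero by construction.
#'
#' @param model A [fit_pca_varimax()] result.
#' @param ratings Ratings tibble with exactly the fitted items.
#' @return A tibble: `subject_id` plus one column per component
#'   (2 clusters x `n_components`).
#' @export
score_components <- function(model, ratings) {
  x <- ratings_values(ratings)
  scores <- purrr::imap(model$clusters, function(fit, nm) {
    missing <- setdiff(fit$items, colnames(x))
    if (length(missing)) {
      abort(sprintf("ratings are missing fitted item(s): %s",
                    paste(missing, collapse = ", ")))
    }
    extra <- setdiff(colnames(x), unlist(purrr::map(model$clusters, "items")))
    if (length(extra)) {
      abort(sprintf("ratings contain item(s) unseen at fit time: %s",
                    paste(extra, collapse = ", ")))
    }
    z <- sweep(sweep(x[, fit$items, drop = FALSE], 2L, fit$center),
               2L, fit$scale, `/`)
    s <- z %*% fit$weights
    colnames(s) <- paste0("cluster", nm, "_pc", seq_len(ncol(s)))
    s
  })
  out <- tibble::as_tibble(do.call(cbind, unname(scores)))
  dplyr::bind_cols(tibble::tibble(subject_id = ratings$subject_id), out)
}

#' Project a new session through a fitted decomposition
#'
#' Identical computation to [score_components()], named separately to make
#' the retest workflow explicit: session-2 ratings are standardized with the
#' SESSION-1 means and standard deviations and multiplied by the SESSION-1
#' weights; nothing is refit on the new session.
#'
#' @inheritParams score_components
#' @param new_ratings Session-2 ratings tibble with the same item set.
#' @return A tibble of component scores for the new session.
#' @export
project_session <- function(model, new_ratings) {
  score_components(model, new_ratings)
}

#' Full thought decomposition in one call
#'
#' Runs [cluster_items()], [fit_pca_varimax()], and [score_components()].
#'
#' @param ratings Ratings tibble.
#' @param n_components Components per cluster (default 3).
#' @return A list with `linkage`, `model`, and `scores`.
#' @export
decompose_thoughts <- function(ratings, n_components = 3L) {
  linkage <- cluster_items(ratings)
  model <- fit_pca_varimax(ratings, linkage, n_components)
  list(linkage = linkage, model = model,
       scores = score_components(model, ratings))
}

#' @export
print.component_model <- function(x, ...) {
  ve <- purrr::map_dbl(x$clusters, "variance_explained")
  cat(sprintf(
    "<component_model> %d components per cluster; variance explained: A %.0f%%, B %.0f%%\n",
    x$n_components, 100 * ve[["A"]], 100 * ve[["B"]]
  ))
  invisible(x)
}
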