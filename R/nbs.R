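#' Stack connectomes into an edge matrix
#'
#' @param connectomes List of [connectome()] matrices (one per subject, same
#'   node count and order).
#' @return A list with `Y` (subjects x edges matrix of upper-triangle
#'   weights in canonical edge order), `edge_index` (tibble: `edge`,
#'   `node_i`, `node_j`, 0-based), `n_nodes`, and `subject_ids`.
#' @export
stack_connectomes <- function(connectomes) {
  if (!length(connectomes)) abort("empty connectome list")
  p <- nrow(connectomes[[1L]])
  if (!all(vapply(connectomes, nrow, integer(1)) == p)) {
    abort("all connectomes must have the same node count")
  }
  Y <- t(vapply(connectomes, function(m) upper_tri_values(unclass(m)),
                numeric(p * (p - 1L) / 2L)))
  list(Y = Y, edge_index = edge_index(p), n_nodes = p,
       subject_ids = purrr::map_chr(connectomes,
                                    ~ attr(.x, "subject_id") %||% NA_character_))
}

#' Build the NBS design matrix
#'
#' Columns are the block of interest (the six thought-pattern scores)
#' followed by the nuisance block: intercept, mean connectivity, age,
#' gender, and motion fraction — the group-level nuisance regressors of the
#' edgewise GLM.
#'
#' @param scores Component-score tibble (`subject_id` + score columns).
#' @param covariates Covariate tibble (`subject_id`, `age`, `gender`,
#'   `motion_fraction`).
#' @param mean_conn Numeric vector of per-subject mean connectivity, in the
#'   same subject order.
#' @return A list of class `nbs_design` with the design matrix `X`,
#'   `interest` and `nuisance` column names, and `subject_ids`.
#' @export
nbs_design <- function(scores, covariates, mean_conn) {
  if (!identical(scores$subject_id, covariates$subject_id)) {
    abort("subject ids of `scores` and `covariates` do not match")
  }
  interest <- as.matrix(scores[setdiff(names(scores), "subject_id")])
  nuisance <- cbind(
    intercept = 1,
    mean_connectivity = mean_conn,
    age = covariates$age,
    gender = covariates$gender,
    motion_fraction = covariates$motion_fraction
  )
  X <- cbind(interest, nuisance)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    abort(sprintf("design matrix is rank deficient; dependent column(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  structure(
    list(X = X, interest = colnames(interest), nuisance = colnames(nuisance),
         subject_ids = scores$subject_id),
    class = "nbs_design"
  )
}

# core vectorized OLS: t-statistics for one contrast column across all edges
edge_t_stats <- function(X, Y, contrast_col, xtx_inv = NULL) {
  n <- nrow(X)
  rank_x <- ncol(X)
  if (is.null(xtx_inv)) xtx_inv <- chol2inv(chol(crossprod(X)))
  beta <- xtx_inv %*% crossprod(X, Y)
  resid <- Y - X %*% beta
  df <- n - rank_x
  s2 <- colSums(resid^2) / df
  cvar <- xtx_inv[contrast_col, contrast_col]
  se <- sqrt(s2 * cvar)
  t <- beta[contrast_col, ] / se
  # perfect fits (zero residual variance) yield infinite t; cap them
  degenerate <- s2 < 1e-24
  if (any(degenerate)) {
    t[degenerate] <- sign(beta[contrast_col, degenerate]) * 1e6
  }
  list(t = as.vector(t), df = df, n_degenerate = sum(degenerate))
}

#' Edgewise GLM over a connectome stack
#'
#' Fits, at every upper-triangle edge, an ordinary least squares regression
#' of edge weight on the full design (interest + nuisance blocks) and
#' returns the t-statistic of the requested contrast column. Edges fit
#' perfectly by the design (zero residual variance) receive a capped finite
#' t of magnitude 1e6 and are counted in a log note.
#'
#' @param stack A [stack_connectomes()] result (or a list of connectomes).
#' @param design An [nbs_design()].
#' @param contrast Name of the design column tested.
#' @return A list of class `edge_stats`: `t` (per-edge t in canonical edge
#'   order), `df`, `contrast`, `edge_index`, `n_nodes`.
#' @export
edgewise_glm <- function(stack, design, contrast) {
  if (!inherits(stack, "list") || is.null(stack$Y)) stack <- stack_connectomes(stack)
  X <- design$X
  if (nrow(X) != nrow(stack$Y)) abort("design and connectome stack disagree on subject count")
  if (nrow(X) < ncol(X) + 2L) abort("need at least rank(design) + 2 subjects")
  if (!contrast %in% colnames(X)) {
    abort(sprintf("contrast '%s' is not a design column", contrast))
  }
  res <- edge_t_stats(X, stack$Y, which(colnames(X) == contrast))
  if (res$n_degenerate > 0) {
    inform(sprintf("%d edge(s) fit perfectly; t capped at 1e6", res$n_degenerate))
  }
  structure(
    list(t = res$t, df = res$df, contrast = contrast,
         edge_index = stack$edge_index, n_nodes = stack$n_nodes),
    class = "edge_stats"
  )
}

# maximal suprathreshold component size (edge count) from a t vector;
# fast path for the permutation loop
max_component_size <- function(t, edge_index, T, sidedness) {
  sel <- suprathreshold_edges(t, T, sidedness)
  if (!any(sel)) return(0L)
  pairs <- cbind(edge_index$node_i[sel], edge_index$node_j[sel]) + 1L
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no == 1L) return(as.integer(nrow(pairs)))
  memb <- comp$membership
  max(tabulate(memb[pairs[, 1L]], comp$no))
}

suprathreshold_edges <- function(t, T, sidedness) {
  switch(sidedness,
         two_sided = abs(t) >= T,
         positive = t >= T,
         negative = t <= -T)
}

#' Extract suprathreshold connected components
#'
#' Selects edges whose t-statistic exceeds the threshold (`|t| >= T` for the
#' default two-sided rule), builds the graph of selected edges, and returns
#' its connected components sorted by size (edge count) in decreasing order.
#'
#' @param stats An [edgewise_glm()] result.
#' @param T Primary threshold on the edge t-statistic (> 0; default 3.2).
#' @param sidedness `"two_sided"` (default), `"positive"`, or `"negative"`.
#' @return A list of components; each has `edges` (tibble `node_i`,
#'   `node_j`, `t`, `sign`, 0-based ids), `nodes` (0-based), and `size`
#'   (edge count).
#' @export
suprathreshold_components <- function(stats, T = 3.2,
                                      sidedness = c("two_sided", "positive",
                                                    "negative")) {
  sidedness <- match.arg(sidedness)
  if (T <= 0) abort("`T` must be > 0")
  sel <- which(suprathreshold_edges(stats$t, T, sidedness))
  if (!length(sel)) return(list())
  ei <- stats$edge_index[sel, ]
  pairs <- cbind(ei$node_i, ei$node_j) + 1L
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  memb <- igraph::components(g)$membership
  edge_comp <- memb[pairs[, 1L]]
  comps <- purrr::map(unique(edge_comp), function(cid) {
    in_comp <- edge_comp == cid
    edges <- tibble::tibble(
      node_i = ei$node_i[in_comp], node_j = ei$node_j[in_comp],
      t = stats$t[sel][in_comp], sign = sign(stats$t[sel][in_comp])
    )
    list(edges = edges,
         nodes = sort(unique(c(edges$node_i, edges$node_j))),
         size = nrow(edges))
  })
  sizes <- purrr::map_int(comps, "size")
  first_node <- purrr::map_int(comps, ~ min(.x$nodes))
  comps[order(-sizes, first_node)]
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Network-based statistic with permutation FWE control
#'
#' Runs the edgewise GLM for one contrast, extracts suprathreshold connected
#' components, and assigns each a family-wise-error-corrected p-value from a
#' permutation null distribution of the maximal component size. Under the
#' default scheme the rows of the interest block (all thought scores
#' jointly) are shuffled while the nuisance-connectome pairing is preserved;
#' Freedman-Lane residual permutation is available as an alternative.
#'
#' @inheritParams edgewise_glm
#' @param T Primary t threshold (default 3.2).
#' @param n_perm Number of permutations (default 5000; at least 100 is
#'   recommended for reporting).
#' @param seed Integer seed for the single permutation generator.
#' @param scheme `"permute_interest"` (default) or `"freedman_lane"`.
#' @param sidedness Edge inclusion rule, as in [suprathreshold_components()].
#' @param alpha Component significance level (default 0.05).
#' @param p_smoothing If `TRUE` (default), p = (k + 1) / (n_perm + 1) where
#'   k counts null maxima at least as large as the observed size; `FALSE`
#'   reproduces the plain k / n_perm proportion.
#' @param exhaustive If `TRUE`, enumerate the full permutation group of the
#'   subject rows instead of sampling (requires <= 8 subjects); `n_perm` and
#'   `p_smoothing` are ignored and p-values are exact proportions over all
#'   n! shuffles.
#' @return A list of class `nbs_result`: `contrast`, `T`, `components`
#'   (from [suprathreshold_components()], each augmented with `fwe_p` and
#'   `significant`), `null_max_sizes`, `n_perm`, `seed`, `alpha`, and
#'   `mask` (N x N matrix in `{-1, 0, +1}`, nonzero exactly on significant
#'   components' edges, signed by the edge association).
#' @export
nbs_test <- function(stack, design, contrast, T = 3.2, n_perm = 5000L,
                     seed = 1L,
                     scheme = c("permute_interest", "freedman_lane"),
                     sidedness = c("two_sided", "positive", "negative"),
                     alpha = 0.05, p_smoothing = TRUE, exhaustive = FALSE) {
  scheme <- match.arg(scheme)
  sidedness <- match.arg(sidedness)
  if (!inherits(stack, "list") || is.null(stack$Y)) stack <- stack_connectomes(stack)
  if (!exhaustive) n_perm <- check_positive_int(n_perm, "n_perm")

  X <- design$X
  n <- nrow(X)
  interest_cols <- match(design$interest, colnames(X))
  nuisance_cols <- match(design$nuisance, colnames(X))
  contrast_col <- which(colnames(X) == contrast)
  if (!length(contrast_col)) abort(sprintf("contrast '%s' is not a design column", contrast))

  observed <- edgewise_glm(stack, design, contrast)
  components <- suprathreshold_components(observed, T, sidedness)

  Y <- stack$Y
  if (scheme == "freedman_lane") {
    # reduced-model fit: permute nuisance-model residuals, keep nuisance fit
    Z <- X[, nuisance_cols, drop = FALSE]
    hz <- Z %*% chol2inv(chol(crossprod(Z))) %*% t(Z)
    Y_fit <- hz %*% Y
    Y_res <- Y - Y_fit
  }
  xtx_inv_obs <- chol2inv(chol(crossprod(X)))

  perm_rows <- if (exhaustive) {
    if (n > 8L) abort("exhaustive enumeration is limited to 8 subjects")
    all_permutations(n)
  } else NULL
  n_iter <- if (exhaustive) nrow(perm_rows) else n_perm

  null_max <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(b) {
      idx <- if (exhaustive) perm_rows[b, ] else sample.int(n)
      if (scheme == "permute_interest") {
        Xp <- X
        Xp[, interest_cols] <- X[idx, interest_cols, drop = FALSE]
        Yb <- Y
        xtx_inv <- NULL
      } else {
        Xp <- X
        Yb <- Y_fit + Y_res[idx, , drop = FALSE]
        xtx_inv <- xtx_inv_obs
      }
      tb <- edge_t_stats(Xp, Yb, contrast_col, xtx_inv = xtx_inv)$t
      as.integer(max_component_size(tb, stack$edge_index, T, sidedness))
    }, integer(1))
  })

  components <- purrr::map(components, function(comp) {
    k <- sum(null_max >= comp$size)
    comp$fwe_p <- if (exhaustive) {
      k / n_iter
    } else if (p_smoothing) {
      (k + 1) / (n_iter + 1)
    } else {
      k / n_iter
    }
    comp$significant <- comp$fwe_p < alpha
    comp
  })

  mask <- matrix(0, stack$n_nodes, stack$n_nodes)
  for (comp in components) {
    if (isTRUE(comp$significant)) {
      ij <- cbind(comp$edges$node_i + 1L, comp$edges$node_j + 1L)
      mask[ij] <- comp$edges$sign
      mask[ij[, 2:1, drop = FALSE]] <- comp$edges$sign
    }
  }

  structure(
    list(contrast = contrast, T = T, components = components,
         null_max_sizes = null_max, n_perm = n_iter, seed = seed,
         alpha = alpha, sidedness = sidedness, scheme = scheme,
         exhaustive = exhaustive, df = observed$df,
         edge_stats = observed, mask = mask),
    class = "nbs_result"
  )
}

#' Mask a connectome to a significant component
#'
#' Retains the subject's weights on the component's edges and zeroes
#' everything else; the component node set is carried as an attribute for
#' downstream graph metrics.
#'
#' @param c A [connectome()].
#' @param result An [nbs_test()] result.
#' @param component_index Index into `result$components`.
#' @return A masked [connectome()] with attribute `component_nodes`
#'   (0-based) and `component_index`.
#' @export
mask_connectome <- function(c, result, component_index = 1L) {
  if (component_index < 1L || component_index > length(result$components)) {
    abort(sprintf("component index %d out of range (1..%d)",
                  component_index, length(result$components)))
  }
  comp <- result$components[[component_index]]
  m <- unclass(c)
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  ij <- cbind(comp$edges$node_i + 1L, comp$edges$node_j + 1L)
  out[ij] <- m[ij]
  out[ij[, 2:1, drop = FALSE]] <- m[ij[, 2:1, drop = FALSE]]
  structure(out, subject_id = attr(c, "subject_id"),
            component_nodes = comp$nodes,
            component_index = component_index,
            class = c("connectome", "matrix", "array"))
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> contrast %s, T = %.2f, %d permutation(s)\n",
              x$contrast, x$T, x$n_perm))
  if (!length(x$components)) {
    cat("  no suprathreshold components\n")
  } else {
    for (i in seq_along(x$components)) {
      comp <- x$components[[i]]
      cat(sprintf("  component %d: %d edges, %d nodes, FWE p = %.4g%s\n",
                  i, comp$size, length(comp$nodes), comp$fwe_p,
                  if (isTRUE(comp$significant)) " *" else ""))
    }
  }
  invisible(x)
}
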