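# Independent oracles used across the test suite. These deliberately avoid
# the package's own code paths (and igraph) so that agreement is informative.

# regression t-statistic for one coefficient via base lm()
oracle_lm_t <- function(y, X, col) {
  df <- as.data.frame(X)
  names(df) <- paste0("v", seq_len(ncol(X)))
  df$y <- y
  fit <- stats::lm(y ~ . - 1, data = df)
  unname(summary(fit)$coefficients[col, "t value"])
}

# connected components of an undirected edge list via union-find
oracle_components <- function(pairs) {
  if (!nrow(pairs)) return(list())
  nodes <- sort(unique(c(pairs[, 1], pairs[, 2])))
  parent <- stats::setNames(nodes, as.character(nodes))
  find <- function(x) {
    while (parent[[as.character(x)]] != x) {
      parent[[as.character(x)]] <<- parent[[as.character(parent[[as.character(x)]])]]
      x <- parent[[as.character(x)]]
    }
    x
  }
  for (r in seq_len(nrow(pairs))) {
    ri <- find(pairs[r, 1]); rj <- find(pairs[r, 2])
    if (ri != rj) parent[[as.character(ri)]] <- rj
  }
  roots <- vapply(pairs[, 1], find, numeric(1))
  split(seq_len(nrow(pairs)), roots)
}

# all-pairs shortest path distances by Floyd-Warshall on a length matrix
oracle_distances <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# betweenness by explicitly enumerating every shortest path between every
# ordered node pair (DFS over the shortest-path DAG), ties split fractionally,
# normalized by (n-1)(n-2)
oracle_betweenness <- function(w) {
  n <- nrow(w)
  len <- ifelse(w != 0, 1 / abs(w), Inf)
  diag(len) <- Inf
  d <- oracle_distances(len)
  count_through <- numeric(n)
  tol <- 1e-9
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(d[s, t])) next
    # enumerate all shortest s->t paths; every prefix of a shortest path is
    # itself shortest, so extend only along DAG edges
    paths <- list()
    stack <- list(s)
    while (length(stack)) {
      path <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1L]] <- path
        next
      }
      for (u in seq_len(n)) {
        if (is.finite(len[v, u]) &&
            abs(d[s, v] + len[v, u] + d[u, t] - d[s, t]) < tol) {
          stack[[length(stack) + 1L]] <- c(path, u)
        }
      }
    }
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      tab <- table(inner)
      idx <- as.integer(names(tab))
      count_through[idx] <- count_through[idx] + as.numeric(tab) / length(paths)
    }
  }
  count_through / ((n - 1) * (n - 2))
}

# random symmetric signed weight matrix with zero diagonal
random_signed_graph <- function(n, density = 0.6) {
  m <- matrix(0, n, n)
  up <- which(upper.tri(m))
  on <- sample(up, round(density * length(up)))
  m[on] <- runif(length(on), -1, 1)
  m + t(m)
}

# small helper: align recovered score columns to planted factors by |cor|;
# returns for each factor the best-matching column's absolute correlation
alignment_correlations <- function(scores_matrix, factors) {
  cc <- abs(stats::cor(scores_matrix, factors))
  apply(cc, 2, max)
}

# build a connectome stack where one edge carries prescribed weights and the
# rest are constant, for regression-oracle tests
stack_with_edge <- function(weights, n_nodes = 4L, edge = c(0L, 1L)) {
  lapply(seq_along(weights), function(s) {
    m <- matrix(0, n_nodes, n_nodes)
    m[edge[1] + 1L, edge[2] + 1L] <- weights[s]
    m[edge[2] + 1L, edge[1] + 1L] <- weights[s]
    connectome(m, subject_id = sprintf("sub-%02d", s))
  })
}

# minimal design for k interest columns without relying on nbs_design
toy_design <- function(interest, nuisance = NULL) {
  X <- cbind(interest, intercept = 1, nuisance)
  structure(list(X = X,
                 interest = colnames(interest),
                 nuisance = setdiff(colnames(X), colnames(interest)),
                 subject_ids = sprintf("sub-%02d", seq_len(nrow(X)))),
            class = "nbs_design")
}

# ratings tibble from a numeric matrix
ratings_tibble <- function(m, ids = sprintf("s%03d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% sprintf("item_%02d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(subject_id = ids), tibble::as_tibble(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
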