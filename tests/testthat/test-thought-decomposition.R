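make_block_ratings <- function(n, n_items_per_block = 5, within = 0.8,
                               seed = 1) {
  # two item blocks driven by independent latent factors; within-block item
  # correlation ~ `within`, across-block 0
  withr::with_seed(seed, {
    lam <- sqrt(within)
    f <- matrix(rnorm(n * 2), n, 2)
    p <- 2 * n_items_per_block
    block <- rep(1:2, each = n_items_per_block)
    x <- f[, block] * lam + matrix(rnorm(n * p), n, p) * sqrt(1 - lam^2)
    ratings_tibble(x)
  })
}

test_that("Ward clustering recovers planted item blocks exactly", {
  ratings <- make_block_ratings(300, 5, within = 0.8, seed = 2)
  linkage <- cluster_items(ratings)
  truth <- rep(c("x", "y"), each = 5)
  tab <- table(linkage$cluster_of_item, truth)
  expect_true(sum(diag(tab)) == 10 || sum(tab[cbind(1:2, 2:1)]) == 10)
})

test_that("identical items merge first at height zero", {
  withr::with_seed(3, {
    x <- matrix(rnorm(50 * 5), 50, 5)
    x <- cbind(x, x[, 1])  # item 6 duplicates item 1
  })
  linkage <- cluster_items(ratings_tibble(x))
  hc <- linkage$hclust
  expect_equal(hc$height[1], 0)
  expect_setequal(abs(hc$merge[1, ]), c(1, 6))
})

test_that("merge heights are non-decreasing (Ward monotonicity)", {
  for (seed in 1:5) {
    withr::with_seed(seed, x <- matrix(sample(1:4, 40 * 8, replace = TRUE), 40, 8))
    hc <- cluster_items(ratings_tibble(x))$hclust
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("clustering input validation and constant-item flagging work", {
  withr::with_seed(1, x <- matrix(sample(1:4, 30 * 3, replace = TRUE), 30, 3))
  expect_error(cluster_items(ratings_tibble(x)), "at least 4 items")
  withr::with_seed(1, x <- cbind(matrix(sample(1:4, 30 * 4, replace = TRUE), 30, 4), 2))
  expect_message(cluster_items(ratings_tibble(x)), "constant")
})

test_that("component-count rules behave as specified", {
  expect_equal(select_n_components(c(2.4, 1.3, 1.1, 0.6),
                                   rule = "eigenvalue_gt_1"), 3)
  # identity correlation matrix: all eigenvalues exactly 1, strict > 1
  expect_equal(select_n_components(rep(1, 8), rule = "eigenvalue_gt_1"), 0)
  expect_equal(select_n_components(c(3, 2, 1, 0.5), rule = "fixed", k = 3), 3)
  expect_error(select_n_components(c(2, 1), rule = "fixed", k = 5), "exceed")
  expect_error(select_n_components(c(1, 2, 3), rule = "eigenvalue_gt_1"),
               "decreasing")
})

test_that("varimax leaves a perfect simple structure intact", {
  # three disjoint item blocks: rotated loadings should stay block-diagonal
  withr::with_seed(4, {
    f <- matrix(rnorm(400 * 3), 400, 3)
    lam <- 0.9
    block <- rep(1:3, each = 3)
    x <- f[, block] * lam + matrix(rnorm(400 * 9), 400, 9) * sqrt(1 - lam^2)
  })
  ratings <- make_block_ratings(400, 5, seed = 5)  # only for a 2-cluster linkage
  fake_linkage <- structure(
    list(cluster_of_item = stats::setNames(
      rep(c("A", "B"), c(9, 9)),
      c(sprintf("item_%02d", 1:9), sprintf("other_%02d", 1:9))
    )),
    class = "item_linkage"
  )
  withr::with_seed(6, other <- matrix(rnorm(400 * 9), 400, 9))
  colnames(other) <- sprintf("other_%02d", 1:9)
  colnames(x) <- sprintf("item_%02d", 1:9)
  model <- fit_pca_varimax(ratings_tibble(cbind(x, other)), fake_linkage, 3)
  l <- model$clusters$A$loadings
  for (j in 1:3) {
    on_block <- sort(abs(l[block == j, ]), decreasing = TRUE)
    primary <- apply(abs(l[block == j, , drop = FALSE]), 1, max)
    expect_true(all(primary > 0.8))
    cross <- apply(abs(l[block == j, , drop = FALSE]), 1, function(v) {
      sort(v, decreasing = TRUE)[2]
    })
    expect_true(all(cross < 0.3))
  }
})

test_that("rotation conserves communalities and Frobenius norm", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 150, n_nodes = 15, seed = 3))
  linkage <- cluster_items(cohort$ratings)
  model <- fit_pca_varimax(cohort$ratings, linkage, 3)
  for (fit in model$clusters) {
    h_before <- rowSums(fit$loadings_unrotated^2)
    h_after <- rowSums(fit$loadings^2)
    expect_lt(max(abs(h_before - h_after)), 1e-8)
    expect_equal(norm(fit$loadings_unrotated, "F"), norm(fit$loadings, "F"),
                 tolerance = 1e-10)
    expect_lte(fit$variance_explained, 1)
  }
})

tucker_congruence <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

test_that("planted 3-factor loadings are recovered with high congruence", {
  # continuous items, planted simple-structure loadings, noise sd 0.2
  withr::with_seed(7, {
    n <- 300
    f <- matrix(rnorm(n * 3), n, 3)
    planted <- matrix(0, 9, 3)
    planted[cbind(1:9, rep(1:3, each = 3))] <- 0.95
    x <- f %*% t(planted) + matrix(rnorm(n * 9, sd = 0.2), n, 9)
    colnames(x) <- sprintf("item_%02d", 1:9)
    withr::with_seed(8, other <- matrix(rnorm(n * 9), n, 9))
    colnames(other) <- sprintf("other_%02d", 1:9)
  })
  fake_linkage <- structure(
    list(cluster_of_item = stats::setNames(
      rep(c("A", "B"), c(9, 9)), c(colnames(x), colnames(other))
    )),
    class = "item_linkage"
  )
  model <- fit_pca_varimax(ratings_tibble(cbind(x, other)), fake_linkage, 3)
  l <- model$clusters$A$loadings
  # align recovered columns to planted ones by absolute congruence
  for (j in 1:3) {
    cong <- apply(l, 2, function(v) abs(tucker_congruence(v, planted[, j])))
    expect_gte(max(cong), 0.95)
  }
})

test_that("component scores equal the matrix-product oracle and are centered", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 120, n_nodes = 15, seed = 9))
  dec <- decompose_thoughts(cohort$ratings)
  scores <- as.matrix(dec$scores[-1])
  expect_lt(max(abs(colMeans(scores))), 1e-10)

  # brute-force oracle for one subject: standardize with model parameters,
  # multiply by stored weights
  model <- dec$model
  x <- as.matrix(cohort$ratings[-1])
  s <- 17
  manual <- unlist(lapply(model$clusters, function(fit) {
    z <- (x[s, fit$items] - fit$center) / fit$scale
    as.vector(z %*% fit$weights)
  }))
  expect_equal(unname(scores[s, ]), unname(manual), tolerance = 1e-12)

  # a subject sitting exactly at the item means scores zero everywhere
  at_means <- dplyr::mutate(cohort$ratings[1, ],
                            dplyr::across(-"subject_id", as.numeric))
  for (fit in model$clusters) at_means[1, fit$items] <- as.list(fit$center)
  z <- score_components(model, at_means)
  expect_lt(max(abs(as.matrix(z[-1]))), 1e-12)
})

test_that("projection reuses session-1 parameters and ignores new covariance", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 150, n_nodes = 15, seed = 10))
  s2 <- simulate_retest(cohort, retest_truth(n_retest = 100))
  dec <- decompose_thoughts(cohort$ratings)

  # idempotence: projecting session 1 reproduces in-sample scores exactly
  expect_equal(project_session(dec$model, cohort$ratings), dec$scores)

  # shifting all items of one cluster moves only that cluster's scores
  shifted <- cohort$ratings
  items_a <- dec$model$clusters$A$items
  shifted[items_a] <- shifted[items_a] + 0.5
  ps <- project_session(dec$model, shifted)
  a_cols <- grep("^clusterA", names(ps), value = TRUE)
  b_cols <- grep("^clusterB", names(ps), value = TRUE)
  expect_false(isTRUE(all.equal(ps[a_cols], dec$scores[a_cols])))
  expect_equal(ps[b_cols], dec$scores[b_cols], tolerance = 1e-12)

  # projection differs from refitting the decomposition on session 2
  projected <- project_session(dec$model, s2$ratings)
  refit <- decompose_thoughts(s2$ratings)
  expect_false(isTRUE(all.equal(as.matrix(projected[-1]),
                                as.matrix(refit$scores[-1]),
                                tolerance = 1e-6)))

  # unseen item labels are rejected
  bad <- dplyr::rename(cohort$ratings, mystery = names(cohort$ratings)[2])
  expect_error(score_components(dec$model, bad), "missing|unseen")
})

test_that("decomposition is deterministic", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 80, n_nodes = 15, seed = 11))
  d1 <- decompose_thoughts(cohort$ratings)
  d2 <- decompose_thoughts(cohort$ratings)
  expect_identical(d1$model$clusters$A$loadings, d2$model$clusters$A$loadings)
  expect_identical(d1$scores, d2$scores)
})
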