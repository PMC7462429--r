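# small synthetic stack: n subjects, p nodes, edge weights i.i.d. noise
noise_stack <- function(n, p, seed, scale = 0.2) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(s) {
      m <- matrix(0, p, p)
      m[upper.tri(m)] <- rnorm(p * (p - 1) / 2, sd = scale)
      connectome(m + t(m), subject_id = sprintf("sub-%03d", s))
    })
  })
}

test_that("edgewise GLM t-statistics match the lm oracle", {
  n <- 8
  withr::with_seed(1, {
    score <- rnorm(n)
    nuis <- rnorm(n)
    weights <- round(rnorm(n, sd = 0.3), 3)
  })
  stack <- stack_with_edge(weights)
  design <- toy_design(cbind(score = score), cbind(nuis = nuis))
  stats <- edgewise_glm(stack, design, "score")
  pos <- 1L  # edge (0,1) is first in canonical order
  X <- design$X
  expect_equal(stats$t[pos], oracle_lm_t(weights, X, 1), tolerance = 1e-10)
  expect_equal(stats$df, n - 3)
})

test_that("perfectly fit edges get a capped finite t with a log note", {
  n <- 12
  withr::with_seed(2, score <- rnorm(n))
  weights <- 0.5 * score  # exact linear function, zero residual
  stack <- stack_with_edge(weights)
  design <- toy_design(cbind(score = score))
  expect_message(stats <- edgewise_glm(stack, design, "score"), "capped")
  expect_true(is.finite(stats$t[1]))
  expect_equal(abs(stats$t[1]), 1e6)
})

test_that("null edges rarely exceed |t| = 3 at n = 100", {
  n <- 100; p <- 20
  stack <- noise_stack(n, p, seed = 3)
  withr::with_seed(4, scores <- matrix(rnorm(n * 2), n, 2,
                                       dimnames = list(NULL, c("s1", "s2"))))
  design <- toy_design(scores)
  stats <- edgewise_glm(stack, design, "s1")
  expect_gt(mean(abs(stats$t) < 3), 0.97)
})

test_that("suprathreshold components match the hand-checkable case", {
  p <- 10
  ei <- thoughtnet:::edge_index(p)
  t_map <- rep(0, nrow(ei))
  hot <- list(c(0, 1), c(1, 2), c(0, 2), c(5, 6), c(6, 7))
  for (e in hot) {
    t_map[ei$node_i == e[1] & ei$node_j == e[2]] <- 4.5
  }
  stats <- structure(list(t = t_map, df = 90, contrast = "x",
                          edge_index = ei, n_nodes = p), class = "edge_stats")
  comps <- suprathreshold_components(stats, T = 3.2)
  expect_length(comps, 2)
  expect_equal(purrr::map_int(comps, "size"), c(3L, 2L))
  expect_equal(comps[[1]]$nodes, c(0, 1, 2))
  expect_equal(comps[[2]]$nodes, c(5, 6, 7))

  # nothing above threshold gives an empty list
  stats$t <- rep(0.5, nrow(ei))
  expect_length(suprathreshold_components(stats, T = 3.2), 0)
})

test_that("component decomposition equals a union-find oracle", {
  p <- 12
  ei <- thoughtnet:::edge_index(p)
  for (rep in 1:50) {
    withr::with_seed(100 + rep, t_map <- rnorm(nrow(ei), sd = 2))
    stats <- structure(list(t = t_map, df = 50, contrast = "x",
                            edge_index = ei, n_nodes = p), class = "edge_stats")
    comps <- suprathreshold_components(stats, T = 3)
    sel <- which(abs(t_map) >= 3)
    pairs <- cbind(ei$node_i[sel], ei$node_j[sel])
    oracle <- oracle_components(pairs)
    expect_equal(length(comps), length(oracle))
    got_sizes <- sort(purrr::map_int(comps, "size"))
    expect_equal(got_sizes, sort(unname(lengths(oracle))))
    # edge sets agree as sets
    got_edges <- lapply(comps, function(cp) {
      sort(paste(cp$edges$node_i, cp$edges$node_j))
    })
    want_edges <- lapply(oracle, function(rows) {
      sort(paste(pairs[rows, 1], pairs[rows, 2]))
    })
    expect_setequal(got_edges, want_edges)
  }
})

test_that("raising the threshold never grows a component", {
  n <- 60; p <- 15
  stack <- noise_stack(n, p, seed = 5)
  withr::with_seed(6, scores <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "s")))
  design <- toy_design(scores)
  stats <- edgewise_glm(stack, design, "s")
  sizes <- vapply(c(1.5, 2.0, 2.5, 3.0), function(T) {
    comps <- suprathreshold_components(stats, T)
    if (length(comps)) comps[[1]]$size else 0L
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("the permutation null is seed-deterministic", {
  n <- 40; p <- 12
  stack <- noise_stack(n, p, seed = 7)
  withr::with_seed(8, scores <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "s")))
  design <- toy_design(scores)
  r1 <- nbs_test(stack, design, "s", T = 2.5, n_perm = 100, seed = 42)
  r2 <- nbs_test(stack, design, "s", T = 2.5, n_perm = 100, seed = 42)
  expect_identical(r1$null_max_sizes, r2$null_max_sizes)
  expect_identical(tidy(r1), tidy(r2))
  r3 <- nbs_test(stack, design, "s", T = 2.5, n_perm = 100, seed = 43)
  expect_false(identical(r1$null_max_sizes, r3$null_max_sizes))
})

test_that("exhaustive permutation p equals the enumeration oracle", {
  # 6 subjects, no nuisance beyond the intercept: all 720 row shuffles
  n <- 6
  withr::with_seed(9, {
    score <- rnorm(n)
    weights1 <- rnorm(n, sd = 0.3)
    weights2 <- 0.4 * score + rnorm(n, sd = 0.15)
  })
  p <- 4
  stack <- lapply(seq_len(n), function(s) {
    m <- matrix(0, p, p)
    m[1, 2] <- m[2, 1] <- weights1[s]
    m[2, 3] <- m[3, 2] <- weights2[s]
    connectome(m, subject_id = sprintf("sub-%d", s))
  })
  design <- toy_design(cbind(s = score))
  T_thr <- 1.5
  res <- nbs_test(stack, design, "s", T = T_thr, seed = 1, exhaustive = TRUE)
  expect_equal(res$n_perm, factorial(n))

  # oracle: enumerate all shuffles, lm-based t per edge, max component size
  perms <- thoughtnet:::all_permutations(n)
  W <- cbind(weights1, weights2)
  edge_nodes <- list(c(1, 2), c(2, 3))
  null_max <- apply(perms, 1, function(idx) {
    X <- cbind(score[idx], 1)
    sizes <- 0L
    above <- vapply(1:2, function(e) {
      abs(oracle_lm_t(W[, e], X, 1)) >= T_thr
    }, logical(1))
    if (above[1] && above[2]) 2L else if (any(above)) 1L else 0L
  })
  for (comp in res$components) {
    expect_equal(comp$fwe_p, mean(null_max >= comp$size))
  }
  expect_equal(sort(res$null_max_sizes), sort(as.integer(null_max)))
})

test_that("masking retains exactly the component's edges", {
  n <- 80; p <- 15
  stack <- noise_stack(n, p, seed = 10)
  withr::with_seed(11, scores <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "s")))
  design <- toy_design(scores)
  res <- nbs_test(stack, design, "s", T = 2, n_perm = 50, seed = 1, alpha = 1)
  expect_gt(length(res$components), 0)
  comp <- res$components[[1]]
  masked <- mask_connectome(stack[[3]], res, 1)
  kept <- which(unclass(masked) != 0, arr.ind = TRUE)
  kept <- kept[kept[, 1] < kept[, 2], , drop = FALSE]
  expect_setequal(paste(kept[, 1] - 1, kept[, 2] - 1),
                  paste(comp$edges$node_i, comp$edges$node_j))
  # weights on retained edges are the subject's own
  for (r in seq_len(nrow(kept))) {
    expect_equal(masked[kept[r, 1], kept[r, 2]],
                 stack[[3]][kept[r, 1], kept[r, 2]])
  }
  # everything off the component is exactly zero
  off <- unclass(masked)
  off[cbind(kept[, 1], kept[, 2])] <- 0
  off[cbind(kept[, 2], kept[, 1])] <- 0
  expect_equal(sum(abs(off)), 0)
  expect_error(mask_connectome(stack[[1]], res, 99), "out of range")
})

test_that("design matrix validation catches rank deficiency and misalignment", {
  n <- 30
  withr::with_seed(12, {
    scores <- tibble::tibble(subject_id = sprintf("s%02d", 1:n),
                             a = rnorm(n), b = rnorm(n))
    cov <- tibble::tibble(subject_id = sprintf("s%02d", 1:n),
                          age = rnorm(n, 21), gender = rbinom(n, 1, 0.5),
                          motion_fraction = runif(n, 0, 0.2))
  })
  scores$b2 <- scores$b  # duplicate column
  expect_error(nbs_design(scores, cov, rnorm(n)), "rank deficient")
  cov2 <- cov; cov2$subject_id[1] <- "zzz"
  expect_error(nbs_design(scores[1:3], cov2, rnorm(n)), "do not match")
  expect_error(nbs_test(noise_stack(10, 5, 1),
                        toy_design(cbind(s = rnorm(10))), "s", n_perm = 0),
               "n_perm")
})
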