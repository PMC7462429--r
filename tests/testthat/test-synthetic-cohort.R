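test_that("parcellation covers every network and is seed-reproducible", {
  p <- make_parcellation(264, 13, seed = 1)
  expect_equal(nrow(p), 264)
  expect_equal(dplyr::n_distinct(p$network), 13)
  expect_true(all(table(p$network) >= 1))

  single <- make_parcellation(10, 1, seed = 0)
  expect_equal(dplyr::n_distinct(single$network), 1)

  a <- make_parcellation(60, 13, seed = 7)
  b <- make_parcellation(60, 13, seed = 7)
  expect_identical(a, b)
  expect_equal(dplyr::n_distinct(a$network), 13)

  expect_error(make_parcellation(5, 13), "exceed")
})

test_that("identical config and seed give a bit-identical cohort", {
  cfg <- cohort_config(n_subjects = 40, n_nodes = 20, seed = 5)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$ratings, c2$ratings)
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(c1$wellbeing, c2$wellbeing)
  expect_identical(c1$connectomes[[17]], c2$connectomes[[17]])
  r1 <- simulate_retest(c1)
  r2 <- simulate_retest(c2)
  expect_identical(r1$ratings, r2$ratings)
  expect_identical(r1$connectomes[[3]], r2$connectomes[[3]])
})

test_that("cohort tables share the subject index and connectomes are valid", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 30, n_nodes = 15, seed = 2))
  ids <- cohort$ratings$subject_id
  expect_identical(cohort$covariates$subject_id, ids)
  expect_identical(cohort$wellbeing$subject_id, ids)
  expect_identical(names(cohort$connectomes), ids)
  m <- unclass(cohort$connectomes[[1]])
  expect_lt(max(abs(m - t(m))), 1e-12)
  expect_equal(unname(diag(m)), rep(0, 15))
  expect_true(all(abs(m) <= 1))
  vals <- as.matrix(cohort$ratings[-1])
  expect_true(all(vals %in% 1:4))
})

test_that("planted edge-score correlation matches the closed-form oracle", {
  # default desk config; analytic r = beta * sd(score) / sd(edge), where the
  # edge variance decomposes into effect^2 + noise^2 + mean-shift^2
  cfg <- desk_cohort_config(seed = 11)
  cohort <- simulate_cohort(cfg)
  pc <- cfg$planted_components[[1]]
  beta <- pc$effect_per_edge
  r_expected <- beta / sqrt(beta^2 + cfg$noise_sd^2 + cfg$mean_shift_sd^2)
  s <- cohort$internals$factor_scores[, pc$target_factor]
  ij <- cbind(pc$edge_set[, 1] + 1L, pc$edge_set[, 2] + 1L)
  r_obs <- mean(vapply(seq_len(nrow(ij)), function(e) {
    w <- vapply(cohort$connectomes, function(m) m[ij[e, 1], ij[e, 2]], numeric(1))
    cor(w, s) * pc$sign_pattern[e]
  }, numeric(1)))
  expect_lt(abs(r_obs - r_expected), 0.1)
})

test_that("zero effect size leaves planted edges uncorrelated with scores", {
  comps <- list(random_planted_component(40, effect_per_edge = 0,
                                         target_factor = 1, seed = 3))
  cfg <- cohort_config(n_subjects = 200, n_nodes = 40, seed = 4,
                       planted_components = comps)
  cohort <- simulate_cohort(cfg)
  pc <- comps[[1]]
  s <- cohort$internals$factor_scores[, 1]
  ij <- cbind(pc$edge_set[, 1] + 1L, pc$edge_set[, 2] + 1L)
  for (e in seq_len(nrow(ij))) {
    w <- vapply(cohort$connectomes, function(m) m[ij[e, 1], ij[e, 2]], numeric(1))
    expect_lt(abs(cor(w, s)), 0.2)
  }
})

test_that("planted edge variance decomposes into effect and noise parts", {
  cfg <- cohort_config(n_subjects = 2000, n_nodes = 40, seed = 6)
  cohort <- simulate_cohort(cfg)
  pc <- cfg$planted_components[[1]]
  expected_var <- pc$effect_per_edge^2 + cfg$noise_sd^2 + cfg$mean_shift_sd^2
  ij <- cbind(pc$edge_set[, 1] + 1L, pc$edge_set[, 2] + 1L)
  for (e in seq_len(3)) {
    w <- vapply(cohort$connectomes, function(m) m[ij[e, 1], ij[e, 2]], numeric(1))
    expect_lt(abs(var(w) - expected_var) / expected_var, 0.05)
  }
})

test_that("a_path = 0 breaks the first mediation path", {
  cfg <- cohort_config(n_subjects = 200, n_nodes = 40, seed = 8,
                       mediation = mediation_truth(a_path = 0))
  cohort <- simulate_cohort(cfg)
  x <- cohort$internals$brain_summary[[2]]
  m <- cohort$internals$factor_scores[, 1]
  y <- cohort$wellbeing$psychological
  res <- mediate(x, m, y, n_boot = 500, seed = 1)
  expect_lt(abs(res$indirect), 2 * res$se_indirect)
  expect_true(res$ci_low <= 0 && res$ci_high >= 0)
})

test_that("saturating planted effects triggers the clipping warning", {
  comps <- list(random_planted_component(20, effect_per_edge = 0.9,
                                         target_factor = 1, seed = 1))
  expect_warning(
    simulate_cohort(cohort_config(n_subjects = 50, n_nodes = 20, seed = 1,
                                  planted_components = comps)),
    "saturated"
  )
})

test_that("retest ICC construction converges to the configured values", {
  cfg <- cohort_config(
    n_subjects = 1000, n_nodes = 20, seed = 9,
    planted_components = list(
      random_planted_component(20, target_factor = 1, seed = 1),
      random_planted_component(20, target_factor = 4, seed = 2)
    ),
    retest = retest_truth(n_retest = 1000, trait_icc = 0.7, state_icc = 0)
  )
  cohort <- simulate_cohort(cfg)
  s2 <- simulate_retest(cohort)
  f1 <- cohort$internals$factor_scores
  f2 <- s2$internals$factor_scores
  icc_trait <- icc(f1[, 4], f2[, 4], n_boot = 50, seed = 1)$icc
  icc_state <- icc(f1[, 1], f2[, 1], n_boot = 50, seed = 1)$icc
  expect_lt(abs(icc_trait - 0.7), 0.05)
  expect_lt(abs(icc_state), 0.1)
})

test_that("perfect trait reliability reproduces session-1 scores exactly", {
  cfg <- cohort_config(n_subjects = 60, n_nodes = 15, seed = 10,
                       retest = retest_truth(n_retest = 40, trait_icc = 1,
                                             state_icc = 0.3))
  cohort <- simulate_cohort(cfg)
  s2 <- simulate_retest(cohort)
  trait_factor <- cfg$planted_components[[2]]$target_factor
  expect_equal(s2$internals$factor_scores[, trait_factor],
               cohort$internals$factor_scores[1:40, trait_factor])
})

test_that("session-to-session change coupling lands near its target", {
  cfg <- cohort_config(n_subjects = 500, n_nodes = 30, seed = 12,
                       planted_components = list(
                         random_planted_component(30, target_factor = 1, seed = 5),
                         random_planted_component(30, target_factor = 4, seed = 6)
                       ),
                       retest = retest_truth(n_retest = 500,
                                             change_coupling = 0.4))
  cohort <- simulate_cohort(cfg)
  s2 <- simulate_retest(cohort)
  pc <- cfg$planted_components[[1]]
  ij <- cbind(pc$edge_set[, 1] + 1L, pc$edge_set[, 2] + 1L)
  w1 <- vapply(cohort$connectomes[1:500],
               function(m) mean(m[ij] * pc$sign_pattern), numeric(1))
  w2 <- vapply(s2$connectomes,
               function(m) mean(m[ij] * pc$sign_pattern), numeric(1))
  ds <- s2$internals$factor_scores[, 1] - cohort$internals$factor_scores[1:500, 1]
  expect_gt(cor(ds, w2 - w1), 0.3)
  expect_lt(cor(ds, w2 - w1), 0.5)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_nodes = 5), "at least 10")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(retest_truth(trait_icc = 1.2), "trait_icc")
  expect_error(planted_component(cbind(2, 1), 0.1), "i < j")
  expect_error(planted_component(rbind(c(0, 1), c(4, 5)), 0.1), "connected")
  cfg <- cohort_config(n_subjects = 20, n_nodes = 15, seed = 1)
  expect_error(simulate_retest(simulate_cohort(cfg),
                               retest_truth(n_retest = 50)),
               "cannot exceed")
})
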