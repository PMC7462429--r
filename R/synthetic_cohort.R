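#' Configuration for a synthetic cohort
#'
#' Bundles every ground-truth parameter of the synthetic cohort generator:
#' cohort size, parcellation size, the experience-sampling item set, the
#' planted connectome components, the mediation model, and the test-retest
#' structure. Defaults emulate the study conditions the pipeline targets:
#' 211 subjects, a 264-node parcellation in 13 networks, 25 Likert items
#' with a 2-cluster / 6-factor structure, and a 40-subject retest arm.
#'
#' @param n_subjects Number of subjects (default 211).
#' @param n_nodes Number of parcellation nodes (default 264; see
#'   [desk_cohort_config()] for a smaller desk-scale setting).
#' @param n_items Number of Likert items (default 25).
#' @param n_networks Number of large-scale networks (default 13).
#' @param planted_components List of [planted_component()] objects; `NULL`
#'   plants the default pair: a state-like mediated component tracking the
#'   first factor of the first item cluster and a trait-like non-mediated
#'   component tracking the first factor of the second cluster.
#' @param mediation A [mediation_truth()] object.
#' @param retest A [retest_truth()] object.
#' @param noise_sd Per-edge connectome noise standard deviation
#'   (correlation units, default 0.16).
#' @param mean_shift_sd Standard deviation of the subject-level mean
#'   connectivity offset applied to all edges (default 0.06); makes the
#'   mean-connectivity nuisance regressor non-degenerate.
#' @param item_loading Loading of each item on its primary latent factor
#'   (default 0.95; items are near-pure indicators so the planted simple
#'   structure survives Likert discretization).
#' @param factor_within_correlation Correlation between latent factors of
#'   the same item cluster (default 0.2); factors of different clusters
#'   are independent. This is what gives the item set its 2-cluster
#'   structure, recoverable by Ward clustering.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 211L,
                          n_nodes = 264L,
                          n_items = 25L,
                          n_networks = 13L,
                          planted_components = NULL,
                          mediation = mediation_truth(),
                          retest = retest_truth(),
                          noise_sd = 0.16,
                          mean_shift_sd = 0.06,
                          item_loading = 0.95,
                          factor_within_correlation = 0.2,
                          seed = 1L) {
  n_subjects <- check_positive_int(n_subjects, "n_subjects")
  n_nodes <- check_positive_int(n_nodes, "n_nodes")
  n_items <- check_positive_int(n_items, "n_items")
  n_networks <- check_positive_int(n_networks, "n_networks")
  if (n_nodes < 10L) abort("`n_nodes` must be at least 10")
  if (n_items < 6L) abort("`n_items` must be at least 6 (two clusters of 3 factors)")
  if (!is.numeric(noise_sd) || noise_sd <= 0) abort("`noise_sd` must be > 0")
  if (mean_shift_sd < 0) abort("`mean_shift_sd` must be >= 0")
  if (item_loading <= 0 || item_loading >= 1) abort("`item_loading` must be in (0, 1)")
  if (factor_within_correlation < 0 || factor_within_correlation >= 1) {
    abort("`factor_within_correlation` must be in [0, 1)")
  }
  if (n_networks > n_nodes) abort("`n_networks` must not exceed `n_nodes`")
  if (is.null(planted_components)) {
    planted_components <- default_planted_components(n_nodes, seed = seed)
  }
  if (is.null(names(planted_components))) {
    names(planted_components) <- paste0("comp", seq_along(planted_components))
  }
  for (pc in planted_components) {
    if (!inherits(pc, "planted_component")) {
      abort("`planted_components` must be a list of planted_component objects")
    }
    if (any(pc$edge_set >= n_nodes) || any(pc$edge_set < 0)) {
      abort("planted component node ids must lie in [0, n_nodes)")
    }
  }
  structure(
    list(
      n_subjects = n_subjects, n_nodes = n_nodes, n_items = n_items,
      n_networks = n_networks, planted_components = planted_components,
      mediation = mediation, retest = retest, noise_sd = noise_sd,
      mean_shift_sd = mean_shift_sd, item_loading = item_loading,
      factor_within_correlation = factor_within_correlation,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Desk-scale cohort configuration
#'
#' The default configuration scaled down to sizes convenient for interactive
#' work and simulation studies: 200 subjects and 60 nodes, all other
#' structure unchanged.
#'
#' @param seed Integer seed (default 11).
#' @param ... Overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
desk_cohort_config <- function(seed = 11L, ...) {
  cohort_config(n_subjects = 200L, n_nodes = 60L, seed = seed, ...)
}

#' Define a planted connectome component
#'
#' A connected set of edges whose weights shift with a latent thought factor;
#' the ground truth that the network-based statistic should recover.
#'
#' @param edge_set Two-column matrix of 0-based node pairs `(i, j)` with
#'   `i < j`; must form a connected graph.
#' @param effect_per_edge Per-unit-score shift in edge weight (correlation
#'   units); must be non-negative.
#' @param sign_pattern Per-edge association sign in `{-1, +1}`; recycled if
#'   length 1.
#' @param target_factor Index (1-6) of the latent thought factor the
#'   component tracks.
#' @param base_weight Optional per-edge baseline weight written into the
#'   shared population matrix at the planted edges; mixing positive and
#'   negative baselines keeps the component's fractional strength
#'   well-defined and gives it a monotone coupling with the target score.
#'   `NULL` leaves the population matrix untouched.
#' @return A list of class `planted_component`.
#' @export
planted_component <- function(edge_set, effect_per_edge, sign_pattern = 1,
                              target_factor = 1L, base_weight = NULL) {
  edge_set <- as.matrix(edge_set)
  storage.mode(edge_set) <- "integer"
  if (ncol(edge_set) != 2L || any(edge_set[, 1L] >= edge_set[, 2L])) {
    abort("`edge_set` must be a two-column matrix of pairs (i, j) with i < j")
  }
  if (effect_per_edge < 0) abort("`effect_per_edge` must be >= 0")
  sign_pattern <- rep_len(sign_pattern, nrow(edge_set))
  if (!all(sign_pattern %in% c(-1, 1))) abort("`sign_pattern` must be -1 or +1")
  if (!edges_connected(edge_set)) abort("`edge_set` must form a connected graph")
  if (!is.null(base_weight)) {
    base_weight <- rep_len(base_weight, nrow(edge_set))
    if (any(abs(base_weight) > 1)) abort("`base_weight` must lie in [-1, 1]")
  }
  structure(
    list(edge_set = edge_set, effect_per_edge = effect_per_edge,
         sign_pattern = sign_pattern, target_factor = as.integer(target_factor),
         base_weight = base_weight),
    class = "planted_component"
  )
}

edges_connected <- function(edge_set) {
  g <- igraph::graph_from_edgelist(edge_set + 1L, directed = FALSE)
  comp <- igraph::components(g)
  nodes_used <- unique(as.vector(edge_set + 1L))
  length(unique(comp$membership[nodes_used])) == 1L
}

#' Draw a random connected planted component
#'
#' @param n_nodes Parcellation size the node ids must fit in.
#' @param n_edges Number of edges (default 10).
#' @param effect_per_edge,sign_pattern,target_factor See [planted_component()].
#' @param seed Integer seed.
#' @return A `planted_component`.
#' @export
random_planted_component <- function(n_nodes, n_edges = 10L,
                                     effect_per_edge = 0.1,
                                     sign_pattern = NULL,
                                     target_factor = 1L, seed = 1L,
                                     base_magnitude = 0.35) {
  withr::with_seed(seed, {
    # random tree over n_edges+1 sampled nodes guarantees connectivity,
    # remaining edges close random cycles within the same node set
    nodes <- sample(n_nodes, n_edges + 1L) - 1L
    edges <- cbind(nodes[1L + seq_len(n_edges - 1L)],
                   vapply(seq_len(n_edges - 1L),
                          function(k) nodes[sample.int(k, 1L)], integer(1)))
    repeat {
      if (nrow(edges) >= n_edges) break
      cand <- sort(sample(nodes, 2L))
      if (!any(edges[, 1L] == cand[1L] & edges[, 2L] == cand[2L]) &&
          cand[1L] != cand[2L]) {
        edges <- rbind(edges, cand)
      }
    }
    edges <- t(apply(edges, 1L, sort))
    edges <- edges[seq_len(n_edges), , drop = FALSE]
    # baseline: ~60% positive, ~40% negative edges so both strength sums are
    # bounded away from zero; score effects mostly increase the positive sum
    # and shrink the negative one, with one flipped edge to keep the
    # component's association signs mixed
    n_neg <- max(1L, round(0.4 * n_edges))
    base_weight <- base_magnitude * rep(c(1, -1), c(n_edges - n_neg, n_neg))
    if (is.null(sign_pattern)) {
      sign_pattern <- rep(1, n_edges)
      sign_pattern[1L] <- -1
    }
  })
  planted_component(edges, effect_per_edge, sign_pattern, target_factor,
                    base_weight = base_weight)
}

default_planted_components <- function(n_nodes, seed = 1L) {
  list(
    state = random_planted_component(n_nodes, n_edges = 10L,
                                     effect_per_edge = 0.1,
                                     target_factor = 1L,
                                     seed = derive_seed(seed, 101L)),
    trait = random_planted_component(n_nodes, n_edges = 10L,
                                     effect_per_edge = 0.1,
                                     target_factor = 4L,
                                     seed = derive_seed(seed, 102L))
  )
}

#' Ground-truth mediation model
#'
#' Parameters of the planted brain -> thought -> well-being chain. The
#' brain -> thought coupling (`a_path`) is realized through the planted edge
#' effect of the mediated component: the generator multiplies that
#' component's `effect_per_edge` by `a_path`, so `a_path = 0` severs the
#' first path entirely.
#'
#' @param a_path Multiplier on the mediated component's edge effect
#'   (default 1).
#' @param b_path Thought -> well-being coefficient on the standardized scale
#'   (default 0.4).
#' @param c_prime Direct brain -> well-being coefficient (default 0.2).
#' @param covariate_effects Named coefficients for `age`, `gender`,
#'   `motion_fraction` in the well-being model.
#' @param social_direct Direct effect of the non-mediated (trait-like)
#'   component's connectivity on social well-being (default 0.3); no thought
#'   path feeds social well-being, so its indirect effect is null by
#'   construction.
#' @param target_factor Latent factor index carrying the mediated path
#'   (default 1, the state-like factor).
#' @param wellbeing_noise_sd Residual standard deviation of the well-being
#'   scores (default 0.8).
#' @return A list of class `mediation_truth`.
#' @export
mediation_truth <- function(a_path = 1, b_path = 0.4, c_prime = 0.2,
                            covariate_effects = c(age = 0.1, gender = 0.1,
                                                  motion_fraction = -0.1),
                            social_direct = 0.3,
                            target_factor = 1L,
                            wellbeing_noise_sd = 0.8) {
  vals <- c(a_path, b_path, c_prime, covariate_effects, social_direct,
            wellbeing_noise_sd)
  if (!all(is.finite(vals))) abort("mediation truth parameters must be finite")
  structure(
    list(a_path = a_path, b_path = b_path, c_prime = c_prime,
         covariate_effects = covariate_effects, social_direct = social_direct,
         target_factor = as.integer(target_factor),
         wellbeing_noise_sd = wellbeing_noise_sd),
    class = "mediation_truth"
  )
}

#' Ground-truth test-retest structure
#'
#' @param n_retest Number of subjects with a second session (default 40).
#' @param trait_icc Population intraclass correlation of the trait-like
#'   factor across sessions, in `[0, 1]` (default 0.7).
#' @param state_icc Population ICC of the state-like factor (default 0.3).
#' @param change_coupling Target correlation between session-to-session
#'   change in the state-like score and change in the planted component's
#'   mean connectivity, in `[-1, 1]` (default 0.4).
#' @return A list of class `retest_truth`.
#' @export
retest_truth <- function(n_retest = 40L, trait_icc = 0.7, state_icc = 0.3,
                         change_coupling = 0.4) {
  n_retest <- check_positive_int(n_retest, "n_retest")
  if (trait_icc < 0 || trait_icc > 1) abort("`trait_icc` must be in [0, 1]")
  if (state_icc < 0 || state_icc > 1) abort("`state_icc` must be in [0, 1]")
  if (abs(change_coupling) > 1) abort("`change_coupling` must be in [-1, 1]")
  structure(
    list(n_retest = n_retest, trait_icc = trait_icc, state_icc = state_icc,
         change_coupling = change_coupling),
    class = "retest_truth"
  )
}

experience_item_labels <- function(n_items) {
  pool <- c("task", "future", "past", "self", "other", "emotion_pos",
            "emotion_neg", "images", "words", "specific", "important",
            "deliberate", "spontaneous", "problem", "habit", "realistic",
            "detailed", "intrusive", "distracting", "vague", "memory",
            "creative", "vivid", "source", "stop")
  if (n_items <= length(pool)) pool[seq_len(n_items)]
  else c(pool, sprintf("item_%02d", seq_len(n_items - length(pool))))
}

# items split into two clusters; within cluster, items cycle over 3 factors;
# cluster A carries factors 1-3, cluster B factors 4-6
item_factor_map <- function(n_items) {
  n_a <- ceiling(n_items / 2)
  cluster <- rep(c("A", "B"), c(n_a, n_items - n_a))
  factor <- integer(n_items)
  factor[cluster == "A"] <- rep_len(1:3, n_a)
  factor[cluster == "B"] <- rep_len(4:6, n_items - n_a)
  tibble::tibble(item = experience_item_labels(n_items),
                 cluster = cluster, factor = factor)
}

# realized per-edge effects after the mediation a_path multiplier
realized_effects <- function(config) {
  purrr::map_dbl(config$planted_components, function(pc) {
    eff <- pc$effect_per_edge
    if (pc$target_factor == config$mediation$target_factor) {
      eff <- eff * config$mediation$a_path
    }
    eff
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates, from a single seed, every table the analysis pipeline consumes:
#' Likert thought ratings produced by 6 latent factors through planted
#' loadings, per-subject signed connectomes equal to a shared population
#' matrix plus a subject-level mean shift, planted score-tracking edge
#' effects, and edge noise (clipped to `[-1, 1]`), covariates (age, gender,
#' motion fraction), and well-being scores following the configured mediation
#' model, where the brain predictor is the log fractional strength of the
#' mediated planted component.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `parcellation`,
#'   `connectomes` (named list of [connectome()] matrices), `ratings`,
#'   `covariates`, `wellbeing` (tibbles keyed by `subject_id`), `truth`
#'   (the config echoed back), and `internals` (latent quantities retained
#'   for retest simulation and for tests).
#' @export
#' @examples
#' cohort <- simulate_cohort(desk_cohort_config(seed = 1))
#' names(cohort)
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a cohort_config")
  n <- config$n_subjects
  p <- config$n_nodes
  n_edges <- p * (p - 1L) / 2L
  subject_ids <- sprintf("sub-%04d", seq_len(n))
  parcellation <- make_parcellation(p, config$n_networks,
                                    seed = derive_seed(config$seed, 1L))
  map <- item_factor_map(config$n_items)
  effects <- realized_effects(config)
  positions <- purrr::map(config$planted_components,
                          ~ edge_positions(.x$edge_set, p))

  out <- withr::with_seed(derive_seed(config$seed, 2L), {
    scores <- draw_factor_scores(n, config$factor_within_correlation)

    # ratings: latent item = loading * factor + residual, cut at the
    # standard-normal quartiles into 1..4
    lam <- config$item_loading
    latent <- scores[, map$factor, drop = FALSE] * lam +
      matrix(rnorm(n * config$n_items), n, config$n_items) * sqrt(1 - lam^2)
    cutpoints <- qnorm(c(0.25, 0.5, 0.75))
    ratings_vals <- matrix(
      findInterval(latent, cutpoints) + 1L, n, config$n_items,
      dimnames = list(NULL, map$item)
    )

    # shared population matrix: correlation of a low-rank factor model,
    # shrunk toward zero so weights stay well inside [-1, 1]
    g <- matrix(rnorm(p * 5L), p, 5L)
    pop <- stats::cov2cor(tcrossprod(g) + diag(5, p)) * 0.6
    base_upper <- upper_tri_values(pop)
    for (k in seq_along(positions)) {
      bw <- config$planted_components[[k]]$base_weight
      if (!is.null(bw)) base_upper[positions[[k]]] <- bw
    }

    mean_shift <- rnorm(n, 0, config$mean_shift_sd)
    n_sat <- 0L
    n_planted_vals <- n * sum(lengths(positions))
    connectomes <- vector("list", n)
    for (s in seq_len(n)) {
      w <- base_upper + mean_shift[s] + rnorm(n_edges, 0, config$noise_sd)
      for (k in seq_along(positions)) {
        w[positions[[k]]] <- w[positions[[k]]] +
          scores[s, config$planted_components[[k]]$target_factor] *
          effects[k] * config$planted_components[[k]]$sign_pattern
      }
      n_sat <- n_sat + sum(abs(w[unlist(positions)]) > 1)
      w <- pmin(pmax(w, -1), 1)
      m <- matrix_from_upper(w, p)
      if (!all(is.finite(m))) abort("internal error: non-finite connectome weights")
      connectomes[[s]] <- connectome(m, subject_id = subject_ids[s],
                                     labels = parcellation$label)
    }
    if (n_planted_vals > 0 && n_sat / n_planted_vals > 0.05) {
      warn(sprintf("clipping saturated %.1f%% of planted edge values",
                   100 * n_sat / n_planted_vals))
    }

    covariates <- tibble::tibble(
      subject_id = subject_ids,
      age = pmin(pmax(round(rnorm(n, 20.85, 2.44)), 18), 31),
      gender = rbinom(n, 1L, 0.61),
      motion_fraction = rbeta(n, 1.5, 18)
    )

    # brain summaries: log fractional strength of each planted component
    brain <- purrr::imap(config$planted_components, function(pc, nm) {
      vapply(connectomes, function(cm) {
        wts <- cm[cbind(pc$edge_set[, 1L] + 1L, pc$edge_set[, 2L] + 1L)]
        pos <- sum(pmax(wts, 0)); neg <- sum(-pmin(wts, 0))
        if (neg == 0) NA_real_ else log(pos / neg)
      }, numeric(1))
    })

    med <- config$mediation
    zscore <- function(x) as.vector(scale(x))
    cov_term <- med$covariate_effects[["age"]] * zscore(covariates$age) +
      med$covariate_effects[["gender"]] * covariates$gender +
      med$covariate_effects[["motion_fraction"]] * zscore(covariates$motion_fraction)
    z_brain1 <- zscore(brain[[1L]])
    psych <- med$c_prime * ifelse(is.na(z_brain1), 0, z_brain1) +
      med$b_path * scores[, med$target_factor] + cov_term +
      rnorm(n, 0, med$wellbeing_noise_sd)
    if (length(brain) >= 2L) {
      z_brain2 <- zscore(brain[[2L]])
      social <- med$social_direct * ifelse(is.na(z_brain2), 0, z_brain2) +
        cov_term + rnorm(n, 0, med$wellbeing_noise_sd)
    } else {
      social <- cov_term + rnorm(n, 0, med$wellbeing_noise_sd)
    }

    list(
      connectomes = stats::setNames(connectomes, subject_ids),
      ratings = tibble::as_tibble(cbind(
        tibble::tibble(subject_id = subject_ids),
        tibble::as_tibble(ratings_vals)
      )),
      covariates = covariates,
      wellbeing = tibble::tibble(subject_id = subject_ids,
                                 psychological = psych, social = social),
      internals = list(
        session = 1L,
        factor_scores = scores,
        item_map = map,
        base_upper = base_upper,
        mean_shift = mean_shift,
        brain_summary = tibble::as_tibble(
          c(list(subject_id = subject_ids), brain)
        )
      )
    )
  })

  structure(
    c(list(parcellation = parcellation), out[c("connectomes", "ratings",
                                               "covariates", "wellbeing")],
      list(truth = config, internals = out$internals)),
    class = "synthetic_cohort"
  )
}

#' Simulate a second (retest) session
#'
#' Regenerates scores, ratings, and connectomes for the retest subjects so
#' that (i) the trait-like factor (the non-mediated component's target) has
#' population ICC `trait_icc` across sessions, (ii) the state-like factor has
#' population ICC `state_icc`, and (iii) the correlation between
#' session-to-session change in the state-like score and change in the
#' planted component's mean edge weight equals `change_coupling`. The last
#' constraint is met by adding a shared session-2 perturbation to the state
#' component's edges whose variance is solved in closed form from the
#' generative variances; when the planted effect cannot admit a coupling as
#' low as requested the perturbation is clamped at zero with a warning.
#'
#' @param cohort A [simulate_cohort()] result (session 1).
#' @param truth A [retest_truth()]; defaults to the cohort's configured one.
#' @return A `synthetic_cohort` holding session-2 data for the first
#'   `n_retest` subjects; `internals$session` is 2 and
#'   `internals$retest_ids` names the subjects.
#' @export
simulate_retest <- function(cohort, truth = cohort$truth$retest) {
  if (!inherits(cohort, "synthetic_cohort")) abort("`cohort` must be a synthetic_cohort")
  config <- cohort$truth
  if (truth$n_retest > config$n_subjects) {
    abort("`n_retest` cannot exceed the cohort size")
  }
  idx <- seq_len(truth$n_retest)
  subject_ids <- cohort$covariates$subject_id[idx]
  p <- config$n_nodes
  n_edges <- p * (p - 1L) / 2L
  map <- cohort$internals$item_map
  effects <- realized_effects(config)
  positions <- purrr::map(config$planted_components,
                          ~ edge_positions(.x$edge_set, p))
  targets <- purrr::map_int(config$planted_components, "target_factor")
  state_factor <- config$mediation$target_factor
  trait_factor <- setdiff(targets, state_factor)[1] %||% NA_integer_
  state_comp <- unname(which(targets == state_factor))[1]

  rho <- rep(truth$state_icc, 6L)
  rho[state_factor] <- truth$state_icc
  if (!is.na(trait_factor)) rho[trait_factor] <- truth$trait_icc

  out <- withr::with_seed(derive_seed(config$seed, 3L), {
    s1 <- cohort$internals$factor_scores[idx, , drop = FALSE]
    eps <- matrix(rnorm(length(idx) * 6L), length(idx), 6L)
    s2 <- sweep(s1, 2L, rho, `*`) +
      sweep(eps, 2L, sqrt(1 - rho^2), `*`)

    lam <- config$item_loading
    latent <- s2[, map$factor, drop = FALSE] * lam +
      matrix(rnorm(length(idx) * config$n_items),
             length(idx), config$n_items) * sqrt(1 - lam^2)
    ratings_vals <- matrix(
      findInterval(latent, qnorm(c(0.25, 0.5, 0.75))) + 1L,
      length(idx), config$n_items, dimnames = list(NULL, map$item)
    )

    # session-2-only shared perturbation sized so the population correlation
    # of (delta score, delta mean planted edge weight) hits change_coupling
    zeta_sd <- 0
    if (!is.na(state_comp) && effects[state_comp] > 0 &&
        truth$change_coupling != 0) {
      beta <- effects[state_comp]
      n_pe <- length(positions[[state_comp]])
      var_ds <- 2 * (1 - rho[state_factor])
      noise_var <- 2 * config$noise_sd^2 / n_pe
      need <- beta^2 * var_ds * (1 / truth$change_coupling^2 - 1) - noise_var
      if (need < 0) {
        warn("requested change_coupling exceeds what the planted effect admits; using the maximum achievable")
        need <- 0
      }
      zeta_sd <- sqrt(need)
    }
    zeta <- rnorm(length(idx), 0, zeta_sd)

    connectomes <- vector("list", length(idx))
    for (s in seq_along(idx)) {
      w <- cohort$internals$base_upper + cohort$internals$mean_shift[idx[s]] +
        rnorm(n_edges, 0, config$noise_sd)
      for (k in seq_along(positions)) {
        # state-like connectivity follows the session-2 score; trait-like
        # components express the stable session-1 score, so their
        # session-to-session changes are decoupled from score changes
        drive <- if (isTRUE(k == state_comp)) {
          s2[s, config$planted_components[[k]]$target_factor]
        } else {
          s1[s, config$planted_components[[k]]$target_factor]
        }
        w[positions[[k]]] <- w[positions[[k]]] +
          drive * effects[k] * config$planted_components[[k]]$sign_pattern
      }
      if (!is.na(state_comp)) {
        w[positions[[state_comp]]] <- w[positions[[state_comp]]] +
          zeta[s] * config$planted_components[[state_comp]]$sign_pattern
      }
      w <- pmin(pmax(w, -1), 1)
      connectomes[[s]] <- connectome(matrix_from_upper(w, p),
                                     subject_id = subject_ids[s],
                                     labels = cohort$parcellation$label)
    }
    list(scores = s2,
         ratings = tibble::as_tibble(cbind(
           tibble::tibble(subject_id = subject_ids),
           tibble::as_tibble(ratings_vals)
         )),
         connectomes = stats::setNames(connectomes, subject_ids))
  })

  structure(
    list(
      parcellation = cohort$parcellation,
      connectomes = out$connectomes,
      ratings = out$ratings,
      covariates = cohort$covariates[idx, ],
      wellbeing = cohort$wellbeing[idx, ],
      truth = config,
      internals = list(session = 2L, factor_scores = out$scores,
                       item_map = map, retest_ids = subject_ids)
    ),
    class = "synthetic_cohort"
  )
}

#' Simulate a standalone mediation triplet
#'
#' Draws `(x, m, y)` from a linear mediation model with standardized path
#' coefficients `a`, `b`, `c_prime` (all marginal variances 1 when the paths
#' permit), plus nuisance covariates with zero true effect. Used for
#' parameter-recovery and coverage studies of [mediate()].
#'
#' @param n Sample size.
#' @param a,b,c_prime True standardized path coefficients.
#' @param seed Integer seed.
#' @return A tibble with columns `x`, `m`, `y`, `age`, `gender`,
#'   `motion_fraction`.
#' @export
simulate_mediation_triplet <- function(n, a = 0.5, b = 0.4, c_prime = 0,
                                       seed = 1L) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    m <- a * x + rnorm(n, 0, sqrt(max(0, 1 - a^2)))
    vy <- 1 - c_prime^2 - b^2 - 2 * a * b * c_prime
    y <- c_prime * x + b * m + rnorm(n, 0, sqrt(max(0.05, vy)))
    tibble::tibble(
      x = x, m = m, y = y,
      age = rnorm(n, 21, 2.4),
      gender = rbinom(n, 1L, 0.61),
      motion_fraction = rbeta(n, 1.5, 18)
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> session %d: %d subjects, %d nodes, %d items, %d planted component(s)\n",
    x$internals$session, nrow(x$covariates), x$truth$n_nodes,
    x$truth$n_items, length(x$truth$planted_components)
  ))
  invisible(x)
}

# six unit-variance latent factors: factors 1-3 (cluster A) and 4-6
# (cluster B) share a within-cluster correlation, clusters are independent
draw_factor_scores <- function(n, rho_within) {
  g <- matrix(rnorm(n * 2L), n, 2L)
  u <- matrix(rnorm(n * 6L), n, 6L)
  cluster_of_factor <- rep(1:2, each = 3L)
  sqrt(rho_within) * g[, cluster_of_factor] + sqrt(1 - rho_within) * u
}
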