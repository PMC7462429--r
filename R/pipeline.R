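#' Pipeline configuration
#'
#' Analysis settings for the end-to-end pipeline. The defaults reproduce
#' the target study settings: primary threshold T = 3.2, 5,000 permutations
#' at alpha = 0.05, 5,000 bootstrap samples, two-sided edge inclusion, and
#' 3 components per item cluster.
#'
#' @param T_threshold Primary edge t threshold (default 3.2).
#' @param n_permutations Permutations for the NBS null (default 5000).
#' @param alpha Component significance level (default 0.05).
#' @param sidedness Edge inclusion rule (default `"two_sided"`).
#' @param scheme Permutation scheme (default `"permute_interest"`).
#' @param n_boot Bootstrap samples for ICC and mediation (default 5000).
#' @param n_components Components retained per item cluster (default 3).
#' @param component_rule `"fixed"` or `"eigenvalue_gt_1"`.
#' @param icc_form ICC form (default `"ICC2_1"`).
#' @param seed Integer seed controlling all randomness.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(T_threshold = 3.2, n_permutations = 5000L,
                            alpha = 0.05,
                            sidedness = c("two_sided", "positive", "negative"),
                            scheme = c("permute_interest", "freedman_lane"),
                            n_boot = 5000L, n_components = 3L,
                            component_rule = c("fixed", "eigenvalue_gt_1"),
                            icc_form = c("ICC2_1", "ICC3_1"),
                            seed = 1L) {
  if (T_threshold <= 0) abort("`T_threshold` must be > 0")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  structure(
    list(T_threshold = T_threshold,
         n_permutations = check_positive_int(n_permutations, "n_permutations"),
         alpha = alpha, sidedness = match.arg(sidedness),
         scheme = match.arg(scheme),
         n_boot = check_positive_int(n_boot, "n_boot"),
         n_components = check_positive_int(n_components, "n_components"),
         component_rule = match.arg(component_rule),
         icc_form = match.arg(icc_form), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Desk-scale pipeline configuration
#'
#' The study-default settings with the Monte Carlo sizes reduced for
#' interactive and simulation work: 1,000 permutations and 1,000 bootstrap
#' samples.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
desk_pipeline_config <- function(seed = 1L, ...) {
  pipeline_config(n_permutations = 1000L, n_boot = 1000L, seed = seed, ...)
}

#' Run the full analysis pipeline
#'
#' Chains every stage on aligned input tables: thought decomposition
#' (Ward clustering, per-cluster varimax PCA, component scores), the
#' network-based statistic for each of the six thought contrasts with mean
#' connectivity, age, gender, and motion fraction as nuisance regressors,
#' graph metrics on every FWE-significant component, test-retest
#' reliability when a second session is supplied (session-1 decomposition
#' imposed on session 2), and percentile-bootstrap mediation of each
#' significant component's log fractional strength on both well-being
#' domains through its thought score, Bonferroni-corrected across the two
#' domains.
#'
#' @param ratings Ratings tibble (`subject_id` + item columns).
#' @param connectomes Named list of [connectome()] matrices keyed by
#'   subject id, aligned with `ratings`.
#' @param covariates Tibble: `subject_id`, `age`, `gender`,
#'   `motion_fraction`.
#' @param wellbeing Tibble: `subject_id`, `psychological`, `social`.
#' @param parcellation Optional [make_parcellation()] table (echoed into
#'   the report).
#' @param retest Optional list with elements `ratings` and `connectomes`
#'   for the second session (a retest `synthetic_cohort` also works).
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` with elements `decomposition`,
#'   `nbs` (one `nbs_result` per contrast), `significant` (tibble of
#'   significant components), `metrics`, `brain` (per-subject log
#'   fractional strength per significant component), `reliability`,
#'   `mediation`, and `provenance`.
#' @export
run_pipeline <- function(ratings, connectomes, covariates, wellbeing,
                         parcellation = NULL, retest = NULL,
                         config = pipeline_config()) {
  check_alignment(ratings, connectomes, covariates, wellbeing)

  # stage 1: thought decomposition
  linkage <- cluster_items(ratings)
  model <- fit_pca_varimax(ratings, linkage, config$n_components)
  scores <- score_components(model, ratings)

  # stage 2: edgewise GLM + NBS per contrast
  stack <- stack_connectomes(connectomes)
  mean_conn <- vapply(connectomes, mean_connectivity, numeric(1))
  design <- nbs_design(scores, covariates, unname(mean_conn))
  contrasts <- design$interest
  nbs <- purrr::imap(stats::setNames(contrasts, contrasts), function(ctr, nm) {
    nbs_test(stack, design, ctr, T = config$T_threshold,
             n_perm = config$n_permutations,
             seed = derive_seed(config$seed, 10L + match(ctr, contrasts)),
             scheme = config$scheme, sidedness = config$sidedness,
             alpha = config$alpha)
  })
  significant <- significant_components(nbs)

  # stage 3: graph metrics and per-subject brain summaries
  metrics <- list(); brain <- list()
  for (i in seq_len(nrow(significant))) {
    ctr <- significant$contrast[i]
    ci <- significant$component[i]
    key <- significant$id[i]
    masked <- purrr::map(connectomes, mask_connectome,
                         result = nbs[[ctr]], component_index = ci)
    metrics[[key]] <- dplyr::bind_rows(
      purrr::map(masked, graph_metrics, component_id = key))
    b <- vapply(masked, function(m) {
      suppressWarnings(fractional_strength(m, "graph")$log_fractional_strength)
    }, numeric(1))
    n_undef <- sum(!is.finite(b))
    if (n_undef > 0) {
      inform(sprintf("component %s: %d subject(s) with undefined log fractional strength treated as missing", key, n_undef))
    }
    brain[[key]] <- ifelse(is.finite(b), b, NA_real_)
  }

  # stage 4: reliability (imposed decomposition on session 2)
  reliability <- NULL
  if (!is.null(retest)) {
    reliability <- reliability_stage(retest, model, scores, nbs, significant,
                                     brain, config)
  }

  # stage 5: mediation per significant component, both well-being domains
  mediation <- purrr::pmap(significant, function(contrast, component, id, ...) {
    med <- purrr::map(c(psychological = "psychological", social = "social"),
                      function(domain) {
        mediate(brain[[id]], scores[[contrast]], wellbeing[[domain]],
                covariates = covariates[c("age", "gender", "motion_fraction")],
                n_boot = config$n_boot,
                seed = derive_seed(config$seed, 20L + component))
      })
    regress <- purrr::map(c(psychological = "psychological", social = "social"),
                          function(domain) {
      fit_linear(wellbeing[[domain]],
                 tibble::tibble(brain = brain[[id]],
                                age = covariates$age, gender = covariates$gender,
                                motion_fraction = covariates$motion_fraction))
    })
    raw_p <- purrr::map_dbl(regress,
                            ~ .x$coefficients$p.value[.x$coefficients$term == "brain"])
    list(component = id, regressions = regress,
         brain_p_bonferroni = bonferroni_domains(raw_p, 2L),
         mediation = med)
  })
  names(mediation) <- significant$id

  structure(
    list(decomposition = list(linkage = linkage, model = model, scores = scores),
         nbs = nbs, significant = significant, metrics = metrics,
         brain = brain, reliability = reliability, mediation = mediation,
         provenance = list(config = config, n_subjects = nrow(ratings),
                           n_nodes = stack$n_nodes,
                           package_version = as.character(utils::packageVersion("thoughtnet")),
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "pipeline_report"
  )
}

check_alignment <- function(ratings, connectomes, covariates, wellbeing) {
  ids <- ratings$subject_id
  if (!identical(covariates$subject_id, ids)) {
    abort("`covariates` subject ids are not aligned with `ratings`")
  }
  if (!identical(wellbeing$subject_id, ids)) {
    abort("`wellbeing` subject ids are not aligned with `ratings`")
  }
  if (!is.null(names(connectomes)) && !identical(names(connectomes), ids)) {
    abort("`connectomes` names are not aligned with `ratings` subject ids")
  }
  if (length(connectomes) != length(ids)) {
    abort("`connectomes` count differs from the subject count")
  }
  invisible(TRUE)
}

significant_components <- function(nbs) {
  rows <- purrr::imap(nbs, function(res, ctr) {
    purrr::imap(res$components, function(comp, i) {
      tibble::tibble(contrast = ctr, component = i, size = comp$size,
                     n_nodes = length(comp$nodes), fwe_p = comp$fwe_p,
                     significant = comp$significant)
    })
  })
  all <- dplyr::bind_rows(purrr::flatten(rows))
  if (!nrow(all)) {
    return(tibble::tibble(contrast = character(), component = integer(),
                          size = integer(), n_nodes = integer(),
                          fwe_p = numeric(), significant = logical(),
                          id = character()))
  }
  sig <- dplyr::filter(all, .data$significant)
  dplyr::mutate(sig, id = paste0(.data$contrast, "_c", .data$component))
}

reliability_stage <- function(retest, model, scores, nbs, significant, brain,
                              config) {
  retest_ratings <- if (inherits(retest, "synthetic_cohort")) retest$ratings else retest$ratings
  retest_conn <- if (inherits(retest, "synthetic_cohort")) retest$connectomes else retest$connectomes
  ids2 <- retest_ratings$subject_id
  idx1 <- match(ids2, scores$subject_id)
  if (anyNA(idx1)) abort("retest subjects missing from session 1")
  scores2 <- project_session(model, retest_ratings)

  comp_names <- setdiff(names(scores), "subject_id")
  score_icc <- purrr::map(stats::setNames(comp_names, comp_names),
                          function(comp) {
    icc(scores[[comp]][idx1], scores2[[comp]], n_boot = config$n_boot,
        seed = derive_seed(config$seed, 30L), form = config$icc_form)
  })

  brain_icc <- list(); change <- list()
  for (i in seq_len(nrow(significant))) {
    ctr <- significant$contrast[i]
    ci <- significant$component[i]
    key <- significant$id[i]
    masked2 <- purrr::map(retest_conn, mask_connectome,
                          result = nbs[[ctr]], component_index = ci)
    brain2 <- vapply(masked2, function(m) {
      suppressWarnings(fractional_strength(m, "graph")$log_fractional_strength)
    }, numeric(1))
    brain2 <- ifelse(is.finite(brain2), brain2, NA_real_)
    brain1 <- brain[[key]][idx1]
    ok <- stats::complete.cases(brain1, brain2)
    brain_icc[[key]] <- icc(brain1[ok], brain2[ok], n_boot = config$n_boot,
                            seed = derive_seed(config$seed, 31L + i),
                            form = config$icc_form)
    change[[key]] <- change_correlation(
      scores2[[ctr]] - scores[[ctr]][idx1],
      ifelse(ok, brain2 - brain1, NA_real_)
    )
  }
  list(score_icc = score_icc, brain_icc = brain_icc, change = change,
       n_retest = length(ids2))
}

#' Simulate a cohort and run the full pipeline on it
#'
#' The "run-all" convenience for synthetic studies: simulates a cohort (and
#' its retest arm) from a [cohort_config()], runs [run_pipeline()], and
#' attaches the ground truth to the report for recovery checks.
#'
#' @param cohort_config A [cohort_config()] (default [desk_cohort_config()]).
#' @param config A [pipeline_config()] (default [desk_pipeline_config()]
#'   seeded from the cohort seed).
#' @param retest Simulate and analyze the retest arm (default `TRUE`).
#' @return A `pipeline_report` with an extra `truth` element (the cohort's
#'   config) and `cohort` (the simulated data).
#' @export
#' @examples
#' \donttest{
#' report <- run_synthetic_pipeline(desk_cohort_config(seed = 1))
#' report$significant
#' }
run_synthetic_pipeline <- function(cohort_config = desk_cohort_config(),
                                   config = desk_pipeline_config(seed = cohort_config$seed),
                                   retest = TRUE) {
  cohort <- simulate_cohort(cohort_config)
  session2 <- if (retest) simulate_retest(cohort) else NULL
  report <- run_pipeline(cohort$ratings, cohort$connectomes,
                         cohort$covariates, cohort$wellbeing,
                         parcellation = cohort$parcellation,
                         retest = session2, config = config)
  report$truth <- cohort_config
  report$cohort <- cohort
  report$retest_cohort <- session2
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  ve <- purrr::map_dbl(x$decomposition$model$clusters, "variance_explained")
  cat(sprintf("<pipeline_report> %d subjects, %d nodes\n",
              x$provenance$n_subjects, x$provenance$n_nodes))
  cat(sprintf("  decomposition: variance explained A %.0f%%, B %.0f%%\n",
              100 * ve[["A"]], 100 * ve[["B"]]))
  cat(sprintf("  NBS: %d significant component(s) across %d contrast(s)\n",
              nrow(x$significant), length(x$nbs)))
  if (nrow(x$significant)) {
    for (i in seq_len(nrow(x$significant))) {
      cat(sprintf("    %s: %d edges, FWE p = %.4g\n",
                  x$significant$id[i], x$significant$size[i],
                  x$significant$fwe_p[i]))
    }
  }
  invisible(x)
}
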