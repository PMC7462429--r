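#' Read and write pipeline input tables
#'
#' CSV readers/writers for the pipeline's documented formats, with schema
#' validation that names the offending column or subject:
#' * ratings: rows = subjects, `subject_id` plus one column per item,
#'   integer values 1-4;
#' * parcellation: `node_id`, `label`, `network`, `x`, `y`, `z`;
#' * covariates: `subject_id`, `age`, `gender` (0/1), `motion_fraction`
#'   in `[0, 1]`;
#' * well-being: `subject_id`, `psychological`, `social`.
#'
#' @param path File path.
#' @return A validated tibble.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_ratings <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, "subject_id", path)
  items <- setdiff(names(df), "subject_id")
  if (length(items) < 4L) abort(sprintf("%s: fewer than 4 item columns", path))
  for (item in items) {
    v <- df[[item]]
    if (anyNA(v)) abort(sprintf("%s: missing ratings in item '%s'", path, item))
    if (!all(v %in% 1:4)) {
      abort(sprintf("%s: item '%s' has values outside the 1-4 Likert range",
                    path, item))
    }
  }
  df
}

#' @rdname pipeline_io
#' @export
read_parcellation <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("node_id", "label", "network", "x", "y", "z"), path)
  if (!identical(as.integer(df$node_id), seq_len(nrow(df)) - 1L)) {
    abort(sprintf("%s: node ids must be contiguous 0..N-1", path))
  }
  if (anyDuplicated(df$label)) abort(sprintf("%s: duplicate node labels", path))
  class(df) <- c("parcellation", class(df))
  df
}

#' @rdname pipeline_io
#' @export
read_covariates <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("subject_id", "age", "gender", "motion_fraction"), path)
  if (!all(df$gender %in% c(0, 1))) abort(sprintf("%s: gender must be 0/1", path))
  if (any(df$motion_fraction < 0 | df$motion_fraction > 1)) {
    abort(sprintf("%s: motion_fraction must lie in [0, 1]", path))
  }
  df
}

#' @rdname pipeline_io
#' @export
read_wellbeing <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("subject_id", "psychological", "social"), path)
  df
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read a connectome directory via a manifest
#'
#' The manifest is a CSV with columns `subject_id` and `path` (TSV files,
#' relative paths resolved against the manifest's directory).
#'
#' @param manifest_path Manifest CSV path.
#' @return A named list of [connectome()] objects.
#' @export
read_connectome_manifest <- function(manifest_path) {
  mf <- readr::read_csv(manifest_path, show_col_types = FALSE)
  require_columns(mf, c("subject_id", "path"), manifest_path)
  base <- dirname(manifest_path)
  out <- purrr::map2(mf$path, mf$subject_id, function(p, sid) {
    full <- if (file.exists(p)) p else file.path(base, p)
    if (!file.exists(full)) {
      abort(sprintf("connectome file not found for subject %s: %s", sid, p))
    }
    read_connectome(full, subject_id = sid)
  })
  stats::setNames(out, mf$subject_id)
}

#' Write NBS outputs to disk
#'
#' Writes the documented NBS output bundle: a suprathreshold edge list TSV
#' (`node_i`, `node_j`, `t`, `sign`, `component_id`), the signed
#' significance mask matrix TSV, and a JSON summary with component sizes,
#' null-distribution quantiles, and FWE p-values.
#'
#' @param result An [nbs_test()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_nbs_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edges <- dplyr::bind_rows(purrr::imap(result$components, function(comp, i) {
    dplyr::mutate(comp$edges, component_id = i)
  }))
  if (!nrow(edges)) {
    edges <- tibble::tibble(node_i = integer(), node_j = integer(),
                            t = numeric(), sign = numeric(),
                            component_id = integer())
  }
  readr::write_tsv(edges, file.path(dir, sprintf("nbs_%s_edges.tsv", result$contrast)))
  readr::write_tsv(tibble::as_tibble(result$mask, .name_repair = "minimal"),
                   file.path(dir, sprintf("nbs_%s_mask.tsv", result$contrast)))
  summary <- list(
    contrast = result$contrast, T_threshold = result$T,
    n_permutations = result$n_perm, seed = result$seed,
    alpha = result$alpha,
    components = purrr::imap(result$components, function(comp, i) {
      list(component_id = i, size = comp$size, n_nodes = length(comp$nodes),
           fwe_p = comp$fwe_p, significant = comp$significant)
    }),
    null_max_quantiles = as.list(quantile(result$null_max_sizes,
                                          c(0.5, 0.9, 0.95, 0.99)))
  )
  jsonlite::write_json(summary, file.path(dir, sprintf("nbs_%s_summary.json", result$contrast)),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a pipeline report to disk
#'
#' Persists the report: component loadings and scores (TSV), the per-stage
#' summary with provenance (JSON), NBS bundles per contrast, and the tidy
#' metrics table.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tidy(report$decomposition$model),
                   file.path(dir, "loadings.tsv"))
  readr::write_tsv(report$decomposition$scores, file.path(dir, "scores.tsv"))
  for (res in report$nbs) write_nbs_result(res, file.path(dir, "nbs"))
  if (length(report$metrics)) {
    readr::write_tsv(dplyr::bind_rows(report$metrics),
                     file.path(dir, "metrics.tsv"))
  }
  summary <- list(
    provenance = report$provenance[c("n_subjects", "n_nodes",
                                     "package_version", "timestamp")],
    config = unclass(report$provenance$config),
    variance_explained = purrr::map_dbl(report$decomposition$model$clusters,
                                        "variance_explained"),
    significant_components = report$significant,
    mediation = purrr::map(report$mediation, function(m) {
      purrr::map(m$mediation, function(x) {
        x[c("a", "b", "c", "c_prime", "indirect", "se_indirect",
            "ci_low", "ci_high", "significant", "n")]
      })
    }),
    reliability = if (!is.null(report$reliability)) list(
      score_icc = purrr::map(report$reliability$score_icc,
                             ~ .x[c("icc", "ci_low", "ci_high", "p")]),
      brain_icc = purrr::map(report$reliability$brain_icc,
                             ~ .x[c("icc", "ci_low", "ci_high", "p")]),
      change = report$reliability$change
    )
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
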