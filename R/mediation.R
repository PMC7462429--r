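#' Covariate-adjusted linear regression with standardized coefficients
#'
#' Ordinary least squares of an outcome on a predictor table. With
#' `standardize = TRUE` (default) the outcome and all continuous predictors
#' are z-scored so coefficients are standardized betas; binary (0/1)
#' predictors are left as indicators. Incomplete rows are dropped with a
#' log note.
#'
#' @param outcome Numeric response vector.
#' @param predictors Data frame of predictors (an intercept is added).
#' @param standardize Z-score outcome and continuous predictors
#'   (default `TRUE`).
#' @return A list of class `linear_fit`: `coefficients` tibble (`term`,
#'   `estimate`, `se`, `statistic`, `p.value`), `df`, `n`, `n_dropped`.
#' @export
fit_linear <- function(outcome, predictors, standardize = TRUE) {
  predictors <- tibble::as_tibble(predictors)
  ok <- stats::complete.cases(outcome, predictors)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(sprintf("dropping %d incomplete case(s)", n_dropped))
  }
  y <- outcome[ok]
  pred <- predictors[ok, , drop = FALSE]
  n <- length(y)
  if (n <= ncol(pred) + 1L) abort("need n > number of predictors + 1")
  if (standardize) {
    y <- zscore_vec(y)
    pred <- dplyr::mutate(pred, dplyr::across(
      dplyr::where(~ is.numeric(.x) && !is_binary(.x)), zscore_vec))
  }
  X <- cbind(intercept = 1, as.matrix(pred))
  if (kappa(crossprod(X), exact = FALSE) > 1e10) {
    abort("predictor matrix is (near-)collinear")
  }
  fit <- stats::lm.fit(X, y)
  df <- n - ncol(X)
  s2 <- sum(fit$residuals^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * diag(xtx_inv))
  t <- fit$coefficients / se
  structure(
    list(coefficients = tibble::tibble(
      term = colnames(X), estimate = unname(fit$coefficients),
      se = unname(se), statistic = unname(t),
      p.value = 2 * pt(abs(t), df, lower.tail = FALSE)
    ), df = df, n = n, n_dropped = n_dropped, residuals = fit$residuals),
    class = "linear_fit"
  )
}

is_binary <- function(x) all(x %in% c(0, 1))

zscore_vec <- function(x) {
  s <- sd(x)
  if (s == 0) abort("cannot standardize a constant variable")
  (x - mean(x)) / s
}

#' Percentile-bootstrap mediation analysis
#'
#' Estimates the indirect effect of `x` (brain connectivity, e.g. the
#' natural log of fractional strength) on `y` (a well-being domain) through
#' the mediator `m` (a thought-pattern score), adjusting every path for the
#' covariates. Paths: `a` from `m ~ x + covariates`; `b` and `c'` from
#' `y ~ x + m + covariates`; `c` from `y ~ x + covariates`. All paths are
#' estimated on the same complete-case subsample, so the OLS decomposition
#' `c = c' + a * b` holds exactly. The indirect effect `a * b` gets a
#' percentile-bootstrap confidence interval from resampling subjects with
#' replacement.
#'
#' @param x,m,y Numeric vectors: predictor, mediator, outcome.
#' @param covariates Optional data frame of covariates (age, gender,
#'   motion fraction in the target pipeline).
#' @param n_boot Bootstrap samples (default 5000; at least 1000 recommended
#'   for reporting).
#' @param seed Integer seed.
#' @param standardize Standardize continuous variables once on the full
#'   analysis sample (default `TRUE`), yielding standardized path
#'   coefficients.
#' @param conf_level Confidence level of the percentile interval
#'   (default 0.95).
#' @return A list of class `mediation_result`: paths `a`, `b`, `c`,
#'   `c_prime`, `indirect`, `se_indirect`, `ci_low`, `ci_high`,
#'   `significant` (CI excludes 0), `n`, `n_dropped`, `n_boot`, `seed`,
#'   `covariate_names`.
#' @export
#' @examples
#' d <- simulate_mediation_triplet(200, a = 0.5, b = 0.4, seed = 1)
#' mediate(d$x, d$m, d$y, n_boot = 500, seed = 1)
mediate <- function(x, m, y, covariates = NULL, n_boot = 5000L, seed = 1L,
                    standardize = TRUE, conf_level = 0.95) {
  n_boot <- check_positive_int(n_boot, "n_boot")
  has_cov <- !is.null(covariates) && ncol(tibble::as_tibble(covariates)) > 0
  covariates <- if (has_cov) tibble::as_tibble(covariates) else NULL
  ok <- if (has_cov) stats::complete.cases(x, m, y, covariates) else
    stats::complete.cases(x, m, y)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) inform(sprintf("dropping %d incomplete case(s)", n_dropped))
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  if (has_cov) covariates <- covariates[ok, , drop = FALSE]
  n <- length(x)
  if (standardize) {
    x <- zscore_vec(x); m <- zscore_vec(m); y <- zscore_vec(y)
    if (has_cov) {
      covariates <- dplyr::mutate(covariates, dplyr::across(
        dplyr::where(~ is.numeric(.x) && !is_binary(.x)), zscore_vec))
    }
  }
  C <- if (has_cov) as.matrix(covariates) else NULL
  paths <- mediation_paths(x, m, y, C)
  alpha <- 1 - conf_level
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      pb <- mediation_paths(x[idx], m[idx], y[idx],
                            if (has_cov) C[idx, , drop = FALSE] else NULL)
      pb$a * pb$b
    }, numeric(1))
  })
  ci <- quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(
    list(a = paths$a, b = paths$b, c = paths$c, c_prime = paths$c_prime,
         indirect = paths$a * paths$b, se_indirect = sd(boot),
         ci_low = ci[1L], ci_high = ci[2L],
         significant = ci[1L] > 0 || ci[2L] < 0,
         conf_level = conf_level, n = n, n_dropped = n_dropped,
         n_boot = n_boot, seed = seed,
         covariate_names = if (has_cov) colnames(C) else character(0)),
    class = "mediation_result"
  )
}

# a, b, c, c' by OLS on a fixed sample; C may be NULL
mediation_paths <- function(x, m, y, C) {
  Xa <- cbind(1, x, C)
  Xb <- cbind(1, x, m, C)
  a <- stats::lm.fit(Xa, m)$coefficients[2L]
  fb <- stats::lm.fit(Xb, y)$coefficients
  c_path <- stats::lm.fit(Xa, y)$coefficients[2L]
  list(a = unname(a), b = unname(fb[3L]), c_prime = unname(fb[2L]),
       c = unname(c_path))
}

#' Bonferroni correction across well-being domains
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param k Number of comparisons (default 2: psychological and social
#'   domains).
#' @return Adjusted p-values, `min(1, k * p)`.
#' @export
#' @examples
#' bonferroni_domains(c(0.014, 0.7))
bonferroni_domains <- function(p_values, k = 2L) {
  k <- check_positive_int(k, "k")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  pmin(1, k * p_values)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation_result> a = %.3f, b = %.3f, c' = %.3f; indirect = %.3f, SE = %.3f, %d%% BCI [%.3f, %.3f]%s (n = %d)\n",
    x$a, x$b, x$c_prime, x$indirect, x$se_indirect,
    round(100 * x$conf_level), x$ci_low, x$ci_high,
    if (x$significant) " *" else "", x$n))
  invisible(x)
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> n = %d, df = %d\n", x$n, x$df))
  print(x$coefficients)
  invisible(x)
}
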