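#' Intraclass correlation between two sessions
#'
#' Test-retest reliability of a per-subject measure across two sessions.
#' The default form is the two-way random-effects, absolute-agreement,
#' single-measure coefficient ICC(2,1); ICC(3,1) (two-way mixed,
#' consistency) is available for sensitivity analyses. The confidence
#' interval is a percentile bootstrap over subjects and the p-value is the
#' one-sided F-test of ICC > 0 from the ANOVA mean squares.
#'
#' @param session1,session2 Paired numeric vectors (no missing values,
#'   at least 5 subjects).
#' @param n_boot Bootstrap resamples for the CI (default 5000).
#' @param seed Integer seed for the bootstrap.
#' @param form `"ICC2_1"` (default) or `"ICC3_1"`.
#' @return A list of class `icc_result`: `icc`, `ci_low`, `ci_high`, `p`,
#'   `form`, `n`, `n_boot`, `seed`.
#' @export
#' @examples
#' s1 <- rnorm(50)
#' icc(s1, s1 + rnorm(50, 0, 0.5), n_boot = 200, seed = 1)
icc <- function(session1, session2, n_boot = 5000L, seed = 1L,
                form = c("ICC2_1", "ICC3_1")) {
  form <- match.arg(form)
  if (length(session1) != length(session2)) abort("sessions must be paired")
  if (anyNA(session1) || anyNA(session2)) abort("missing pairs are not allowed")
  n <- length(session1)
  if (n < 5L) abort("at least 5 subjects are required")
  est <- icc_point(session1, session2, form)
  if (est$zero_subject_var) {
    warn("zero between-subject variance; ICC set to 0")
  }
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      icc_point(session1[idx], session2[idx], form)$icc
    }, numeric(1))
  })
  ci <- quantile(boot, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  structure(
    list(icc = est$icc, ci_low = ci[1L], ci_high = ci[2L], p = est$p,
         form = form, n = n, n_boot = n_boot, seed = seed),
    class = "icc_result"
  )
}

# single-measure ICC from two-way ANOVA mean squares, k = 2 sessions
icc_point <- function(s1, s2, form) {
  n <- length(s1)
  k <- 2
  x <- cbind(s1, s2)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  grand <- mean(x)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  zero_subject_var <- var(row_means) < 1e-24
  icc <- if (zero_subject_var) {
    0
  } else if (form == "ICC2_1") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  p <- if (mse < 1e-24) {
    if (zero_subject_var) 1 else .Machine$double.xmin
  } else {
    pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  list(icc = icc, p = max(p, .Machine$double.xmin), zero_subject_var = zero_subject_var)
}

#' Correlation of session-to-session changes
#'
#' Pearson correlation between the change in a thought-pattern score and the
#' change in the associated brain connectivity across sessions, with the
#' two-sided t-based p-value. Distinguishes a state-like coupling (score and
#' connectivity changing together) from trait-like stability.
#'
#' @param delta_scores,delta_connectivity Paired vectors of differences
#'   (session 2 minus session 1), at least 5 subjects.
#' @return A list with `r`, `p`, and `n`.
#' @export
change_correlation <- function(delta_scores, delta_connectivity) {
  if (length(delta_scores) != length(delta_connectivity)) {
    abort("difference vectors must be paired")
  }
  ok <- stats::complete.cases(delta_scores, delta_connectivity)
  x <- delta_scores[ok]; y <- delta_connectivity[ok]
  if (length(x) < 5L) abort("at least 5 complete pairs are required")
  if (sd(x) == 0 || sd(y) == 0) abort("zero-variance difference vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s = %.3f, 95%% BCI [%.3f, %.3f], p = %.3g (n = %d)\n",
              x$form, x$icc, x$ci_low, x$ci_high, x$p, x$n))
  invisible(x)
}
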