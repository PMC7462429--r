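#' Construct or validate a connectome matrix
#'
#' A connectome is a fully connected, undirected, signed weighted matrix of
#' pairwise correlations among parcellation nodes: symmetric, zero diagonal,
#' weights in `[-1, 1]`. No thresholding or binarization is applied.
#'
#' @param m Square numeric matrix.
#' @param subject_id Subject identifier carried as an attribute.
#' @param labels Optional node labels (row/column names).
#' @return The validated matrix with class `connectome`.
#' @export
connectome <- function(m, subject_id = NA_character_, labels = NULL) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("connectome must be a square matrix")
  if (!all(is.finite(m))) abort("connectome weights must be finite")
  if (max(abs(m - t(m))) >= 1e-12) {
    abort("connectome must be symmetric (|A - t(A)| < 1e-12)")
  }
  if (any(abs(diag(m)) > 1e-12)) abort("connectome diagonal must be zero")
  if (any(m < -1 - 1e-12) || any(m > 1 + 1e-12)) {
    abort("connectome weight out of [-1, 1]")
  }
  diag(m) <- 0
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  structure(m, subject_id = subject_id, class = c("connectome", "matrix", "array"))
}

#' Build a connectome from ROI time series
#'
#' Computes all pairwise Pearson correlations between node time series. Raw
#' correlation coefficients are retained by default; an optional Fisher
#' z-transform is available for sensitivity analyses (weights are then no
#' longer bounded by 1 and range validation is skipped).
#'
#' @param ts Numeric matrix, timepoints x nodes (at least 10 timepoints);
#'   column names are used as node labels.
#' @param subject_id Subject identifier.
#' @param fisher_z If `TRUE`, apply `atanh` to the correlations.
#' @return A [connectome()].
#' @export
#' @examples
#' ts <- matrix(rnorm(200 * 5), 200, 5)
#' c1 <- build_connectome(ts, subject_id = "sub-0001")
build_connectome <- function(ts, subject_id = NA_character_, fisher_z = FALSE) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 10L) abort("time series must have at least 10 timepoints")
  if (any(!is.finite(ts))) abort("time series contains non-finite values")
  sds <- apply(ts, 2L, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant (zero-variance) time series at node id(s): %s",
                  paste(which(sds == 0) - 1L, collapse = ", ")))
  }
  r <- cor(ts)
  diag(r) <- 0
  if (fisher_z) {
    r <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
    return(structure(r, subject_id = subject_id,
                     class = c("connectome", "matrix", "array")))
  }
  connectome(r, subject_id = subject_id, labels = colnames(ts))
}

#' Mean connectivity of a connectome
#'
#' Mean weight over the strict upper triangle, so each undirected edge is
#' counted once. Used as a subject-level nuisance regressor in the
#' network-based statistic.
#'
#' @param c A [connectome()].
#' @return A single number.
#' @export
mean_connectivity <- function(c) {
  mean(upper_tri_values(unclass(c)))
}

#' Read / write a connectome as TSV
#'
#' The on-disk format is a square tab-separated table with a header row of
#' node labels; weights are written with full (round-trip) precision.
#' Reading validates squareness, symmetry (tolerance 1e-10), zero diagonal,
#' and the `[-1, 1]` weight range.
#'
#' @param path File path.
#' @param c A [connectome()].
#' @param subject_id Subject id to attach on read.
#' @return `read_connectome` returns a [connectome()];
#'   `write_connectome` returns `path` invisibly.
#' @export
read_connectome <- function(path, subject_id = NA_character_) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    abort(sprintf("connectome file %s is not square (%d x %d)",
                  path, nrow(m), ncol(m)))
  }
  if (max(abs(m - t(m))) > 1e-10) {
    abort(sprintf("connectome file %s is asymmetric beyond tolerance", path))
  }
  if (any(m < -1 - 1e-12) || any(m > 1 + 1e-12)) {
    abort(sprintf("connectome file %s: weight out of [-1, 1]", path))
  }
  m <- (m + t(m)) / 2
  connectome(m, subject_id = subject_id, labels = colnames(m))
}

#' @rdname read_connectome
#' @export
write_connectome <- function(c, path) {
  m <- unclass(c)
  labels <- colnames(m) %||% sprintf("ROI_%03d", seq_len(ncol(m)) - 1L)
  lines <- c(
    paste(labels, collapse = "\t"),
    apply(m, 1L, function(row) {
      paste(formatC(row, digits = 17, format = "g"), collapse = "\t")
    })
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d nodes, subject %s, mean connectivity %.4f\n",
              nrow(x), attr(x, "subject_id"), mean_connectivity(x)))
  invisible(x)
}
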