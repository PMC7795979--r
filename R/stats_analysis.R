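#' Pearson correlation matrix of the texture descriptors
#'
#' @param table a `feature_table` with at least 3 cases and no constant
#'   descriptor column.
#' @return A `corr_matrix`: symmetric matrix with unit diagonal and the
#'   descriptor names as dimnames.
#' @export
correlation_matrix <- function(table) {
  assert_feature_table(table)
  if (nrow(table) < 3L) stop("need at least 3 cases", call. = FALSE)
  X <- as.matrix(as.data.frame(table)[, feature_names()])
  const <- apply(X, 2, function(col) max(col) == min(col))
  if (any(const)) {
    stop("constant descriptor column(s): ",
         paste(feature_names()[const], collapse = ", "), call. = FALSE)
  }
  as_corr_matrix(cor(X))
}

#' Validate / construct a correlation matrix object
#'
#' @param values square symmetric numeric matrix with unit diagonal and
#'   entries in \[-1, 1\]; row/column names are kept as variable labels.
#' @return A `corr_matrix`.
#' @export
as_corr_matrix <- function(values) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("correlation matrix must be square", call. = FALSE)
  }
  if (max(abs(values - t(values))) > 1e-6) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(values) - 1)) > 1e-9) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  if (max(abs(values)) > 1 + 1e-9) {
    stop("correlation entries must lie in [-1, 1]", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    nm <- if (nrow(values) == 5L) feature_names() else
      paste0("v", seq_len(nrow(values)))
    dimnames(values) <- list(nm, nm)
  }
  structure(values, class = c("corr_matrix", "matrix", "array"))
}

#' Read a correlation matrix from CSV
#'
#' Expects a header row of variable names and one row per variable (the
#' first column holding the row labels).
#'
#' @param path CSV path.
#' @return A `corr_matrix`.
#' @export
read_corr_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  as_corr_matrix(as.matrix(df))
}

#' Principal components as the eigendecomposition of a correlation matrix
#'
#' Eigenvalues are returned in descending order with the percentage of
#' variance each explains and the running cumulative percentage. For a
#' correlation matrix the eigenvalues sum to the number of variables.
#' Small negative round-off eigenvalues are clipped to zero with a warning.
#'
#' @param corr a `corr_matrix` (or plain symmetric matrix with unit
#'   diagonal).
#' @return A `pca_result`: list with `eigenvalues`, `pct_var`,
#'   `cum_pct_var`.
#' @export
pca_eigen <- function(corr) {
  corr <- as_corr_matrix(unclass(corr))
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < 0)) {
    if (any(ev < -1e-8)) {
      warning("negative eigenvalue(s) clipped to zero", call. = FALSE)
    }
    ev[ev < 0] <- 0
  }
  ev <- sort(ev, decreasing = TRUE)
  pct <- 100 * ev / sum(ev)
  structure(list(eigenvalues = ev, pct_var = pct,
                 cum_pct_var = cumsum(pct)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  m <- rbind(Variance = x$eigenvalues, `% of var.` = x$pct_var,
             `Cumulative % of var.` = x$cum_pct_var)
  colnames(m) <- paste0("PC", seq_along(x$eigenvalues))
  print(round(m, 3))
  invisible(x)
}

#' Kaiser criterion: number of components to retain
#'
#' Counts the eigenvalues strictly greater than 1 — the components that
#' explain more variance than a single standardised variable.
#'
#' @param x a `pca_result` or a numeric vector of eigenvalues.
#' @return Integer count.
#' @export
kaiser_retained <- function(x) {
  ev <- if (inherits(x, "pca_result")) x$eigenvalues else as.numeric(x)
  sum(ev > 1)
}

#' Variable with the strongest overall correlation
#'
#' Ranks variables by the mean absolute off-diagonal correlation with the
#' other variables; used to single out the descriptor that carries the most
#' shared signal (entropy, in the study's data).
#'
#' @param corr a `corr_matrix`.
#' @return list with `variable` (label of the maximiser; ties go to the
#'   lowest index with `tie = TRUE`), `mean_abs_r` (named vector of
#'   per-variable means) and `tie` flag.
#' @export
strongest_variable <- function(corr) {
  corr <- as_corr_matrix(unclass(corr))
  n <- nrow(corr)
  means <- vapply(seq_len(n), function(i) mean(abs(corr[i, -i])), numeric(1))
  names(means) <- rownames(corr)
  top <- which(means == max(means))
  list(variable = rownames(corr)[top[1L]], mean_abs_r = means,
       tie = length(top) > 1L)
}

#' Correlation + PCA summary of a feature table
#'
#' Convenience wrapper producing the full statistical stage for one set:
#' the descriptor correlation matrix, its eigendecomposition, the Kaiser
#' retention count and the strongest variable.
#'
#' @param table a `feature_table`.
#' @return list with `correlation`, `pca`, `kaiser`, `strongest`.
#' @export
stats_summary <- function(table) {
  cm <- correlation_matrix(table)
  res <- pca_eigen(cm)
  list(correlation = cm, pca = res, kaiser = kaiser_retained(res),
       strongest = strongest_variable(cm))
}

#' @export
print.corr_matrix <- function(x, digits = 3, ...) {
  print(round(unclass(x), digits))
  invisible(x)
}
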