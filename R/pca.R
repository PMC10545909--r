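#' The six kinetic feature columns used for phenotyping
#'
#' Column names of the per-cell feature table analysed by
#' [standardize_features()] and [principal_components()].
#' @export
FEATURE_COLS <- c("NPQav", "NPQmax", "Induction", "Decay", "Fmax", "AreaFrac")

#' z-score the analysis columns of a feature table
#'
#' Each of the six kinetic feature columns is centred on its mean and
#' divided by its sample (n - 1) standard deviation, so that a subsequent
#' PCA operates on the correlation matrix. Rows containing undefined
#' features are dropped (with a message); metadata columns pass through.
#'
#' @param table data.frame with the feature columns (and any metadata).
#' @param feature_cols Names of the analysis columns.
#' @return The standardized table; dropped-row count in attribute
#'   `dropped`.
#' @export
standardize_features <- function(table, feature_cols = FEATURE_COLS) {
  if (!all(feature_cols %in% names(table)))
    stop("missing feature columns: ",
         paste(setdiff(feature_cols, names(table)), collapse = ", "))
  complete <- stats::complete.cases(table[feature_cols])
  if (any(!complete))
    message("dropping ", sum(!complete), " row(s) with undefined features")
  table <- table[complete, , drop = FALSE]
  if (nrow(table) < 2) stop("at least 2 complete rows are required")
  for (col in feature_cols) {
    s <- stats::sd(table[[col]])
    if (s == 0) stop("zero-variance column: ", col)
    table[[col]] <- (table[[col]] - mean(table[[col]])) / s
  }
  attr(table, "dropped") <- sum(!complete)
  table
}

#' Correlation-matrix PCA of a standardized feature table
#'
#' Singular value decomposition of the z-scored data matrix, equivalent to
#' an eigendecomposition of the correlation matrix: loadings are the
#' orthonormal principal directions ordered by decreasing variance, scores
#' the projections of each cell, and explained variance the eigenvalue as
#' a percentage of the number of variables (the trace of a correlation
#' matrix). Loading signs are fixed so that each component's
#' largest-magnitude entry is positive, making the output deterministic.
#'
#' @param standardized Output of [standardize_features()].
#' @param feature_cols Names of the analysis columns.
#' @return A `pca_result`: list with `loadings` (p x p, variables x
#'   components), `scores` (n x p), `eigenvalues`,
#'   `explained_variance_pct`, `n`.
#' @export
principal_components <- function(standardized, feature_cols = FEATURE_COLS) {
  X <- as.matrix(standardized[, feature_cols, drop = FALSE])
  if (!is.numeric(X)) stop("feature columns must be numeric")
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("at least 2 rows are required")
  sv <- svd(X)
  eigenvalues <- sv$d^2 / (n - 1)  # eigenvalues of the correlation matrix
  loadings <- sv$v
  scores <- X %*% loadings
  for (j in seq_len(p)) {           # deterministic sign convention
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(feature_cols, paste0("PC", seq_len(p)))
  colnames(scores) <- paste0("PC", seq_len(p))
  structure(list(loadings = loadings, scores = scores,
                 eigenvalues = eigenvalues,
                 explained_variance_pct = 100 * eigenvalues / p,
                 n = n),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d cells, %d components\n", x$n, ncol(x$loadings)))
  cat("explained variance (%):",
      paste(sprintf("%.1f", x$explained_variance_pct), collapse = ", "), "\n")
  invisible(x)
}

#' Mean silhouette width of a grouping on (component) scores
#'
#' Small self-contained silhouette: for each point, a = mean distance to
#' its own group, b = smallest mean distance to another group, width =
#' (b - a)/max(a, b). A positive mean indicates the grouping is separated
#' in the given coordinates. Used to check which principal components
#' separate genotypes or cell types.
#'
#' @param x Numeric vector or matrix of coordinates (e.g. one PC's scores).
#' @param groups Group labels, length nrow(x).
#' @return Mean silhouette width.
#' @export
silhouette_mean <- function(x, groups) {
  x <- as.matrix(x)
  g <- as.factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  dm <- as.matrix(stats::dist(x))
  w <- vapply(seq_len(nrow(x)), function(i) {
    own <- which(g == g[i]); own <- own[own != i]
    if (!length(own)) return(0)
    a <- mean(dm[i, own])
    b <- min(vapply(setdiff(levels(g), as.character(g[i])),
                    function(l) mean(dm[i, g == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(w)
}

#' Write PCA outputs (loadings, scores, explained variance) as CSV
#'
#' @param pca A `pca_result`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_pca <- function(pca, dir, prefix = "pca") {
  stopifnot(inherits(pca, "pca_result"))
  paths <- file.path(dir, paste0(prefix, c("_loadings.csv", "_scores.csv",
                                           "_explained.csv")))
  utils::write.csv(data.frame(variable = rownames(pca$loadings), pca$loadings),
                   paths[1], row.names = FALSE)
  utils::write.csv(as.data.frame(pca$scores), paths[2], row.names = FALSE)
  utils::write.csv(data.frame(component = colnames(pca$loadings),
                              eigenvalue = pca$eigenvalues,
                              explained_pct = pca$explained_variance_pct),
                   paths[3], row.names = FALSE)
  invisible(paths)
}
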