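#' Sample Pearson correlation with degeneracy checks
#'
#' @param x,y equal-length numeric vectors of at least 3 values; both
#'   must be non-constant (a zero-variance vector has no defined
#'   correlation).
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_cor <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 3 || anyNA(x) || anyNA(y)) {
    stop("`x` and `y` must be equal-length numeric vectors of >= 3 values",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant vector has no defined correlation",
         call. = FALSE)
  }
  stats::cor(x, y)
}

#' Indicator-importance ranking by correlation
#'
#' Correlates each of the seven indicator score columns with a forecast
#' outcome (typically the continuous forecast margin, or the binary
#' prediction) and ranks indicators by absolute correlation, descending.
#'
#' @param table a session table or 7-column score matrix.
#' @param outcomes numeric vector, one value per row.
#' @return An object of class `correlation_report`: a data.frame with
#'   columns `indicator`, `r`, `abs_r`, ordered by `abs_r` descending,
#'   with attribute `n` (sample size).
#' @export
indicator_correlations <- function(table, outcomes) {
  S <- as_score_matrix(table)
  if (length(outcomes) != nrow(S)) {
    stop("`outcomes` length must match the number of rows", call. = FALSE)
  }
  r <- vapply(seq_len(ncol(S)), function(k) pearson_cor(S[, k], outcomes),
              numeric(1))
  report <- data.frame(
    indicator = indicator_codes(),
    r = r,
    abs_r = abs(r),
    stringsAsFactors = FALSE
  )
  report <- report[order(-report$abs_r), ]
  rownames(report) <- NULL
  structure(report, n = nrow(S),
            class = c("correlation_report", "data.frame"))
}

#' Cluster the indicators by importance
#'
#' Groups the seven indicators with k-means (20 seeded restarts, best
#' within-cluster sum of squares kept). The default feature is
#' one-dimensional — each indicator's correlation with the forecast
#' outcome — so the clusters are correlation bands (strong / moderate /
#' weak for k = 3).
#'
#' @param features a named numeric vector (one value per indicator) or a
#'   matrix with one row per indicator.
#' @param k number of clusters, between 1 and the number of indicators.
#' @param seed optional RNG seed for the restarts.
#' @param nstart number of random restarts (default 20).
#' @return An object of class `cluster_assignment`: a list with
#'   `cluster` (named vector of cluster ids), `centroids`, `withinss`
#'   (total within-cluster sum of squares) and `k`.
#' @examples
#' r <- c(STT = 0.748, SPT = 0.779, ENT = 0.497, RET = 0.336,
#'        RST = 0.522, RCT = 0.329, BST = 0.881)
#' cluster_indicators(r, k = 3, seed = 1)
#' @export
cluster_indicators <- function(features, k = 3, seed = NULL, nstart = 20) {
  if (is.null(dim(features))) {
    mat <- matrix(as.numeric(features), ncol = 1,
                  dimnames = list(names(features), NULL))
  } else {
    mat <- as.matrix(features)
  }
  if (!is.numeric(mat) || any(!is.finite(mat))) {
    stop("`features` must be finite numeric", call. = FALSE)
  }
  n <- nrow(mat)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k != floor(k) ||
      k > n) {
    stop("`k` must be an integer between 1 and the number of indicators (",
         n, ")", call. = FALSE)
  }
  fit <- with_rng(seed, {
    if (k == n) {
      # every point its own cluster; kmeans() refuses duplicate centres,
      # so assign directly (the optimum has zero within-cluster scatter
      # when points are distinct)
      list(cluster = seq_len(n), centers = mat, tot.withinss = 0)
    } else {
      stats::kmeans(mat, centers = k, nstart = nstart)
    }
  })
  cluster <- fit$cluster
  names(cluster) <- rownames(mat)
  structure(
    list(cluster = cluster, centroids = fit$centers,
         withinss = fit$tot.withinss, k = as.integer(k)),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("k-means clustering of indicators (k = ", x$k, ", total WSS = ",
      format(x$withinss, digits = 6), ")\n", sep = "")
  for (cl in sort(unique(x$cluster))) {
    members <- names(x$cluster)[x$cluster == cl]
    cat("  cluster ", cl, ": ", paste(members, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
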