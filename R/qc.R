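#' Principal component scores for samples
#'
#' Projects samples onto the top principal components of the probe-centered
#' log2 intensity matrix (singular value decomposition; no variance scaling).
#' Replicates of one tissue are expected to land closer to each other than to
#' samples of other tissues. Component signs follow a deterministic
#' convention: the largest-magnitude score coordinate of each component is
#' positive.
#'
#' @param x An `expr_matrix` on the log2 scale (normalized).
#' @param n_components Number of components to retain; at most
#'   `min(samples - 1, probes)`.
#' @return Object of class `"pca_result"`: list with `scores` (samples x
#'   components) and `explained_variance_fraction` (per retained component,
#'   non-increasing, summing to at most 1 over all components).
#' @export
pca_scores <- function(x, n_components = 2L) {
  stopifnot(inherits(x, "expr_matrix"))
  n_samp <- ncol(x$values)
  if (n_samp < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  max_k <- min(n_samp - 1L, nrow(x$values))
  if (n_components > max_k) {
    stop(sprintf("n_components (%d) exceeds min(samples - 1, probes) = %d",
                 n_components, max_k), call. = FALSE)
  }
  # t(): samples in rows; center = TRUE centers each probe
  pc <- stats::prcomp(t(x$values), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(scores = scores,
         explained_variance_fraction = ev[seq_len(n_components)],
         loadings_available = FALSE),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA scores: %d samples x %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("explained variance fraction:",
      paste(sprintf("%.3f", x$explained_variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

#' Sample-by-sample Spearman correlation matrix
#'
#' Rank-based correlation between all pairs of samples (ties receive mean
#' ranks), invariant under any strictly monotone per-sample transform of the
#' intensities. A constant sample has no defined rank correlation; its entries
#' are `NA` and a warning names the sample.
#'
#' @param x An `expr_matrix`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$values) < 2L) stop("need at least 2 samples", call. = FALSE)
  const <- apply(x$values, 2L, function(v) diff(range(v)) == 0)
  rho <- suppressWarnings(stats::cor(x$values, method = "spearman"))
  if (any(const)) {
    warning("constant sample(s), correlation undefined: ",
            paste(colnames(x$values)[const], collapse = ", "))
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
    diag(rho) <- 1
  }
  rho
}

#' Agglomerative clustering of samples from a correlation matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - correlation`. Replicates of one tissue should merge before any
#' cross-tissue merge when group structure dominates the noise.
#'
#' @param corr Symmetric correlation matrix (e.g. from [spearman_matrix()]).
#' @return An [stats::hclust] object (merge sequence and heights).
#' @export
cluster_samples <- function(corr) {
  corr <- as.matrix(corr)
  if (anyNA(corr)) {
    stop("correlation matrix contains undefined entries", call. = FALSE)
  }
  stats::hclust(stats::as.dist(1 - corr), method = "average")
}

#' Do the dendrogram leaves partition into the known groups?
#'
#' Convenience QC check: cutting the dendrogram into as many clusters as there
#' are groups must reproduce the group assignment exactly (every replicate set
#' forms its own cluster).
#'
#' @param hc An [stats::hclust] object over the samples.
#' @param sheet A `sample_sheet` covering those samples.
#' @return `TRUE` if the cut matches the groups, else `FALSE`.
#' @export
replicates_cluster_together <- function(hc, sheet) {
  groups <- sheet$sample_to_group[hc$labels]
  k <- length(unique(groups))
  cut <- stats::cutree(hc, k = k)
  # the partition matches iff cluster id is a bijection of group label
  tab <- table(cut, groups)
  all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
}
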