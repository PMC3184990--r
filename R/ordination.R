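# Ordination and exploratory screening: PCA of Procrustes coordinates,
# outlier detection, UPGMA phenograms with cophenetic correlation.

#' Principal component analysis of shape coordinates
#'
#' Eigendecomposition of the covariance matrix of the tangent-space shape
#' coordinates.  For 2D data four degrees of freedom are absorbed by the
#' superimposition, so at most `min(n - 1, 2k - 4)` eigenvalues are nonzero;
#' components beyond the numerical rank are reported with zero variance.
#' Eigenvector signs are fixed so the largest-magnitude loading of each
#' component is positive.
#'
#' @param aligned an `aligned_shapes` object, or an `n x p` coordinate
#'   matrix.
#' @return an object of class `shape_pca`: `eigenvalues` (descending),
#'   `eigenvectors` (orthonormal columns), `scores` (mean-centered
#'   projections), `pct_variance`, `center`.
#' @export
shape_pca <- function(aligned) {
  X <- if (inherits(aligned, "aligned_shapes")) aligned$shapes else as.matrix(aligned)
  n <- nrow(X)
  if (n < 3) stop("PCA needs at least 3 specimens")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  e <- eigen(stats::cov(Xc), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  tolv <- max(vals) * 1e-12
  vals[vals < tolv] <- 0
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    m <- which.max(abs(vecs[, j]))
    if (vecs[m, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- Xc %*% vecs
  rownames(scores) <- rownames(X)
  structure(list(eigenvalues = vals, eigenvectors = vecs, scores = scores,
                 pct_variance = 100 * vals / sum(vals), center = ctr),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  nz <- sum(x$eigenvalues > 0)
  cat("Shape PCA:", nz, "nonzero components\n")
  m <- min(4, nz)
  cat(sprintf("  PC1-%d explain %.1f%% of variance\n", m,
              sum(x$pct_variance[seq_len(m)])))
  invisible(x)
}

#' Screen for shape outliers and summarize size by group
#'
#' Flags specimens whose squared Procrustes distance to the consensus
#' exceeds the `1 - 1/n` quantile of a scaled chi-square fitted to the
#' eigenvalue spectrum (Satterthwaite moment matching: scale
#' `sum(lambda^2)/sum(lambda)`, effective dimensionality
#' `sum(lambda)^2/sum(lambda^2)`), a normal-model screen for specimens
#' unusually distant from the mean.  Also returns Tukey five-number
#' summaries of centroid size per group.
#'
#' @param aligned an `aligned_shapes` object.
#' @param groups optional factor for the size summaries (defaults to a
#'   single group).
#' @param quantile flag threshold quantile; default `1 - 1/n`.
#' @return an object of class `outlier_report`: data frame `shape` with
#'   per-specimen distances and flags, and matrix `size_summary` with rows
#'   min / q1 / median / q3 / max per group.
#' @export
outlier_screen <- function(aligned, groups = NULL, quantile = NULL) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  X <- aligned$shapes
  n <- nrow(X)
  d2 <- rowSums(sweep(X, 2, colMeans(X))^2)
  lam <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  scale_ <- sum(lam^2) / sum(lam)
  h <- sum(lam)^2 / sum(lam^2)
  if (is.null(quantile)) quantile <- 1 - 1 / n
  cutoff <- scale_ * stats::qchisq(quantile, df = h)
  flags <- d2 > cutoff
  if (is.null(groups)) groups <- factor(rep("all", n))
  groups <- factor(groups)
  size_summary <- sapply(levels(groups), function(g)
    stats::fivenum(aligned$centroid_sizes[groups == g]))
  rownames(size_summary) <- c("min", "q1", "median", "q3", "max")
  structure(list(shape = data.frame(distance = sqrt(d2), squared = d2,
                                    flagged = flags,
                                    row.names = aligned$labels),
                 cutoff = cutoff, effective_dim = h,
                 size_summary = size_summary),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  nf <- sum(x$shape$flagged)
  cat("Outlier screen:", nf, "of", nrow(x$shape), "specimens flagged",
      sprintf("(cutoff %.4g, effective dim %.1f)\n", x$cutoff, x$effective_dim))
  invisible(x)
}

#' UPGMA phenogram with cophenetic correlation
#'
#' Average-linkage clustering of a shape distance matrix, with the
#' cophenetic correlation (Pearson correlation between the original and
#' tree-implied distances) quantifying the distortion introduced by the
#' tree: 1 means no distortion.
#'
#' @param dist an `n x n` symmetric non-negative matrix with zero diagonal,
#'   or a `dist` object.
#' @param linkage `"upgma"` (average; default), `"single"` or `"complete"`,
#'   for comparing the distortion of alternative tree-building algorithms.
#' @return an object of class `phenogram_result`: `tree` (an `hclust`),
#'   `cophenetic_r`, and `newick` (the tree serialized with branch lengths).
#' @export
upgma_phenogram <- function(dist, linkage = c("upgma", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (!inherits(dist, "dist")) {
    dist <- as.matrix(dist)
    if (!isSymmetric(unname(dist), tol = 1e-8)) stop("distance matrix must be symmetric")
    if (any(dist < 0)) stop("distance matrix must be non-negative")
    if (any(abs(diag(dist)) > 1e-12)) stop("distance matrix must have zero diagonal")
    dist <- stats::as.dist(dist)
  }
  method <- switch(linkage, upgma = "average", single = "single",
                   complete = "complete")
  tree <- stats::hclust(dist, method = method)
  coph <- stats::cophenetic(tree)
  # degenerate case: a tree with all cophenetic distances equal carries no
  # ordering information, so the correlation is undefined
  r <- if (stats::sd(coph) == 0 || stats::sd(dist) == 0) NA_real_
       else stats::cor(as.vector(dist), as.vector(coph))
  newick <- ape::write.tree(ape::as.phylo(tree))
  structure(list(tree = tree, cophenetic_r = r, newick = newick,
                 linkage = linkage),
            class = "phenogram_result")
}

#' @export
print.phenogram_result <- function(x, ...) {
  cat(sprintf("%s phenogram of %d specimens, cophenetic correlation %.3f\n",
              toupper(x$linkage), length(x$tree$order), x$cophenetic_r))
  invisible(x)
}
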