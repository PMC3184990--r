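# Tree-averaging and the two-group test battery: t and permutation tests on
# size, Hotelling T^2, Mahalanobis and Procrustes distance permutation tests,
# dummy-coded regression tests, Box's M, and two-group discriminant analysis
# with jackknife (leave-one-out) cross-validation.
#
# All multivariate tests operate on the principal-component subspace with
# eigenvalues above 1e-12 of the largest, so degrees of freedom are computed
# from the true shape dimensionality (2k - 4 on full-rank 2D data).

#' Average aligned shapes and sizes within trees
#'
#' Pools the pseudo-replicated observations (leaves x replicas) of each tree
#' into a single arithmetic mean shape and mean centroid size, carrying the
#' population label along.
#'
#' @param aligned an `aligned_shapes` object with classifiers.
#' @return a list of class `tree_averaged`: `shapes` (trees x 2k),
#'   `sizes`, `population` (factor), `tree` (factor of tree labels).
#' @export
average_by_tree <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  cls <- aligned$classifiers
  if (is.null(cls)) stop("dataset has no classifiers")
  tr <- factor(cls$tree)
  counts <- as.vector(table(tr))
  shapes <- rowsum(aligned$shapes, tr) / counts
  sizes <- as.vector(rowsum(aligned$centroid_sizes, tr) / counts)
  pop <- factor(tapply(as.character(cls$population), tr, function(x) x[1]))
  structure(list(shapes = shapes, sizes = sizes,
                 population = pop[levels(tr)], tree = factor(levels(tr)),
                 k = aligned$k, mean_shape = aligned$mean_shape),
            class = "tree_averaged")
}

#' @export
print.tree_averaged <- function(x, ...) {
  cat("Tree-averaged dataset:", nrow(x$shapes), "trees in",
      nlevels(x$population), "populations\n")
  invisible(x)
}

# PC-subspace scores retaining eigenvalues > tol * max (shared by the
# multivariate tests so df are computed on the non-degenerate dimension).
# max_p additionally caps the dimension (with a warning) so small samples
# keep positive error df.
pc_subspace <- function(X, tol = 1e-12, max_p = Inf) {
  p <- shape_pca(X)
  keep <- which(p$eigenvalues > tol * max(p$eigenvalues))
  if (length(keep) > max_p) {
    warning(sprintf("reducing the PC subspace from %d to %d dimensions to keep positive error df",
                    length(keep), max_p))
    keep <- keep[seq_len(max_p)]
  }
  list(scores = p$scores[, keep, drop = FALSE], p = length(keep), pca = p)
}

perm_pvalue <- function(observed, permuted) {
  (1 + sum(permuted >= observed - 1e-12)) / (length(permuted) + 1)
}

#' Two-sample t test on size with permutation P
#'
#' Pooled-variance two-sample t with `n1 + n2 - 2` degrees of freedom,
#' two-sided parametric P, and a permutation P obtained by comparing |t|
#' against `n_perm` random relabelings.  (`t^2` equals the corresponding
#' `F(1, n1 + n2 - 2)`.)
#'
#' @param sizes numeric response.
#' @param groups two-level factor.
#' @param n_perm number of permutations (default 10000).
#' @return list of class `two_sample_result`: `statistic` (t), `df`,
#'   `p_parametric`, `p_permutation`, `n_permutations`.
#' @export
size_t_test <- function(sizes, groups, n_perm = 10000) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  g1 <- sizes[groups == levels(groups)[1]]
  g2 <- sizes[groups == levels(groups)[2]]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  tstat <- function(a, b) {
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    if (sp2 == 0) stop("zero pooled variance")
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }
  t_obs <- tstat(g1, g2)
  df <- n1 + n2 - 2
  p_par <- 2 * stats::pt(abs(t_obs), df, lower.tail = FALSE)
  perm <- replicate(n_perm, {
    idx <- sample(n1 + n2)
    x <- c(g1, g2)[idx]
    abs(tstat(x[seq_len(n1)], x[n1 + seq_len(n2)]))
  })
  structure(list(statistic = t_obs, df = df, p_parametric = p_par,
                 p_permutation = perm_pvalue(abs(t_obs), perm),
                 n_permutations = n_perm, test = "t"),
            class = "two_sample_result")
}

#' @export
print.two_sample_result <- function(x, ...) {
  cat(sprintf("%s test: statistic %.4g", x$test, x$statistic))
  if (!is.null(x$df)) cat(", df", paste(x$df, collapse = ", "))
  if (!is.null(x$p_parametric)) cat(sprintf(", P = %.4g", x$p_parametric))
  if (!is.null(x$p_permutation))
    cat(sprintf(", P(perm) = %.4g [%d perms]", x$p_permutation, x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Dummy-coded regression test for a two-group difference
#'
#' Regresses a (possibly multivariate) response on a single covariate
#' coding one group as -1 and the other as +1; reports the percentage of
#' total variance explained and its permutation P value.  In the univariate
#' case the percentage equals 100 times the squared point-biserial
#' correlation.
#'
#' @param response numeric vector or matrix.
#' @param groups two-level factor.
#' @param n_perm number of permutations (default 10000).
#' @return list with `pct_variance`, `p_permutation`, `n_permutations`.
#' @export
dummy_regression_test <- function(response, groups, n_perm = 10000) {
  response <- as.matrix(response)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  dummy <- ifelse(groups == levels(groups)[1], -1, 1)
  pct <- function(d) {
    dc <- d - mean(d)
    Yc <- sweep(response, 2, colMeans(response))
    beta <- crossprod(Yc, dc) / sum(dc^2)
    100 * sum((outer(dc, as.vector(beta)))^2) / sum(Yc^2)
  }
  obs <- pct(dummy)
  perm <- replicate(n_perm, pct(sample(dummy)))
  list(pct_variance = obs, p_permutation = perm_pvalue(obs, perm),
       n_permutations = n_perm)
}

pooled_cov <- function(X, groups) {
  groups <- factor(groups)
  S <- 0
  for (g in levels(groups)) {
    Xg <- X[groups == g, , drop = FALSE]
    S <- S + crossprod(sweep(Xg, 2, colMeans(Xg)))
  }
  S / (nrow(X) - nlevels(groups))
}

#' Hotelling's T-squared test for two multivariate means
#'
#' Computed on the non-degenerate PC subspace of the shapes so that the
#' degrees of freedom of the F approximation,
#' `(p, n1 + n2 - p - 1)`, reflect the true dimensionality.
#'
#' @param shapes `n x 2k` matrix (tangent coordinates or PC scores).
#' @param groups two-level factor.
#' @return `two_sample_result` with `statistic` (T^2), `df` (F df pair),
#'   `p_parametric`, and `mahalanobis_d`.
#' @export
hotelling_t2 <- function(shapes, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  sub <- pc_subspace(as.matrix(shapes), max_p = nrow(as.matrix(shapes)) - 3)
  Y <- sub$scores; p <- sub$p
  n1 <- sum(groups == levels(groups)[1]); n2 <- sum(groups == levels(groups)[2])
  if (n1 + n2 - 2 <= p)
    stop("singular: p must be smaller than n1 + n2 - 2 (reduce the PC subspace)")
  d <- colMeans(Y[groups == levels(groups)[1], , drop = FALSE]) -
       colMeans(Y[groups == levels(groups)[2], , drop = FALSE])
  S <- pooled_cov(Y, groups)
  d2 <- as.numeric(crossprod(d, solve(S, d)))
  T2 <- (n1 * n2 / (n1 + n2)) * d2
  Fv <- T2 * (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p)
  pval <- stats::pf(Fv, p, n1 + n2 - p - 1, lower.tail = FALSE)
  structure(list(statistic = T2, df = c(p, n1 + n2 - p - 1),
                 p_parametric = pval, F = Fv, mahalanobis_d = sqrt(d2),
                 p_permutation = NULL, test = "Hotelling T2"),
            class = "two_sample_result")
}

#' Permutation test on a between-group distance
#'
#' Observed Mahalanobis distance (via the pooled within-group covariance on
#' the PC subspace) or Procrustes distance (Euclidean norm of the mean
#' difference in tangent space) between the two group means, compared with
#' the distribution obtained from `n_perm` random relabelings;
#' `P = (1 + #{permuted >= observed}) / (n_perm + 1)`.
#'
#' @param shapes `n x 2k` matrix.
#' @param groups two-level factor.
#' @param metric `"mahalanobis"` or `"procrustes"`.
#' @param n_perm number of permutations (default 10000).
#' @return `two_sample_result` with the observed distance in `statistic`.
#' @export
distance_permutation_test <- function(shapes, groups,
                                      metric = c("mahalanobis", "procrustes"),
                                      n_perm = 10000) {
  metric <- match.arg(metric)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  X <- as.matrix(shapes)
  if (metric == "mahalanobis") {
    sub <- pc_subspace(X, max_p = nrow(X) - 3)
    X <- sub$scores
    if (nrow(X) - 2 <= sub$p) stop("singular pooled covariance: reduce the PC subspace")
  }
  dist_fun <- function(g) {
    d <- colMeans(X[g == levels(groups)[1], , drop = FALSE]) -
         colMeans(X[g == levels(groups)[2], , drop = FALSE])
    if (metric == "mahalanobis") {
      S <- pooled_cov(X, g)
      sqrt(as.numeric(crossprod(d, solve(S, d))))
    } else sqrt(sum(d^2))
  }
  obs <- dist_fun(groups)
  perm <- replicate(n_perm, dist_fun(sample(groups)))
  structure(list(statistic = obs, df = NULL, p_parametric = NULL,
                 p_permutation = perm_pvalue(obs, perm),
                 n_permutations = n_perm,
                 test = paste(metric, "distance")),
            class = "two_sample_result")
}

# Mahalanobis classification rule for two groups with equal priors
da_rule <- function(train, train_groups) {
  lv <- levels(train_groups)
  m1 <- colMeans(train[train_groups == lv[1], , drop = FALSE])
  m2 <- colMeans(train[train_groups == lv[2], , drop = FALSE])
  S <- pooled_cov(train, train_groups)
  Sinv <- solve(S)
  w <- Sinv %*% (m1 - m2)
  classify <- function(x) {
    d1 <- as.numeric(crossprod(x - m1, Sinv %*% (x - m1)))
    d2 <- as.numeric(crossprod(x - m2, Sinv %*% (x - m2)))
    if (d1 <= d2) lv[1] else lv[2]  # tie -> group 1 (measure-zero event)
  }
  list(w = as.vector(w), m1 = m1, m2 = m2, classify = classify)
}

#' Two-group discriminant analysis with jackknife cross-validation
#'
#' Fisher's linear discriminant for two groups on the non-degenerate PC
#' subspace: discriminant vector `S_pooled^-1 (m1 - m2)`, classification by
#' the smaller Mahalanobis distance to a group mean (equal priors).  The
#' resubstitution table classifies each specimen with the rule fitted on
#' everyone; the jackknife table refits means, pooled covariance and rule
#' with each specimen held out, so the held-out specimen never influences
#' the model that classifies it.
#'
#' @param shapes `n x 2k` matrix (tangent coordinates).
#' @param groups two-level factor.
#' @param cross_validate compute the jackknife table (default TRUE).
#' @return object of class `discriminant_result`: `discriminant_vector`
#'   (in the PC subspace), `scores`, `confusion_resub` and
#'   `confusion_jackknife` (2 x 2 row-percentage tables), counts tables,
#'   `group_mean_shapes` (in the original coordinate space), accuracies.
#' @export
discriminant_analysis <- function(shapes, groups, cross_validate = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  X0 <- as.matrix(shapes)
  sub <- pc_subspace(X0, max_p = nrow(X0) - 3)
  X <- sub$scores
  n <- nrow(X)
  if (n - 2 <= sub$p)
    stop("singular covariance: reduce the PC subspace before discriminant analysis")
  lv <- levels(groups)
  rule <- da_rule(X, groups)
  scores <- as.vector(X %*% rule$w)
  pred_resub <- vapply(seq_len(n), function(i) rule$classify(X[i, ]), "")
  pred_jack <- rep(NA_character_, n)
  if (cross_validate) {
    for (i in seq_len(n)) {
      r <- da_rule(X[-i, , drop = FALSE], droplevels(groups[-i]))
      pred_jack[i] <- r$classify(X[i, ])
    }
  }
  conf <- function(pred) {
    tab <- table(factor(groups, lv), factor(pred, lv))
    counts <- unclass(tab)
    pct <- 100 * counts / rowSums(counts)
    list(counts = counts, pct = pct,
         accuracy = 100 * sum(diag(counts)) / sum(counts))
  }
  cr <- conf(pred_resub)
  cj <- if (cross_validate) conf(pred_jack) else NULL
  gm <- rbind(colMeans(X0[groups == lv[1], , drop = FALSE]),
              colMeans(X0[groups == lv[2], , drop = FALSE]))
  rownames(gm) <- lv
  structure(list(discriminant_vector = rule$w, scores = scores,
                 groups = groups,
                 predicted_resub = pred_resub,
                 predicted_jackknife = if (cross_validate) pred_jack else NULL,
                 confusion_resub = cr$pct, confusion_resub_counts = cr$counts,
                 accuracy_resub = cr$accuracy,
                 confusion_jackknife = if (cross_validate) cj$pct else NULL,
                 confusion_jackknife_counts = if (cross_validate) cj$counts else NULL,
                 accuracy_jackknife = if (cross_validate) cj$accuracy else NULL,
                 group_mean_shapes = gm, p = sub$p),
            class = "discriminant_result")
}

#' @export
print.discriminant_result <- function(x, ...) {
  cat("Two-group discriminant analysis on", x$p, "PCs\n")
  cat(sprintf("  resubstitution accuracy: %.1f%%\n", x$accuracy_resub))
  if (!is.null(x$accuracy_jackknife)) {
    cat(sprintf("  jackknife accuracy:      %.1f%%\n", x$accuracy_jackknife))
    cat("  jackknife classification table (row %):\n")
    print(round(x$confusion_jackknife, 1))
  }
  invisible(x)
}

#' Box's M test of covariance homogeneity
#'
#' Compares group covariance matrices via the log-determinant statistic
#' with its chi-square approximation.  When some group has fewer
#' observations than dimensions, the statistic is computed on a reduced PC
#' subspace (with a warning) so the determinants exist.
#'
#' @param shapes `n x p` matrix.
#' @param groups factor (two or more levels).
#' @return list with `M`, `chi2` (the scaled statistic), `chi2_df`, `P`,
#'   and the dimensionality `p` used.
#' @export
boxs_m <- function(shapes, groups) {
  groups <- factor(groups)
  X <- as.matrix(shapes)
  sub <- pc_subspace(X)
  X <- sub$scores
  ns <- table(groups)
  p <- ncol(X)
  if (any(ns <= p)) {
    p_new <- min(ns) - 1L
    warning(sprintf("group size <= dimension: reducing to the first %d PCs", p_new))
    X <- X[, seq_len(p_new), drop = FALSE]
    p <- p_new
  }
  g <- nlevels(groups)
  n <- nrow(X)
  logdet <- function(S) determinant(S, logarithm = TRUE)$modulus[1]
  Sp <- pooled_cov(X, groups)
  M <- (n - g) * logdet(Sp)
  for (lev in levels(groups)) {
    Xg <- X[groups == lev, , drop = FALSE]
    M <- M - (nrow(Xg) - 1) * logdet(stats::cov(Xg))
  }
  c1 <- (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1)) *
    (sum(1 / (ns - 1)) - 1 / (n - g))
  chi2 <- M * (1 - c1)
  df <- (g - 1) * p * (p + 1) / 2
  list(M = M, chi2 = chi2, chi2_df = df,
       P = stats::pchisq(chi2, df, lower.tail = FALSE), p = p)
}

#' Run the full two-group test battery on tree-averaged data
#'
#' Convenience wrapper reproducing the tree-level comparison: size t test
#' with permutations, dummy-regression variance percentages for size and
#' shape, Hotelling T^2, Mahalanobis- and Procrustes-distance permutation
#' tests, and the jackknifed discriminant analysis.
#'
#' @param shapes `n x 2k` matrix of (tree-averaged) tangent coordinates.
#' @param sizes numeric vector of centroid sizes (omit with `NULL` to skip
#'   the size tests).
#' @param groups two-level factor.
#' @param n_perm permutations for each permutation test (default 10000).
#' @return a list of class `test_battery` with the individual results.
#' @export
group_test_battery <- function(shapes, sizes, groups, n_perm = 10000) {
  out <- list()
  if (!is.null(sizes)) {
    out$size_t <- size_t_test(sizes, groups, n_perm)
    out$size_dummy <- dummy_regression_test(sizes, groups, n_perm)
  }
  out$shape_dummy <- dummy_regression_test(shapes, groups, n_perm)
  out$hotelling <- hotelling_t2(shapes, groups)
  out$mahalanobis <- distance_permutation_test(shapes, groups, "mahalanobis", n_perm)
  out$procrustes <- distance_permutation_test(shapes, groups, "procrustes", n_perm)
  out$da <- discriminant_analysis(shapes, groups)
  out$boxs_m <- tryCatch(boxs_m(shapes, groups), warning = function(w) {
    suppressWarnings(boxs_m(shapes, groups))
  })
  class(out) <- "test_battery"
  out
}

#' @export
print.test_battery <- function(x, ...) {
  if (!is.null(x$size_t)) print(x$size_t)
  print(x$hotelling)
  print(x$mahalanobis)
  print(x$procrustes)
  print(x$da)
  invisible(x)
}
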