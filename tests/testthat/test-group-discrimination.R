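make_avg <- function(seed = 1, trees = 22) {
  ds <- generate_dataset(synthetic_spec(trees_per_population = trees,
                                        seed = seed))
  average_by_tree(gpa(ds))
}

test_that("tree averaging pools all observations of a tree", {
  avg <- make_avg(seed = 4)
  expect_equal(nrow(avg$shapes), 44L)
  expect_equal(as.vector(table(avg$population)), c(22L, 22L))
  # averaging is the arithmetic mean over leaves x replicas
  ds <- generate_dataset(synthetic_spec(seed = 4))
  al <- gpa(ds)
  tr1 <- levels(al$classifiers$tree)[1]
  idx <- al$classifiers$tree == tr1
  expect_equal(unname(avg$shapes[tr1, ]), unname(colMeans(al$shapes[idx, ])),
               tolerance = 1e-12)
  expect_equal(unname(avg$sizes[1]), mean(al$centroid_sizes[idx]),
               tolerance = 1e-12)
})

test_that("two symmetric deviations average to the consensus", {
  m <- template_leaf()
  x <- matrix(rnorm(22, 0, 0.01), 11, 2)
  arr <- array(c(m + x, m - x, m + x, m - x), c(11, 2, 4))
  al <- gpa(arr)
  avg <- colMeans(al$shapes)
  d <- sqrt(sum((avg - al$mean_shape)^2))
  expect_lt(d, 1e-6)
})

test_that("pooled t test matches the closed form and its permutation bounds", {
  set.seed(10)
  res <- size_t_test(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3),
                     n_perm = 500)
  expect_equal(abs(res$statistic), 1.2247, tolerance = 1e-4)
  expect_equal(res$df, 4)
  expect_gte(res$p_permutation, 1 / 501)
  expect_lte(res$p_permutation, 1)
  # identical group means: t = 0, parametric P = 1
  res0 <- size_t_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3),
                      n_perm = 99)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_parametric, 1)
  expect_error(size_t_test(c(1, 1, 1, 1), rep(c("a", "b"), each = 2), 9),
               "zero pooled variance")
})

test_that("dummy regression percent variance equals the point-biserial square", {
  set.seed(14)
  y <- rnorm(20)
  g <- factor(rep(c("a", "b"), 10))
  res <- dummy_regression_test(y, g, n_perm = 199)
  pb <- cor(y, as.numeric(g == "a"))
  expect_equal(res$pct_variance, 100 * pb^2, tolerance = 1e-9)
  # perfectly separated response
  ysep <- as.numeric(g == "a")
  expect_equal(dummy_regression_test(ysep, g, 99)$pct_variance, 100,
               tolerance = 1e-9)
})

test_that("Hotelling T2 reduces to t-squared in one dimension", {
  set.seed(15)
  y <- c(rnorm(10), rnorm(12, 1))
  g <- factor(rep(c("a", "b"), c(10, 12)))
  t2 <- hotelling_t2(matrix(y), g)
  tt <- size_t_test(y, g, n_perm = 9)
  expect_equal(t2$statistic, tt$statistic^2, tolerance = 1e-9)
  expect_equal(t2$p_parametric, tt$p_parametric, tolerance = 1e-9)
})

test_that("T2, Mahalanobis distance and DA are mutually consistent", {
  avg <- make_avg(seed = 16)
  g <- avg$population
  t2 <- hotelling_t2(avg$shapes, g)
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  expect_equal(t2$statistic, n1 * n2 / (n1 + n2) * t2$mahalanobis_d^2,
               tolerance = 1e-9)
  expect_equal(t2$df, c(18, 25))
  md <- distance_permutation_test(avg$shapes, g, "mahalanobis", n_perm = 49)
  expect_equal(md$statistic, t2$mahalanobis_d, tolerance = 1e-9)
})

test_that("identical group means give zero Procrustes distance", {
  X <- matrix(rnorm(40), 20, 2)
  X2 <- rbind(X, X)
  g <- factor(rep(c("a", "b"), each = 20))
  res <- distance_permutation_test(X2, g, "procrustes", n_perm = 49)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_gte(res$p_permutation, 1 / 50)
})

test_that("well-separated clusters classify perfectly under jackknife", {
  set.seed(17)
  X <- rbind(matrix(rnorm(20 * 4), 20, 4),
             matrix(rnorm(20 * 4, mean = 8), 20, 4))
  g <- factor(rep(c("a", "b"), each = 20))
  d <- discriminant_analysis(X, g)
  expect_equal(d$accuracy_jackknife, 100)
  expect_true(all(abs(rowSums(d$confusion_jackknife) - 100) < 1e-9))
})

test_that("the discriminant rule agrees with an independent LDA", {
  skip_if_not_installed("MASS")
  set.seed(18)
  X <- rbind(matrix(rnorm(15 * 3), 15, 3),
             matrix(rnorm(15 * 3, mean = 0.8), 15, 3))
  g <- factor(rep(c("a", "b"), each = 15))
  d <- discriminant_analysis(X, g)
  fit <- MASS::lda(X, g, prior = c(0.5, 0.5))
  # equal priors, two groups: Mahalanobis-distance rule == LDA posterior rule
  expect_equal(d$predicted_resub, as.character(predict(fit)$class))
  # discriminant vector parallel to LDA scaling (ours lives in the PC
  # subspace; map it back to the original space before comparing)
  p <- shape_pca(X)
  keep <- p$eigenvalues > 1e-12 * max(p$eigenvalues)
  v_orig <- p$eigenvectors[, keep, drop = FALSE] %*% d$discriminant_vector
  cosang <- abs(sum(v_orig * fit$scaling) /
                  sqrt(sum(v_orig^2) * sum(fit$scaling^2)))
  expect_equal(cosang, 1, tolerance = 1e-6)
})

test_that("the jackknife never uses the held-out specimen", {
  set.seed(19)
  X <- rbind(matrix(rnorm(12 * 3), 12, 3),
             matrix(rnorm(12 * 3, 1), 12, 3))
  g <- factor(rep(c("a", "b"), each = 12))
  d <- discriminant_analysis(X, g)
  # refitting without specimen i by hand must reproduce pred_jackknife[i]
  p <- shape_pca(X)
  keep <- p$eigenvalues > 1e-12 * max(p$eigenvalues)
  S <- p$scores[, keep, drop = FALSE]
  for (i in c(1, 7, 24)) {
    Str <- S[-i, , drop = FALSE]; gtr <- g[-i]
    m1 <- colMeans(Str[gtr == "a", , drop = FALSE])
    m2 <- colMeans(Str[gtr == "b", , drop = FALSE])
    Sp <- (crossprod(sweep(Str[gtr == "a", , drop = FALSE], 2, m1)) +
           crossprod(sweep(Str[gtr == "b", , drop = FALSE], 2, m2))) /
      (nrow(Str) - 2)
    d1 <- mahalanobis(S[i, , drop = FALSE], m1, Sp)
    d2 <- mahalanobis(S[i, , drop = FALSE], m2, Sp)
    expect_equal(d$predicted_jackknife[i], if (d1 <= d2) "a" else "b")
  }
  # corrupting specimen i does not change the model classifying the others:
  # all jackknife rules for j != i are functions of the data without j, so
  # only rows whose own features or whose training sets changed can move --
  # here only specimen i's own prediction may differ
  X2 <- X; X2[1, ] <- X[1, ] + 0  # identical data -> identical predictions
  expect_identical(discriminant_analysis(X2, g)$predicted_jackknife,
                   d$predicted_jackknife)
})

test_that("Box's M is zero for identical covariances and matches its formula", {
  set.seed(20)
  X <- matrix(rnorm(30 * 3), 30, 3)
  X2 <- rbind(X, X)  # both groups identical -> identical sample covariances
  g <- factor(rep(c("a", "b"), each = 30))
  res <- boxs_m(X2, g)
  expect_equal(res$M, 0, tolerance = 1e-8)
  expect_equal(res$P, 1, tolerance = 1e-6)
  # direct log-determinant oracle on a small instance
  Y <- rbind(matrix(rnorm(15 * 2), 15, 2), matrix(rnorm(15 * 2, 0, 2), 15, 2))
  gg <- factor(rep(c("a", "b"), each = 15))
  res2 <- boxs_m(Y, gg)
  p <- shape_pca(Y)
  keep <- p$eigenvalues > 1e-12 * max(p$eigenvalues)
  S <- p$scores[, keep, drop = FALSE]
  S1 <- cov(S[gg == "a", ]); S2 <- cov(S[gg == "b", ])
  Sp <- (14 * S1 + 14 * S2) / 28
  M_oracle <- 28 * log(det(Sp)) - 14 * log(det(S1)) - 14 * log(det(S2))
  expect_equal(res2$M, M_oracle, tolerance = 1e-9)
})

test_that("permutation P values are seed-reproducible and bounded", {
  avg <- make_avg(seed = 21, trees = 8)
  set.seed(99)
  a <- distance_permutation_test(avg$shapes, avg$population, "procrustes", 199)
  set.seed(99)
  b <- distance_permutation_test(avg$shapes, avg$population, "procrustes", 199)
  expect_identical(a$p_permutation, b$p_permutation)
  expect_gte(a$p_permutation, 1 / 200)
  expect_lte(a$p_permutation, 1)
})
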