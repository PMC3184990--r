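make_avg_allom <- function(seed = 2) {
  ds <- generate_dataset(synthetic_spec(seed = seed))
  average_by_tree(gpa(ds))
}

test_that("an exactly linear shape-size relation is fully explained", {
  set.seed(30)
  n <- 20
  sizes <- runif(n, 50, 90)
  B <- rnorm(8, 0, 0.01)
  shapes <- outer(sizes, B) + matrix(rep(rnorm(8), each = n), n, 8)
  fit <- shape_size_regression(shapes, sizes, n_perm = 49)
  expect_equal(fit$pct_variance, 100, tolerance = 1e-9)
  expect_equal(unname(fit$slope), B, tolerance = 1e-9)
  # predicted + residual reconstructs the centered observations exactly
  recon <- fit$predicted + fit$residuals
  expect_equal(recon, sweep(shapes, 2, colMeans(shapes)), tolerance = 1e-9)
})

test_that("null allometry yields noise-scale fit and calibrated permutation P", {
  set.seed(31)
  ps <- replicate(40, {
    shapes <- matrix(rnorm(20 * 6), 20, 6)
    sizes <- runif(20, 50, 90)
    shape_size_regression(shapes, sizes, n_perm = 99)$p_permutation
  })
  # P should be roughly uniform: around half below 0.5
  expect_gt(mean(ps < 0.5), 0.25)
  expect_lt(mean(ps < 0.05), 0.25)
  expect_error(shape_size_regression(matrix(rnorm(12), 6, 2), rep(2, 6), 9),
               "constant")
})

test_that("Pillai traces match the independent MANOVA oracle", {
  avg <- make_avg_allom(seed = 33)
  m <- mancova(avg$shapes, avg$sizes, avg$population)
  # independent route: stats::manova with sequential terms; the last term's
  # Pillai statistic matches ours for each hypothesis
  p <- shape_pca(avg$shapes)
  keep <- p$eigenvalues > 1e-12 * max(p$eigenvalues)
  Y <- p$scores[, keep, drop = FALSE]
  g <- factor(avg$population); s <- avg$sizes
  pillai_of <- function(form, term) {
    sm <- summary(stats::manova(form), test = "Pillai")
    sm$stats[term, "Pillai"]
  }
  expect_equal(m$pillai[m$term == "slopes"],
               pillai_of(Y ~ g + s + g:s, "g:s"), tolerance = 1e-8)
  expect_equal(m$pillai[m$term == "intercepts"],
               pillai_of(Y ~ s + g, "g"), tolerance = 1e-8)
  expect_equal(m$pillai[m$term == "size_only"],
               pillai_of(Y ~ s, "s"), tolerance = 1e-8)
  # df pairs for 44 trees and p = 18: (18, 23), (18, 24), (18, 25)
  expect_equal(m$df2, c(23, 24, 25))
  # Pillai-F identity for 1-df hypotheses
  expect_equal(m$F, (m$pillai / (1 - m$pillai)) * (m$df2 / m$df1),
               tolerance = 1e-10)
})

test_that("model fits are nested: separate >= parallel >= single line", {
  avg <- make_avg_allom(seed = 34)
  m <- mancova(avg$shapes, avg$sizes, avg$population)
  fits <- m$pct_model   # total fitted SS % of the fuller model per row
  expect_gte(fits[1] + 1e-9, fits[2])
  expect_gte(fits[2] + 1e-9, fits[3])
})

test_that("log and raw size give nearly equal fits for a small size range", {
  avg <- make_avg_allom(seed = 35)
  set.seed(1); raw <- shape_size_regression(avg$shapes, avg$sizes, 9)
  set.seed(1); lg <- shape_size_regression(avg$shapes, avg$sizes, 9, use_log = TRUE)
  expect_equal(raw$pct_variance, lg$pct_variance, tolerance = 0.02)
})

test_that("size-correction removes within-group allometry exactly", {
  avg <- make_avg_allom(seed = 36)
  sc <- size_correct(avg$shapes, avg$sizes, avg$population)
  # pooled within-group regression of corrected shapes on size ~ 0%
  Xw <- sc$shapes; sw <- avg$sizes
  for (g in levels(avg$population)) {
    i <- avg$population == g
    Xw[i, ] <- sweep(sc$shapes[i, ], 2, colMeans(sc$shapes[i, ]))
    sw[i] <- avg$sizes[i] - mean(avg$sizes[i])
  }
  B <- crossprod(Xw, sw) / sum(sw^2)
  pct_resid <- 100 * sum(outer(sw, as.vector(B))^2) / sum(Xw^2)
  expect_lt(pct_resid, 1e-8)
})

test_that("group mean differences are invariant to the common size", {
  avg <- make_avg_allom(seed = 37)
  g <- avg$population
  diff_at <- function(cs) {
    sc <- size_correct(avg$shapes, avg$sizes, g, common_size = cs)
    colMeans(sc$shapes[g == levels(g)[1], ]) -
      colMeans(sc$shapes[g == levels(g)[2], ])
  }
  expect_equal(diff_at(mean(avg$sizes)), diff_at(55), tolerance = 1e-10)
  expect_equal(diff_at(0), diff_at(100), tolerance = 1e-10)
})

test_that("zero-allometry correction is a near-identity", {
  ds <- null_dataset(synthetic_spec(seed = 38), "no_allometry")
  avg <- average_by_tree(gpa(ds))
  sc <- size_correct(avg$shapes, avg$sizes, avg$population)
  # slope is noise-scale, so corrected shapes barely move
  move <- max(abs(sc$shapes - avg$shapes))
  spread <- stats::sd(avg$shapes)
  expect_lt(move, spread)
  # and B = 0 exactly gives the identity
  sc0 <- size_correct(avg$shapes, avg$sizes * 0 + rep(c(60, 80),
                                                      length.out = 44),
                      avg$population)
  corrected_manual <- avg$shapes - outer(rep(c(60, 80), length.out = 44) -
                                           sc0$common_size, sc0$pooled_slope)
  expect_equal(sc0$shapes, corrected_manual, tolerance = 1e-12)
})

test_that("size-correction refuses under significantly different slopes", {
  avg <- make_avg_allom(seed = 39)
  expect_error(size_correct(avg$shapes, avg$sizes, avg$population,
                            slopes_p = 0.01), "parallel")
  expect_s3_class(size_correct(avg$shapes, avg$sizes, avg$population,
                               slopes_p = 0.01, force = TRUE),
                  "size_corrected")
})

test_that("the corrected-shape battery matches direct delegation", {
  avg <- make_avg_allom(seed = 40)
  sc <- size_correct(avg$shapes, avg$sizes, avg$population)
  set.seed(5)
  b1 <- rerun_group_tests_on_corrected(sc, n_perm = 49)
  set.seed(5)
  b2 <- group_test_battery(sc$shapes, NULL, avg$population, n_perm = 49)
  expect_equal(b1$hotelling$statistic, b2$hotelling$statistic)
  expect_equal(b1$procrustes$p_permutation, b2$procrustes$p_permutation)
})
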