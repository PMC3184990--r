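# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written without reusing package internals.

# n jittered copies of a base triangle (small-variation regime)
jittered_triangles <- function(n, sd = 0.01, seed = 1) {
  set.seed(seed)
  base <- matrix(c(0, 0, 1, 0, 0.4, 0.9), 3, 2, byrow = TRUE)
  arr <- array(NA_real_, c(3, 2, n))
  for (i in seq_len(n)) {
    m <- base + matrix(rnorm(6, 0, sd), 3, 2)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    arr[, , i] <- sweep(m %*% R, 2, runif(2, -3, 3), "+")
  }
  arr
}

# brute-force minimal distance between two configurations after centering,
# unit scaling, and an exhaustive grid search over the rotation angle
oracle_rotation_distance <- function(a, b, step = 0.002) {
  prep <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- prep(a); b <- prep(b)
  thetas <- seq(0, 2 * pi, by = step)
  dists <- vapply(thetas, function(th) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    sqrt(sum((a %*% R - b)^2))
  }, 1)
  min(dists)
}

# cophenetic distances recomputed by an independent traversal of the
# hclust merge structure (height of the smallest cluster joining i and j)
oracle_cophenetic <- function(hc) {
  n <- length(hc$order)
  D <- matrix(0, n, n)
  members <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    get_side <- function(v) if (v < 0) -v else members[[v]]
    left <- get_side(hc$merge[s, 1]); right <- get_side(hc$merge[s, 2])
    for (i in left) for (j in right) D[i, j] <- D[j, i] <- hc$height[s]
    members[[s]] <- c(left, right)
  }
  D
}

# bending-energy matrix assembled by the explicit closed form
# B = K^-1 - K^-1 P (P' K^-1 P)^-1 P' K^-1  (independent of the package's
# inverse-of-the-bordered-system route)
oracle_bending_matrix <- function(ref) {
  D2 <- as.matrix(dist(ref))^2
  K <- ifelse(D2 == 0, 0, D2 * log(D2))
  P <- cbind(1, ref)
  Kinv <- solve(K)
  Kinv - Kinv %*% P %*% solve(t(P) %*% Kinv %*% P) %*% t(P) %*% Kinv
}

# balanced nested toy dataset with known structure for ANOVA tests
toy_nested <- function(seed = 5, unbalanced = FALSE) {
  set.seed(seed)
  pops <- c("AA", "BB")
  rows <- list()
  for (p in seq_along(pops)) {
    n_tree <- if (unbalanced && p == 1) 4 else 3
    for (tr in seq_len(n_tree)) {
      n_leaf <- if (unbalanced && tr == 1) 3 else 2
      for (lf in seq_len(n_leaf)) {
        n_rep <- if (unbalanced && lf == 1) 3 else 2
        for (r in seq_len(n_rep)) {
          rows[[length(rows) + 1]] <- data.frame(
            population = pops[p],
            tree = paste0(pops[p], "_t", tr),
            leaf = paste0(pops[p], "_t", tr, "_l", lf),
            replica = r)
        }
      }
    }
  }
  cls <- do.call(rbind, rows)
  n <- nrow(cls)
  y <- 2 * (cls$population == "AA") + rnorm(nlevels(factor(cls$tree)))[as.integer(factor(cls$tree))] +
    0.5 * rnorm(nlevels(factor(cls$leaf)))[as.integer(factor(cls$leaf))] + 0.1 * rnorm(n)
  list(values = cbind(y, 0.5 * y + rnorm(n, 0, 0.2)), classifiers = cls)
}

# sequential (hierarchical) SS via indicator-variable least squares:
# residual-SS drops along null -> +population -> +tree -> +leaf
oracle_sequential_ss <- function(values, cls) {
  values <- as.matrix(values)
  rss <- function(X) {
    fit <- lm.fit(X, values)
    sum(as.matrix(fit$residuals)^2)
  }
  n <- nrow(values)
  X0 <- matrix(1, n, 1)
  Xp <- model.matrix(~ factor(cls$population))
  Xt <- model.matrix(~ factor(cls$tree))
  Xl <- model.matrix(~ factor(cls$leaf))
  r0 <- rss(X0); rp <- rss(Xp); rt <- rss(Xt); rl <- rss(Xl)
  c(populations = r0 - rp, trees = rp - rt, leaves = rt - rl, error = rl,
    total = r0)
}

# rebuild a k x 2 x n array from interleaved flat rows (test-local copy)
unflatten_coords_test <- function(mat) {
  n <- nrow(mat); k <- ncol(mat) / 2
  arr <- array(NA_real_, c(k, 2, n))
  for (i in seq_len(n)) arr[, , i] <- matrix(mat[i, ], k, 2, byrow = TRUE)
  arr
}

write_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}
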