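ref8 <- function() {
  set.seed(50)
  template_leaf()[c(1, 2, 3, 5, 7, 9, 10, 11), ]
}

test_that("identity and affine targets have zero bending energy", {
  ref <- ref8()
  fit <- tps_fit(ref, ref)
  expect_equal(max(abs(fit$W)), 0, tolerance = 1e-10)
  expect_equal(fit$A, rbind(c(0, 0), c(1, 0), c(0, 1)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(fit$bending_energy, 0, tolerance = 1e-12)
  # pure shear: affine part carries it, no bending
  Sh <- rbind(c(1, 0.3), c(0.1, 1))
  fit2 <- tps_fit(ref, ref %*% Sh)
  expect_equal(max(abs(fit2$W)), 0, tolerance = 1e-8)
  expect_lt(abs(fit2$bending_energy), 1e-12)
  expect_equal(fit2$A[2:3, ], Sh, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the warp interpolates the landmarks exactly", {
  set.seed(51)
  ref <- ref8()
  tgt <- ref + matrix(rnorm(16, 0, 0.05), 8, 2)
  fit <- tps_fit(ref, tgt)
  expect_equal(tps_warp_points(fit, ref), tgt, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_gt(fit$bending_energy, 0)
  expect_error(tps_fit(cbind(1:5, 2 * (1:5)), cbind(1:5, 1:5)), "collinear")
})

test_that("warped points match an independent per-point evaluation", {
  set.seed(52)
  ref <- ref8()
  tgt <- ref + matrix(rnorm(16, 0, 0.05), 8, 2)
  fit <- tps_fit(ref, tgt)
  pts <- matrix(runif(20, -0.5, 0.5), 10, 2)
  got <- tps_warp_points(fit, pts)
  # direct formula, no matrix reuse
  for (i in 1:10) {
    p <- pts[i, ]
    r2 <- rowSums(sweep(ref, 2, p)^2)
    U <- ifelse(r2 == 0, 0, r2 * log(r2))
    want <- as.vector(t(fit$A) %*% c(1, p) + t(fit$W) %*% U)
    expect_equal(unname(got[i, ]), want, tolerance = 1e-10)
  }
})

test_that("Jacobian determinants: identity, uniform scale, finite differences", {
  ref <- ref8()
  pts <- matrix(runif(16, -0.4, 0.4), 8, 2)
  expect_equal(jacobian_expansion(tps_fit(ref, ref), pts), rep(1, 8),
               tolerance = 1e-9)
  cc <- 1.7
  expect_equal(jacobian_expansion(tps_fit(ref, cc * ref), pts),
               rep(cc^2, 8), tolerance = 1e-8)
  set.seed(53)
  tgt <- ref + matrix(rnorm(16, 0, 0.04), 8, 2)
  fit <- tps_fit(ref, tgt)
  jac <- jacobian_expansion(fit, pts)
  h <- 1e-6
  for (i in 1:8) {
    p <- pts[i, ]
    fx <- (tps_warp_points(fit, rbind(p + c(h, 0))) -
           tps_warp_points(fit, rbind(p - c(h, 0)))) / (2 * h)
    fy <- (tps_warp_points(fit, rbind(p + c(0, h))) -
           tps_warp_points(fit, rbind(p - c(0, h)))) / (2 * h)
    J_num <- fx[1] * fy[2] - fy[1] * fx[2]
    expect_equal(jac[i], J_num, tolerance = 1e-6)
  }
})

test_that("diagram geometry: straight identity grids, lollipop lengths,
           affine-exact outlines", {
  ref <- ref8()
  g <- make_grid(tps_fit(ref, ref), n_cells = 5)
  for (ln in seq_along(g$before))
    expect_equal(g$after[[ln]], g$before[[ln]], tolerance = 1e-9)
  expect_equal(g$jacobian, rep(1, nrow(g$nodes)), tolerance = 1e-9)

  set.seed(54)
  tgt <- ref + matrix(rnorm(16, 0, 0.05), 8, 2)
  lp <- lollipops(ref, tgt)
  expect_equal(lp$length, sqrt(rowSums((tgt - ref)^2)), tolerance = 1e-12)

  shift <- c(0.3, -0.2)
  fit_tr <- tps_fit(ref, sweep(ref, 2, shift, "+"))
  outline <- matrix(runif(14, -0.4, 0.4), 7, 2)
  wo <- warp_outline(fit_tr, outline)
  expect_equal(wo$after[[1]], sweep(outline, 2, shift, "+"), tolerance = 1e-9)

  wf <- warp_wireframe(ref, tgt, cbind(1:7, 2:8))
  expect_length(wf$before, 7)
  expect_error(warp_wireframe(ref, tgt, cbind(1, 9)), "out of range")
})

test_that("magnification is the stated affine interpolation", {
  ref <- ref8()
  set.seed(55)
  tgt <- ref + matrix(rnorm(16, 0, 0.05), 8, 2)
  expect_equal(magnify(ref, tgt, 1), tgt)
  expect_equal(magnify(ref, tgt, 1e-12), ref, tolerance = 1e-10)
  # doubling a PC score: the magnified shape is the shape at twice the score
  m <- as.vector(t(ref)); v <- rnorm(16); v <- v / sqrt(sum(v^2))
  s1 <- m + 0.05 * v; s2 <- m + 0.1 * v
  expect_equal(magnify(m, s1, 2), s2, tolerance = 1e-12)
  # un-magnifying recovers the target
  mg <- magnify(ref, tgt, 3)
  expect_equal(magnify(ref, mg, 1 / 3), tgt, tolerance = 1e-12)
})

test_that("partial warps and uniform components carry all shape information", {
  ds <- generate_dataset(synthetic_spec(trees_per_population = 6, seed = 56))
  al <- gpa(ds)
  pw <- partial_warps(al)
  k <- al$k
  expect_length(pw$eigenvalues, k - 3)
  expect_true(all(pw$eigenvalues > 0))
  expect_equal(ncol(pw$scores), 2 * (k - 3))
  expect_equal(ncol(pw$uniform), 2)
  d_full <- dist(al$shapes)
  d_pw <- dist(cbind(pw$scores, pw$uniform))
  expect_equal(as.vector(d_pw), as.vector(d_full), tolerance = 1e-9)
})

test_that("bending-energy matrix has k - 3 nonzero eigenvalues and matches
           the closed-form oracle", {
  ds <- generate_dataset(synthetic_spec(trees_per_population = 4, seed = 57))
  al <- gpa(ds)
  pw <- partial_warps(al)
  ref <- matrix(al$mean_shape, al$k, 2, byrow = TRUE)
  Be <- oracle_bending_matrix(ref)
  ev <- eigen(Be, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) > 1e-9 * max(abs(ev))), al$k - 3)
  expect_equal(sort(pw$eigenvalues), sort(ev[seq_len(al$k - 3)]),
               tolerance = 1e-8)
  # scores match a brute-force projection with the oracle's eigenvectors
  eo <- eigen(Be, symmetric = TRUE)
  dev <- sweep(al$shapes, 2, al$mean_shape)
  for (j in seq_len(al$k - 3)) {
    e_j <- eo$vectors[, j]
    sx <- dev[, seq(1, 2 * al$k, 2)] %*% e_j
    sy <- dev[, seq(2, 2 * al$k, 2)] %*% e_j
    # eigenvectors are sign/rotation ambiguous; compare the per-warp score
    # norms, which are basis-invariant
    norm_oracle <- sqrt(sx^2 + sy^2)
    norm_pkg <- sqrt(pw$scores[, 2 * j - 1]^2 + pw$scores[, 2 * j]^2)
    expect_equal(as.vector(norm_pkg), as.vector(norm_oracle), tolerance = 1e-8)
  }
})

test_that("TPS geometry is independent of the superimposition frame", {
  # the same two shapes expressed in a Procrustes frame and in a baseline
  # frame give warps related by the similarity transforms between frames
  set.seed(60)
  base <- template_leaf()
  A <- base + matrix(rnorm(22, 0, 0.02), 11, 2)
  B <- base + matrix(rnorm(22, 0, 0.02), 11, 2)
  # partial Procrustes frame built by hand: center, unit size, rotate B on A
  pre <- function(m) { m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2)) }
  P1 <- pre(A); Bp <- pre(B)
  a <- sum(Bp[, 1] * P1[, 2] - Bp[, 2] * P1[, 1]); b <- sum(Bp * P1)
  th <- atan2(a, b)
  P2 <- Bp %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  bs <- baseline_superimpose(array(c(A, B), c(11, 2, 2)), c(1, 11))
  B1 <- bs[, , 1]; B2 <- bs[, , 2]
  # similarity maps between frames, estimated from the landmark pairs
  sim_fit <- function(from, to) {
    zf <- complex(real = from[, 1], imaginary = from[, 2])
    zt <- complex(real = to[, 1], imaginary = to[, 2])
    ab <- qr.solve(cbind(1 + 0i, zf), zt)
    function(pts) {
      z <- complex(real = pts[, 1], imaginary = pts[, 2]) * ab[2] + ab[1]
      cbind(Re(z), Im(z))
    }
  }
  S_ref <- sim_fit(P1, B1)   # Procrustes frame -> baseline frame (reference)
  S_tgt <- sim_fit(P2, B2)
  fit_p <- tps_fit(P1, P2)
  fit_b <- tps_fit(B1, B2)
  pts <- sweep(matrix(runif(24, -0.2, 0.2), 12, 2), 2, colMeans(P1), "+")
  lhs <- tps_warp_points(fit_b, S_ref(pts))
  rhs <- S_tgt(tps_warp_points(fit_p, pts))
  expect_equal(lhs, rhs, tolerance = 1e-6)
})
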