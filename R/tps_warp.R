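# Thin-plate-spline interpolation and visualization geometry: deformation
# grids, warped outlines and wireframes, displacement (lollipop) vectors,
# Jacobian expansion factors, magnification, partial warps and uniform
# components.  Kernel convention: U(r) = r^2 log(r^2) with U(0) = 0 (the
# factor of 2 relative to r^2 log r is absorbed into the weights).

tps_kernel <- function(r2) ifelse(r2 == 0, 0, r2 * log(r2))

tps_L_matrix <- function(reference) {
  k <- nrow(reference)
  D2 <- as.matrix(stats::dist(reference))^2
  K <- tps_kernel(D2)
  P <- cbind(1, reference)
  rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
}

#' Fit a thin-plate spline between two landmark configurations
#'
#' Solves the standard TPS linear system so the warp maps the reference
#' landmarks exactly onto the target landmarks while minimizing the
#' idealized bending energy.  The map decomposes into an affine part
#' (3 x 2 matrix: constant, x and y terms per output coordinate) and
#' nonaffine kernel weights (k x 2) that satisfy the side conditions
#' `colSums(W) = 0` and `t(reference) %*% W = 0`.
#'
#' @param reference `k x 2` reference configuration (`k >= 4` for a
#'   nonsingular nonaffine part; not collinear).
#' @param target `k x 2` target configuration.
#' @return object of class `tps_coefficients`: `reference`, `target`,
#'   `W` (k x 2 nonaffine weights), `A` (3 x 2 affine part),
#'   `bending_energy` (`trace(t(W) K W)`, zero iff the map is affine).
#' @export
tps_fit <- function(reference, target) {
  reference <- as.matrix(reference); target <- as.matrix(target)
  stopifnot(ncol(reference) == 2, all(dim(reference) == dim(target)))
  k <- nrow(reference)
  if (k < 3) stop("at least 3 landmarks are required")
  if (qr(cbind(1, reference))$rank < 3)
    stop("collinear reference configuration: TPS system is singular")
  L <- tps_L_matrix(reference)
  rhs <- rbind(target, matrix(0, 3, 2))
  sol <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular TPS system (coincident or degenerate landmarks): ",
         conditionMessage(e)))
  W <- sol[seq_len(k), , drop = FALSE]
  A <- sol[k + 1:3, , drop = FALSE]
  K <- L[seq_len(k), seq_len(k)]
  be <- sum(diag(t(W) %*% K %*% W))
  structure(list(reference = reference, target = target, W = W, A = A,
                 bending_energy = be),
            class = "tps_coefficients")
}

#' @export
print.tps_coefficients <- function(x, ...) {
  cat(sprintf("Thin-plate spline on %d landmarks, bending energy %.4g\n",
              nrow(x$reference), x$bending_energy))
  invisible(x)
}

#' Evaluate a thin-plate-spline warp at arbitrary points
#'
#' `f(x, y) = A' (1, x, y) + sum_i W_i U(||(x, y) - ref_i||)` per output
#' coordinate.
#'
#' @param coeffs a `tps_coefficients` object from [tps_fit()].
#' @param points `m x 2` matrix of points to warp.
#' @return `m x 2` matrix of warped points.
#' @export
tps_warp_points <- function(coeffs, points) {
  points <- matrix(as.numeric(points), ncol = 2)
  ref <- coeffs$reference
  d2 <- outer(rowSums(points^2), rowSums(ref^2), "+") -
    2 * points %*% t(ref)
  d2 <- pmax(d2, 0)
  U <- tps_kernel(d2)
  cbind(1, points) %*% coeffs$A + U %*% coeffs$W
}

#' Jacobian expansion factors of a TPS warp
#'
#' Determinant of the analytic Jacobian of the warp at each point: values
#' above 1 indicate local area expansion, between 0 and 1 contraction.
#' Negative values (grid fold-over, possible under large magnifications)
#' are reported as-is with a warning.
#'
#' @inheritParams tps_warp_points
#' @return numeric vector of determinants, one per point.
#' @export
jacobian_expansion <- function(coeffs, points) {
  points <- matrix(as.numeric(points), ncol = 2)
  ref <- coeffs$reference
  m <- nrow(points)
  dets <- numeric(m)
  for (i in seq_len(m)) {
    dx <- points[i, 1] - ref[, 1]
    dy <- points[i, 2] - ref[, 2]
    s <- dx^2 + dy^2
    # d/dx [s log s] = (log s + 1) * 2 dx, with limit 0 as s -> 0
    g <- ifelse(s == 0, 0, log(s) + 1)
    J <- rbind(coeffs$A[2, ] + colSums(coeffs$W * (2 * g * dx)),
               coeffs$A[3, ] + colSums(coeffs$W * (2 * g * dy)))
    dets[i] <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  }
  if (any(dets <= 0))
    warning("negative Jacobian determinants: the warp folds over at some points")
  dets
}

#' Deformation grid geometry for a TPS warp
#'
#' Builds a rectilinear grid over the reference bounding box (expanded by a
#' margin), warps its nodes, and attaches the Jacobian expansion factor at
#' every node.  Only geometry is produced; rendering is left to any
#' plotting layer.
#'
#' @param coeffs a `tps_coefficients` object.
#' @param n_cells grid cells per side (default 20).
#' @param margin fractional bounding-box expansion (default 0.1).
#' @return object of class `shape_diagram` (kind `"grid"`): lists
#'   `before` and `after` of polylines (each an `m x 2` matrix), node
#'   matrices and `jacobian` per node.
#' @export
make_grid <- function(coeffs, n_cells = 20, margin = 0.1) {
  ref <- coeffs$reference
  rx <- range(ref[, 1]); ry <- range(ref[, 2])
  ex <- diff(rx) * margin; ey <- diff(ry) * margin
  xs <- seq(rx[1] - ex, rx[2] + ex, length.out = n_cells + 1)
  ys <- seq(ry[1] - ey, ry[2] + ey, length.out = n_cells + 1)
  nodes <- unname(as.matrix(expand.grid(xs, ys)))
  warped <- tps_warp_points(coeffs, nodes)
  jac <- suppressWarnings(jacobian_expansion(coeffs, nodes))
  nb <- length(xs)
  idx <- matrix(seq_len(nrow(nodes)), nrow = nb)   # rows: x index, cols: y index
  before <- after <- list()
  for (j in seq_len(ncol(idx))) {                  # horizontal lines
    before[[length(before) + 1L]] <- nodes[idx[, j], , drop = FALSE]
    after[[length(after) + 1L]] <- warped[idx[, j], , drop = FALSE]
  }
  for (i in seq_len(nrow(idx))) {                  # vertical lines
    before[[length(before) + 1L]] <- nodes[idx[i, ], , drop = FALSE]
    after[[length(after) + 1L]] <- warped[idx[i, ], , drop = FALSE]
  }
  structure(list(kind = "grid", before = before, after = after,
                 nodes = nodes, warped_nodes = warped, jacobian = jac),
            class = "shape_diagram")
}

#' Warp an outline polyline through a TPS
#'
#' @param coeffs a `tps_coefficients` object.
#' @param outline two-column matrix of vertices in the reference frame.
#' @return `shape_diagram` of kind `"outline"` with `before` and `after`
#'   polylines.
#' @export
warp_outline <- function(coeffs, outline) {
  outline <- as.matrix(outline)
  structure(list(kind = "outline", before = list(outline),
                 after = list(tps_warp_points(coeffs, outline))),
            class = "shape_diagram")
}

#' Wireframe link segments for a reference and target configuration
#'
#' @param reference,target `k x 2` configurations in a common frame.
#' @param wireframe two-column matrix of 1-based landmark index pairs.
#' @return `shape_diagram` of kind `"wireframe"`: per-link segments for the
#'   reference (`before`) and target (`after`).
#' @export
warp_wireframe <- function(reference, target, wireframe) {
  wireframe <- matrix(as.integer(wireframe), ncol = 2)
  k <- nrow(reference)
  if (any(wireframe < 1L | wireframe > k)) stop("wireframe index out of range")
  seg <- function(cfg) lapply(seq_len(nrow(wireframe)), function(i)
    cfg[wireframe[i, ], , drop = FALSE])
  structure(list(kind = "wireframe", before = seg(as.matrix(reference)),
                 after = seg(as.matrix(target))),
            class = "shape_diagram")
}

#' Displacement (lollipop) vectors between two configurations
#'
#' One arrow per landmark from the reference position to the target
#' position; lengths equal the per-landmark Euclidean displacements.
#'
#' @param reference,target `k x 2` configurations in a common frame.
#' @return `shape_diagram` of kind `"lollipop"` with `from`, `to` and
#'   `length` per landmark.
#' @export
lollipops <- function(reference, target) {
  reference <- as.matrix(reference); target <- as.matrix(target)
  stopifnot(all(dim(reference) == dim(target)))
  structure(list(kind = "lollipop", from = reference, to = target,
                 length = sqrt(rowSums((target - reference)^2))),
            class = "shape_diagram")
}

#' @export
print.shape_diagram <- function(x, ...) {
  cat("Shape diagram of kind", shQuote(x$kind), "\n")
  invisible(x)
}

#' Magnify the shape difference between a reference and a target
#'
#' `reference + m * (target - reference)`: `m = 1` reproduces the target,
#' `m = 0` the reference; larger factors exaggerate small differences for
#' display (the result is then not an observed shape and the factor should
#' always be reported).
#'
#' @param reference,target configurations or flat shape vectors in a common
#'   frame.
#' @param m positive magnification factor.
#' @return the magnified target, in the shape of the inputs.
#' @export
magnify <- function(reference, target, m) {
  stopifnot(m > 0)
  reference + m * (target - reference)
}

#' Partial warp and uniform component scores
#'
#' Eigendecomposition of the bending-energy matrix of the reference
#' configuration (the upper-left `k x k` block of the inverse TPS system
#' matrix).  The `k - 3` eigenvectors with nonzero eigenvalue are the
#' principal warps; projecting each specimen's deviation from the consensus
#' onto them (once per coordinate) gives `2(k - 3)` partial warp scores.
#' The uniform components are the scores on an orthonormal basis of the
#' 2-dimensional complement of the partial-warp subspace within the tangent
#' space (computed numerically).  Together the scores carry exactly the
#' same information as the tangent coordinates: pairwise distances are
#' preserved.
#'
#' @param aligned an `aligned_shapes` object; the reference is its
#'   consensus.
#' @return object of class `partial_warps`: `scores`
#'   (`n x 2(k-3)` partial warp scores), `uniform` (`n x 2`),
#'   `eigenvalues` (bending energies of the principal warps),
#'   `principal_warps` (k x (k-3) eigenvectors), `basis` (the full
#'   orthonormal 2k-space basis used).
#' @export
partial_warps <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  ref <- shape_to_config(aligned$mean_shape)
  k <- nrow(ref)
  if (qr(cbind(1, ref))$rank < 3) stop("collinear consensus configuration")
  L <- tps_L_matrix(ref)
  Linv <- solve(L)
  Be <- Linv[seq_len(k), seq_len(k)]
  Be <- (Be + t(Be)) / 2
  e <- eigen(Be, symmetric = TRUE)
  nz <- seq_len(k - 3)                      # descending order: k-3 nonzero
  E <- e$vectors[, nz, drop = FALSE]
  lambda <- e$values[nz]
  # embed each principal warp twice in the interleaved 2k space (x and y)
  embed <- function(v, coord) {
    out <- numeric(2 * k)
    out[seq(coord, 2 * k, by = 2)] <- v
    out
  }
  pw_basis <- matrix(0, 2 * k, 2 * (k - 3))
  for (j in seq_len(k - 3)) {
    pw_basis[, 2 * j - 1] <- embed(E[, j], 1)
    pw_basis[, 2 * j] <- embed(E[, j], 2)
  }
  # similarity directions at the consensus: translations, scale, rotation
  m <- aligned$mean_shape
  rot <- as.vector(t(cbind(-ref[, 2], ref[, 1])))
  sim <- cbind(embed(rep(1, k), 1), embed(rep(1, k), 2), m, rot)
  sim <- qr.Q(qr(sim))
  # uniform = complement of (similarity + partial warps) in R^2k
  proj <- cbind(sim, pw_basis)
  resid_basis <- diag(2 * k) - proj %*% t(proj)
  sv <- svd(resid_basis)
  uniform_basis <- sv$u[, sv$d > 0.5, drop = FALSE]
  if (ncol(uniform_basis) != 2)
    stop("unexpected dimension of the uniform subspace")
  dev <- sweep(aligned$shapes, 2, aligned$mean_shape)
  structure(list(scores = dev %*% pw_basis,
                 uniform = dev %*% uniform_basis,
                 eigenvalues = lambda,
                 principal_warps = E,
                 basis = cbind(pw_basis, uniform_basis)),
            class = "partial_warps")
}

#' @export
print.partial_warps <- function(x, ...) {
  cat(sprintf("Partial warps: %d principal warps (+2 uniform components) for %d specimens\n",
              length(x$eigenvalues), nrow(x$scores)))
  invisible(x)
}
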