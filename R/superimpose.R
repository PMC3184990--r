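# Generalized Procrustes analysis and related geometry.
#
# Conventions used throughout:
#  * shapes as flat 2k vectors interleave coordinates x1 y1 x2 y2 ...
#  * the "partial" fit retains the unit-centroid-size constraint (no cosine
#    rescaling); "full" additionally rescales each pre-shape by cos(rho)
#  * after convergence the consensus is aligned to its principal axes and the
#    sign fixed so the first nonzero coordinate is positive, making outputs
#    reproducible up to machine tolerance

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid.  Invariant under rotation and translation, and scales
#' linearly under uniform scaling.
#'
#' @param config a `k x 2` coordinate matrix (or a flat `2k` vector).
#' @return a positive scalar (same units as the coordinates).
#' @export
centroid_size <- function(config) {
  if (is.null(dim(config))) config <- shape_to_config(config)
  if (nrow(config) < 3) stop("at least 3 landmarks are required")
  centered <- sweep(config, 2, colMeans(config))
  cs <- sqrt(sum(centered^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincide (centroid size 0)")
  cs
}

# optimal rotation angle aligning X (k x 2) onto Y by least squares,
# rotations only (no reflection): maximize trace(t(Y) %*% X %*% t(R))
optimal_rotation <- function(X, Y) {
  a <- sum(X[, 1] * Y[, 2] - X[, 2] * Y[, 1])
  b <- sum(X[, 1] * Y[, 1] + X[, 2] * Y[, 2])
  theta <- atan2(a, b)
  # X %*% R rotates each landmark by theta counterclockwise
  matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
}

rotate_config <- function(X, R) X %*% R

# align a centered unit-size configuration matrix to its principal axes with
# deterministic signs (first coordinate of the first axis loading positive)
principal_axis_rotation <- function(m) {
  e <- eigen(stats::cov(m), symmetric = TRUE)
  R <- e$vectors
  if (det(R) < 0) R[, 2] <- -R[, 2]
  R
}

#' Generalized Procrustes alignment with tangent projection
#'
#' Iteratively centers each configuration, scales it to unit centroid size,
#' rotates it onto the current consensus by least squares (2D rotations
#' only; reflections are never allowed), and re-estimates the consensus
#' until it stabilizes.  The aligned pre-shapes are then orthogonally
#' projected onto the Euclidean space tangent to the shape sphere at the
#' consensus, where all downstream statistics operate.
#'
#' @param dataset a `landmark_dataset`, or a `k x 2 x n` array.
#' @param fit `"partial"` (default: unit centroid size retained) or
#'   `"full"` (each pre-shape rescaled by the cosine of its Procrustes
#'   distance to the consensus before projection).
#' @param tol convergence tolerance on the summed squared change of the
#'   consensus between iterations (default `1e-10`).
#' @param max_iter maximum number of iterations (default 100); hitting it
#'   flags `converged = FALSE` but still returns the result.
#' @return an object of class `aligned_shapes` with elements
#'   `shapes` (`n x 2k` tangent coordinates), `mean_shape` (`2k` consensus,
#'   unit centroid size), `centroid_sizes`, `n_iterations`, `converged`,
#'   `k`, `labels`, and the classifiers carried over from the dataset.
#' @export
gpa <- function(dataset, fit = c("partial", "full"), tol = 1e-10,
                max_iter = 100) {
  fit <- match.arg(fit)
  if (!inherits(dataset, "landmark_dataset")) dataset <- landmark_dataset(dataset)
  arr <- dataset$coords
  k <- dim(arr)[1]; n <- dim(arr)[3]
  if (n < 2) stop("at least 2 configurations are required")
  sizes <- numeric(n)
  pre <- array(NA_real_, dim(arr))
  for (i in seq_len(n)) {
    m <- arr[, , i]
    sizes[i] <- centroid_size(m)
    pre[, , i] <- sweep(m, 2, colMeans(m)) / sizes[i]
  }
  # initialize consensus at the first pre-shape
  consensus <- pre[, , 1]
  it <- 0L; converged <- FALSE
  rotated <- pre
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_len(n))
      rotated[, , i] <- rotate_config(pre[, , i], optimal_rotation(pre[, , i], consensus))
    new_cons <- apply(rotated, c(1, 2), mean)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sum((new_cons - consensus)^2)
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  # reproducible orientation: consensus on its principal axes
  R <- principal_axis_rotation(consensus)
  consensus <- rotate_config(consensus, R)
  if (consensus[which(abs(consensus) > 1e-12)[1]] < 0) consensus <- -consensus
  for (i in seq_len(n))
    rotated[, , i] <- rotate_config(pre[, , i], optimal_rotation(pre[, , i], consensus))
  mhat <- config_to_shape(consensus)           # unit vector (CS 1)
  X <- flatten_coords(rotated)                 # n x 2k, each row unit norm
  ip <- as.vector(X %*% mhat)                  # cos(rho) per specimen
  if (fit == "full") X <- X * ip
  # orthogonal projection onto the affine tangent plane {y : y . mhat = 1}
  Xt <- X - outer(as.vector(X %*% mhat) - 1, mhat)
  rownames(Xt) <- dataset$labels
  structure(list(shapes = Xt, mean_shape = mhat, centroid_sizes = sizes,
                 n_iterations = it, converged = converged, k = k,
                 labels = dataset$labels, classifiers = dataset$classifiers,
                 fit = fit, cos_rho = ip),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat("Procrustes-aligned shapes:", nrow(x$shapes), "specimens,",
      x$k, "landmarks\n")
  cat(sprintf("  %s fit, %d iterations (%s), mean centroid size %.3f mm\n",
              x$fit, x$n_iterations,
              if (x$converged) "converged" else "NOT converged",
              mean(x$centroid_sizes)))
  invisible(x)
}

#' Procrustes (tangent-space) distance between two shape vectors
#'
#' Euclidean norm of the difference of two tangent-space shape vectors from
#' a common alignment.
#'
#' @param a,b flat shape vectors of equal length.
#' @return a non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  if (length(a) != length(b)) stop("shape vectors have different lengths")
  sqrt(sum((a - b)^2))
}

#' Tangent-space approximation diagnostics
#'
#' For each specimen computes the Riemannian Procrustes distance to the
#' consensus, `rho = acos(<pre-shape, consensus>)`, and the Euclidean
#' distance of its tangent projection to the consensus, then fits a
#' no-intercept least-squares line of Euclidean on Procrustes distance.
#' Slope and uncentered correlation near 1 indicate that the flat tangent
#' space is an excellent approximation of the curved shape space.
#'
#' @param aligned an `aligned_shapes` object from [gpa()].
#' @return an object of class `tangent_check`: `slope`, `correlation`, and a
#'   data frame `distances` with per-specimen `procrustes` and `euclidean`
#'   distances to the consensus.
#' @export
tangent_space_check <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  rho <- acos(pmin(1, pmax(-1, aligned$cos_rho)))
  eu <- sqrt(rowSums(sweep(aligned$shapes, 2, aligned$mean_shape)^2))
  if (all(rho < 1e-7)) stop("no shape variation: all specimens equal the consensus")
  slope <- sum(eu * rho) / sum(rho^2)
  correlation <- sum(eu * rho) / sqrt(sum(eu^2) * sum(rho^2))
  structure(list(slope = slope, correlation = correlation,
                 distances = data.frame(procrustes = rho, euclidean = eu,
                                        row.names = aligned$labels)),
            class = "tangent_check")
}

#' @export
print.tangent_check <- function(x, ...) {
  cat(sprintf("Tangent-space check: slope %.3f, correlation %.3f\n",
              x$slope, x$correlation))
  cat(sprintf("  Procrustes distance to consensus: mean %.3f, max %.3f\n",
              mean(x$distances$procrustes), max(x$distances$procrustes)))
  invisible(x)
}

#' Bookstein baseline superimposition
#'
#' Translates, rotates and rescales every configuration so that landmark
#' `baseline[1]` lands exactly on (0,0) and landmark `baseline[2]` on (1,0).
#' Used to demonstrate that shape distances are nearly superimposition-free
#' while landmark-wise variation is not.
#'
#' @param dataset a `landmark_dataset` or `k x 2 x n` array.
#' @param baseline integer pair of distinct 1-based landmark indices.
#' @return a `k x 2 x n` array of baseline shape coordinates.
#' @export
baseline_superimpose <- function(dataset, baseline) {
  if (!inherits(dataset, "landmark_dataset")) dataset <- landmark_dataset(dataset)
  arr <- dataset$coords
  i <- baseline[1]; j <- baseline[2]
  if (i == j) stop("baseline landmarks must be distinct")
  if (any(c(i, j) < 1) || any(c(i, j) > dataset$k)) stop("baseline index out of range")
  out <- array(NA_real_, dim(arr)); dimnames(out) <- dimnames(arr)
  for (s in seq_len(dataset$n)) {
    z <- complex(real = arr[, 1, s], imaginary = arr[, 2, s])
    denom <- z[j] - z[i]
    if (Mod(denom) == 0)
      stop(sprintf("coincident baseline points in specimen '%s'", dataset$labels[s]))
    w <- (z - z[i]) / denom
    out[, , s] <- cbind(Re(w), Im(w))
  }
  out
}
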