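# Allometry: multivariate regression of shape on size, Pillai-trace MANCOVA
# for slopes and intercepts, and pooled within-group size-correction.

#' Multivariate regression of shape on size
#'
#' Least-squares fit of every shape coordinate on (optionally
#' log-transformed) centroid size.  The percentage of total shape variance
#' explained is `100 * SS_predicted / SS_total` summed over coordinates;
#' significance is assessed by permuting sizes.  Regression scores are the
#' projections of the centered shapes on the direction of the slope vector
#' (for allometric scatterplots).
#'
#' @param shapes `n x 2k` matrix of tangent coordinates.
#' @param sizes numeric vector of centroid sizes (mm).
#' @param n_perm number of permutations (default 10000).
#' @param use_log regress on `log(size)` instead of size (default FALSE).
#' @return object of class `allometry_regression`: `slope` (2k vector per
#'   unit size), `intercept`, `pct_variance`, `p_permutation`, `scores`,
#'   `predicted`, `residuals`.
#' @export
shape_size_regression <- function(shapes, sizes, n_perm = 10000,
                                  use_log = FALSE) {
  X <- as.matrix(shapes)
  if (nrow(X) < 3) stop("at least 3 specimens are required")
  if (use_log) {
    if (any(sizes <= 0)) stop("sizes must be positive for the log transform")
    sizes <- log(sizes)
  }
  if (stats::var(sizes) == 0) stop("sizes are constant")
  fit_pct <- function(s) {
    sc <- s - mean(s)
    Yc <- sweep(X, 2, colMeans(X))
    B <- crossprod(Yc, sc) / sum(sc^2)          # 2k x 1
    pred <- outer(sc, as.vector(B))
    100 * sum(pred^2) / sum(Yc^2)
  }
  sc <- sizes - mean(sizes)
  Yc <- sweep(X, 2, colMeans(X))
  B <- as.vector(crossprod(Yc, sc) / sum(sc^2))
  pred <- outer(sc, B)
  pct <- 100 * sum(pred^2) / sum(Yc^2)
  perm <- replicate(n_perm, fit_pct(sample(sizes)))
  intercept <- colMeans(X) - B * mean(sizes)
  scores <- as.vector(Yc %*% B) / sqrt(sum(B^2))
  structure(list(slope = B, intercept = intercept, pct_variance = pct,
                 p_permutation = (1 + sum(perm >= pct - 1e-12)) / (n_perm + 1),
                 n_permutations = n_perm, scores = scores,
                 predicted = pred, residuals = Yc - pred, use_log = use_log),
            class = "allometry_regression")
}

#' @export
print.allometry_regression <- function(x, ...) {
  cat(sprintf("Shape-on-%ssize regression: %.1f%% of variance explained, P(perm) = %.4g\n",
              if (x$use_log) "log " else "", x$pct_variance, x$p_permutation))
  invisible(x)
}

# residual cross-product trace of a least-squares fit Y ~ X
fit_ss <- function(Y, X) {
  qrX <- qr(X)
  res <- qr.resid(qrX, Y)
  list(E = crossprod(res), rank = qrX$rank)
}

pillai_term <- function(Y, X_full, X_reduced) {
  full <- fit_ss(Y, X_full)
  red <- fit_ss(Y, X_reduced)
  H <- red$E - full$E
  V <- sum(diag(H %*% solve(H + full$E)))
  list(V = V, rank_full = full$rank,
       ss_full = sum(diag(full$E)), ss_red = sum(diag(red$E)))
}

#' Pillai-trace MANCOVA for allometric slopes and intercepts
#'
#' Three nested comparisons on the PC subspace of the shapes:
#' \describe{
#'   \item{slopes}{the group-by-size interaction: separate-slopes model
#'     `[1, group, size, group:size]` against parallel lines
#'     `[1, group, size]`.}
#'   \item{intercepts}{the group term after removing the interaction:
#'     parallel lines against a single line `[1, size]`.}
#'   \item{size_only}{the size term in `[1, size]` against the null model.}
#' }
#' Each hypothesis has one degree of freedom (two groups, one covariate),
#' so Pillai's trace `V` converts exactly to
#' `F = (V / (1 - V)) * (df2 / p)` with `df1 = p` and
#' `df2 = n - rank(full model) - p + 1`.
#'
#' Two "percent explained" summaries are reported per term, because both
#' appear in applied work: `pct_incremental` (the sequential gain in fitted
#' SS over the total shape SS) and `pct_model` (the total fit of the fuller
#' model).
#'
#' @param shapes `n x 2k` matrix of tangent coordinates.
#' @param sizes numeric vector of centroid sizes.
#' @param groups two-level factor.
#' @return data frame of class `mancova_result` with one row per term:
#'   `term`, `pillai`, `F`, `df1`, `df2`, `P`, `pct_incremental`,
#'   `pct_model`.
#' @export
mancova <- function(shapes, sizes, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  sub <- pc_subspace(as.matrix(shapes), max_p = nrow(as.matrix(shapes)) - 5)
  Y <- sub$scores; p <- sub$p
  n <- nrow(Y)
  if (n <= p + 3) stop("too few specimens for the MANCOVA: reduce the PC subspace")
  g <- ifelse(groups == levels(groups)[1], -1, 1)
  s <- sizes
  one <- rep(1, n)
  X_int <- cbind(one, g, s, g * s)
  X_par <- cbind(one, g, s)
  X_size <- cbind(one, s)
  X_null <- cbind(one)
  ss_tot <- sum(sweep(Y, 2, colMeans(Y))^2)
  row_for <- function(term, full, reduced) {
    pt <- pillai_term(Y, full, reduced)
    df2 <- n - pt$rank_full - p + 1
    Fv <- (pt$V / (1 - pt$V)) * (df2 / p)
    data.frame(term = term, pillai = pt$V, F = Fv, df1 = p, df2 = df2,
               P = stats::pf(Fv, p, df2, lower.tail = FALSE),
               pct_incremental = 100 * (pt$ss_red - pt$ss_full) / ss_tot,
               pct_model = 100 * (1 - pt$ss_full / ss_tot),
               stringsAsFactors = FALSE)
  }
  out <- rbind(row_for("slopes", X_int, X_par),
               row_for("intercepts", X_par, X_size),
               row_for("size_only", X_size, X_null))
  class(out) <- c("mancova_result", "data.frame")
  out
}

#' @export
print.mancova_result <- function(x, digits = 4, ...) {
  cat("Pillai-trace MANCOVA (shape on size by group)\n")
  print.data.frame(format(x, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Pooled within-group size-correction of shapes
#'
#' Fits parallel allometric lines by regressing within-group-centered
#' shapes on within-group-centered sizes (the pooled within-group slope
#' `B`), then replaces every shape by its residual from its group's line
#' added back to the prediction at a common size:
#' `corrected_i = shape_i - B * (size_i - common_size)`.
#' The within-group allometric variation is thereby removed; group mean
#' differences of the corrected shapes do not depend on the choice of
#' `common_size` (parallel lines keep constant separation).
#'
#' The parallel-slopes assumption should be checked first with [mancova()];
#' when the slopes test is significant at 0.05 the function refuses to run
#' unless `force = TRUE`.
#'
#' @param shapes `n x 2k` matrix of tangent coordinates.
#' @param sizes numeric centroid sizes.
#' @param groups factor of group labels.
#' @param common_size the size at which shapes are reconstructed; default
#'   the grand mean of `sizes`.
#' @param slopes_p optional P value of the slopes (interaction) test; if
#'   below 0.05 and `force` is FALSE, an error is raised.
#' @param force override the parallel-slopes guard (default FALSE).
#' @return object of class `size_corrected`: `shapes` (corrected, n x 2k),
#'   `pooled_slope`, `common_size`.
#' @export
size_correct <- function(shapes, sizes, groups, common_size = NULL,
                         slopes_p = NULL, force = FALSE) {
  X <- as.matrix(shapes)
  groups <- factor(groups)
  if (any(is.na(groups))) stop("missing group labels")
  if (!is.null(slopes_p) && slopes_p < 0.05 && !force)
    stop("allometric slopes differ significantly between groups (P = ",
         signif(slopes_p, 3), "); size-correction assumes parallel lines. ",
         "Pass force = TRUE to override.")
  if (is.null(common_size)) common_size <- mean(sizes)
  Xw <- X; sw <- sizes
  for (gl in levels(groups)) {
    idx <- groups == gl
    Xw[idx, ] <- sweep(X[idx, , drop = FALSE], 2,
                       colMeans(X[idx, , drop = FALSE]))
    sw[idx] <- sizes[idx] - mean(sizes[idx])
  }
  if (sum(sw^2) == 0) stop("no within-group size variation")
  B <- as.vector(crossprod(Xw, sw) / sum(sw^2))
  corrected <- X - outer(sizes - common_size, B)
  structure(list(shapes = corrected, pooled_slope = B,
                 common_size = common_size, groups = groups),
            class = "size_corrected")
}

#' @export
print.size_corrected <- function(x, ...) {
  cat(sprintf("Size-corrected shapes: %d specimens reconstructed at common size %.3f mm\n",
              nrow(x$shapes), x$common_size))
  invisible(x)
}

#' Re-run the two-group test battery on size-corrected shapes
#'
#' @param corrected a `size_corrected` object (or an `n x 2k` matrix).
#' @param groups two-level factor (taken from the object when omitted).
#' @param n_perm permutations (default 10000).
#' @return a `test_battery` (see [group_test_battery()]); size tests are
#'   skipped since the corrected data carry no size response.
#' @export
rerun_group_tests_on_corrected <- function(corrected, groups = NULL,
                                           n_perm = 10000) {
  if (inherits(corrected, "size_corrected")) {
    if (is.null(groups)) groups <- corrected$groups
    corrected <- corrected$shapes
  }
  group_test_battery(corrected, sizes = NULL, groups = groups, n_perm = n_perm)
}
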