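# Hierarchical (sequential) ANOVA for centroid size and, under the isotropic
# model, for Procrustes shape coordinates, with the corrected F ratio that
# compares populations against trees rather than leaves.

#' Hierarchical sum-of-squares decomposition for a nested design
#'
#' Sequential decomposition via nested group means for the hierarchy
#' populations > trees > leaves > replicas: each effect is adjusted for all
#' effects earlier in the hierarchy.  The population component is the
#' count-weighted deviation of population means from the grand mean, the
#' tree component the deviation of tree means about their population means,
#' the leaf component leaf means about tree means, and the error component
#' the observations about leaf means.  For a multivariate response the
#' components are summed over columns (the isotropic model).  The four
#' components always sum to the total SS about the grand mean, balanced or
#' not.
#'
#' @param values an `n x d` numeric matrix (or length-`n` vector): `d = 1`
#'   for centroid size, `d = 2k` for shape coordinates.
#' @param classifiers data frame with columns `population`, `tree`, `leaf`
#'   (as from [parse_classifiers()]).
#' @return named numeric vector with components `populations`, `trees`,
#'   `leaves`, `error`, `total`.
#' @export
hierarchical_ss <- function(values, classifiers) {
  values <- as.matrix(values)
  need <- c("population", "tree", "leaf")
  if (!all(need %in% names(classifiers))) stop("missing classifier column")
  if (anyNA(classifiers[need])) stop("missing classifier value")
  n <- nrow(values)
  if (nrow(classifiers) != n) stop("classifier table length must equal row count")
  grand <- colMeans(values)
  group_means_expanded <- function(f) {
    f <- factor(f)
    m <- rowsum(values, f) / as.vector(table(f))
    m[as.integer(f), , drop = FALSE]
  }
  mp <- group_means_expanded(classifiers$population)
  mt <- group_means_expanded(classifiers$tree)
  ml <- group_means_expanded(classifiers$leaf)
  ss <- function(a, b) sum((a - b)^2)
  grand_mat <- matrix(grand, n, ncol(values), byrow = TRUE)
  out <- c(populations = ss(mp, grand_mat),
           trees = ss(mt, mp),
           leaves = ss(ml, mt),
           error = ss(values, ml))
  singletons <- table(classifiers$leaf)
  if (any(singletons < 2))
    warning("some leaves have a single replica: they contribute zero error df")
  c(out, total = ss(values, grand_mat))
}

#' Hierarchical Procrustes ANOVA table
#'
#' Builds the four-row ANOVA (populations, trees, leaves, error) for
#' centroid size or, under the isotropic model, for shape.  F ratios follow
#' the hierarchy: populations over trees (the manually corrected ratio that
#' treats trees as the random effect), trees over leaves, leaves over
#' error; P values come from the F distribution at the corresponding
#' degrees of freedom.
#'
#' Two df conventions are offered.  `"morphoj"` (default) replicates the
#' convention of the original software output: populations `P - 1`, trees
#' `T - 1`, leaves `(L - 1) - (P - 1) - (T - 1)`, error `n - L`, all
#' multiplied by `2k - 4` for shape.  The statistically orthodox
#' `"nested"` convention uses trees `T - P` and leaves `L - T` instead.
#'
#' @param dataset an `aligned_shapes` object with classifiers attached (for
#'   both responses; sizes and tangent coordinates are taken from it), or a
#'   list with elements `values` (n x d matrix) and `classifiers`.
#' @param response `"size"` or `"shape"`.
#' @param df_convention `"morphoj"` (default) or `"nested"`.
#' @return an object of class `anova_table`: data frame `table` with
#'   columns `effect`, `pct_SS`, `SS`, `MS`, `df`, `F`, `P`; plus
#'   `total_SS`, `response`, `df_convention`, `shape_dims`.
#' @export
procrustes_anova <- function(dataset, response = c("size", "shape"),
                             df_convention = c("morphoj", "nested")) {
  response <- match.arg(response)
  df_convention <- match.arg(df_convention)
  if (inherits(dataset, "aligned_shapes")) {
    cls <- dataset$classifiers
    if (is.null(cls)) stop("dataset has no classifiers")
    values <- if (response == "size") matrix(dataset$centroid_sizes, ncol = 1)
              else dataset$shapes
    k <- dataset$k
  } else {
    cls <- dataset$classifiers
    values <- as.matrix(dataset$values)
    k <- ncol(values) / 2
  }
  P <- nlevels(factor(cls$population))
  Tn <- nlevels(factor(cls$tree))
  L <- nlevels(factor(cls$leaf))
  n <- nrow(values)
  balanced <- length(unique(table(cls$leaf))) == 1L &&
    length(unique(table(cls$tree))) == 1L &&
    length(unique(table(cls$population))) == 1L
  if (!balanced)
    warning("unbalanced design: sequential SS are well defined but pct_SS interpretation weakens")
  comp <- hierarchical_ss(values, cls)
  shape_dims <- if (response == "shape") 2L * k - 4L else 1L
  df1 <- switch(df_convention,
                morphoj = c(P - 1, Tn - 1, (L - 1) - (P - 1) - (Tn - 1), n - L),
                nested = c(P - 1, Tn - P, L - Tn, n - L))
  dfv <- df1 * shape_dims
  SS <- unname(comp[c("populations", "trees", "leaves", "error")])
  MS <- ifelse(dfv > 0, SS / dfv, NA_real_)
  ratio <- function(num, den) if (is.na(MS[num]) || is.na(MS[den]) ||
                                  MS[den] == 0) NA_real_ else MS[num] / MS[den]
  Fv <- c(if (P >= 2) ratio(1, 2) else NA_real_, ratio(2, 3), ratio(3, 4),
          NA_real_)
  safe_p <- function(F, d1, d2) {
    if (is.na(F) || d1 < 1 || d2 < 1) NA_real_ else f_pvalue(F, d1, d2)
  }
  Pv <- c(safe_p(Fv[1], dfv[1], dfv[2]), safe_p(Fv[2], dfv[2], dfv[3]),
          safe_p(Fv[3], dfv[3], dfv[4]), NA_real_)
  tab <- data.frame(effect = c("populations", "trees", "leaves", "error"),
                    pct_SS = 100 * SS / comp[["total"]],
                    SS = SS, MS = MS, df = dfv, F = Fv, P = Pv,
                    stringsAsFactors = FALSE)
  if (P < 2) tab <- tab[-1, ]
  structure(list(table = tab, total_SS = comp[["total"]], response = response,
                 df_convention = df_convention, shape_dims = shape_dims),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, digits = 4, ...) {
  cat(sprintf("Hierarchical %s ANOVA (%s df convention)\n",
              x$response, x$df_convention))
  tab <- x$table
  tab$pct_SS <- sprintf("%.1f%%", tab$pct_SS)
  print(format(tab, digits = digits), row.names = FALSE)
  cat(sprintf("total SS = %.*g\n", digits, x$total_SS))
  invisible(x)
}

#' Percent of total sum of squares per effect
#'
#' @param table an `anova_table` from [procrustes_anova()], or a numeric
#'   vector of SS components (percentages are then taken over their sum).
#' @return numeric vector of percentages in `[0, 100]` summing to 100.
#' @export
percent_ss <- function(table) {
  if (inherits(table, "anova_table")) {
    if (table$total_SS <= 0) stop("total SS must be positive")
    return(stats::setNames(100 * table$table$SS / table$total_SS,
                           table$table$effect))
  }
  ss <- as.numeric(table)
  if (sum(ss) <= 0) stop("total SS must be positive")
  100 * ss / sum(ss)
}

#' Upper-tail P value of the F distribution
#'
#' @param F observed F statistic (non-negative).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return upper-tail probability in `[0, 1]`.
#' @export
f_pvalue <- function(F, df1, df2) {
  stopifnot(F >= 0, df1 >= 1, df2 >= 1)
  stats::pf(F, df1, df2, lower.tail = FALSE)
}
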