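# End-to-end orchestration of the protocol: read/classify -> GPA + tangent
# check -> outlier screen -> PCA + phenogram -> hierarchical ANOVA (size,
# shape) -> tree averaging -> two-group test battery -> allometry + MANCOVA
# -> size-correction -> battery on corrected shapes -> diagram geometry.

#' Run the complete morphometric protocol
#'
#' Executes every stage of the analysis in order on a landmark dataset and
#' returns a structured report bundle.  Cross-module consistency checks
#' (total-SS conservation between the superimposition and the ANOVA, the
#' Hotelling/Mahalanobis identity `T2 = n1 n2 / (n1 + n2) * d^2`, and the
#' Pillai-F identity) are executed on every run and any failure is fatal.
#'
#' @param dataset a `landmark_dataset` with classifiers (or a path handled
#'   by `input`); see [generate_dataset()] for synthetic input.
#' @param input optional path to a TPS or NTS file (extension decides the
#'   reader) used when `dataset` is NULL.
#' @param classifier_ranges ranges for [parse_classifiers()] when the
#'   dataset labels still need parsing.
#' @param fit GPA flavor, `"partial"` or `"full"`.
#' @param df_convention ANOVA df convention, `"morphoj"` or `"nested"`.
#' @param n_perm permutations for every permutation test (default 10000).
#' @param seed integer seed controlling all randomization (recorded in the
#'   bundle).
#' @param use_log regress shape on log size (default FALSE).
#' @param common_size common size for the size-correction (default grand
#'   mean).
#' @param force_parallel run the size-correction even when the slopes test
#'   is significant at 0.05 (default FALSE: the stage is skipped with a
#'   warning instead).
#' @param magnification magnification factor for the diagram geometry
#'   (default 10).
#' @param out_dir optional directory: numeric tables are written there as
#'   tab-delimited text, aligned shapes as NTS and the phenogram as Newick.
#' @return a list of class `report_bundle` with elements `tangent_check`,
#'   `outliers`, `pca`, `phenogram`, `anova_size`, `anova_shape`,
#'   `tree_averaged`, `battery`, `allometry`, `mancova`, `size_corrected`,
#'   `battery_corrected`, `diagrams`, `aligned`, and `meta` (seed, options,
#'   package version).
#' @export
run_protocol <- function(dataset = NULL, input = NULL,
                         classifier_ranges = NULL,
                         fit = c("partial", "full"),
                         df_convention = c("morphoj", "nested"),
                         n_perm = 10000, seed = 42L, use_log = FALSE,
                         common_size = NULL, force_parallel = FALSE,
                         magnification = 10, out_dir = NULL) {
  fit <- match.arg(fit)
  df_convention <- match.arg(df_convention)
  if (is.null(dataset)) {
    if (is.null(input)) stop("stage 'read': provide a dataset or an input path")
    dataset <- if (grepl("\\.tps$", input, ignore.case = TRUE)) read_tps(input)
               else read_nts(input)
  }
  if (is.null(dataset$classifiers)) {
    args <- list(labels = dataset$labels)
    if (!is.null(classifier_ranges)) args$ranges <- classifier_ranges
    dataset$classifiers <- tryCatch(do.call(parse_classifiers, args),
      error = function(e) stop("stage 'classify': ", conditionMessage(e)))
  }
  set.seed(seed)
  aligned <- gpa(dataset, fit = fit)
  tc <- tangent_space_check(aligned)
  groups_all <- dataset$classifiers$population
  outliers <- outlier_screen(aligned, groups = groups_all)
  pca <- shape_pca(aligned)
  phen <- upgma_phenogram(stats::dist(aligned$shapes))
  anova_size <- procrustes_anova(aligned, "size", df_convention)
  anova_shape <- procrustes_anova(aligned, "shape", df_convention)
  # consistency: tangent deviation SS equals the ANOVA total shape SS
  ss_tangent <- sum(sweep(aligned$shapes, 2, colMeans(aligned$shapes))^2)
  if (abs(ss_tangent - anova_shape$total_SS) > 1e-8 * max(1, ss_tangent))
    stop("consistency failure: tangent-space SS does not match the ANOVA total SS")
  replicated <- all(table(dataset$classifiers$leaf) >= 2)
  if (!replicated)
    warning("no replicas: the measurement-error stratum is untestable")
  avg <- average_by_tree(aligned)
  two_groups <- nlevels(avg$population) == 2
  battery <- allom <- manc <- corrected <- battery_corr <- NULL
  if (two_groups) {
    battery <- group_test_battery(avg$shapes, avg$sizes, avg$population, n_perm)
    t2 <- battery$hotelling
    n1 <- sum(avg$population == levels(avg$population)[1])
    n2 <- sum(avg$population == levels(avg$population)[2])
    if (abs(t2$statistic - n1 * n2 / (n1 + n2) * t2$mahalanobis_d^2) >
        1e-6 * max(1, t2$statistic))
      stop("consistency failure: T2 does not equal n1*n2/(n1+n2) * d^2")
    allom <- shape_size_regression(avg$shapes, avg$sizes, n_perm, use_log)
    manc <- mancova(avg$shapes, avg$sizes, avg$population)
    f_check <- (manc$pillai / (1 - manc$pillai)) * (manc$df2 / manc$df1)
    if (any(abs(f_check - manc$F) > 1e-8 * pmax(1, manc$F)))
      stop("consistency failure: Pillai-F identity violated")
    slopes_p <- manc$P[manc$term == "slopes"]
    corrected <- tryCatch(
      size_correct(avg$shapes, avg$sizes, avg$population,
                   common_size = common_size, slopes_p = slopes_p,
                   force = force_parallel),
      error = function(e) { warning("size-correction skipped: ",
                                    conditionMessage(e)); NULL })
    if (!is.null(corrected))
      battery_corr <- rerun_group_tests_on_corrected(corrected, n_perm = n_perm)
  }
  diagrams <- NULL
  if (two_groups) {
    cons <- shape_to_config(aligned$mean_shape)
    gm <- avg$shapes
    means <- lapply(levels(avg$population), function(gl)
      shape_to_config(colMeans(gm[avg$population == gl, , drop = FALSE])))
    names(means) <- levels(avg$population)
    diagrams <- lapply(means, function(mshape) {
      tgt <- magnify(cons, mshape, magnification)
      cf <- tps_fit(cons, tgt)
      list(grid = make_grid(cf),
           lollipop = lollipops(cons, tgt),
           wireframe = if (!is.null(dataset$wireframe))
             warp_wireframe(cons, tgt, dataset$wireframe) else NULL,
           outline = if (!is.null(dataset$outline))
             warp_outline(cf, dataset$outline) else NULL,
           magnification = magnification)
    })
  }
  bundle <- structure(list(
    tangent_check = tc, outliers = outliers, pca = pca, phenogram = phen,
    anova_size = anova_size, anova_shape = anova_shape,
    tree_averaged = avg, battery = battery, allometry = allom,
    mancova = manc, size_corrected = corrected,
    battery_corrected = battery_corr, diagrams = diagrams,
    aligned = aligned,
    meta = list(seed = seed, fit = fit, df_convention = df_convention,
                n_perm = n_perm, use_log = use_log,
                magnification = magnification,
                version = as.character(utils::packageVersion("leafgmm")))),
    class = "report_bundle")
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("== Morphometric protocol report (seed", x$meta$seed, ") ==\n")
  print(x$tangent_check)
  print(x$anova_size); print(x$anova_shape)
  if (!is.null(x$battery)) { cat("-- tree-averaged tests --\n"); print(x$battery) }
  if (!is.null(x$allometry)) print(x$allometry)
  if (!is.null(x$mancova)) print(x$mancova)
  if (!is.null(x$battery_corrected)) {
    cat("-- tests on size-corrected shapes --\n"); print(x$battery_corrected)
  }
  invisible(x)
}

write_report <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# leafgmm %s | seed %d | df %s | %d permutations",
                   bundle$meta$version, bundle$meta$seed,
                   bundle$meta$df_convention, bundle$meta$n_perm)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  }
  wt(bundle$anova_size$table, "anova_size.tsv")
  wt(bundle$anova_shape$table, "anova_shape.tsv")
  wt(data.frame(pc = seq_along(bundle$pca$pct_variance),
                eigenvalue = bundle$pca$eigenvalues,
                pct_variance = bundle$pca$pct_variance), "pca_eigenvalues.tsv")
  if (!is.null(bundle$mancova)) wt(as.data.frame(bundle$mancova), "mancova.tsv")
  writeLines(bundle$phenogram$newick, file.path(out_dir, "phenogram.nwk"))
  al <- bundle$aligned
  write_nts(landmark_dataset(al$shapes, labels = al$labels),
            file.path(out_dir, "aligned_shapes.nts"))
  invisible(out_dir)
}

#' Reproduce the oak case-study battery from a raw NTS file
#'
#' Deterministic pipeline for the published two-population sessile-oak
#' dataset (176 configurations of 11 landmarks: 2 populations x 22 trees x
#' 2 leaves x 2 replicas), distributed as supplementary data of the original
#' study and not bundled here.  Returns the quantities that the published
#' tables report,
#' computed by this package: tangent-check slope and correlation, mean and
#' maximum Procrustes distances to the consensus, tree-averaged PC variance
#' percentages, the size t statistic, Hotelling T2, Mahalanobis and
#' Procrustes distances, jackknife classification tables, and the MANCOVA
#' Pillai traces, for full and size-corrected shapes.
#'
#' @param nts_path path to the raw NTS data file.
#' @param fit GPA flavor to use (default partial).
#' @param n_perm permutations (default 10000).
#' @param seed seed for the permutation tests.
#' @return a list with the named summary quantities and the full
#'   `report_bundle`.
#' @export
reproduce_oak_analysis <- function(nts_path, fit = "partial",
                                   n_perm = 10000, seed = 42L) {
  bundle <- run_protocol(input = nts_path, fit = fit, n_perm = n_perm,
                         seed = seed)
  avg_pca <- shape_pca(bundle$tree_averaged$shapes)
  list(
    tangent_slope = bundle$tangent_check$slope,
    tangent_correlation = bundle$tangent_check$correlation,
    mean_procrustes_distance = mean(bundle$tangent_check$distances$procrustes),
    max_procrustes_distance = max(bundle$tangent_check$distances$procrustes),
    pc12_pct = sum(avg_pca$pct_variance[1:2]),
    pc14_pct = sum(avg_pca$pct_variance[1:4]),
    size_t = bundle$battery$size_t$statistic,
    hotelling_t2 = bundle$battery$hotelling$statistic,
    mahalanobis_d = bundle$battery$mahalanobis$statistic,
    procrustes_d = bundle$battery$procrustes$statistic,
    jackknife = bundle$battery$da$confusion_jackknife,
    mancova = bundle$mancova,
    hotelling_t2_corrected = bundle$battery_corrected$hotelling$statistic,
    mahalanobis_d_corrected = bundle$battery_corrected$mahalanobis$statistic,
    procrustes_d_corrected = bundle$battery_corrected$procrustes$statistic,
    jackknife_corrected = bundle$battery_corrected$da$confusion_jackknife,
    bundle = bundle)
}
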