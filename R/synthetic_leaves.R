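# Synthetic leaf-landmark generator emulating a balanced two-population x
# 22-trees x 2-leaves x 2-replicas sampling design with hierarchical shape
# variance components (tree > leaf >> digitizing error, population smallest),
# population size offsets and a weak common allometric trend.
#
# Effects are added in the tangent space at the template (small-perturbation
# regime) after projecting out the similarity directions, so the generating
# per-coordinate variances map directly onto the ANOVA variance strata.

#' Template half-leaf landmark configuration
#'
#' A fixed, documented 11-point configuration sketching the right half of a
#' lobed oak-like leaf (petiole base, blade base, alternating lobe tips and
#' sinuses up the margin, apex), centered at the origin and scaled to unit
#' centroid size.  This is a synthetic stand-in fixture: it is not digitized
#' from any specimen, and no analysis result depends on its exact values.
#'
#' @return an `11 x 2` matrix, centroid at the origin, centroid size 1.
#' @export
template_leaf <- function() {
  pts <- matrix(c(
    0.00, -1.20,   # petiole base
    0.00, -0.75,   # petiole / blade junction
    0.28, -0.55,   # basal lobe margin
    0.26, -0.30,   # first sinus
    0.42, -0.12,   # second lobe tip
    0.34,  0.10,   # second sinus
    0.45,  0.32,   # widest lobe tip
    0.30,  0.52,   # third sinus
    0.25,  0.70,   # distal lobe tip
    0.12,  0.88,   # subapical margin
    0.00,  1.05    # apex
  ), ncol = 2, byrow = TRUE)
  pts <- sweep(pts, 2, colMeans(pts))
  pts / sqrt(sum(pts^2))
}

# orthonormal basis of the similarity directions (translations, scale,
# rotation) at a centered reference, in the interleaved 2k space
similarity_basis <- function(ref) {
  k <- nrow(ref)
  tx <- rep(c(1, 0), k); ty <- rep(c(0, 1), k)
  sc <- config_to_shape(ref)
  rot <- config_to_shape(cbind(-ref[, 2], ref[, 1]))
  qr.Q(qr(cbind(tx, ty, sc, rot)))
}

project_tangent <- function(v, sim) v - sim %*% crossprod(sim, v)

# two fixed, deterministic unit directions in the tangent space at the
# template: used for the population shape offset and the allometric trend
fixed_tangent_directions <- function(ref) {
  k <- nrow(ref)
  sim <- similarity_basis(ref)
  idx <- seq_len(2 * k)
  v1 <- as.vector(project_tangent(sin(2 * pi * idx / (2 * k)), sim))
  v2 <- as.vector(project_tangent(cos(4 * pi * idx / (2 * k)), sim))
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- v2 - v1 * sum(v1 * v2)
  v2 <- v2 / sqrt(sum(v2^2))
  cbind(offset = v1, allometry = v2)
}

#' Specification of a synthetic leaf-landmark dataset
#'
#' Defaults emulate the balanced study design: 2 populations x 22 trees x
#' 2 leaves x 2 replicas, per-coordinate tangent-space shape SDs ordered
#' tree > leaf >> digitizing error with a small fixed population offset, a
#' weak shared allometric trend, and lognormal centroid sizes (mm) with a
#' small population mean offset and tree- and leaf-level components.
#'
#' @param n_populations,trees_per_population,leaves_per_tree,replicas_per_leaf
#'   design counts (defaults 2, 22, 2, 2).
#' @param sigma_pop SD of an optional random population shape effect
#'   (default 0: population differences come from `population_offset`).
#' @param sigma_tree,sigma_leaf,sigma_error per-coordinate tangent-space
#'   SDs of the tree, leaf and replica (digitizing) shape effects.
#' @param population_offset magnitude of the fixed population mean-shape
#'   offset (tangent-space norm; populations sit at +/- offset/2).
#' @param size_means population mean centroid sizes in mm (recycled to
#'   `n_populations`).
#' @param sigma_size_tree,sigma_size_leaf SDs (mm) of the tree and leaf
#'   size components (applied on the log scale relative to the population
#'   mean, keeping sizes positive and mildly right-skewed).
#' @param allometry magnitude of the common allometric trend: tangent-space
#'   shape displacement per mm of centroid size.
#' @param seed integer seed: identical spec + seed give a bit-identical
#'   dataset.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_populations = 2, trees_per_population = 22,
                           leaves_per_tree = 2, replicas_per_leaf = 2,
                           sigma_pop = 0, sigma_tree = 0.0217,
                           sigma_leaf = 0.0160, sigma_error = 0.00086,
                           population_offset = 0.0388,
                           size_means = c(70.6, 69.4),
                           sigma_size_tree = 1.67, sigma_size_leaf = 1.41,
                           allometry = 0.0143, seed = 1L) {
  sig <- c(sigma_pop, sigma_tree, sigma_leaf, sigma_error,
           sigma_size_tree, sigma_size_leaf)
  if (any(sig < 0)) stop("all sigma parameters must be non-negative")
  if (any(size_means <= 0)) stop("size means must be positive")
  structure(list(n_populations = n_populations,
                 trees_per_population = trees_per_population,
                 leaves_per_tree = leaves_per_tree,
                 replicas_per_leaf = replicas_per_leaf,
                 sigma_pop = sigma_pop, sigma_tree = sigma_tree,
                 sigma_leaf = sigma_leaf, sigma_error = sigma_error,
                 population_offset = population_offset,
                 size_means = rep_len(size_means, n_populations),
                 sigma_size_tree = sigma_size_tree,
                 sigma_size_leaf = sigma_size_leaf,
                 allometry = allometry, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic leaf-landmark dataset
#'
#' For every population, tree, leaf and replica, the shape is the template
#' plus (all in the tangent space at the template) the fixed population
#' offset, a tree effect, a leaf effect, replica digitizing noise, and the
#' allometric displacement proportional to the deviation of the specimen's
#' size from the grand mean size.  Replicas of a leaf share its shape and
#' size exactly except for the digitizing noise.  Configurations are scaled
#' to their size in mm and given a random rotation and translation
#' (the digitizing frame), and labels follow the
#' `Popul_Txx_Ly_Rz` filename convention so classifiers round-trip through
#' [parse_classifiers()].
#'
#' @param spec a `synthetic_spec`.
#' @return a `landmark_dataset` with classifiers attached and an attribute
#'   `"truth"` holding the generating spec and per-level effect norms.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  ref <- template_leaf()
  k <- nrow(ref)
  m <- config_to_shape(ref)
  sim <- similarity_basis(ref)
  dirs <- fixed_tangent_directions(ref)
  tnoise <- function(sd) {
    if (sd == 0) return(numeric(2 * k))
    as.vector(project_tangent(stats::rnorm(2 * k, 0, sd), sim))
  }
  pop_names <- sprintf("Pop%02d", seq_len(spec$n_populations))
  pop_names[seq_len(min(2, spec$n_populations))] <-
    c("Campo", "Busso")[seq_len(min(2, spec$n_populations))]
  grand_size <- mean(spec$size_means)
  n <- spec$n_populations * spec$trees_per_population *
    spec$leaves_per_tree * spec$replicas_per_leaf
  coords <- array(NA_real_, c(k, 2, n))
  labels <- character(n)
  sizes_true <- numeric(n)
  i <- 0L
  for (p in seq_len(spec$n_populations)) {
    pop_shift <- if (spec$n_populations == 2)
      (if (p == 1) 0.5 else -0.5) * spec$population_offset * dirs[, "offset"]
    else tnoise(spec$sigma_pop)
    pop_rand <- if (spec$sigma_pop > 0 && spec$n_populations == 2)
      tnoise(spec$sigma_pop) else 0
    for (tr in seq_len(spec$trees_per_population)) {
      tree_shape <- tnoise(spec$sigma_tree)
      tree_logsize <- stats::rnorm(1, 0, spec$sigma_size_tree / spec$size_means[p])
      for (lf in seq_len(spec$leaves_per_tree)) {
        leaf_shape <- tnoise(spec$sigma_leaf)
        leaf_logsize <- stats::rnorm(1, 0, spec$sigma_size_leaf / spec$size_means[p])
        size <- spec$size_means[p] * exp(tree_logsize + leaf_logsize)
        base_shape <- m + pop_shift + pop_rand + tree_shape + leaf_shape +
          spec$allometry * (size - grand_size) * dirs[, "allometry"]
        for (r in seq_len(spec$replicas_per_leaf)) {
          i <- i + 1L
          shp <- base_shape + tnoise(spec$sigma_error)
          cfg <- shape_to_config(shp) * size
          theta <- stats::runif(1, 0, 2 * pi)
          R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
          shift <- stats::runif(2, -10, 10)
          coords[, , i] <- sweep(cfg %*% R, 2, shift, "+")
          labels[i] <- sprintf("%s_T%02d_L%d_R%d", pop_names[p], tr, lf, r)
          sizes_true[i] <- size
        }
      }
    }
  }
  cls <- parse_classifiers(labels)
  ds <- landmark_dataset(coords, labels = labels, classifiers = cls)
  attr(ds, "truth") <- list(spec = spec, sizes = sizes_true,
                            directions = dirs, template = ref)
  ds
}

#' Generate a dataset with a named effect forced to zero
#'
#' Null generators for type-I error calibration of the test battery.
#'
#' @param spec a `synthetic_spec`.
#' @param null one of `"no_group_difference"` (population shape offset and
#'   size mean differences removed, so groups are exchangeable),
#'   `"no_allometry"` (allometric trend removed), `"equal_slopes"`
#'   (populations keep their offsets but share one allometric slope, which
#'   is also the generator's default regime).
#' @return a `landmark_dataset`.
#' @export
null_dataset <- function(spec = synthetic_spec(),
                         null = c("no_group_difference", "no_allometry",
                                  "equal_slopes")) {
  null <- match.arg(null)
  if (null == "no_group_difference") {
    spec$population_offset <- 0
    spec$size_means <- rep(mean(spec$size_means), spec$n_populations)
  } else if (null == "no_allometry") {
    spec$allometry <- 0
  }
  # equal_slopes: the generator always uses a single shared allometric
  # vector, so the default spec already satisfies this null
  generate_dataset(spec)
}
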