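#' leafgmm: landmark-based geometric morphometrics of leaf form
#'
#' Implements a complete landmark-based protocol for hierarchical taxonomic
#' comparison of leaf form: TPS/NTS file handling, generalized Procrustes
#' superimposition with tangent-space projection, PCA and UPGMA phenograms,
#' hierarchical Procrustes ANOVA with measurement-error partitioning,
#' tree-averaged two-group tests and cross-validated discriminant analysis,
#' MANCOVA allometry with pooled within-group size-correction, and
#' thin-plate-spline visualization geometry.
#'
#' @keywords internal
#' @aliases leafgmm-package
"_PACKAGE"

# ---- internal helpers ------------------------------------------------------

# coords are stored as a k x 2 x n array; the flat (row-per-specimen)
# representation interleaves coordinates as x1 y1 x2 y2 ... (NTS column order)
flatten_coords <- function(arr) {
  k <- dim(arr)[1]; n <- dim(arr)[3]
  out <- matrix(NA_real_, n, 2 * k)
  for (i in seq_len(n)) out[i, ] <- as.vector(t(arr[, , i]))
  rownames(out) <- dimnames(arr)[[3]]
  out
}

unflatten_coords <- function(mat) {
  n <- nrow(mat); k <- ncol(mat) / 2
  arr <- array(NA_real_, c(k, 2, n))
  for (i in seq_len(n)) arr[, , i] <- matrix(mat[i, ], k, 2, byrow = TRUE)
  dimnames(arr)[[3]] <- rownames(mat)
  arr
}

shape_to_config <- function(v) matrix(v, length(v) / 2, 2, byrow = TRUE)
config_to_shape <- function(m) as.vector(t(m))

#' Construct a landmark dataset
#'
#' Bundles landmark configurations with specimen labels and optional
#' classifiers, wireframe links and outline polyline into a single object
#' used by all downstream analyses.
#'
#' @param coords a `k x 2 x n` numeric array of landmark coordinates (mm),
#'   or an `n x 2k` matrix with columns interleaved `x1 y1 x2 y2 ...`.
#' @param labels character vector of specimen labels (length `n`).
#' @param classifiers optional data frame with columns `population`, `tree`,
#'   `leaf`, `replica` (see [parse_classifiers()]).
#' @param wireframe optional two-column integer matrix of 1-based landmark
#'   index pairs to draw as links.
#' @param outline optional two-column numeric matrix: an ordered polyline in
#'   the coordinate frame of some reference configuration.
#' @param scale_factors optional numeric vector of per-specimen scale factors
#'   (mm per pixel) already applied to `coords`; kept as metadata.
#' @return an object of class `landmark_dataset`.
#' @export
landmark_dataset <- function(coords, labels = NULL, classifiers = NULL,
                             wireframe = NULL, outline = NULL,
                             scale_factors = NULL) {
  if (is.matrix(coords) && length(dim(coords)) == 2L) coords <- unflatten_coords(coords)
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 2L)
  k <- dim(coords)[1]; n <- dim(coords)[3]
  if (k < 3) stop("at least 3 landmarks are required")
  if (!all(is.finite(coords))) stop("non-finite landmark coordinates")
  if (is.null(labels)) labels <- dimnames(coords)[[3]]
  if (is.null(labels)) labels <- sprintf("specimen_%03d", seq_len(n))
  if (length(labels) != n) stop("label count does not match configuration count")
  dimnames(coords)[[3]] <- labels
  if (!is.null(classifiers) && nrow(classifiers) != n)
    stop("classifier table length must equal configuration count")
  if (!is.null(wireframe)) {
    wireframe <- matrix(as.integer(wireframe), ncol = 2)
    if (any(wireframe < 1L | wireframe > k))
      stop("wireframe indices must lie in [1, k]")
  }
  structure(list(coords = coords, labels = labels, classifiers = classifiers,
                 wireframe = wireframe, outline = outline,
                 scale_factors = scale_factors, k = k, n = n),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("Landmark dataset:", x$n, "configurations of", x$k, "landmarks (2D)\n")
  if (!is.null(x$classifiers))
    cat("  classifiers:", paste(names(x$classifiers), collapse = ", "), "\n")
  if (!is.null(x$wireframe)) cat("  wireframe:", nrow(x$wireframe), "links\n")
  if (!is.null(x$outline)) cat("  outline:", nrow(x$outline), "vertices\n")
  invisible(x)
}

# ---- TPS -------------------------------------------------------------------

#' Read a TPS landmark file
#'
#' Parses the ASCII TPS dialect: per record an `LM=k` header, `k` lines of
#' two whitespace-separated numbers, and optional `IMAGE=`, `ID=`, `SCALE=`
#' lines.  `CURVES=`/`POINTS=` blocks are parsed and skipped (outlines are
#' imported through [read_outline()]).  If a record carries a `SCALE=`
#' factor its coordinates are multiplied by it (pixels to mm); records
#' without one inherit the first record's scale, matching the common
#' digitizing practice of setting the scale on the first image only.
#'
#' @param path path to a TPS file.
#' @param default_scale scale factor used when no record carries `SCALE=`;
#'   default 1 (coordinates already in mm).
#' @return a `landmark_dataset`.
#' @export
read_tps <- function(path, default_scale = 1) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  recs <- list(); i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE))
      stop(sprintf("TPS parse error at line %d: expected 'LM=' header, got '%s'",
                   i, lines[i]))
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", lines[i], ignore.case = TRUE)))
    if (is.na(k) || k < 1) stop(sprintf("TPS parse error at line %d: bad LM value", i))
    i <- i + 1L
    pts <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      if (i > length(lines)) stop("TPS parse error: unexpected end of file in point block")
      vals <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
      if (length(vals) != 2 || anyNA(vals))
        stop(sprintf("TPS parse error at line %d (record %d, point %d): non-numeric coordinate",
                     i, length(recs) + 1L, j))
      pts[j, ] <- vals
      i <- i + 1L
    }
    rec <- list(points = pts, id = NULL, image = NULL, scale = NA_real_)
    # trailing keyword lines for this record
    while (i <= length(lines) && !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      ln <- lines[i]
      if (grepl("^IMAGE\\s*=", ln, ignore.case = TRUE)) {
        rec$image <- sub("^IMAGE\\s*=\\s*", "", ln, ignore.case = TRUE)
      } else if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
        rec$id <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE)) {
        rec$scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", ln, ignore.case = TRUE))
        if (!is.finite(rec$scale) || rec$scale <= 0)
          stop(sprintf("TPS parse error at line %d: SCALE must be a positive number", i))
      } else if (grepl("^CURVES\\s*=", ln, ignore.case = TRUE)) {
        ncurves <- as.integer(sub("^CURVES\\s*=\\s*", "", ln, ignore.case = TRUE))
        i <- i + 1L
        for (cv in seq_len(ncurves)) {
          if (!grepl("^POINTS\\s*=", lines[i], ignore.case = TRUE))
            stop(sprintf("TPS parse error at line %d: expected POINTS= in CURVES block", i))
          np <- as.integer(sub("^POINTS\\s*=\\s*", "", lines[i], ignore.case = TRUE))
          i <- i + np + 1L  # skip curve points (curves are not landmarks)
        }
        next
      }
      # unknown keyword lines are tolerated and skipped
      i <- i + 1L
    }
    recs[[length(recs) + 1L]] <- rec
  }
  if (!length(recs)) stop("TPS file contains no records")
  ks <- vapply(recs, function(r) nrow(r$points), 1L)
  if (length(unique(ks)) != 1L)
    stop("TPS records have heterogeneous landmark counts")
  first_scale <- recs[[1]]$scale
  scales <- vapply(recs, function(r) {
    if (is.finite(r$scale)) r$scale
    else if (is.finite(first_scale)) first_scale
    else default_scale
  }, 1)
  labels <- vapply(seq_along(recs), function(j) {
    r <- recs[[j]]
    if (!is.null(r$id) && nzchar(r$id)) r$id
    else if (!is.null(r$image) && nzchar(r$image)) sub("\\.[A-Za-z0-9]+$", "", r$image)
    else sprintf("specimen_%03d", j)
  }, "")
  arr <- array(NA_real_, c(ks[1], 2, length(recs)))
  for (j in seq_along(recs)) arr[, , j] <- recs[[j]]$points * scales[j]
  landmark_dataset(arr, labels = labels, scale_factors = scales)
}

#' Write a TPS landmark file
#'
#' Inverse of [read_tps()].  Coordinates are written in mm (`SCALE=` is not
#' emitted, so a round trip reproduces the stored coordinates exactly at the
#' stated print precision).
#'
#' @param dataset a `landmark_dataset` (or a `k x 2 x n` array).
#' @param path output path.
#' @param digits significant digits to print (default 12).
#' @return `path`, invisibly.
#' @export
write_tps <- function(dataset, path, digits = 12) {
  if (!inherits(dataset, "landmark_dataset")) dataset <- landmark_dataset(dataset)
  if (dataset$n < 1) stop("cannot write an empty dataset")
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(dataset$n)) {
    cat(sprintf("LM=%d\n", dataset$k), file = con)
    m <- dataset$coords[, , i]
    for (j in seq_len(dataset$k))
      cat(format(m[j, 1], digits = digits), format(m[j, 2], digits = digits),
          "\n", file = con)
    cat(sprintf("ID=%s\n", dataset$labels[i]), file = con)
  }
  invisible(path)
}

# ---- NTS -------------------------------------------------------------------

#' Read an NTS landmark file
#'
#' Parses the rectangular NTS dialect: a header line
#' `1 n 2k missing-flag dim=2`, an optional row-label block (marked by an
#' `L` suffix on the row count), and `n` data rows `x1 y1 x2 y2 ...`.
#' Comment lines starting with `"` are skipped.
#'
#' @param path path to an NTS file.
#' @return a `landmark_dataset` with labels taken from the label block when
#'   present.
#' @export
read_nts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "\"")]
  if (!length(lines)) stop("empty NTS file")
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  if (length(hdr) < 4) stop("malformed NTS header")
  nfield <- hdr[2]
  labeled <- grepl("L$", nfield, ignore.case = TRUE)
  n <- as.integer(sub("L$", "", nfield, ignore.case = TRUE))
  ncol_ <- as.integer(hdr[3])
  if (is.na(n) || is.na(ncol_)) stop("malformed NTS header")
  if (ncol_ %% 2 != 0)
    stop("NTS column count is odd: expected 2 coordinates per landmark")
  body <- lines[-1]
  labels <- NULL
  if (labeled) {
    # the label block may span one or more lines; collect n tokens
    toks <- character(0); used <- 0L
    while (length(toks) < n) {
      used <- used + 1L
      toks <- c(toks, strsplit(body[used], "\\s+")[[1]])
    }
    if (length(toks) != n) stop("NTS label block does not contain exactly n labels")
    labels <- toks
    body <- body[-seq_len(used)]
  }
  vals <- suppressWarnings(as.numeric(unlist(strsplit(body, "\\s+"))))
  if (anyNA(vals)) stop("non-numeric value in NTS data block")
  if (length(vals) != n * ncol_)
    stop(sprintf("NTS data block has %d values, header promises %d x %d",
                 length(vals), n, ncol_))
  mat <- matrix(vals, nrow = n, ncol = ncol_, byrow = TRUE)
  rownames(mat) <- labels
  landmark_dataset(mat, labels = labels)
}

#' Write an NTS landmark file
#'
#' Emits the header `1 nL 2k 0 dim=2` with a row-label block (the `L`
#' marks labeled rows), one data row per specimen with columns interleaved
#' `x1 y1 x2 y2 ...`.
#'
#' @inheritParams write_tps
#' @return `path`, invisibly.
#' @export
write_nts <- function(dataset, path, digits = 12) {
  if (!inherits(dataset, "landmark_dataset")) dataset <- landmark_dataset(dataset)
  if (dataset$n < 1) stop("cannot write an empty dataset")
  con <- file(path, "w"); on.exit(close(con))
  cat(sprintf("1 %dL %d 0 dim=2\n", dataset$n, 2 * dataset$k), file = con)
  cat(paste(dataset$labels, collapse = " "), "\n", file = con, sep = "")
  flat <- flatten_coords(dataset$coords)
  for (i in seq_len(dataset$n))
    cat(paste(format(flat[i, ], digits = digits, trim = TRUE), collapse = " "),
        "\n", file = con, sep = "")
  invisible(path)
}

# ---- classifiers -----------------------------------------------------------

#' Extract nested classifiers from specimen labels
#'
#' Specimen labels such as `"Busso_T01_L1_R1"` encode the sampling hierarchy
#' by fixed character positions: here characters 1-5 give the population,
#' 1-9 the tree, 1-12 the leaf and characters 14-15 the replica ("R1" or
#' "R2"; non-digits are stripped).  Ranges are 1-based inclusive
#' `c(first, last)` pairs.
#'
#' @param labels character vector of specimen labels.
#' @param ranges named list with elements `population`, `tree`, `leaf`,
#'   `replica`, each a length-2 integer vector of character positions.
#'   Defaults to the `Popul_Txx_Ly_Rz` filename convention.
#' @return a data frame with factor columns `population`, `tree`, `leaf` and
#'   integer column `replica`; nesting consistency (each leaf under one tree,
#'   each tree under one population) is validated.
#' @export
parse_classifiers <- function(labels,
                              ranges = list(population = c(1, 5),
                                            tree = c(1, 9),
                                            leaf = c(1, 12),
                                            replica = c(14, 15))) {
  need <- c("population", "tree", "leaf", "replica")
  if (!all(need %in% names(ranges))) stop("ranges must name population, tree, leaf, replica")
  widest <- max(vapply(ranges, function(r) r[2], 1))
  short <- nchar(labels) < widest
  if (any(short))
    stop(sprintf("label '%s' is shorter than the widest classifier range (%d)",
                 labels[which(short)[1]], widest))
  sub_ <- function(r) substr(labels, r[1], r[2])
  population <- sub_(ranges$population)
  tree <- sub_(ranges$tree)
  leaf <- sub_(ranges$leaf)
  replica_chr <- sub_(ranges$replica)
  replica <- suppressWarnings(as.integer(gsub("[^0-9]", "", replica_chr)))
  if (anyNA(replica))
    stop("replica range does not contain an integer in all labels")
  # nesting consistency: a child value must map to exactly one parent value
  check_nesting <- function(child, parent, what) {
    tab <- unique(data.frame(child, parent))
    dup <- tab$child[duplicated(tab$child)]
    if (length(dup))
      stop(sprintf("nesting violation: %s '%s' appears under more than one parent",
                   what, dup[1]))
  }
  check_nesting(tree, population, "tree")
  check_nesting(leaf, tree, "leaf")
  data.frame(population = factor(population), tree = factor(tree),
             leaf = factor(leaf), replica = replica,
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---- outline ---------------------------------------------------------------

#' Read an outline polyline file
#'
#' Plain two-column `x y` ASCII in the coordinate frame of the reference
#' configuration.  A single leading count line (one integer) is tolerated
#' and skipped; no resampling is performed.
#'
#' @param path path to the outline file.
#' @return an ordered two-column matrix of vertices.
#' @export
read_outline <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[\\s,]+", perl = TRUE)
  if (length(toks) && length(toks[[1]]) == 1L &&
      !is.na(suppressWarnings(as.numeric(toks[[1]])))) toks <- toks[-1]
  vals <- lapply(toks, function(tk) suppressWarnings(as.numeric(tk)))
  bad <- which(vapply(vals, function(v) length(v) != 2 || anyNA(v), TRUE))
  if (length(bad)) stop(sprintf("outline parse error at data line %d", bad[1]))
  out <- do.call(rbind, vals)
  if (nrow(out) < 3) stop("an outline needs at least 3 vertices")
  colnames(out) <- c("x", "y")
  out
}

#' Write an outline polyline file
#'
#' @param outline two-column matrix of vertices.
#' @param path output path.
#' @param digits significant digits (default 12).
#' @return `path`, invisibly.
#' @export
write_outline <- function(outline, path, digits = 12) {
  utils::write.table(format(outline, digits = digits, trim = TRUE), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
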