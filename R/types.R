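#' Construct a 3D dataset
#'
#' A dataset is a named, ordered set of N 3D points. When `chain = TRUE`
#' the points are understood sequentially, each connected to the previous
#' and next point by a solid line (the natural representation for a protein
#' backbone); otherwise each point is an independent particle (a cell
#' population, PCA scores, ...). Point order is significant: an information
#' layer refers to points by position.
#'
#' @param points Numeric N x 3 matrix (or coercible) of (x, y, z)
#'   coordinates; all values must be finite and N >= 1.
#' @param name Text label of the dataset.
#' @param chain Logical; connect consecutive points with line segments.
#' @param source_dialect One of `"json"`, `"xml"`, `"csv"` or `NA` when the
#'   object was built in memory.
#' @return An object of class `pw_dataset`.
#' @seealso [read_dataset()], [write_dataset()], [validate_pair()]
#' @export
#' @examples
#' ds <- pw_dataset(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), name = "demo")
#' ds
pw_dataset <- function(points, name = "dataset", chain = FALSE,
                       source_dialect = NA_character_) {
  points <- as.matrix(points)
  if (ncol(points) != 3) {
    stop_issue("BAD_ARITY", sprintf("points must have 3 columns, got %d", ncol(points)))
  }
  if (nrow(points) < 1) {
    stop_issue("EMPTY_DATASET", "a dataset must hold at least one point")
  }
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) {
    bad <- which(!is.finite(points), arr.ind = TRUE)[1, 1]
    stop_issue("BAD_COORDINATE", "non-finite coordinate",
               locus = sprintf("point %d", bad))
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  stopifnot(is.character(name), length(name) == 1,
            is.logical(chain), length(chain) == 1, !is.na(chain))
  structure(list(name = name, chain = chain, points = points,
                 source_dialect = source_dialect),
            class = "pw_dataset")
}

#' @export
print.pw_dataset <- function(x, ...) {
  cat(sprintf("<pw_dataset> '%s': %d points, %s\n", x$name, nrow(x$points),
              if (x$chain) "chained (polyline)" else "particles"))
  invisible(x)
}

#' Number of points in a dataset
#' @param ds A [pw_dataset()].
#' @return Integer point count.
#' @export
n_points <- function(ds) nrow(ds$points)

#' Construct an information layer
#'
#' An information layer assigns each point of a dataset to one of
#' `num_classes` classes (e.g. the cluster a pseudo-cell belongs to, or
#' whether a gene is expressed). Values are canonical 0-based integers in
#' `[0, num_classes - 1]`, in the same order as the dataset's points.
#'
#' @param values Integer vector of per-point class identifiers (0-based).
#' @param num_classes Declared number of classes; defaults to
#'   `max(values) + 1`. May exceed the number of classes actually observed
#'   (declared-but-empty classes are legal and flagged only as warnings at
#'   validation time).
#' @param name Optional layer label.
#' @param labels Optional character vector of length `num_classes` naming
#'   the classes.
#' @return An object of class `pw_layer`.
#' @export
#' @examples
#' pw_layer(c(0, 0, 1), num_classes = 2, labels = c("head", "trunk"))
pw_layer <- function(values, num_classes = NULL, name = NULL, labels = NULL) {
  values <- as.integer(values)
  if (length(values) < 1 || anyNA(values)) {
    stop_issue("VALUE_OUT_OF_RANGE", "values must be a non-empty integer vector")
  }
  if (is.null(num_classes)) num_classes <- max(values) + 1L
  num_classes <- as.integer(num_classes)
  if (is.na(num_classes) || num_classes < 1) {
    stop_issue("VALUE_OUT_OF_RANGE", "num_classes must be a positive integer")
  }
  if (any(values < 0L | values >= num_classes)) {
    bad <- which(values < 0L | values >= num_classes)[1]
    stop_issue("VALUE_OUT_OF_RANGE",
               sprintf("value %d outside [0, %d]", values[bad], num_classes - 1L),
               locus = sprintf("value %d", bad))
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != num_classes) {
      stop_issue("LABEL_COUNT_MISMATCH",
                 sprintf("%d labels for %d classes", length(labels), num_classes))
    }
  }
  if (!is.null(name)) stopifnot(is.character(name), length(name) == 1)
  structure(list(name = name, num_classes = num_classes,
                 labels = labels, values = values),
            class = "pw_layer")
}

#' @export
print.pw_layer <- function(x, ...) {
  cat(sprintf("<pw_layer>%s %d values, %d classes%s\n",
              if (is.null(x$name)) "" else sprintf(" '%s':", x$name),
              length(x$values), x$num_classes,
              if (is.null(x$labels)) "" else " (labelled)"))
  invisible(x)
}

#' Construct an information file
#'
#' One information file can carry several layers over the same dataset
#' (e.g. the partitions produced by two clustering algorithms). All layers
#' must have values of equal length.
#'
#' @param layers A list of [pw_layer()] objects, or a single layer.
#' @param source_dialect As in [pw_dataset()].
#' @return An object of class `pw_infofile`.
#' @export
pw_infofile <- function(layers, source_dialect = NA_character_) {
  if (inherits(layers, "pw_layer")) layers <- list(layers)
  if (length(layers) < 1) {
    stop_issue("EMPTY_INFORMATION", "an information file needs at least one layer")
  }
  stopifnot(all(vapply(layers, inherits, logical(1), "pw_layer")))
  lens <- vapply(layers, function(l) length(l$values), integer(1))
  if (length(unique(lens)) != 1) {
    stop_issue("RAGGED_LAYERS",
               paste("layer lengths differ:", paste(lens, collapse = ", ")))
  }
  structure(list(layers = layers, source_dialect = source_dialect),
            class = "pw_infofile")
}

#' @export
print.pw_infofile <- function(x, ...) {
  cat(sprintf("<pw_infofile> %d layer(s) over %d points\n",
              length(x$layers), length(x$layers[[1]]$values)))
  for (l in x$layers) print(l)
  invisible(x)
}

#' Cross-validate a dataset against an information file
#'
#' Checks the pairing contract: every layer's values must be in the same
#' order and of the same length as the dataset's points. Declared classes
#' with no member points are reported as warnings, not errors.
#'
#' @param ds A [pw_dataset()].
#' @param info A [pw_infofile()] or single [pw_layer()].
#' @return A data frame of issues (see [validation_issue()]); zero rows
#'   means the pair is clean. Errors and warnings are rows, never
#'   conditions.
#' @export
#' @examples
#' ex <- worked_example()
#' validate_pair(ex$dataset, ex$information)   # zero rows
validate_pair <- function(ds, info) {
  stopifnot(inherits(ds, "pw_dataset"))
  if (inherits(info, "pw_layer")) info <- pw_infofile(list(info))
  stopifnot(inherits(info, "pw_infofile"))
  issues <- no_issues()
  n <- n_points(ds)
  for (i in seq_along(info$layers)) {
    l <- info$layers[[i]]
    locus <- sprintf("layer %d", i)
    if (length(l$values) != n) {
      issues <- rbind(issues, validation_issue(
        "LENGTH_MISMATCH",
        sprintf("layer has %d values but dataset has %d points",
                length(l$values), n),
        locus = locus))
      next
    }
    present <- unique(l$values)
    if (length(present) < l$num_classes) {
      empty <- setdiff(seq_len(l$num_classes) - 1L, present)
      issues <- rbind(issues, validation_issue(
        "EMPTY_CLASS",
        sprintf("declared classes with no points: %s",
                paste(empty, collapse = ", ")),
        locus = locus))
    }
  }
  issues
}
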