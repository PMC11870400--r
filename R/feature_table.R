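#' Construct a feature table
#'
#' A feature table is the package's central container: a numeric matrix of
#' peak intensities with samples as rows and features (detected m/z /
#' retention-time peaks) as columns. Row and column names carry the sample
#' and feature identifiers and must be unique. Missing cells are stored as 0,
#' reflecting the sparse nature of untargeted LC-MS feature tables.
#'
#' Raw intensities must be finite and non-negative at ingest; tables that have
#' passed scaling (see [scale_auto()]) may hold negative values, which is why
#' non-negativity is enforced by the readers and the preprocessing stages
#' rather than by this constructor.
#'
#' @param values numeric matrix, samples x features, with unique non-empty
#'   rownames (sample ids) and colnames (feature ids).
#' @param annotations optional data.frame of per-feature annotations (e.g.
#'   columns `mz`, `rt`), one row per feature in column order.
#' @return an object of class `feature_table` (a matrix with an
#'   `annotations` attribute).
#' @examples
#' m <- matrix(c(1, 0, 3, 2, 1, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
#' ft <- feature_table(m)
#' dim(ft)
#' @export
feature_table <- function(values, annotations = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (samples x features)", call. = FALSE)
  }
  if (nrow(values) == 0L) {
    stop("feature table must have at least one sample", call. = FALSE)
  }
  sample_ids <- rownames(values)
  feature_ids <- colnames(values)
  if (is.null(sample_ids) || anyNA(sample_ids) || any(sample_ids == "")) {
    stop("'values' must have non-empty rownames (sample ids)", call. = FALSE)
  }
  # zero features is a legal (if degenerate) filter outcome
  if (ncol(values) == 0L) {
    dimnames(values) <- list(sample_ids, character(0))
    feature_ids <- character(0)
  } else if (is.null(feature_ids) || anyNA(feature_ids) || any(feature_ids == "")) {
    stop("'values' must have non-empty colnames (feature ids)", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature id: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("feature table values must all be finite", call. = FALSE)
  }
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (nrow(annotations) != length(feature_ids)) {
      stop("'annotations' must have one row per feature", call. = FALSE)
    }
    rownames(annotations) <- feature_ids
  }
  structure(values, annotations = annotations,
            class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features\n", nrow(x), ncol(x)))
  ann <- attr(x, "annotations")
  if (!is.null(ann)) {
    cat("Feature annotations: ", paste(colnames(ann), collapse = ", "), "\n", sep = "")
  }
  rng <- range(x)
  cat(sprintf("Value range: [%.6g, %.6g]; zero cells: %.1f%%\n",
              rng[1], rng[2], 100 * mean(x == 0)))
  invisible(x)
}

#' @export
as.matrix.feature_table <- function(x, ...) {
  attr(x, "annotations") <- NULL
  class(x) <- c("matrix", "array")
  x
}

#' Feature annotations of a table
#'
#' @param table a [feature_table()].
#' @return the per-feature annotation data.frame, or `NULL`.
#' @export
feature_annotations <- function(table) {
  attr(table, "annotations")
}

# Coerce a plain matrix-like input, preserving a feature_table as-is.
as_feature_table <- function(x) {
  if (inherits(x, "feature_table")) return(x)
  feature_table(as.matrix(x))
}

# Rebuild a feature_table after subsetting/transforming its values, keeping
# annotations for the surviving features.
rebuild_table <- function(values, template) {
  ann <- attr(template, "annotations")
  if (!is.null(ann)) ann <- ann[colnames(values), , drop = FALSE]
  feature_table(values, annotations = ann)
}

check_nonnegative <- function(values, context) {
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("%s: negative intensity at sample '%s', feature '%s' (raw intensities must be >= 0)",
                 context, rownames(values)[bad[1]], colnames(values)[bad[2]]),
         call. = FALSE)
  }
  invisible(TRUE)
}
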