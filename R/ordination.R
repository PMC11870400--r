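# Classical PCoA (Gower double-centering + eigendecomposition) and PCA.
# Both return a "metord_ord" object: the fitted ordination.

#' Principal Coordinate Analysis (classical MDS)
#'
#' Embeds samples from a dissimilarity matrix so that Euclidean distances in
#' the embedding approximate the input dissimilarities. The classical
#' closed-form solution is used: square the distances elementwise, form
#' A = -D^2/2, double-center with J = I - 11'/n into B = JAJ (Gower
#' centering), and take the symmetric eigendecomposition of B. Coordinates on
#' axis a are eigenvector_a * sqrt(lambda_a) for positive eigenvalues; axes
#' with non-positive eigenvalues are dropped from the coordinates.
#'
#' Non-Euclidean dissimilarities (e.g. Bray-Curtis) can yield negative
#' eigenvalues; their summed magnitude is reported as
#' `negative_eigenvalue_mass`, a diagnostic of embedding distortion. No
#' Lingoes/Cailliez correction is applied. The proportion explained of each
#' axis is its eigenvalue over the sum of positive eigenvalues.
#'
#' Eigenvalues within `max(abs(eigenvalues)) * 1e-12` of zero are treated as
#' zero. Eigenvector signs are fixed deterministically by making each
#' eigenvector's largest-magnitude element positive.
#'
#' @param dm a `distance_matrix` from [pairwise_distances()], a [stats::dist]
#'   object, or a symmetric hollow numeric matrix with ids as dimnames.
#' @param num_axes number of axes to keep in the coordinates, or `NULL` for
#'   all positive axes. The full eigenvalue spectrum is always computed and
#'   stored.
#' @return an object of class `metord_ord` with elements `ids`,
#'   `eigenvalues` (full spectrum, descending), `coordinates` (n x k),
#'   `proportion_explained` (positive axes), `negative_eigenvalue_mass`,
#'   `method`, `metric`.
#' @examples
#' m <- matrix(rnorm(24), 6, 4,
#'             dimnames = list(paste0("s", 1:6), paste0("f", 1:4)))
#' fit <- pcoa(pairwise_distances(m, "euclidean"))
#' fit
#' @export
pcoa <- function(dm, num_axes = NULL) {
  metric <- if (inherits(dm, "distance_matrix")) attr(dm, "metric") else NULL
  m <- unclass_distance(dm)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("s", seq_len(n))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12)) ||
      any(abs(diag(m)) > 1e-12)) {
    stop("input is not a valid distance matrix (must be symmetric and hollow)",
         call. = FALSE)
  }
  a <- -0.5 * m^2
  # Gower centering: subtract row and column means, add back grand mean
  rm_ <- rowMeans(a)
  b <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(a)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  lambda <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  vectors <- fix_signs(vectors)
  tol <- max(abs(lambda), 0) * 1e-12
  lambda[abs(lambda) <= tol] <- 0
  pos <- which(lambda > 0)
  k <- if (is.null(num_axes)) length(pos) else min(num_axes, length(pos))
  coords <- vectors[, pos[seq_len(k)], drop = FALSE] *
    rep(sqrt(lambda[pos[seq_len(k)]]), each = n)
  dimnames(coords) <- list(rownames(m), paste0("PCo", seq_len(k)))
  new_metord_ord(
    ids = rownames(m),
    eigenvalues = lambda,
    coordinates = coords,
    proportion_explained = if (length(pos)) lambda[pos] / sum(lambda[pos]) else numeric(0),
    negative_eigenvalue_mass = sum(abs(lambda[lambda < 0])),
    method = "pcoa",
    metric = metric
  )
}

#' Principal Component Analysis
#'
#' Column-centers the feature table and decomposes it by SVD. Sample scores
#' are U S (restricted to `num_axes`); eigenvalues are the squared singular
#' values, so their sum equals the total variance times (n - 1). On a
#' Euclidean distance matrix of the same data, [pcoa()] reproduces these
#' scores and eigenvalues up to per-axis sign.
#'
#' @param table a [feature_table()] or numeric matrix, >= 2 samples.
#' @param num_axes number of axes to keep in the scores, or `NULL` for all.
#' @return a `metord_ord` object (see [pcoa()]); `method = "pca"`.
#' @export
pca <- function(table, num_axes = NULL) {
  x <- as.matrix(table)
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  lambda <- sv$d^2
  tol <- max(lambda, 0) * 1e-12
  lambda[lambda <= tol] <- 0
  # sign convention on the feature loadings, applied to scores consistently
  flip <- apply(sv$v, 2, function(v) if (v[which.max(abs(v))] < 0) -1 else 1)
  scores_full <- sv$u %*% diag(sv$d, nrow = length(sv$d)) *
    rep(flip, each = nrow(x))
  pos <- which(lambda > 0)
  k <- if (is.null(num_axes)) length(pos) else min(num_axes, length(pos))
  coords <- scores_full[, pos[seq_len(k)], drop = FALSE]
  dimnames(coords) <- list(rownames(x), paste0("PC", seq_len(k)))
  new_metord_ord(
    ids = rownames(x),
    eigenvalues = lambda,
    coordinates = coords,
    proportion_explained = if (length(pos)) lambda[pos] / sum(lambda[pos]) else numeric(0),
    negative_eigenvalue_mass = 0,
    method = "pca",
    metric = "euclidean"
  )
}

new_metord_ord <- function(ids, eigenvalues, coordinates,
                           proportion_explained, negative_eigenvalue_mass,
                           method, metric) {
  structure(list(ids = ids, eigenvalues = eigenvalues,
                 coordinates = coordinates,
                 proportion_explained = proportion_explained,
                 negative_eigenvalue_mass = negative_eigenvalue_mass,
                 method = method, metric = metric),
            class = "metord_ord")
}

# Deterministic eigenvector orientation: largest-|element| entry positive.
fix_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' @export
print.metord_ord <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat(sprintf("%s ordination%s: %d samples, %d axes retained\n",
              toupper(x$method),
              if (!is.null(x$metric)) paste0(" (", x$metric, ")") else "",
              length(x$ids), k))
  if (k > 0) {
    pe <- 100 * x$proportion_explained[seq_len(min(k, 3L))]
    cat("Proportion explained: ",
        paste(sprintf("%s %.1f%%", colnames(x$coordinates)[seq_along(pe)], pe),
              collapse = ", "), "\n", sep = "")
  }
  if (x$negative_eigenvalue_mass > 0) {
    cat(sprintf("Negative eigenvalue mass: %.4g\n", x$negative_eigenvalue_mass))
  }
  invisible(x)
}

#' @export
summary.metord_ord <- function(object, ...) {
  print(object)
  k <- length(object$proportion_explained)
  if (k) {
    tab <- data.frame(
      eigenvalue = object$eigenvalues[seq_len(k)],
      proportion_explained = object$proportion_explained,
      cumulative = cumsum(object$proportion_explained),
      row.names = paste0("axis", seq_len(k))
    )
    print(utils::head(tab, 10))
  }
  invisible(object)
}

#' @export
as.matrix.metord_ord <- function(x, ...) x$coordinates

#' Scatter plot of an ordination
#'
#' Plots two ordination axes with axis labels carrying the proportion of
#' (positive-eigenvalue) variation explained, optionally colored by a
#' metadata column.
#'
#' @param x a `metord_ord` object.
#' @param axes length-2 integer vector of axes to plot.
#' @param metadata optional metadata data.frame (sample ids as row names).
#' @param color_by optional metadata column used to color points.
#' @param ... passed to [graphics::plot()].
#' @export
plot.metord_ord <- function(x, axes = c(1, 2), metadata = NULL,
                            color_by = NULL, ...) {
  k <- ncol(x$coordinates)
  if (k < 1L) stop("ordination has no axes to plot", call. = FALSE)
  axes <- axes[axes <= k]
  if (length(axes) == 1L) axes <- c(axes, axes)
  lab <- function(a) sprintf("%s (%.1f%%)", colnames(x$coordinates)[a],
                             100 * x$proportion_explained[a])
  col <- "black"; legend_groups <- NULL
  if (!is.null(metadata) && !is.null(color_by)) {
    if (!color_by %in% colnames(metadata)) {
      stop(sprintf("column '%s' not in metadata; available: %s", color_by,
                   paste(colnames(metadata), collapse = ", ")), call. = FALSE)
    }
    groups <- factor(metadata[x$ids, color_by])
    col <- as.integer(groups) + 1L
    legend_groups <- levels(groups)
  }
  graphics::plot(x$coordinates[, axes[1]], x$coordinates[, axes[2]],
                 xlab = lab(axes[1]), ylab = lab(axes[2]), col = col,
                 pch = 19, ...)
  if (!is.null(legend_groups)) {
    graphics::legend("topright", legend = legend_groups, col =
                       seq_along(legend_groups) + 1L, pch = 19, cex = 0.8)
  }
  invisible(x)
}
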