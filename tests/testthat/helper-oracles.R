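# Independent oracles and tiny fixture builders. Everything here deliberately
# recomputes quantities by a different route than the package (explicit double
# loops, stats::dist, vegan::vegdist, prcomp, cmdscale) so the two paths
# cross-check each other.

toy_table <- function(seed, n = 10, p = 6, sparsity = 0.2, lognormal = TRUE) {
  set.seed(seed)
  vals <- if (lognormal) {
    matrix(rlnorm(n * p, meanlog = 3, sdlog = 1), n, p)
  } else {
    matrix(abs(rnorm(n * p)), n, p)
  }
  vals[matrix(runif(n * p) < sparsity, n, p)] <- 0
  dimnames(vals) <- list(sprintf("s%02d", seq_len(n)),
                         sprintf("f%03d", seq_len(p)))
  feature_table(vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

retained_ids <- function(filter_result) {
  colnames(filter_result$table) %||% character(0)
}

# Brute-force blank filter: explicit loops over features and samples.
oracle_blank_filter <- function(values, is_blank, k, p) {
  keep <- logical(ncol(values))
  for (j in seq_len(ncol(values))) {
    blank_mean <- mean(values[is_blank, j])
    n_pass <- 0L
    nonblank_rows <- which(!is_blank)
    for (i in nonblank_rows) {
      if (values[i, j] > k * blank_mean) n_pass <- n_pass + 1L
    }
    keep[j] <- (n_pass / length(nonblank_rows)) >= p
  }
  colnames(values)[keep]
}

# Direct per-pair formula evaluation, one explicit double loop, formulas
# written independently of the package registry.
oracle_pair_distance <- function(x, y, metric, tab = NULL) {
  bx <- x > 0; by <- y > 0
  a <- sum(bx & by); b <- sum(bx & !by); cc <- sum(!bx & by)
  d <- sum(!bx & !by); ntot <- length(x)
  switch(metric,
    braycurtis = sum(abs(x - y)) / sum(x + y),
    euclidean = sqrt(sum((x - y)^2)),
    sqeuclidean = sum((x - y)^2),
    cityblock = sum(abs(x - y)),
    chebyshev = max(abs(x - y)),
    canberra = {
      den <- abs(x) + abs(y)
      sum((abs(x - y) / den)[den > 0])
    },
    cosine = 1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2)),
    correlation = 1 - cor(x, y),
    minkowski = (sum(abs(x - y)^3))^(1/3),
    seuclidean = {
      v <- apply(tab, 2, var)
      sqrt(sum(((x - y)^2 / v)[v > 0]))
    },
    jensenshannon = {
      pp <- x / sum(x); qq <- y / sum(y); m <- (pp + qq) / 2
      h <- function(w) -sum(w[w > 0] * log(w[w > 0]))
      sqrt(max(h(m) - (h(pp) + h(qq)) / 2, 0))
    },
    mahalanobis = {
      vi <- solve(cov(tab))
      sqrt(drop(t(x - y) %*% vi %*% (x - y)))
    },
    hamming = (b + cc) / ntot,
    jaccard = if (a + b + cc == 0) 0 else (b + cc) / (a + b + cc),
    dice = if (2 * a + b + cc == 0) 0 else (b + cc) / (2 * a + b + cc),
    russellrao = (ntot - a) / ntot,
    rogerstanimoto = 2 * (b + cc) / (ntot + b + cc),
    sokalsneath = if (a + 2 * (b + cc) == 0) 0 else
      2 * (b + cc) / (a + 2 * (b + cc)),
    yule = if (b * cc == 0) 0 else 2 * b * cc / (a * d + b * cc),
    matching = (b + cc) / ntot,
    stop("no oracle for ", metric))
}

oracle_distance_matrix <- function(tab, metric) {
  x <- as.matrix(tab)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- oracle_pair_distance(x[i, ], x[j, ], metric, x)
    }
  }
  d
}

# Minimal independent parser for the ordination text format.
parse_ordination_file <- function(path) {
  txt <- readLines(path)
  blocks <- split(txt, cumsum(txt == ""))
  blocks <- lapply(blocks, function(b) b[b != ""])
  out <- list()
  for (b in blocks) {
    hdr <- strsplit(b[1], "\t")[[1]]
    if (hdr[1] == "Eigvals") {
      out$eigvals <- as.numeric(strsplit(b[2], "\t")[[1]])
    } else if (hdr[1] == "Proportion explained") {
      out$prop <- as.numeric(strsplit(b[2], "\t")[[1]])
    } else if (hdr[1] == "Site") {
      rows <- strsplit(b[-1], "\t")
      out$ids <- vapply(rows, `[[`, character(1), 1)
      out$coords <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
    }
  }
  out
}

# Row-subset a feature table, keeping annotations.
rebuild_ft <- function(table, keep_rows) {
  feature_table(as.matrix(table)[keep_rows, , drop = FALSE],
                annotations = feature_annotations(table))
}

# Mean silhouette width of labels over a 2-D embedding.
mean_silhouette <- function(coords, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             dist(coords[, 1:2, drop = FALSE]))
  mean(sil[, "sil_width"])
}

expect_table_equal <- function(a, b, tol = 1e-12) {
  expect_identical(rownames(a), rownames(b))
  expect_identical(colnames(a), colnames(b))
  expect_equal(unname(as.matrix(a)), unname(as.matrix(b)), tolerance = tol)
}
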