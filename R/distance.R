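# Dissimilarity engine: twenty pairwise measures over samples of a feature
# table, one consistent registry. Binary measures operate on presence
# (intensity > 0); abundance measures use the raw values. Definitions follow
# the standard pairwise-distance catalogue; each formula is documented on
# ?dissimilarity_metrics.

# Measures only meaningful on non-negative data: warn if applied after
# scaling, which introduces negative values.
NONNEG_METRICS <- c("braycurtis", "jaccard", "dice", "jensenshannon", "canberra")

BINARY_METRICS <- c("jaccard", "dice", "russellrao", "rogerstanimoto",
                    "sokalsneath", "yule", "matching", "hamming")

#' Registered dissimilarity measures
#'
#' The twenty selectable measures. For vectors x, y over p features, with
#' a/b/c/d the presence-pattern counts (both / only-x / only-y / neither,
#' presence meaning intensity > 0):
#'
#' * `braycurtis`: sum|x-y| / sum(x+y)
#' * `euclidean`: sqrt(sum (x-y)^2)
#' * `sqeuclidean`: sum (x-y)^2
#' * `cityblock`: sum |x-y|
#' * `chebyshev`: max |x-y|
#' * `canberra`: sum |x-y| / (|x|+|y|), zero-denominator terms contribute 0
#' * `cosine`: 1 - x.y / (|x||y|)
#' * `correlation`: 1 - Pearson correlation of x and y
#' * `minkowski`: (sum |x-y|^p)^(1/p), order p = 3
#' * `seuclidean`: sqrt(sum (x-y)^2 / V_j), V_j the per-feature variance
#'   (n-1 denominator) over the whole table; constant features contribute 0
#' * `jensenshannon`: sqrt of the Jensen-Shannon divergence (natural log)
#'   of the rows rescaled to probability vectors
#' * `mahalanobis`: sqrt((x-y) S^+ (x-y)'), S^+ the Moore-Penrose
#'   pseudoinverse of the feature covariance matrix of the table (the
#'   pseudoinverse handles the p > n case typical of feature tables)
#' * `hamming`: (b+c)/p on presence patterns
#' * `jaccard`: (b+c)/(a+b+c), 0 when both patterns are empty
#' * `dice`: (b+c)/(2a+b+c), 0 when both patterns are empty
#' * `russellrao`: (p-a)/p
#' * `rogerstanimoto`: 2(b+c)/(p+b+c)
#' * `sokalsneath`: 2(b+c)/(a+2(b+c)), 0 when both patterns are empty
#' * `yule`: 2bc/(ad+bc), 0 when bc = 0
#' * `matching`: (b+c)/p (simple matching distance)
#'
#' @return character vector of the twenty metric names.
#' @export
dissimilarity_metrics <- function() {
  c("braycurtis", "euclidean", "sqeuclidean", "cityblock", "chebyshev",
    "canberra", "cosine", "correlation", "minkowski", "seuclidean",
    "jensenshannon", "mahalanobis", "hamming", "jaccard", "dice",
    "russellrao", "rogerstanimoto", "sokalsneath", "yule", "matching")
}

#' Pairwise dissimilarities between samples
#'
#' Computes the symmetric, hollow n x n dissimilarity matrix between the rows
#' (samples) of a feature table under one of the twenty registered measures
#' (see [dissimilarity_metrics()] for formulas). Measures defined only for
#' non-negative data (`braycurtis`, `jaccard`, `dice`, `jensenshannon`,
#' `canberra`) emit a warning when the table contains negative values, as
#' happens after scaling.
#'
#' @param table a [feature_table()] or numeric matrix, >= 2 samples.
#' @param metric one of [dissimilarity_metrics()].
#' @param p Minkowski order (only for `metric = "minkowski"`), default 3.
#' @return a `distance_matrix`: square numeric matrix with sample ids on both
#'   dimnames and a `metric` attribute; coerce with [as.dist()].
#' @examples
#' m <- matrix(c(1, 0, 3, 2, 1, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
#' pairwise_distances(feature_table(m), "braycurtis")
#' @export
pairwise_distances <- function(table, metric, p = 3) {
  x <- if (inherits(table, "feature_table")) as.matrix(table) else as.matrix(table)
  if (!is.character(metric) || length(metric) != 1 ||
      !metric %in% dissimilarity_metrics()) {
    stop("unknown metric '", as.character(metric)[1], "'; valid metrics: ",
         paste(dissimilarity_metrics(), collapse = ", "), call. = FALSE)
  }
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (metric %in% NONNEG_METRICS && any(x < 0)) {
    warning("metric '", metric, "' assumes non-negative data but the table ",
            "contains negative values (scaled input?)", call. = FALSE)
  }
  n <- nrow(x)
  ids <- rownames(x)
  pairfun <- metric_pair_function(metric, x, p = p)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      v <- pairfun(x[i, ], x[j, ])
      if (!is.finite(v)) {
        stop("metric '", metric, "' is undefined for sample pair '",
             ids[i], "' / '", ids[j], "'", call. = FALSE)
      }
      d[i, j] <- d[j, i] <- v
    }
  }
  new_distance_matrix(d, metric = metric)
}

# Returns a function(x, y) for one pair; table-level statistics (variances,
# covariance pseudoinverse) are precomputed here.
metric_pair_function <- function(metric, x, p = 3) {
  if (metric %in% BINARY_METRICS) {
    bin <- function(v) v > 0
    counts <- function(xi, yi) {
      xb <- bin(xi); yb <- bin(yi)
      c(a = sum(xb & yb), b = sum(xb & !yb), c = sum(!xb & yb),
        d = sum(!xb & !yb))
    }
    return(switch(metric,
      jaccard = function(xi, yi) {
        k <- counts(xi, yi); den <- k["a"] + k["b"] + k["c"]
        if (den == 0) 0 else unname((k["b"] + k["c"]) / den)
      },
      dice = function(xi, yi) {
        k <- counts(xi, yi); den <- 2 * k["a"] + k["b"] + k["c"]
        if (den == 0) 0 else unname((k["b"] + k["c"]) / den)
      },
      russellrao = function(xi, yi) {
        k <- counts(xi, yi); unname((sum(k) - k["a"]) / sum(k))
      },
      rogerstanimoto = function(xi, yi) {
        k <- counts(xi, yi); r <- 2 * (k["b"] + k["c"])
        unname(r / (sum(k) + k["b"] + k["c"]))
      },
      sokalsneath = function(xi, yi) {
        k <- counts(xi, yi); r <- 2 * (k["b"] + k["c"])
        if (k["a"] + r == 0) 0 else unname(r / (k["a"] + r))
      },
      yule = function(xi, yi) {
        k <- counts(xi, yi); r <- 2 * k["b"] * k["c"]
        if (r == 0) 0 else unname(r / (k["a"] * k["d"] + k["b"] * k["c"]))
      },
      matching = ,
      hamming = function(xi, yi) {
        k <- counts(xi, yi); unname((k["b"] + k["c"]) / sum(k))
      }))
  }
  switch(metric,
    braycurtis = function(xi, yi) {
      den <- sum(xi + yi)
      if (den == 0) return(NaN)
      sum(abs(xi - yi)) / den
    },
    euclidean = function(xi, yi) sqrt(sum((xi - yi)^2)),
    sqeuclidean = function(xi, yi) sum((xi - yi)^2),
    cityblock = function(xi, yi) sum(abs(xi - yi)),
    chebyshev = function(xi, yi) max(abs(xi - yi)),
    canberra = function(xi, yi) {
      num <- abs(xi - yi); den <- abs(xi) + abs(yi)
      sum(ifelse(den == 0, 0, num / den))
    },
    cosine = function(xi, yi) {
      nx <- sqrt(sum(xi^2)); ny <- sqrt(sum(yi^2))
      if (nx == 0 || ny == 0) return(NaN)
      1 - sum(xi * yi) / (nx * ny)
    },
    correlation = function(xi, yi) {
      xc <- xi - mean(xi); yc <- yi - mean(yi)
      nx <- sqrt(sum(xc^2)); ny <- sqrt(sum(yc^2))
      if (nx == 0 || ny == 0) return(NaN)
      1 - sum(xc * yc) / (nx * ny)
    },
    minkowski = function(xi, yi) sum(abs(xi - yi)^p)^(1 / p),
    seuclidean = {
      v <- apply(x, 2, stats::var)
      function(xi, yi) {
        term <- (xi - yi)^2
        sqrt(sum(ifelse(v == 0, 0, term / ifelse(v == 0, 1, v))))
      }
    },
    jensenshannon = function(xi, yi) {
      if (any(xi < 0) || any(yi < 0) || sum(xi) == 0 || sum(yi) == 0) return(NaN)
      pp <- xi / sum(xi); qq <- yi / sum(yi)
      m <- (pp + qq) / 2
      kl <- function(a, b) {
        use <- a > 0
        sum(a[use] * log(a[use] / b[use]))
      }
      js <- (kl(pp, m) + kl(qq, m)) / 2
      sqrt(max(js, 0))
    },
    mahalanobis = {
      vi <- MASS::ginv(stats::cov(x))
      function(xi, yi) {
        dlt <- xi - yi
        sqrt(max(drop(dlt %*% vi %*% dlt), 0))
      }
    })
}

new_distance_matrix <- function(values, metric) {
  structure(values, metric = metric,
            class = c("distance_matrix", "matrix", "array"))
}

unclass_distance <- function(dm) {
  if (inherits(dm, "dist")) return(as.matrix(dm))
  m <- as.matrix(dm)
  attr(m, "metric") <- NULL
  class(m) <- c("matrix", "array")
  m
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("Distance matrix (%s): %d samples\n",
              attr(x, "metric") %||% "?", nrow(x)))
  print(unclass_distance(x)[seq_len(min(nrow(x), 6L)),
                            seq_len(min(ncol(x), 6L))])
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @export
as.dist.distance_matrix <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(unclass_distance(m), diag = diag, upper = upper)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
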