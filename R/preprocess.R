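# Preprocessing stages, applied in fixed order:
# blank filter -> normalization (tic | pqn | none) -> scaling (auto | pareto | none).

#' Filter features by blank-sample intensity
#'
#' Removes background features (solvent, environmental and instrument
#' contaminants) using the blank samples in the run. For each feature the mean
#' intensity over blank samples is computed; the feature is retained iff the
#' fraction of non-blank samples whose intensity strictly exceeds
#' `fold_threshold` times that blank mean is at least `min_nonblank_fraction`.
#'
#' The comparison is strict (`>`), so a feature absent from all blanks (blank
#' mean 0) is retained as soon as enough non-blank samples have any positive
#' intensity. Filtering removes features only: blank samples stay in the
#' returned table so that their separation remains visible in ordination
#' plots (drop them later with `drop_blanks` in [run_pipeline()] if desired).
#'
#' @param table a [feature_table()] of raw non-negative intensities.
#' @param metadata metadata data.frame aligned with `table` (sample ids as row
#'   names).
#' @param blank_column metadata column designating blanks.
#' @param blank_value value of `blank_column` marking a blank sample.
#' @param fold_threshold positive fold ratio k: intensities must exceed
#'   k x mean blank intensity. Default 3.
#' @param min_nonblank_fraction required fraction of qualifying non-blank
#'   samples, in (0, 1]. Default 0.9.
#' @return a list with the filtered `table` and a `report` of class
#'   `filter_report` (`n_features_before`, `n_features_after`, `n_removed`,
#'   `retained_fraction`, `removed_feature_ids`).
#' @examples
#' sim <- simulate_feature_table(fixture_spec(seed = 1))
#' res <- blank_filter(sim$table, sim$metadata, "sample_type", "blank",
#'                     fold_threshold = 2, min_nonblank_fraction = 0.5)
#' res$report
#' @export
blank_filter <- function(table, metadata, blank_column, blank_value,
                         fold_threshold = 3, min_nonblank_fraction = 0.9) {
  table <- as_feature_table(table)
  check_nonnegative(unclass(table), "blank_filter")
  if (!is.numeric(fold_threshold) || length(fold_threshold) != 1 ||
      fold_threshold <= 0) {
    stop("'fold_threshold' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(min_nonblank_fraction) || length(min_nonblank_fraction) != 1 ||
      min_nonblank_fraction <= 0 || min_nonblank_fraction > 1) {
    stop("'min_nonblank_fraction' must be in (0, 1]", call. = FALSE)
  }
  if (!blank_column %in% colnames(metadata)) {
    stop(sprintf("blank column '%s' not in metadata; available: %s",
                 blank_column, paste(colnames(metadata), collapse = ", ")),
         call. = FALSE)
  }
  ids <- rownames(table)
  if (!all(ids %in% rownames(metadata))) {
    stop("metadata lacks sample(s): ",
         paste(setdiff(ids, rownames(metadata)), collapse = ", "),
         call. = FALSE)
  }
  is_blank <- metadata[ids, blank_column] == blank_value
  if (!any(is_blank)) {
    stop("no blank samples found (", blank_column, " == '", blank_value,
         "'); skip the blank filter instead", call. = FALSE)
  }
  if (all(is_blank)) {
    stop("no non-blank samples: cannot apply blank filter", call. = FALSE)
  }
  blank_mean <- colMeans(table[is_blank, , drop = FALSE])
  nonblank <- table[!is_blank, , drop = FALSE]
  exceeds <- sweep(nonblank, 2, fold_threshold * blank_mean, `>`)
  frac <- colMeans(exceeds)
  keep <- frac >= min_nonblank_fraction
  report <- structure(list(
    n_features_before = ncol(table),
    n_features_after = sum(keep),
    n_removed = sum(!keep),
    retained_fraction = sum(keep) / ncol(table),
    removed_feature_ids = colnames(table)[!keep]
  ), class = "filter_report")
  filtered <- rebuild_table(table[, keep, drop = FALSE], table)
  list(table = filtered, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Blank filter: removed %d of %d features (retained %d, %.1f%%)\n",
              x$n_removed, x$n_features_before, x$n_features_after,
              100 * x$retained_fraction))
  invisible(x)
}

#' Total ion current (TIC) normalization
#'
#' Divides every intensity by its sample's total summed intensity, so each
#' output row sums to 1. Standard first-line normalization for LC-MS feature
#' tables with comparable ionization efficiency across samples.
#'
#' @param table a [feature_table()] of non-negative intensities.
#' @return the row-normalized [feature_table()].
#' @export
normalize_tic <- function(table) {
  table <- as_feature_table(table)
  check_nonnegative(unclass(table), "normalize_tic")
  tic <- rowSums(table)
  if (any(tic <= 0)) {
    stop("sample(s) with zero total intensity: ",
         paste(rownames(table)[tic <= 0], collapse = ", "), call. = FALSE)
  }
  rebuild_table(unclass(table) / tic, table)
}

#' Probabilistic quotient normalization (PQN)
#'
#' Corrects per-sample dilution by the median fold change against a reference
#' spectrum: (1) TIC-normalize each sample; (2) build the reference as the
#' per-feature median across all TIC-normalized samples; (3) for each sample
#' form quotients x_j / r_j over features where both the sample and the
#' reference are positive; (4) divide the TIC-normalized row by the median
#' quotient. Multiplying a sample by any positive constant leaves its PQN
#' output unchanged.
#'
#' @param table a [feature_table()] of non-negative intensities, >= 2 samples.
#' @return the PQN-normalized [feature_table()].
#' @export
normalize_pqn <- function(table) {
  table <- normalize_tic(table)
  if (nrow(table) < 2L) {
    stop("PQN needs at least 2 samples to form a reference spectrum",
         call. = FALSE)
  }
  vals <- unclass(table)
  ref <- apply(vals, 2, stats::median)
  out <- vals
  for (i in seq_len(nrow(vals))) {
    use <- ref > 0 & vals[i, ] > 0
    if (!any(use)) {
      stop("sample '", rownames(vals)[i],
           "' shares no positive feature with the reference spectrum",
           call. = FALSE)
    }
    d <- stats::median(vals[i, use] / ref[use])
    out[i, ] <- vals[i, ] / d
  }
  rebuild_table(out, table)
}

#' Auto-scaling (unit variance scaling)
#'
#' Centers each feature column and divides by its sample standard deviation
#' (denominator n - 1), giving every feature mean 0 and variance 1 so that
#' high-intensity features no longer dominate downstream distances. Constant
#' columns become all-zero with a warning.
#'
#' @param table a [feature_table()] with >= 2 samples.
#' @return the scaled [feature_table()] (values may be negative).
#' @export
scale_auto <- function(table) {
  scale_by(table, function(s) s)
}

#' Pareto scaling
#'
#' Centers each feature column and divides by the square root of its sample
#' standard deviation, damping dominant features while preserving more of the
#' original data structure than auto-scaling. Constant columns become
#' all-zero with a warning.
#'
#' @inheritParams scale_auto
#' @return the scaled [feature_table()].
#' @export
scale_pareto <- function(table) {
  scale_by(table, sqrt)
}

scale_by <- function(table, denom_fun) {
  table <- as_feature_table(table)
  if (nrow(table) < 2L) {
    stop("scaling needs at least 2 samples", call. = FALSE)
  }
  vals <- unclass(table)
  mu <- colMeans(vals)
  s <- apply(vals, 2, stats::sd)
  const <- s == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) set to zero under scaling: ",
            paste(utils::head(colnames(vals)[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ..." else "", call. = FALSE)
  }
  denom <- ifelse(const, 1, denom_fun(s))
  out <- sweep(sweep(vals, 2, mu, `-`), 2, denom, `/`)
  out[, const] <- 0
  rebuild_table(out, table)
}

#' Run the full preprocessing chain
#'
#' Applies, in fixed order: optional blank filter, then normalization
#' (`"tic"`, `"pqn"` or `"none"`), then scaling (`"auto"`, `"pareto"` or
#' `"none"`). `"none"` at either stage is the identity, supporting tables
#' already normalized or scaled elsewhere (e.g. by internal standards).
#'
#' @param table a [feature_table()] of raw non-negative intensities.
#' @param metadata metadata data.frame aligned with `table` (needed only when
#'   the filter is enabled).
#' @param filter `NULL` to skip the blank filter, otherwise a list with
#'   `blank_column`, `blank_value` and optional `fold_threshold`,
#'   `min_nonblank_fraction` (see [blank_filter()]).
#' @param normalization one of `"tic"`, `"pqn"`, `"none"`.
#' @param scaling one of `"auto"`, `"pareto"`, `"none"`.
#' @return list with the processed `table` and the filter `report`
#'   (`NULL` when the filter was skipped).
#' @export
preprocess <- function(table, metadata = NULL, filter = NULL,
                       normalization = c("none", "tic", "pqn"),
                       scaling = c("none", "auto", "pareto")) {
  normalization <- match.arg(normalization)
  scaling <- match.arg(scaling)
  table <- as_feature_table(table)
  report <- NULL
  if (!is.null(filter)) {
    if (is.null(metadata)) {
      stop("metadata is required when the blank filter is enabled", call. = FALSE)
    }
    stopifnot(is.list(filter))
    args <- filter[intersect(names(filter),
                             c("fold_threshold", "min_nonblank_fraction"))]
    res <- do.call(blank_filter,
                   c(list(table = table, metadata = metadata,
                          blank_column = filter$blank_column,
                          blank_value = filter$blank_value), args))
    table <- res$table
    report <- res$report
  }
  table <- switch(normalization,
                  none = table,
                  tic = normalize_tic(table),
                  pqn = normalize_pqn(table))
  table <- switch(scaling,
                  none = table,
                  auto = scale_auto(table),
                  pareto = scale_pareto(table))
  list(table = table, report = report)
}
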