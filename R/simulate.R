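# Synthetic LC-MS/MS feature tables with the statistical structure the
# pipeline assumes: tagged blanks, contaminant features enriched in blanks,
# and sparse group-structured biological features with lognormal intensities.

#' Specification of a synthetic feature-table fixture
#'
#' Defines the generative model for [simulate_feature_table()]. Intensities
#' are lognormal (the standard model for LC-MS peak areas) with multiplicative
#' group effects. Contaminant features are drawn at full intensity in blank
#' samples and attenuated tenfold in biological samples; biological features
#' appear only at trace level in blanks (a thousandfold attenuation,
#' emulating carry-over), and each is a marker of one group, where its
#' intensity is multiplied by `effect_size`. Zeros are injected into the
#' biological block at rate `sparsity`.
#'
#' @param n_blank number of blank samples (>= 0), default 4.
#' @param n_groups number of biological groups, default 3.
#' @param n_samples_per_group samples per group, default 8.
#' @param n_contaminant_features features enriched in blanks, default 100.
#' @param n_biological_features group-structured features, default 400.
#' @param sparsity fraction of zero cells injected into the biological block,
#'   in \[0, 1), default 0.3.
#' @param effect_size multiplicative group shift (fold) for marker features,
#'   >= 1, default 4.
#' @param noise_sd lognormal sigma (log-scale standard deviation), default 0.5.
#' @param base_log_mean log-scale mean peak area, default `log(1e5)`.
#' @param seed integer seed; one seed governs all draws.
#' @return a validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_blank = 4, n_groups = 3, n_samples_per_group = 8,
                         n_contaminant_features = 100,
                         n_biological_features = 400,
                         sparsity = 0.3, effect_size = 4, noise_sd = 0.5,
                         base_log_mean = log(1e5), seed = 1) {
  spec <- list(n_blank = n_blank, n_groups = n_groups,
               n_samples_per_group = n_samples_per_group,
               n_contaminant_features = n_contaminant_features,
               n_biological_features = n_biological_features,
               sparsity = sparsity, effect_size = effect_size,
               noise_sd = noise_sd, base_log_mean = base_log_mean, seed = seed)
  counts <- spec[c("n_groups", "n_samples_per_group",
                   "n_contaminant_features", "n_biological_features")]
  if (any(vapply(counts, function(v) !is.numeric(v) || v < 1, logical(1)))) {
    stop("group/sample/feature counts must all be >= 1", call. = FALSE)
  }
  if (!is.numeric(n_blank) || n_blank < 0) {
    stop("'n_blank' must be >= 0", call. = FALSE)
  }
  if (sparsity < 0 || sparsity >= 1) stop("'sparsity' must be in [0, 1)", call. = FALSE)
  if (effect_size < 1) stop("'effect_size' must be >= 1", call. = FALSE)
  if (noise_sd <= 0) stop("'noise_sd' must be positive", call. = FALSE)
  structure(spec, class = "fixture_spec")
}

#' Simulate a feature table with blanks and group structure
#'
#' Draws a synthetic samples x features intensity table, metadata with a
#' `sample_type` column tagging blanks and a `group` column, and a ground
#' truth labelling each feature `contaminant` or `biological` and giving the
#' marker group of each biological feature. The same seed always reproduces
#' the same table.
#'
#' @param spec a [fixture_spec()].
#' @return list with `table` (a [feature_table()] with mz/rt annotations),
#'   `metadata` (data.frame, id column attribute `sample_id`), and
#'   `ground_truth` (data.frame with `feature_id`, `type`, `marker_group`).
#' @examples
#' sim <- simulate_feature_table(fixture_spec(seed = 7))
#' sim$table
#' table(sim$ground_truth$type)
#' @export
simulate_feature_table <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n_bio_samples <- spec$n_groups * spec$n_samples_per_group
  n_samples <- spec$n_blank + n_bio_samples
  n_features <- spec$n_contaminant_features + spec$n_biological_features

  sample_ids <- c(
    if (spec$n_blank > 0) sprintf("blank_%02d", seq_len(spec$n_blank)),
    sprintf("grp%d_s%02d", rep(seq_len(spec$n_groups),
                               each = spec$n_samples_per_group),
            rep(seq_len(spec$n_samples_per_group), spec$n_groups))
  )
  group <- c(rep("blank", spec$n_blank),
             rep(paste0("group", seq_len(spec$n_groups)),
                 each = spec$n_samples_per_group))
  is_blank <- group == "blank"

  feature_ids <- sprintf("F%04d", seq_len(n_features))
  type <- rep(c("contaminant", "biological"),
              c(spec$n_contaminant_features, spec$n_biological_features))
  marker_group <- rep(NA_character_, n_features)
  marker_group[type == "biological"] <-
    paste0("group", rep_len(seq_len(spec$n_groups), spec$n_biological_features))

  # per-feature lognormal baseline
  mu <- stats::rnorm(n_features, spec$base_log_mean, 1)
  vals <- matrix(0, n_samples, n_features,
                 dimnames = list(sample_ids, feature_ids))
  for (j in seq_len(n_features)) {
    noise <- stats::rnorm(n_samples, 0, spec$noise_sd)
    if (type[j] == "contaminant") {
      v <- exp(mu[j] + noise)
      v[!is_blank] <- v[!is_blank] / 10  # attenuated carry-over in samples
    } else {
      shift <- ifelse(group == marker_group[j], log(spec$effect_size), 0)
      v <- exp(mu[j] + shift + noise)
      # trace-level carry-over in blanks (~1/1000 of sample intensity)
      v[is_blank] <- v[is_blank] / 1000
    }
    vals[, j] <- v
  }
  if (spec$sparsity > 0 && spec$n_blank < n_samples) {
    bio_cols <- which(type == "biological")
    drop <- matrix(stats::runif(n_bio_samples * length(bio_cols)) < spec$sparsity,
                   n_bio_samples, length(bio_cols))
    sub <- vals[!is_blank, bio_cols, drop = FALSE]
    sub[drop] <- 0
    vals[!is_blank, bio_cols] <- sub
  }

  annotations <- data.frame(
    mz = round(stats::runif(n_features, 100, 1200), 4),
    rt = round(stats::runif(n_features, 10, 600), 2)
  )
  metadata <- data.frame(
    sample_type = ifelse(is_blank, "blank", "biological"),
    group = group,
    row.names = sample_ids,
    stringsAsFactors = FALSE
  )
  attr(metadata, "id_column") <- "sample_id"
  list(
    table = feature_table(vals, annotations = annotations),
    metadata = metadata,
    ground_truth = data.frame(feature_id = feature_ids, type = type,
                              marker_group = marker_group,
                              stringsAsFactors = FALSE)
  )
}

#' Write a simulated fixture in the GNPS quantification dialect
#'
#' Emits the files the readers consume end-to-end: a feature-per-row
#' quantification CSV whose sample columns carry the `.mzML Peak area`
#' decoration, a metadata TSV, and (when ground truth is supplied) a JSON
#' sidecar labelling each feature.
#'
#' @param table a [feature_table()].
#' @param metadata metadata data.frame.
#' @param dir output directory (created if needed).
#' @param ground_truth optional ground-truth data.frame from
#'   [simulate_feature_table()].
#' @return named character vector of the paths written.
#' @export
write_gnps_dialect <- function(table, metadata, dir, ground_truth = NULL) {
  table <- as_feature_table(table)
  if (ncol(table) == 0L || nrow(table) == 0L) {
    stop("cannot write an empty feature table", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- feature_annotations(table)
  mz <- if (!is.null(ann) && "mz" %in% colnames(ann)) ann$mz else
    seq_len(ncol(table))
  rt <- if (!is.null(ann) && "rt" %in% colnames(ann)) ann$rt else
    seq_len(ncol(table))
  quant_path <- file.path(dir, "feature_table.csv")
  header <- paste(c("row ID", "row m/z", "row retention time",
                    paste0(rownames(table), ".mzML Peak area")), collapse = ",")
  rows <- vapply(seq_len(ncol(table)), function(j) {
    paste(c(colnames(table)[j], fmt12(mz[j]), fmt12(rt[j]),
            fmt12(table[, j])), collapse = ",")
  }, character(1))
  write_lines_safely(c(header, rows), quant_path)
  meta_path <- file.path(dir, "metadata.tsv")
  write_metadata(metadata, meta_path)
  paths <- c(table = quant_path, metadata = meta_path)
  if (!is.null(ground_truth)) {
    gt_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(ground_truth, gt_path, dataframe = "columns",
                         na = "null")
    paths <- c(paths, ground_truth = gt_path)
  }
  paths
}
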