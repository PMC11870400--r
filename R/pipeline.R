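# End-to-end orchestration: read -> align -> preprocess -> distances -> PCoA
# -> exports. One validated config object describes a full analysis run.

#' Build a validated pipeline configuration
#'
#' Collects every parameter of one analysis run. Enumerations are validated
#' here, before any I/O. Defaults follow the showcase configuration for
#' LC-MS/MS feature tables: TIC normalization, auto-scaling and Bray-Curtis
#' dissimilarity.
#'
#' @param table_path path to the feature table.
#' @param metadata_path path to the metadata file.
#' @param id_column metadata sample-id column, default `"sample_id"`.
#' @param dialect `"gnps"` (mzMine/GNPS quantification CSV),
#'   `"plain_samples"` (samples in rows) or `"plain_features"`.
#' @param blank_column,blank_value metadata column/value tagging blank
#'   samples (needed when `filter_enabled` or `drop_blanks`).
#' @param filter_enabled apply the blank filter? default `TRUE`.
#' @param fold_threshold,min_nonblank_fraction blank-filter parameters, see
#'   [blank_filter()].
#' @param drop_blanks drop blank samples after filtering, before ordination?
#'   default `FALSE` (blanks stay visible in the plot).
#' @param normalization `"tic"`, `"pqn"` or `"none"`.
#' @param scaling `"auto"`, `"pareto"` or `"none"`.
#' @param metric one of [dissimilarity_metrics()].
#' @param num_axes axes kept in the ordination result and file, `NULL` for
#'   the full positive spectrum.
#' @param color_by,shape_by metadata columns for the scatter export
#'   (`color_by = NULL` falls back to the first metadata column).
#' @param output_dir directory for all artifacts.
#' @param seed integer seed recorded with the run.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(table_path, metadata_path,
                            id_column = "sample_id",
                            dialect = c("gnps", "plain_samples", "plain_features"),
                            blank_column = NULL, blank_value = "blank",
                            filter_enabled = TRUE,
                            fold_threshold = 3, min_nonblank_fraction = 0.9,
                            drop_blanks = FALSE,
                            normalization = c("tic", "pqn", "none"),
                            scaling = c("auto", "pareto", "none"),
                            metric = "braycurtis",
                            num_axes = NULL,
                            color_by = NULL, shape_by = NULL,
                            output_dir = "metord_output", seed = 1) {
  dialect <- match.arg(dialect)
  normalization <- match.arg(normalization)
  scaling <- match.arg(scaling)
  if (!metric %in% dissimilarity_metrics()) {
    stop("unknown metric '", metric, "'; valid metrics: ",
         paste(dissimilarity_metrics(), collapse = ", "), call. = FALSE)
  }
  if ((filter_enabled || drop_blanks) && is.null(blank_column)) {
    stop("'blank_column' is required when the blank filter or drop_blanks is enabled",
         call. = FALSE)
  }
  structure(list(
    table_path = table_path, metadata_path = metadata_path,
    id_column = id_column, dialect = dialect,
    blank_column = blank_column, blank_value = blank_value,
    filter_enabled = isTRUE(filter_enabled),
    fold_threshold = fold_threshold,
    min_nonblank_fraction = min_nonblank_fraction,
    drop_blanks = isTRUE(drop_blanks),
    normalization = normalization, scaling = scaling, metric = metric,
    num_axes = num_axes, color_by = color_by, shape_by = shape_by,
    output_dir = output_dir, seed = seed
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; `overrides`
#' (e.g. parsed CLI flags) take precedence over file values.
#'
#' @param path YAML file path.
#' @param overrides named list of values overriding the file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Reads the feature table and metadata, aligns them, applies the
#' preprocessing chain, computes the dissimilarity matrix and the PCoA, and
#' writes all artifacts into `config$output_dir`: the processed table
#' (`filtered_table.tsv`), the filter report (`filter_report.json`), the
#' distance matrix (`distance_matrix.tsv`), the ordination file
#' (`ordination.txt`), the interactive scatter (`scatter.html`) and a run log
#' (`run_log.txt`) recording all parameters, stage dimensions and the
#' features-removed count. The run is deterministic given the config and
#' inputs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the output `paths`, the processed `table`,
#'   the filter `report`, the `distances` and the `ordination`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("metord run (%s)", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 "parameters:",
                 vapply(setdiff(names(config), c("")), function(k) {
                   sprintf("  %s: %s", k,
                           paste(format(config[[k]]), collapse = ","))
                 }, character(1)))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s (check the corresponding inputs/parameters)",
                   name, conditionMessage(e)), call. = FALSE)
    })
  }

  table <- stage("read_table", switch(config$dialect,
    gnps = read_gnps_quant_table(config$table_path),
    plain_samples = read_plain_table(config$table_path, "samples_in_rows"),
    plain_features = read_plain_table(config$table_path, "features_in_rows")))
  metadata <- stage("read_metadata",
                    read_metadata(config$metadata_path, config$id_column))
  aligned <- stage("align", align_samples(table, metadata))
  table <- aligned$table
  metadata <- aligned$metadata
  log_lines <- c(log_lines, sprintf("input: %d samples x %d features",
                                    nrow(table), ncol(table)))

  filter <- if (config$filter_enabled) {
    list(blank_column = config$blank_column, blank_value = config$blank_value,
         fold_threshold = config$fold_threshold,
         min_nonblank_fraction = config$min_nonblank_fraction)
  }
  pre <- stage("preprocess",
               preprocess(table, metadata, filter = filter,
                          normalization = config$normalization,
                          scaling = config$scaling))
  table <- pre$table
  report <- pre$report
  if (!is.null(report)) {
    log_lines <- c(log_lines,
                   sprintf("blank filter: removed %d of %d features (%d retained)",
                           report$n_removed, report$n_features_before,
                           report$n_features_after))
  }
  if (config$drop_blanks) {
    keep <- metadata[rownames(table), config$blank_column] != config$blank_value
    table <- rebuild_table(unclass(table)[keep, , drop = FALSE], table)
    log_lines <- c(log_lines, sprintf("dropped %d blank sample(s) before ordination",
                                      sum(!keep)))
  }
  log_lines <- c(log_lines, sprintf("processed: %d samples x %d features",
                                    nrow(table), ncol(table)))

  dm <- stage("distances", pairwise_distances(table, config$metric))
  ord <- stage("pcoa", pcoa(dm, num_axes = config$num_axes))
  log_lines <- c(log_lines,
                 sprintf("pcoa: %d positive axes, negative eigenvalue mass %.6g",
                         length(ord$proportion_explained),
                         ord$negative_eigenvalue_mass))

  paths <- c(
    filtered_table = file.path(config$output_dir, "filtered_table.tsv"),
    filter_report = file.path(config$output_dir, "filter_report.json"),
    distance_matrix = file.path(config$output_dir, "distance_matrix.tsv"),
    ordination = file.path(config$output_dir, "ordination.txt"),
    scatter = file.path(config$output_dir, "scatter.html"),
    run_log = file.path(config$output_dir, "run_log.txt")
  )
  stage("write_outputs", {
    write_plain_table(table, paths[["filtered_table"]])
    jsonlite::write_json(
      if (is.null(report)) list(filter_enabled = FALSE) else
        list(filter_enabled = TRUE,
             n_features_before = report$n_features_before,
             n_features_after = report$n_features_after,
             n_removed = report$n_removed,
             retained_fraction = report$retained_fraction,
             removed_feature_ids = report$removed_feature_ids),
      paths[["filter_report"]], auto_unbox = TRUE, digits = NA)
    write_distance_matrix(dm, paths[["distance_matrix"]])
    write_ordination(ord, paths[["ordination"]])
    color_by <- config$color_by %||% colnames(metadata)[1]
    render_scatter(ord, metadata, color_by = color_by,
                   shape_by = config$shape_by, path = paths[["scatter"]],
                   title = sprintf("PCoA (%s)", config$metric))
    writeLines(log_lines, paths[["run_log"]])
  })
  invisible(list(paths = paths, table = table, report = report,
                 distances = dm, ordination = ord))
}
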