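# Tabular readers/writers: GNPS/mzMine quantification tables, plain tables,
# metadata, distance matrices and ordination files. All numeric output uses 12
# significant digits so every writer/reader pair round-trips to 1e-12.

GNPS_REQUIRED_COLUMNS <- c("row ID", "row m/z", "row retention time")

# 15 significant digits: enough for 1e-12-relative round-trips
fmt12 <- function(x) sprintf("%.15g", x)

sniff_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

read_char_table <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  df
}

# Parse a character matrix of intensities, reporting the first offending cell
# (1-based data row, column name) on non-numeric input. Empty cells become 0.
parse_intensities <- function(chr, path) {
  chr[is.na(chr) | chr == ""] <- "0"
  num <- suppressWarnings(array(as.numeric(chr), dim = dim(chr),
                                dimnames = dimnames(chr)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric intensity '%s' at data row %d, column '%s' of %s",
                 chr[bad[1], bad[2]], bad[1], colnames(chr)[bad[2]], path),
         call. = FALSE)
  }
  num
}

#' Read a GNPS/mzMine feature quantification table
#'
#' Parses the feature-per-row CSV dialect exported by mzMine and the GNPS
#' feature-based molecular networking workflow: mandatory columns `row ID`,
#' `row m/z` and `row retention time` followed by one peak-area column per
#' sample. The result is transposed into the canonical samples x features
#' orientation. Sample ids are the per-sample column headers with one trailing
#' `" Peak area"` token and one `.mzML`/`.mzXML` extension (case-insensitive)
#' stripped, so that they match typical metadata sample ids.
#'
#' Empty cells are stored as 0 (feature tables are sparse); m/z and retention
#' time are kept as feature annotations.
#'
#' @param path path to the CSV file.
#' @return a [feature_table()] with `mz` and `rt` feature annotations.
#' @export
read_gnps_quant_table <- function(path) {
  df <- read_char_table(path, ",")
  # mzMine exports often end rows with a trailing comma -> drop empty columns
  df <- df[, !(colnames(df) == "" | grepl("^Unnamed", colnames(df))), drop = FALSE]
  missing <- setdiff(GNPS_REQUIRED_COLUMNS, colnames(df))
  if (length(missing)) {
    stop("not a GNPS/mzMine quantification table: missing column(s) ",
         paste(sprintf("'%s'", missing), collapse = ", "), " in ", path,
         call. = FALSE)
  }
  feature_ids <- df[["row ID"]]
  if (anyDuplicated(feature_ids)) {
    stop("duplicate 'row ID' value: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }
  mz <- suppressWarnings(as.numeric(df[["row m/z"]]))
  rt <- suppressWarnings(as.numeric(df[["row retention time"]]))
  sample_cols <- setdiff(colnames(df), GNPS_REQUIRED_COLUMNS)
  if (!length(sample_cols)) {
    stop("quantification table has no sample columns: ", path, call. = FALSE)
  }
  chr <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(chr) <- feature_ids
  vals <- parse_intensities(chr, path)
  if (nrow(vals) == 0L) stop("empty quantification table: ", path, call. = FALSE)
  sample_ids <- canonicalize_sample_names(sample_cols)
  values <- t(vals)
  rownames(values) <- sample_ids
  check_nonnegative(values, path)
  feature_table(values, annotations = data.frame(mz = mz, rt = rt))
}

# Strip one trailing " Peak area" token and one mzML/mzXML extension.
canonicalize_sample_names <- function(x) {
  x <- sub(" Peak area$", "", x)
  sub("\\.(mzML|mzXML)$", "", x, ignore.case = TRUE)
}

#' Read a plain samples-by-features table
#'
#' Reads a simple delimited table with one id column (the first) and a numeric
#' body, in either orientation. Comma/tab is inferred from the file extension
#' (`.csv` vs `.tsv`/`.txt`) unless `sep` is given. Empty cells become 0;
#' negative values are rejected because raw intensities must be non-negative.
#'
#' @param path path to the file.
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`.
#' @param sep optional field delimiter overriding extension-based inference.
#' @return a [feature_table()] in samples x features orientation.
#' @export
read_plain_table <- function(path,
                             orientation = c("samples_in_rows", "features_in_rows"),
                             sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- sniff_sep(path, sep)
  df <- read_char_table(path, sep)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("empty or id-only table: ", path, call. = FALSE)
  }
  ids <- df[[1]]
  chr <- as.matrix(df[, -1, drop = FALSE])
  rownames(chr) <- ids
  vals <- parse_intensities(chr, path)
  if (orientation == "features_in_rows") vals <- t(vals)
  check_nonnegative(vals, path)
  feature_table(vals)
}

#' Write a feature table as a plain delimited file
#'
#' Samples in rows, features in columns, first column `sample_id`. Values are
#' written with 12 significant digits so [read_plain_table()] round-trips.
#'
#' @param table a [feature_table()].
#' @param path output path; delimiter inferred from the extension unless `sep`
#'   is given.
#' @param sep optional field delimiter.
#' @return `path`, invisibly.
#' @export
write_plain_table <- function(table, path, sep = NULL) {
  table <- as_feature_table(table)
  sep <- sniff_sep(path, sep)
  header <- paste(c("sample_id", colnames(table)), collapse = sep)
  rows <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(rownames(table)[i], fmt12(table[i, ])), collapse = sep)
  }, character(1))
  write_lines_safely(c(header, rows), path)
  invisible(path)
}

#' Read sample metadata
#'
#' Reads a delimited metadata file (tab by default) and returns a data.frame
#' of per-sample attributes, all kept verbatim as strings, with sample ids as
#' row names. The id column's name is remembered in the `"id_column"`
#' attribute so [write_metadata()] can restore it.
#'
#' @param path path to the metadata file.
#' @param id_column name of the column holding sample identifiers.
#' @param sep optional field delimiter (default inferred; tab for `.tsv`/`.txt`).
#' @return a data.frame with one row per sample.
#' @export
read_metadata <- function(path, id_column, sep = NULL) {
  sep <- sniff_sep(path, sep)
  df <- read_char_table(path, sep)
  if (!id_column %in% colnames(df)) {
    stop(sprintf("id column '%s' not found; available columns: %s",
                 id_column, paste(colnames(df), collapse = ", ")),
         call. = FALSE)
  }
  ids <- df[[id_column]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample id in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out <- df[, setdiff(colnames(df), id_column), drop = FALSE]
  rownames(out) <- ids
  attr(out, "id_column") <- id_column
  out
}

#' Write sample metadata
#'
#' @param metadata a data.frame as returned by [read_metadata()].
#' @param path output path.
#' @param sep optional field delimiter.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path, sep = NULL) {
  sep <- sniff_sep(path, sep)
  id_column <- attr(metadata, "id_column")
  if (is.null(id_column)) id_column <- "sample_id"
  header <- paste(c(id_column, colnames(metadata)), collapse = sep)
  rows <- vapply(seq_len(nrow(metadata)), function(i) {
    paste(c(rownames(metadata)[i], as.character(unlist(metadata[i, ], use.names = FALSE))),
          collapse = sep)
  }, character(1))
  write_lines_safely(c(header, rows), path)
  invisible(path)
}

#' Align a feature table and metadata on shared samples
#'
#' Restricts both objects to the intersection of their sample ids, in the
#' table's order, and reports which ids were dropped from each side.
#'
#' @param table a [feature_table()].
#' @param metadata a metadata data.frame (sample ids as row names).
#' @return a list with elements `table`, `metadata`, `dropped_table_ids`,
#'   `dropped_metadata_ids`.
#' @export
align_samples <- function(table, metadata) {
  table <- as_feature_table(table)
  shared <- intersect(rownames(table), rownames(metadata))
  if (!length(shared)) {
    stop("no sample ids shared between feature table and metadata", call. = FALSE)
  }
  dropped_t <- setdiff(rownames(table), shared)
  dropped_m <- setdiff(rownames(metadata), shared)
  if (length(dropped_t)) {
    message("align: dropping ", length(dropped_t), " table sample(s): ",
            paste(dropped_t, collapse = ", "))
  }
  if (length(dropped_m)) {
    message("align: dropping ", length(dropped_m), " metadata sample(s): ",
            paste(dropped_m, collapse = ", "))
  }
  out_meta <- metadata[shared, , drop = FALSE]
  attr(out_meta, "id_column") <- attr(metadata, "id_column")
  list(table = rebuild_table(table[shared, , drop = FALSE], table),
       metadata = out_meta,
       dropped_table_ids = dropped_t,
       dropped_metadata_ids = dropped_m)
}

#' Write an ordination result in the ecology text format
#'
#' Writes the block-structured ordination exchange format used by ecology and
#' omics tools: an `Eigvals` block, a `Proportion explained` block, and a
#' `Site` block of per-sample coordinates, tab-separated, with blank lines
#' between blocks. Only the axes retained in the result's coordinates are
#' written.
#'
#' @param result a [pcoa()]/[pca()] result of class `metord_ord`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ordination <- function(result, path) {
  if (!inherits(result, "metord_ord")) {
    stop("'result' must be a 'metord_ord' ordination result", call. = FALSE)
  }
  k <- ncol(result$coordinates)
  n <- nrow(result$coordinates)
  if (is.null(k) || k == 0L || n == 0L) {
    stop("ordination result has no axes/samples to write", call. = FALSE)
  }
  eig <- result$eigenvalues[seq_len(k)]
  prop <- result$proportion_explained[seq_len(k)]
  lines <- c(
    paste(c("Eigvals", k), collapse = "\t"),
    paste(fmt12(eig), collapse = "\t"),
    "",
    paste(c("Proportion explained", k), collapse = "\t"),
    paste(fmt12(prop), collapse = "\t"),
    "",
    paste(c("Site", n, k), collapse = "\t"),
    vapply(seq_len(n), function(i) {
      paste(c(result$ids[i], fmt12(result$coordinates[i, ])), collapse = "\t")
    }, character(1))
  )
  write_lines_safely(lines, path)
  invisible(path)
}

#' Read an ordination file written by [write_ordination()]
#'
#' @param path path to the ordination text file.
#' @return a list with `eigenvalues`, `proportion_explained`, `ids` and
#'   `coordinates`.
#' @export
read_ordination <- function(path) {
  lines <- readLines(path)
  block_at <- function(name) {
    i <- grep(paste0("^", name, "\t"), lines)
    if (!length(i)) stop("ordination file lacks block '", name, "': ", path,
                         call. = FALSE)
    i[1]
  }
  i_eig <- block_at("Eigvals")
  eig <- as.numeric(strsplit(lines[i_eig + 1L], "\t", fixed = TRUE)[[1]])
  i_prop <- block_at("Proportion explained")
  prop <- as.numeric(strsplit(lines[i_prop + 1L], "\t", fixed = TRUE)[[1]])
  i_site <- block_at("Site")
  hdr <- strsplit(lines[i_site], "\t", fixed = TRUE)[[1]]
  n <- as.integer(hdr[2]); k <- as.integer(hdr[3])
  site <- strsplit(lines[i_site + seq_len(n)], "\t", fixed = TRUE)
  ids <- vapply(site, `[[`, character(1), 1L)
  coords <- t(vapply(site, function(r) as.numeric(r[-1]), numeric(k)))
  rownames(coords) <- ids
  list(eigenvalues = eig, proportion_explained = prop, ids = ids,
       coordinates = coords)
}

#' Write a distance matrix as a square TSV
#'
#' @param dm a [pairwise_distances()] result (`distance_matrix`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- unclass_distance(dm)
  if (nrow(m) == 0L) stop("empty distance matrix", call. = FALSE)
  header <- paste(c("", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt12(m[i, ])), collapse = "\t")
  }, character(1))
  write_lines_safely(c(header, rows), path)
  invisible(path)
}

#' Read a square TSV distance matrix
#'
#' @param path path written by [write_distance_matrix()].
#' @return a `distance_matrix` object.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          row.names = 1, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!identical(rownames(m), colnames(m))) {
    stop("distance matrix ids differ between rows and columns: ", path,
         call. = FALSE)
  }
  new_distance_matrix(m, metric = "file")
}

write_lines_safely <- function(lines, path) {
  tryCatch(writeLines(lines, path),
           error = function(e) stop("failed to write '", path, "': ",
                                    conditionMessage(e), call. = FALSE),
           warning = function(w) stop("failed to write '", path, "': ",
                                      conditionMessage(w), call. = FALSE))
}
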