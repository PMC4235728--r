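#' Construct a peak table
#'
#' A peak table holds size-called electropherogram peaks: one row per detected
#' fragment, with the sample it came from, the technical replicate, the called
#' fragment length in base pairs and the peak intensity in relative
#' fluorescence units (RFU).
#'
#' @param records data.frame with columns `sample_id`, `replicate_id`,
#'   `size_bp`, `intensity_rfu`.
#' @param provenance free-text source tag recorded as an attribute.
#' @return A `peak_table`, a validated data.frame.
#' @export
peak_table <- function(records, provenance = "unknown") {
  required <- c("sample_id", "replicate_id", "size_bp", "intensity_rfu")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    schema_error(paste0("peak table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  records <- as.data.frame(records)[, required]
  records$sample_id <- as.character(records$sample_id)
  records$replicate_id <- as.character(records$replicate_id)
  records$size_bp <- as.numeric(records$size_bp)
  records$intensity_rfu <- as.numeric(records$intensity_rfu)
  if (any(!nzchar(records$sample_id)) || any(!nzchar(records$replicate_id))) {
    validation_error("sample_id and replicate_id must be non-empty")
  }
  if (any(is.na(records$size_bp)) || any(records$size_bp <= 0)) {
    validation_error("size_bp must be a positive number for every peak")
  }
  if (any(is.na(records$intensity_rfu)) || any(records$intensity_rfu < 0)) {
    validation_error("intensity_rfu must be non-negative for every peak")
  }
  rownames(records) <- NULL
  structure(records, provenance = provenance,
            class = c("peak_table", "data.frame"))
}

#' Read a peak table from delimited text
#'
#' Reads a fragment-analyzer export (tab- or comma-separated, auto-detected
#' from the header line). A dialect mapping translates vendor column names to
#' the canonical schema.
#'
#' @param path file path.
#' @param dialect named character vector mapping canonical names
#'   (`sample_id`, `replicate_id`, `size_bp`, `intensity_rfu`) to the column
#'   names used in the file. Defaults to the canonical names themselves.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path,
                            dialect = c(sample_id = "sample_id",
                                        replicate_id = "replicate_id",
                                        size_bp = "size_bp",
                                        intensity_rfu = "intensity_rfu")) {
  if (!file.exists(path)) empty_input_error(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) empty_input_error(paste0("empty peak table file: ", path))
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  header <- trimws(strsplit(lines[1], sep, fixed = TRUE)[[1]])
  required <- c("sample_id", "replicate_id", "size_bp", "intensity_rfu")
  if (!all(required %in% names(dialect))) {
    schema_error("dialect must name all four canonical peak-table columns")
  }
  idx <- match(unname(dialect[required]), header)
  if (anyNA(idx)) {
    schema_error(paste0("missing column(s) in ", path, ": ",
                        paste(dialect[required][is.na(idx)], collapse = ", ")))
  }
  if (length(lines) == 1) {
    empty_input_error(paste0("peak table has a header but no data rows: ", path))
  }
  data_lines <- lines[-1]
  fields <- strsplit(data_lines, sep, fixed = TRUE)
  n_read <- 0L
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- trimws(fields[[i]])
    if (length(f) < max(idx)) {
      parse_error(sprintf("line %d of %s: expected %d fields, found %d",
                          i + 1L, path, length(header), length(f)))
    }
    size <- suppressWarnings(as.numeric(f[idx[3]]))
    inten <- suppressWarnings(as.numeric(f[idx[4]]))
    if (is.na(size) || is.na(inten)) {
      parse_error(sprintf("line %d of %s: non-numeric size or intensity", i + 1L, path))
    }
    rows[[i]] <- list(sample_id = f[idx[1]], replicate_id = f[idx[2]],
                      size_bp = size, intensity_rfu = inten)
    n_read <- n_read + 1L
  }
  df <- data.frame(
    sample_id = vapply(rows, `[[`, "", "sample_id"),
    replicate_id = vapply(rows, `[[`, "", "replicate_id"),
    size_bp = vapply(rows, `[[`, 0, "size_bp"),
    intensity_rfu = vapply(rows, `[[`, 0, "intensity_rfu"),
    stringsAsFactors = FALSE
  )
  stopifnot(n_read == length(data_lines))
  peak_table(df, provenance = path)
}

#' Write a peak table to TSV
#' @param peaks a [peak_table()].
#' @param path output file.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.table(as.data.frame(peaks), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an OTU table
#'
#' Samples in rows, OTUs in columns. `abundance_kind` distinguishes raw read
#' counts (sequencing) from relative fluorescence intensities (ARISA), where
#' each row sums to one.
#'
#' @param abundance numeric matrix, samples x OTUs, with row and column names.
#' @param abundance_kind `"read_count"` or `"relative_intensity"`.
#' @return An `otu_table` (a matrix with an `abundance_kind` attribute).
#' @export
otu_table <- function(abundance, abundance_kind = c("read_count", "relative_intensity")) {
  abundance_kind <- match.arg(abundance_kind)
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || (ncol(abundance) > 0 && is.null(colnames(abundance)))) {
    validation_error("OTU table needs sample (row) and OTU (column) names")
  }
  if (anyDuplicated(rownames(abundance))) validation_error("duplicate sample ids in OTU table")
  if (anyDuplicated(colnames(abundance))) validation_error("duplicate OTU ids in OTU table")
  if (any(is.na(abundance)) || any(abundance < 0)) {
    validation_error("OTU table entries must be non-negative and non-missing")
  }
  if (abundance_kind == "relative_intensity") {
    rs <- rowSums(abundance)
    bad <- abs(rs - 1) > 1e-9 & rs > 0
    if (any(bad)) {
      validation_error(paste0("relative-intensity rows must sum to 1: ",
                              paste(rownames(abundance)[bad], collapse = ", ")))
    }
    if (any(rs == 0)) {
      warning("all-zero sample row(s) in relative-intensity table: ",
              paste(rownames(abundance)[rs == 0], collapse = ", "))
    }
  }
  structure(abundance, abundance_kind = abundance_kind,
            class = c("otu_table", class(abundance)))
}

#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  kind <- attr(x, "abundance_kind")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "abundance_kind") <- kind
    class(out) <- c("otu_table", class(unclass(out)))
  }
  out
}

#' Abundance kind of an OTU table
#' @param table an [otu_table()].
#' @export
abundance_kind <- function(table) attr(table, "abundance_kind")

#' Read / write an OTU table (TSV, samples in rows)
#'
#' The first column holds sample ids; remaining columns are OTUs. Writing then
#' reading reproduces ids, ordering and values to 1e-12.
#'
#' @param path file path.
#' @param abundance_kind kind recorded on the returned table.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, abundance_kind = c("read_count", "relative_intensity")) {
  abundance_kind <- match.arg(abundance_kind)
  if (!file.exists(path)) empty_input_error(paste0("file not found: ", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) empty_input_error(paste0("empty OTU table: ", path))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) validation_error(paste0("duplicate sample ids in ", path))
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  otu_table(mat, abundance_kind)
}

#' @rdname read_otu_table
#' @param table an [otu_table()].
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table),
                   as.data.frame(unclass(table), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove rare OTUs from a count table
#'
#' Drops OTUs whose total read count across all samples is below `min_count`.
#' With the default of 3 this removes singleton and doubleton clusters, the
#' standard denoising step for pyrosequencing OTU tables.
#'
#' @param table an [otu_table()] of kind `read_count`.
#' @param min_count minimum total count an OTU must reach to be kept.
#' @return The filtered [otu_table()]; sample rows are preserved.
#' @export
remove_rare_otus <- function(table, min_count = 3) {
  if (abundance_kind(table) != "read_count") {
    type_error("remove_rare_otus applies to read-count tables only")
  }
  if (min_count < 1) validation_error("min_count must be >= 1")
  keep <- colSums(table) >= min_count
  out <- unclass(table)[, keep, drop = FALSE]
  otu_table(out, "read_count")
}

#' Read sample metadata (sample -> group)
#'
#' Two-column TSV mapping each sample id to its group label (here: age group).
#'
#' @param path file path.
#' @return A named character vector of class `sample_metadata`: names are
#'   sample ids, values are group labels.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) empty_input_error(paste0("file not found: ", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) empty_input_error(paste0("empty metadata file: ", path))
  sample_metadata(df[[1]], df[[2]])
}

#' Construct sample metadata
#' @param sample_ids character vector of sample ids.
#' @param groups group label per sample.
#' @export
sample_metadata <- function(sample_ids, groups) {
  sample_ids <- as.character(sample_ids)
  groups <- as.character(groups)
  if (anyDuplicated(sample_ids)) {
    validation_error(paste0("duplicate sample id(s) in metadata: ",
                            paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  structure(stats::setNames(groups, sample_ids), class = "sample_metadata")
}

#' @rdname sample_metadata
#' @param meta a `sample_metadata` object.
#' @param path output TSV.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(data.frame(sample_id = names(meta), group = unname(unclass(meta))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Look up groups for a set of samples; missing samples are a join error that
# names the offender.
groups_for <- function(meta, sample_ids) {
  missing <- setdiff(sample_ids, names(meta))
  if (length(missing) > 0) {
    join_error(paste0("sample(s) missing from metadata: ",
                      paste(missing, collapse = ", ")))
  }
  unname(unclass(meta)[sample_ids])
}

#' Read / write a labeled square distance matrix (TSV)
#'
#' @param path file path.
#' @return A `dist_matrix` (see [distance_matrix()]).
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) empty_input_error(paste0("file not found: ", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = 1, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  dist_matrix(m, metric = "unknown")
}

#' @rdname read_distance_matrix
#' @param D a `dist_matrix`.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(sample_id = rownames(D),
                   as.data.frame(unclass(D), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a distance matrix object
#'
#' @param m square symmetric numeric matrix with matching dimnames, zero
#'   diagonal and entries in `[0, 1]` for Bray-Curtis.
#' @param metric metric name tag.
#' @export
dist_matrix <- function(m, metric = "bray_curtis") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) validation_error("distance matrix must be square")
  if (is.null(rownames(m))) validation_error("distance matrix needs sample labels")
  colnames(m) <- colnames(m) %||% rownames(m)
  if (!identical(rownames(m), colnames(m))) {
    validation_error("distance matrix row and column labels differ")
  }
  if (max(abs(m - t(m))) > 1e-12) validation_error("distance matrix is not symmetric")
  if (any(abs(diag(m)) > 1e-12)) validation_error("distance matrix diagonal is not zero")
  if (any(m < 0)) validation_error("distances must be non-negative")
  diag(m) <- 0
  m <- (m + t(m)) / 2
  structure(m, metric = metric, class = c("dist_matrix", class(unclass(m))))
}
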