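#' Read an abundance matrix from TSV
#'
#' Expects a tab-separated file with a header row, a first column of feature
#' ids and one numeric column per sample. Ragged rows, duplicate feature ids,
#' negative values and non-numeric entries produce descriptive errors citing
#' the offending line.
#'
#' @param path file path.
#' @param kind,kingdom,level tags for the resulting matrix (see
#'   [abundance_matrix()]).
#' @return an `abund_matrix`.
#' @export
read_abundance <- function(path, kind = "counts", kingdom = "virus", level = "species") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stopf("%s: ragged row at line %d (%d fields, expected %d)", path, bad, nf[bad], nf[1])
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stopf("%s: duplicate feature id '%s'", path, ids[duplicated(ids)][1])
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    for (j in seq_len(ncol(vals))) {
      v <- suppressWarnings(as.numeric(vals[, j]))
      if (anyNA(v) && !all(is.na(vals[, j]))) {
        row <- which(is.na(v))[1]
        stopf("%s: non-numeric value '%s' at line %d", path, vals[row, j], row + 1L)
      }
    }
    vals <- matrix(as.numeric(vals), nrow(vals), ncol(vals), dimnames = dimnames(vals))
  }
  if (anyNA(vals)) {
    row <- which(rowSums(is.na(vals)) > 0)[1]
    stopf("%s: missing value at line %d", path, row + 1L)
  }
  neg <- which(rowSums(vals < 0) > 0)
  if (length(neg)) stopf("%s: negative value at line %d", path, neg[1] + 1L)
  rownames(vals) <- ids
  abundance_matrix(vals, kind = kind, kingdom = kingdom, level = level)
}

#' Write an abundance matrix to TSV
#'
#' Inverse of [read_abundance()]: feature ids in the first column (named
#' `feature`), one column per sample, full numeric precision.
#'
#' @param m an `abund_matrix`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_abundance <- function(m, path) {
  df <- data.frame(feature = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the per-sample metadata (and survival) table
#'
#' @param path TSV with at least `sample` and `group` columns; `time_months`
#'   and `event` columns, when present, describe the ablated subset.
#' @return data frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "group")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample)) stopf("%s: duplicate sample ids", path)
  if ("event" %in% colnames(df)) {
    ev <- df$event[!is.na(df$event)]
    if (length(ev) && !all(ev %in% c(0, 1))) stopf("%s: event must be 0/1", path)
  }
  if ("time_months" %in% colnames(df)) {
    tm <- df$time_months[!is.na(df$time_months)]
    if (any(tm <= 0)) stopf("%s: follow-up times must be positive", path)
  }
  df
}

#' Read the virus taxonomy/host/lifestyle table
#'
#' @param path TSV with `species` plus lineage (`genus`, `family`, `order`),
#'   `host_class`, and lifestyle/marker columns.
#' @return data frame.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"species" %in% colnames(df)) stopf("%s: missing 'species' column", path)
  markers <- intersect(c("marker_1", "marker_2", "marker_3"), colnames(df))
  if (length(markers) && "lifestyle" %in% colnames(df)) {
    flag <- rowSums(as.matrix(df[, markers, drop = FALSE]) > 0, na.rm = TRUE) > 0
    temp <- !is.na(df$lifestyle) & df$lifestyle == "temperate"
    if (any(temp != flag)) {
      stopf("%s: lifestyle 'temperate' must coincide with at least one marker flag", path)
    }
  }
  df
}
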