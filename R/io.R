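# Tab-separated I/O for feature tables, labels, distance matrices and
# embeddings. Numbers are written with 10 significant digits; readers
# validate type invariants and name the offending row/column on failure.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop_fmds("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

num_cols <- function(df, path) {
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn))
        stop_fmds("non-numeric cell in column '", names(df)[j], "' of ", path,
                  " (row ", which(is.na(vn))[1], ")")
      df[[j]] <- vn
    }
    if (anyNA(df[[j]]))
      stop_fmds("missing value in column '", names(df)[j], "' of ", path)
  }
  df
}

#' Read / write a feature table (TSV, samples in rows)
#'
#' The first column holds sample ids; remaining columns are features.
#'
#' @param path file path.
#' @param table a `feature_table`.
#' @param relative logical, validate rows as relative abundances.
#' @return `read_table()` returns a `feature_table`; `write_table()`
#'   invisibly returns `path`.
#' @export
read_table <- function(path, relative = FALSE) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L) stop_fmds("feature table needs an id column plus features: ", path)
  ids <- as.character(df[[1]])
  df <- num_cols(df[-1], path)
  m <- as.matrix(df)
  rownames(m) <- ids
  feature_table(m, relative = relative)
}

#' @rdname read_table
#' @export
write_table <- function(table, path) {
  x <- as_table_matrix(table)
  df <- data.frame(sample_id = rownames(x), check.names = FALSE)
  for (j in seq_len(ncol(x))) df[[colnames(x)[j]]] <- fmt_num(x[, j])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a square distance matrix (TSV)
#'
#' Sample ids appear both as header row and first column, and must agree;
#' asymmetry beyond 1e-12 is an error naming the offending cell.
#'
#' @param path file path.
#' @param D a `dist_matrix`.
#' @param metric metric name recorded on the returned object.
#' @export
read_distance <- function(path, metric = "unknown") {
  df <- read_tsv_checked(path)
  ids <- as.character(df[[1]])
  df <- num_cols(df[-1], path)
  if (ncol(df) != length(ids))
    stop_fmds("distance file not square: ", length(ids), " rows vs ",
              ncol(df), " columns in ", path)
  if (!identical(ids, names(df)))
    stop_fmds("row ids and column headers disagree in ", path, " (first mismatch: '",
              ids[which(ids != names(df))[1]], "')")
  m <- as.matrix(df)
  dimnames(m) <- list(ids, ids)
  dist_matrix(m, metric = metric)
}

#' @rdname read_distance
#' @export
write_distance <- function(D, path) {
  m <- unclass(as_dist_matrix(D))
  df <- data.frame(sample_id = rownames(m), check.names = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- fmt_num(m[, j])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write group labels (TSV: sample_id, group)
#'
#' @param path file path.
#' @param sample_ids if given, labels are checked against and reordered to
#'   this sample ordering; missing or surplus ids are errors.
#' @param labels integer label vector (named by sample id if available).
#' @export
read_labels <- function(path, sample_ids = NULL) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L) stop_fmds("labels file needs columns sample_id, group: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop_fmds("duplicate sample ids in ", path, ": ",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  g <- df[[2]]
  suppressWarnings(gn <- as.integer(as.numeric(g)))
  if (anyNA(gn)) {
    gn <- as.integer(factor(g, levels = unique(g)))
  }
  names(gn) <- ids
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, ids)
    if (length(missing))
      stop_fmds("labels file ", path, " missing sample id(s): ",
                paste(missing, collapse = ", "))
    extra <- setdiff(ids, sample_ids)
    if (length(extra))
      stop_fmds("labels file ", path, " has unknown sample id(s): ",
                paste(extra, collapse = ", "))
    gn <- gn[sample_ids]
  }
  group_labels(gn)
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  ids <- names(labels)
  if (is.null(ids)) ids <- paste0("sample", seq_along(labels))
  utils::write.table(data.frame(sample_id = ids, group = as.integer(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a 2D embedding (TSV: sample_id, dim1, dim2)
#'
#' @param path file path.
#' @param Z an `embedding`.
#' @export
read_embedding <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) != 3L) stop_fmds("embedding file needs columns sample_id, dim1, dim2: ", path)
  ids <- as.character(df[[1]])
  df <- num_cols(df[-1], path)
  embedding(t(as.matrix(df)), sample_ids = ids)
}

#' @rdname read_embedding
#' @export
write_embedding <- function(Z, path) {
  zc <- unclass(as_embedding(Z))
  df <- data.frame(sample_id = colnames(zc),
                   dim1 = fmt_num(zc[1, ]), dim2 = fmt_num(zc[2, ]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
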