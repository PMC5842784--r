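#' SUVR tables: subjects x ROIs matrices of regional tracer uptake
#'
#' A `suvr_table` holds one group's regional FDG uptake ratios: one row per
#' subject, one column per ROI, with subject identifiers as row names. SUVR
#' values are dimensionless ratios (uptake normalized to a reference region,
#' pons-normalized in the motivating design), typically in 0.5--2.0.
#'
#' @param x numeric matrix (subjects x ROIs) or a data frame whose first
#'   column is the subject identifier and whose remaining columns are ROIs.
#' @param group group label carried along to downstream networks.
#' @param subject_ids optional character vector of subject identifiers;
#'   defaults to the row names (or first data-frame column).
#' @return an object of class `suvr_table`: a numeric matrix with
#'   `dimnames = list(subject_ids, roi_labels)` and a `group` attribute.
#' @export
suvr_table <- function(x, group = NA_character_, subject_ids = NULL) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1L]])
    x <- as.matrix(x[-1L])
    rownames(x) <- ids
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("'x' must be a numeric matrix or a data frame with a subject-id column")
  }
  if (!is.null(subject_ids)) rownames(x) <- subject_ids
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("ROI%03d", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate subject identifiers")
  structure(x, group = group, class = c("suvr_table", "matrix", "array"))
}

#' @export
print.suvr_table <- function(x, ...) {
  cat(sprintf("SUVR table: %d subjects x %d ROIs (group: %s)\n",
              nrow(x), ncol(x), attr(x, "group")))
  invisible(x)
}

roi_labels <- function(x) colnames(x)

#' Read / write SUVR tables as delimited text
#'
#' CSV with a header row; the first column is the subject identifier, the
#' remaining columns are ROIs.
#'
#' @param path file path.
#' @param group group label to attach on read.
#' @param table a [suvr_table()].
#' @return `read_suvr_csv()` returns a `suvr_table`; `write_suvr_csv()`
#'   returns `path` invisibly.
#' @export
read_suvr_csv <- function(path, group = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  suvr_table(df, group = group)
}

#' @rdname read_suvr_csv
#' @export
write_suvr_csv <- function(table, path) {
  df <- data.frame(subject_id = rownames(table),
                   as.data.frame(unclass(table)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pool several SUVR tables into one
#'
#' Row-concatenates tables sharing the same ROI columns, preserving subject
#' identity, e.g. to combine subgroups into a single larger group before
#' rebuilding a network.
#'
#' @param tables list of [suvr_table()] objects with identical ROI columns.
#' @param group group label for the pooled table.
#' @return a pooled `suvr_table`.
#' @export
pool_groups <- function(tables, group = "pooled") {
  stopifnot(length(tables) >= 1L)
  ref <- colnames(tables[[1L]])
  for (t in tables) {
    if (!identical(colnames(t), ref)) stop("ROI columns differ across tables")
  }
  if (length(tables) == 1L) return(tables[[1L]])
  ids <- unlist(lapply(tables, rownames), use.names = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate subject_id across tables: ", paste(unique(dup), collapse = ", "))
  }
  pooled <- do.call(rbind, lapply(tables, unclass))
  suvr_table(pooled, group = group)
}
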