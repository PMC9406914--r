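#' Construct a feature table
#'
#' A `feature_table` bundles a numeric feature matrix (rows are voice
#' recordings, columns are named vocal features) with a binary outcome label
#' (1 = case, 0 = healthy control) and a subject identifier. One subject may
#' own several rows (repeated recordings of the sustained vowel), so the
#' subject id is carried separately from the row index.
#'
#' @param x numeric matrix with unique column names; rows are recordings.
#' @param labels binary vector (0/1) of length `nrow(x)`.
#' @param subject_ids vector of subject identifiers of length `nrow(x)`.
#'   Defaults to one subject per row.
#' @param groups optional named character vector mapping feature names to
#'   group tags (e.g. `"mfcc"`, `"tqwt"`).
#' @return an object of class `feature_table` with elements `x`, `labels`,
#'   `subject_ids` and `groups`.
#' @export
#' @examples
#' ft <- feature_table(matrix(rnorm(8), 4, 2,
#'                            dimnames = list(NULL, c("f1", "f2"))),
#'                     labels = c(1, 1, 0, 0))
#' ft
feature_table <- function(x, labels, subject_ids = NULL, groups = NULL) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix", call. = FALSE)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x)))
    stop("feature names must be unique", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x))
    stop("length(labels) must equal nrow(x)", call. = FALSE)
  if (length(labels) && !all(labels %in% c(0L, 1L)))
    stop("labels must contain only 0 and 1", call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(nrow(x)))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(x))
    stop("length(subject_ids) must equal nrow(x)", call. = FALSE)
  if (!is.null(groups)) {
    groups <- groups[colnames(x)[colnames(x) %in% names(groups)]]
  }
  structure(list(x = x, labels = labels, subject_ids = subject_ids,
                 groups = groups),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$x), " recordings x ", ncol(x$x),
      " features\n", sep = "")
  cat("  subjects: ", length(unique(x$subject_ids)),
      "   cases (label 1): ", sum(x$labels),
      "   controls (label 0): ", sum(x$labels == 0L), "\n", sep = "")
  if (!is.null(x$groups))
    cat("  feature groups: ",
        paste(names(table(x$groups)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

#' Subset rows of a feature table
#'
#' @param x a `feature_table`.
#' @param i row index vector.
#' @param ... ignored.
#' @return a `feature_table` with the selected rows.
#' @export
`[.feature_table` <- function(x, i, ...) {
  feature_table(x$x[i, , drop = FALSE], x$labels[i], x$subject_ids[i],
                groups = x$groups)
}

#' Read a feature table from CSV
#'
#' Reads a comma-separated table in the UCI Parkinson's speech dialect: one
#' header row, a subject-id column, a binary class column, and numeric
#' feature columns. The label and id columns are removed from the feature
#' matrix; every remaining column must parse as a real number. The table is
#' expected to be complete: an empty or non-numeric cell is a parse error
#' (reported with its row and column), not an imputation case.
#'
#' @param path path to a CSV file (UTF-8, `.` decimal separator).
#' @param label_column name of the binary class column (default `"class"`).
#' @param id_column name of the subject-id column (default `"id"`).
#' @return a [feature_table].
#' @export
read_feature_table <- function(path, label_column = "class",
                               id_column = "id") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character",
                    na.strings = NULL),
    error = function(e) stop("cannot read '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop("empty feature table: ", path, call. = FALSE)
  for (col in c(label_column, id_column))
    if (!col %in% names(df))
      stop("column '", col, "' not found in ", path,
           " (configure `label_column` / `id_column`)", call. = FALSE)
  feat_names <- setdiff(names(df), c(label_column, id_column))
  if (length(feat_names) == 0L)
    stop("no feature columns in ", path, call. = FALSE)
  x <- matrix(NA_real_, nrow(df), length(feat_names),
              dimnames = list(NULL, feat_names))
  for (j in seq_along(feat_names)) {
    raw <- df[[feat_names[j]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad))
      stop("non-numeric or missing value in column '", feat_names[j],
           "', row ", bad[1L], " (value: '", raw[bad[1L]], "')",
           call. = FALSE)
    x[, j] <- val
  }
  lab <- suppressWarnings(as.integer(df[[label_column]]))
  if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
    stop("label column '", label_column, "' must contain only 0/1",
         call. = FALSE)
  feature_table(x, lab, df[[id_column]])
}

#' Write a feature table to CSV
#'
#' Emits the same dialect [read_feature_table] reads: an `id` column, the
#' feature columns, and a `class` column.
#'
#' @param table a [feature_table].
#' @param path output path.
#' @param label_column,id_column column names to write.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, label_column = "class",
                                id_column = "id") {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(table$subject_ids, as.data.frame(table$x), table$labels,
                   check.names = FALSE)
  names(df) <- c(id_column, colnames(table$x), label_column)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Count missing cells in a feature table
#'
#' Parsing already rejects missing cells, so a table read from disk reports
#' 0; tables constructed in memory may carry `NA`/`NaN` sentinels, which are
#' counted here. Provided for preprocessing-report parity.
#'
#' @param table a [feature_table].
#' @return integer count of missing feature cells.
#' @export
check_missing <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  sum(is.na(table$x))
}
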