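# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. With seed = NULL the current stream is used
# (and consumed).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Largest-remainder apportionment of round(n * fraction) test rows across
# classes: each class gets floor(n_c * fraction), and the remaining units go
# to the classes with the largest fractional remainders. This reproduces
# exact per-class counts (e.g. 141 of 564 positives at fraction 0.25) while
# the total matches round(n * fraction).
apportion_test_counts <- function(class_sizes, fraction) {
  target <- round(sum(class_sizes) * fraction)
  quota <- class_sizes * fraction
  base <- floor(quota)
  extra <- target - sum(base)
  counts <- base
  if (extra > 0) {
    take <- order(quota - base, decreasing = TRUE)[seq_len(extra)]
    counts[take] <- counts[take] + 1L
  } else if (extra < 0) {
    give <- order(quota - base)[seq_len(-extra)]
    counts[give] <- counts[give] - 1L
  }
  as.integer(counts)
}

#' Seeded stratified train/test split
#'
#' Partitions a feature table into disjoint train and test tables while
#' preserving the class proportions. Per-class test counts follow
#' largest-remainder apportionment so that the totals equal
#' `round(n * test_fraction)` exactly: a 756-row table with 564 positives
#' split at 0.25 yields 567 train rows and 189 test rows with 141 positives
#' in the test partition.
#'
#' By default rows (recordings) are split independently, matching the common
#' protocol for this table even though one subject owns several rows. Set
#' `by_subject = TRUE` for a leakage-aware variant that assigns all
#' recordings of one subject to the same side (stratified on the subject's
#' class); per-class row counts are then only approximate.
#'
#' @param table a [feature_table]; each class must have at least 2 rows.
#' @param test_fraction fraction of rows assigned to the test side, in (0,1).
#' @param seed integer seed; equal seeds give identical splits.
#' @param by_subject logical; split whole subjects instead of rows.
#' @return a list with components `train` and `test` (both [feature_table]s)
#'   and `test_idx` (the test row indices in the original table).
#' @export
#' @examples
#' coh <- generate_cohort(spec = cohort_spec(n_cases = 10, n_controls = 6,
#'                                           seed = 1))
#' sp <- stratified_split(coh$table, 0.25, seed = 1)
#' nrow(sp$train$x); nrow(sp$test$x)
stratified_split <- function(table, test_fraction, seed = NULL,
                             by_subject = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  n <- nrow(table$x)
  if (any(table(table$labels) < 2L))
    stop("each class needs at least 2 rows to split", call. = FALSE)

  if (by_subject) {
    subj <- unique(table$subject_ids)
    subj_lab <- table$labels[match(subj, table$subject_ids)]
    classes <- sort(unique(subj_lab))
    counts <- apportion_test_counts(
      as.integer(table(factor(subj_lab, levels = classes))), test_fraction)
    test_subj <- with_seed(seed, {
      picked <- character(0)
      for (i in seq_along(classes))
        picked <- c(picked, sample(subj[subj_lab == classes[i]], counts[i]))
      picked
    })
    test_idx <- which(table$subject_ids %in% test_subj)
  } else {
    classes <- sort(unique(table$labels))
    counts <- apportion_test_counts(
      as.integer(table(factor(table$labels, levels = classes))),
      test_fraction)
    test_idx <- with_seed(seed, {
      idx <- integer(0)
      for (i in seq_along(classes)) {
        pool <- which(table$labels == classes[i])
        idx <- c(idx, sample(pool, counts[i]))
      }
      sort(idx)
    })
  }

  train_idx <- setdiff(seq_len(n), test_idx)
  for (side in list(train_idx, test_idx))
    if (length(unique(table$labels[side])) < 2L)
      stop("split leaves a partition without both classes; ",
           "adjust `test_fraction`", call. = FALSE)
  list(train = table[train_idx], test = table[test_idx],
       test_idx = test_idx)
}
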