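#' Default vocal-feature schema
#'
#' Returns the canonical grouping of the UCI Parkinson's speech feature
#' table: 21 baseline dysphonia measures (5 jitter, 6 shimmer, 5
#' fundamental-frequency, 2 harmonicity, RPDE, DFA, PPE), 11 time-frequency
#' features (3 intensity, 4 formant, 4 bandwidth), 84 MFCC statistics (13
#' cepstral coefficients + log-energy, each with first and second
#' derivatives, summarized by mean and standard deviation: 14 x 3 x 2 = 84),
#' 182 wavelet-transform features, 22 vocal-fold features (3 GQ, 6 GNE,
#' 7 VFER, 6 EMD) and 432 tunable-Q wavelet-transform features, plus one
#' demographic column (gender). The vocal groups sum to 752 columns; with
#' gender the default table is 753 columns wide. Loaders impose no fixed
#' width, since published column totals for this table vary by one or two
#' depending on which bookkeeping columns are counted.
#'
#' @return a `feature_schema`: data frame with columns `group` and `n`.
#' @export
#' @examples
#' default_schema()
default_schema <- function() {
  feature_schema(data.frame(
    group = c("baseline", "time_frequency", "mfcc", "wt", "vocal_fold",
              "tqwt", "demographic"),
    n = c(21L, 11L, 84L, 182L, 22L, 432L, 1L)))
}

#' Construct a feature schema
#'
#' @param groups data frame with character column `group` (unique names) and
#'   integer column `n` (column counts, each >= 1).
#' @return an object of class `feature_schema`.
#' @export
feature_schema <- function(groups) {
  stopifnot(is.data.frame(groups), all(c("group", "n") %in% names(groups)))
  if (anyDuplicated(groups$group)) stop("group names must be unique",
                                        call. = FALSE)
  if (any(groups$n < 1L)) stop("each group needs >= 1 column",
                               call. = FALSE)
  groups$n <- as.integer(groups$n)
  structure(groups, class = c("feature_schema", "data.frame"))
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> ", sum(x$n), " columns in ", nrow(x),
      " groups\n", sep = "")
  print.data.frame(x)
  invisible(x)
}

# Column names for a schema: group_001, group_002, ...
schema_feature_names <- function(schema) {
  unlist(mapply(function(g, n) sprintf("%s_%03d", g, seq_len(n)),
                schema$group, schema$n, SIMPLIFY = FALSE), use.names = FALSE)
}

#' Specify a synthetic cohort
#'
#' Defaults mirror the geometry of the source cohort: 188 case subjects and
#' 64 healthy controls, each contributing three recordings of a sustained
#' vowel, for 756 rows. `n_informative` vocal columns receive a
#' between-class mean shift of `effect_size` (in standard-deviation units);
#' the remainder are class-independent noise. Repeated recordings of one
#' subject share a subject-level random effect with intraclass correlation
#' `within_subject_rho`.
#'
#' @param n_cases number of case (PWP) subjects.
#' @param n_controls number of healthy-control subjects.
#' @param recordings_per_subject recordings per subject.
#' @param n_informative count of class-shifted columns.
#' @param effect_size standardized mean difference planted in informative
#'   columns (>= 0).
#' @param within_subject_rho intraclass correlation of one subject's
#'   repeated recordings, in [0, 1).
#' @param seed integer seed; equal seeds reproduce identical cohorts.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 188L, n_controls = 64L,
                        recordings_per_subject = 3L, n_informative = 30L,
                        effect_size = 1.0, within_subject_rho = 0.5,
                        seed = NULL) {
  stopifnot(n_cases >= 1L, n_controls >= 1L, recordings_per_subject >= 1L,
            n_informative >= 0L, effect_size >= 0,
            within_subject_rho >= 0, within_subject_rho < 1)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 recordings_per_subject = as.integer(recordings_per_subject),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 within_subject_rho = within_subject_rho,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic vocal-biomarker cohort
#'
#' Emulates the shape of the UCI Parkinson's speech feature table without
#' touching audio: Gaussian feature blocks with unit marginal variance, a
#' subject-level random effect giving within-subject correlation
#' `within_subject_rho` across a subject's recordings, and `n_informative`
#' randomly chosen vocal columns whose case/control means differ by
#' `effect_size` standard deviations. The demographic column (if present in
#' the schema) is a per-subject Bernoulli gender indicator drawn with the
#' source cohort's male/female ratios (107/188 for cases, 23/64 for
#' controls) and is never planted as informative beyond that marginal
#' association.
#'
#' @param schema a [feature_schema] (default [default_schema()]).
#' @param spec a [cohort_spec].
#' @return a list of class `ebgwo_cohort` with components `table` (a
#'   [feature_table]) and `truth` (character vector of informative feature
#'   names).
#' @export
#' @examples
#' coh <- generate_cohort(spec = cohort_spec(n_cases = 6, n_controls = 4,
#'                                           n_informative = 3, seed = 7))
#' coh$table
#' coh$truth
generate_cohort <- function(schema = default_schema(),
                            spec = cohort_spec()) {
  stopifnot(inherits(schema, "feature_schema"),
            inherits(spec, "cohort_spec"))
  feat <- schema_feature_names(schema)
  group_of <- rep(schema$group, schema$n)
  names(group_of) <- feat
  vocal <- feat[group_of != "demographic"]
  if (spec$n_informative > length(vocal))
    stop("n_informative (", spec$n_informative, ") exceeds the ",
         length(vocal), " available vocal columns", call. = FALSE)

  n_subj <- spec$n_cases + spec$n_controls
  reps <- spec$recordings_per_subject
  n_rows <- n_subj * reps
  subj_lab <- rep(c(1L, 0L), c(spec$n_cases, spec$n_controls))
  subj_ids <- sprintf("S%03d", seq_len(n_subj))

  with_seed(spec$seed, {
    truth <- if (spec$n_informative > 0)
      sort(sample(vocal, spec$n_informative)) else character(0)

    rho <- spec$within_subject_rho
    p <- length(feat)
    # subject effect b ~ N(0, rho), recording noise e ~ N(0, 1 - rho):
    # marginal variance 1, within-subject correlation rho
    b <- matrix(stats::rnorm(n_subj * p, sd = sqrt(rho)), n_subj, p)
    e <- matrix(stats::rnorm(n_rows * p, sd = sqrt(1 - rho)), n_rows, p)
    x <- b[rep(seq_len(n_subj), each = reps), , drop = FALSE] + e
    colnames(x) <- feat

    shift_cols <- match(truth, feat)
    if (length(shift_cols))
      x[, shift_cols] <- x[, shift_cols] +
        spec$effect_size * rep(subj_lab, each = reps)

    demo <- which(group_of == "demographic")
    if (length(demo)) {
      p_male <- ifelse(subj_lab == 1L, 107 / 188, 23 / 64)
      gender <- stats::rbinom(n_subj, 1L, p_male)
      for (j in demo) x[, j] <- gender[rep(seq_len(n_subj), each = reps)]
    }

    table <- feature_table(x, rep(subj_lab, each = reps),
                           rep(subj_ids, each = reps), groups = group_of)
    structure(list(table = table, truth = truth), class = "ebgwo_cohort")
  })
}

#' @export
print.ebgwo_cohort <- function(x, ...) {
  cat("<ebgwo_cohort>\n")
  print(x$table)
  cat("  planted informative columns: ", length(x$truth), "\n", sep = "")
  invisible(x)
}

#' Audit planted class shifts
#'
#' Computes, for each named column, the observed standardized mean
#' difference between case and control rows (difference of class means over
#' the pooled within-class standard deviation). For planted informative
#' columns the observed shift estimates the generator's `effect_size`; for
#' noise columns it is near 0.
#'
#' @param table a [feature_table] containing both classes.
#' @param truth character vector of column names to audit (typically the
#'   generator's truth set). An empty set yields an empty audit.
#' @return named numeric vector of observed standardized mean differences.
#' @export
planted_column_audit <- function(table, truth) {
  stopifnot(inherits(table, "feature_table"))
  if (length(unique(table$labels)) < 2L)
    stop("audit requires both classes in the table", call. = FALSE)
  truth <- as.character(truth)
  if (length(truth) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  missing_cols <- setdiff(truth, colnames(table$x))
  if (length(missing_cols))
    stop("unknown columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  case <- table$labels == 1L
  vapply(truth, function(nm) {
    a <- table$x[case, nm]
    b <- table$x[!case, nm]
    pooled <- sqrt(((length(a) - 1) * stats::var(a) +
                    (length(b) - 1) * stats::var(b)) /
                   (length(a) + length(b) - 2))
    if (pooled == 0) return(0)
    (mean(a) - mean(b)) / pooled
  }, numeric(1))
}

#' Write a synthetic cohort to disk
#'
#' Emits the feature table in the CSV dialect [read_feature_table] reads and
#' the truth set as a JSON list of column names.
#'
#' @param cohort an `ebgwo_cohort` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ebgwo_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "cohort.csv")
  truth <- file.path(dir, "truth.json")
  write_feature_table(cohort$table, csv)
  jsonlite::write_json(cohort$truth, truth)
  invisible(c(table = csv, truth = truth))
}
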