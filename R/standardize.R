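#' Fit z-score standardization parameters
#'
#' Computes the per-feature mean and standard deviation used for z-score
#' standardization, x' = (x - mu) / sigma. The population convention
#' (divide by n) is used for sigma; at cohort sample sizes the difference
#' from the n - 1 convention is immaterial, but the convention must be fixed
#' for exact reproducibility.
#'
#' @param table a [feature_table] with at least one row.
#' @return an object of class `standardization_params` with numeric vectors
#'   `mu` and `sigma`, named by feature.
#' @seealso [standardize_apply()]
#' @export
#' @examples
#' ft <- feature_table(cbind(f1 = c(1, 2, 3)), labels = c(0, 1, 0))
#' standardize_fit(ft)$sigma  # population sd of 1,2,3 = sqrt(2/3)
standardize_fit <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$x) < 1L) stop("table has no rows", call. = FALSE)
  mu <- colMeans(table$x)
  # two-pass population sd: stable on large-magnitude columns
  sigma <- sqrt(colMeans(sweep(table$x, 2L, mu, "-")^2))
  structure(list(mu = mu, sigma = sigma), class = "standardization_params")
}

#' @export
print.standardization_params <- function(x, ...) {
  cat("<standardization_params> ", length(x$mu), " features\n", sep = "")
  invisible(x)
}

#' Apply z-score standardization
#'
#' Replaces each feature cell x by (x - mu) / sigma using previously fitted
#' parameters (typically fitted on the training partition only). Features
#' with sigma = 0 (constant in the fitting data) map to 0 everywhere rather
#' than erroring, so degenerate columns pass through the pipeline. Labels and
#' subject ids are unchanged.
#'
#' @param table a [feature_table].
#' @param params a `standardization_params` object dimensioned like `table`.
#' @return a standardized [feature_table].
#' @export
standardize_apply <- function(table, params) {
  stopifnot(inherits(table, "feature_table"),
            inherits(params, "standardization_params"))
  if (length(params$mu) != ncol(table$x))
    stop("standardization params have ", length(params$mu),
         " features but table has ", ncol(table$x), call. = FALSE)
  z <- sweep(table$x, 2L, params$mu, "-")
  sigma <- params$sigma
  nz <- sigma > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2L, sigma[nz], "/")
  z[, !nz] <- 0
  feature_table(z, table$labels, table$subject_ids, groups = table$groups)
}

#' Serialize standardization parameters to JSON
#'
#' @param params a `standardization_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_standardization_params <- function(params, path) {
  stopifnot(inherits(params, "standardization_params"))
  jsonlite::write_json(
    list(features = names(params$mu),
         mu = unname(params$mu), sigma = unname(params$sigma)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read standardization parameters from JSON
#'
#' @param path path written by [write_standardization_params()].
#' @return a `standardization_params` object.
#' @export
read_standardization_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mu = stats::setNames(obj$mu, obj$features),
                 sigma = stats::setNames(obj$sigma, obj$features)),
            class = "standardization_params")
}
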