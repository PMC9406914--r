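#' Experiment run configuration
#'
#' Composes the full workflow configuration: data source (a CSV path in the
#' UCI speech dialect, or a synthetic [cohort_spec()]), the stratified
#' split, the EBGWO selector, the wrapper fitness, and the downstream
#' classifiers. Every stochastic component derives its seed from the single
#' master `seed` (cohort: seed; split: seed + 1; selection: seed + 2;
#' classifiers: seed + 3), so a run is fully reproducible from one integer.
#'
#' @param data optional CSV path; when `NULL` a synthetic cohort is
#'   generated from `synthetic`.
#' @param synthetic a [cohort_spec()] used when `data` is `NULL`.
#' @param schema [feature_schema] for synthetic generation.
#' @param label_column,id_column CSV column names.
#' @param test_fraction held-out test fraction (default 0.25).
#' @param seed master seed.
#' @param pack_size,max_iter,levy_beta,levy_alpha,levy_prob,p_explore
#'   selector parameters; see [gwo_config()] and [ebgwo()].
#' @param alpha_weight,induction_k,holdout_fraction wrapper-fitness
#'   parameters; see [fitness_spec()].
#' @param classifiers character vector of classifier kinds (see
#'   [classifier_spec()]); all four by default.
#' @param scale_before_split logical; when `TRUE`, standardization is fitted on
#'   the full table before splitting (the historical protocol for this
#'   table). The default fits on the training partition only, which avoids
#'   test-set leakage into the scaling.
#' @return an object of class `run_config`.
#' @export
run_config <- function(data = NULL, synthetic = cohort_spec(),
                       schema = default_schema(),
                       label_column = "class", id_column = "id",
                       test_fraction = 0.25, seed = 1L,
                       pack_size = 10L, max_iter = 1000L,
                       levy_beta = 0.5, levy_alpha = 0.1, levy_prob = 0.5,
                       p_explore = 0.2, alpha_weight = 0.99,
                       induction_k = 5L, holdout_fraction = 0.2,
                       classifiers = c("knn", "svm", "tree", "gbt"),
                       scale_before_split = FALSE) {
  if (length(classifiers) == 0L)
    stop("no classifiers configured", call. = FALSE)
  classifiers <- match.arg(classifiers, c("knn", "svm", "tree", "gbt"),
                           several.ok = TRUE)
  structure(list(data = data, synthetic = synthetic, schema = schema,
                 label_column = label_column, id_column = id_column,
                 test_fraction = test_fraction, seed = as.integer(seed),
                 pack_size = pack_size, max_iter = max_iter,
                 levy_beta = levy_beta, levy_alpha = levy_alpha,
                 levy_prob = levy_prob, p_explore = p_explore,
                 alpha_weight = alpha_weight, induction_k = induction_k,
                 holdout_fraction = holdout_fraction,
                 classifiers = classifiers, scale_before_split = scale_before_split),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; a `synthetic:`
#' block maps onto [cohort_spec()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), "synthetic")]
  if (!is.null(y$synthetic))
    args$synthetic <- do.call(cohort_spec, y$synthetic)
  do.call(run_config, args)
}

# restrict a feature table to named columns
ft_select_columns <- function(table, cols) {
  feature_table(table$x[, cols, drop = FALSE], table$labels,
                table$subject_ids, groups = table$groups)
}

#' Run the full selection-and-evaluation experiment
#'
#' Executes the workflow end to end: load or generate the feature table,
#' z-score standardize (fitted on the training partition unless
#' `scale_before_split`), stratified 75/25 split, EBGWO feature selection on the
#' training partition only, then baseline (all features) versus proposed
#' (selected features) evaluation of each configured classifier on the
#' identical test partition. The test partition never reaches
#' standardization fitting or wrapper fitness.
#'
#' @param config a [run_config()].
#' @return an object of class `ebgwo_report` with `metrics` (one row per
#'   classifier x variant: accuracy, precision, recall, f1, auc,
#'   n_features, wall_time), `selection` (the [ebgwo()] fit), `confusions`
#'   (per classifier/variant), `log` (stage lines) and `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed (master seed ", config$seed, "): ",
           conditionMessage(e), call. = FALSE))
  }

  table <- stage("load", {
    if (!is.null(config$data)) {
      note("reading feature table from ", config$data)
      read_feature_table(config$data, config$label_column,
                         config$id_column)
    } else {
      spec <- config$synthetic; spec$seed <- config$seed
      note("generating synthetic cohort (", spec$n_cases, " cases, ",
           spec$n_controls, " controls x ", spec$recordings_per_subject,
           " recordings)")
      generate_cohort(config$schema, spec)$table
    }
  })
  note("table: ", nrow(table$x), " rows x ", ncol(table$x), " features; ",
       check_missing(table), " missing cells")

  split <- stage("split", stratified_split(table, config$test_fraction,
                                           seed = config$seed + 1L))
  std <- stage("standardize", {
    if (config$scale_before_split) {
      params <- standardize_fit(table)
      note("standardization fitted on the full table (scale_before_split)")
    } else {
      params <- standardize_fit(split$train)
      note("standardization fitted on the training partition")
    }
    list(train = standardize_apply(split$train, params),
         test = standardize_apply(split$test, params),
         params = params)
  })
  note("split: ", nrow(std$train$x), " train / ", nrow(std$test$x),
       " test rows")

  sel <- stage("select", select_features(
    std$train,
    gwo_config(dim = ncol(std$train$x), pack_size = config$pack_size,
               max_iter = config$max_iter, levy_beta = config$levy_beta,
               levy_alpha = config$levy_alpha,
               levy_prob = config$levy_prob, seed = config$seed + 2L),
    fitness_spec(alpha_weight = config$alpha_weight,
                 induction_k = config$induction_k,
                 holdout_fraction = config$holdout_fraction),
    p_explore = config$p_explore))
  note("EBGWO selected ", length(sel$selected), "/", length(sel$mask),
       " features (best fitness ", format(sel$best_fitness, digits = 6),
       ")")

  variants <- list(
    baseline = list(train = std$train, test = std$test),
    proposed = list(train = ft_select_columns(std$train, sel$selected),
                    test = ft_select_columns(std$test, sel$selected)))

  rows <- list(); confusions <- list()
  for (kind in config$classifiers) {
    for (variant in names(variants)) {
      v <- variants[[variant]]
      spec <- classifier_spec(kind, seed = config$seed + 3L)
      t0 <- proc.time()[["elapsed"]]
      out <- stage(paste0("evaluate:", kind, ":", variant),
                   fit_predict(spec, v$train, v$test))
      wall <- proc.time()[["elapsed"]] - t0
      cm <- confusion(v$test$labels, out$predictions)
      m <- classification_metrics(cm)
      rows[[paste(kind, variant)]] <- data.frame(
        classifier = kind, variant = variant,
        accuracy = m$accuracy, precision = m$precision,
        recall = m$recall, f1 = m$f1,
        auc = auc_rank(out$scores, v$test$labels),
        n_features = ncol(v$train$x), wall_time = wall)
      confusions[[paste0(kind, "_", variant)]] <- cm
      note(kind, " ", variant, ": accuracy ",
           sprintf("%.3f", m$accuracy))
    }
  }

  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  structure(list(metrics = metrics, selection = sel,
                 confusions = confusions,
                 standardization = std$params,
                 n_total = length(sel$mask),
                 n_selected = length(sel$selected),
                 reduction = 1 - length(sel$selected) / length(sel$mask),
                 log = log_lines, config = config),
            class = "ebgwo_report")
}

#' @export
print.ebgwo_report <- function(x, ...) {
  cat("EBGWO experiment report (master seed ", x$config$seed, ")\n",
      sep = "")
  cat("selection: ", x$n_selected, "/", x$n_total, " features (",
      sprintf("%.1f%%", 100 * x$reduction), " reduction)\n", sep = "")
  print(x$metrics, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write report artifacts to a directory
#'
#' Emits `report.csv` (metric rows), `report.json` (metrics + selection
#' summary), `selection.json`, `trace.csv`, one `confusion_<classifier>.json`
#' per classifier (baseline and proposed matrices), and `run.log`.
#'
#' @param report an `ebgwo_report` from [run_experiment()].
#' @param outdir output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "ebgwo_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(report_csv = file.path(outdir, "report.csv"),
             report_json = file.path(outdir, "report.json"),
             selection = file.path(outdir, "selection.json"),
             trace = file.path(outdir, "trace.csv"),
             log = file.path(outdir, "run.log"))
  tryCatch({
    utils::write.csv(report$metrics, paths[["report_csv"]],
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = report$config$seed,
           selection = list(n_selected = report$n_selected,
                            n_total = report$n_total,
                            reduction = report$reduction,
                            best_fitness = report$selection$best_fitness),
           metrics = report$metrics[setdiff(names(report$metrics),
                                            "wall_time")]),
      paths[["report_json"]], digits = NA, auto_unbox = TRUE,
      dataframe = "rows")
    write_selection(report$selection, paths[["selection"]])
    write_trace(report$selection, paths[["trace"]])
    writeLines(report$log, paths[["log"]])
    for (kind in unique(report$metrics$classifier)) {
      p <- file.path(outdir, paste0("confusion_", kind, ".json"))
      both <- lapply(c(baseline = "baseline", proposed = "proposed"),
                     function(v) {
                       cm <- report$confusions[[paste0(kind, "_", v)]]
                       list(TP = cm$TP, TN = cm$TN, FP = cm$FP, FN = cm$FN)
                     })
      jsonlite::write_json(both, p, auto_unbox = TRUE)
      paths[[paste0("confusion_", kind)]] <- p
    }
  }, error = function(e)
    stop("failed writing report to '", outdir, "': ",
         conditionMessage(e), call. = FALSE))
  invisible(paths)
}
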