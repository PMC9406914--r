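#' Confusion matrix for binary predictions
#'
#' Positive class is 1 (case/PWP). TP: predicted 1, actual 1. TN: predicted
#' 0, actual 0. FP (type I): predicted 1, actual 0. FN (type II): predicted
#' 0, actual 1.
#'
#' @param labels actual binary labels.
#' @param predictions predicted binary labels, same length.
#' @return an object of class `confusion_matrix` with integer fields `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion <- function(labels, predictions) {
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length", call. = FALSE)
  if (length(labels) < 1L) stop("need at least one instance", call. = FALSE)
  if (!all(c(labels, predictions) %in% c(0L, 1L)))
    stop("labels and predictions must be 0/1", call. = FALSE)
  structure(list(TP = sum(labels == 1L & predictions == 1L),
                 TN = sum(labels == 0L & predictions == 0L),
                 FP = sum(labels == 0L & predictions == 1L),
                 FN = sum(labels == 1L & predictions == 0L)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(actual = c("1", "0"),
                              predicted = c("1", "0")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy = (TP+TN)/total, precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = harmonic mean of precision and recall. Undefined ratios (zero
#' denominator) are reported as `NA`, not as 0.
#'
#' @param cm a [confusion()] matrix.
#' @return named list with `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  if (total < 1L) stop("empty confusion matrix", call. = FALSE)
  precision <- if (cm$TP + cm$FP == 0L) NA_real_ else cm$TP / (cm$TP + cm$FP)
  recall <- if (cm$TP + cm$FN == 0L) NA_real_ else cm$TP / (cm$TP + cm$FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(accuracy = (cm$TP + cm$TN) / total,
       precision = precision, recall = recall, f1 = f1)
}

#' Rank-based AUC (Mann-Whitney identity)
#'
#' Ranks all scores ascending with average ranks for ties; with S_p the sum
#' of positive-instance ranks, AUC = (S_p - n_p (n_p + 1) / 2) /
#' (n_p n_n). Equivalent to the fraction of positive/negative pairs ranked
#' correctly, with half credit for score ties, and invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores real vector, higher = more case-like.
#' @param labels binary labels (1 = positive), same length.
#' @return the AUC in [0, 1].
#' @export
#' @examples
#' auc_rank(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  n_p <- sum(labels == 1L); n_n <- sum(labels == 0L)
  if (n_p == 0L || n_n == 0L)
    stop("AUC requires both classes", call. = FALSE)
  s_p <- sum(rank(scores)[labels == 1L])
  (s_p - n_p * (n_p + 1) / 2) / (n_p * n_n)
}

#' Downstream classifier specification
#'
#' The four evaluation classifiers: `"knn"` (k-nearest neighbours, default
#' k = 5), `"svm"` (support vector machine with radial kernel, default
#' cost 1), `"tree"` (CART decision tree, rpart defaults), and `"gbt"`
#' (leaf-wise gradient-boosted trees via xgboost with loss-guided growth,
#' default 100 rounds, 31 leaves, learning rate 0.1). Hyperparameters are
#' explicit config, overridable through `params`.
#'
#' @param kind one of `"knn"`, `"svm"`, `"tree"`, `"gbt"`.
#' @param params named list of hyperparameter overrides.
#' @param seed integer seed for stochastic trainers.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("knn", "svm", "tree", "gbt"),
                            params = list(), seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    knn = list(k = 5L),
    svm = list(cost = 1),
    tree = list(),
    gbt = list(nrounds = 100L, max_leaves = 31L, learning_rate = 0.1))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown ", kind, " hyperparameters: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  defaults[names(params)] <- params
  structure(list(kind = kind, params = defaults, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train a classifier and score a test table
#'
#' Trains the specified classifier on the training table and returns hard
#' 0/1 predictions plus continuous case scores (higher = more case-like)
#' on the test table. Deterministic for a fixed spec seed.
#'
#' @param spec a [classifier_spec()].
#' @param train,test [feature_table]s sharing the same feature columns;
#'   `train` must contain both classes.
#' @return list with integer `predictions` and numeric `scores`.
#' @export
fit_predict <- function(spec, train, test) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(train, "feature_table"),
            inherits(test, "feature_table"))
  if (!identical(colnames(train$x), colnames(test$x)))
    stop("train and test must share feature columns", call. = FALSE)
  if (length(unique(train$labels)) < 2L)
    stop("training table must contain both classes", call. = FALSE)
  ylev <- factor(train$labels, levels = c(0L, 1L))

  with_seed(spec$seed, switch(spec$kind,
    knn = {
      pred <- class::knn(train$x, test$x, ylev, k = spec$params$k,
                         use.all = TRUE, prob = TRUE)
      pwin <- attr(pred, "prob")
      hard <- as.integer(as.character(pred))
      list(predictions = hard,
           scores = ifelse(hard == 1L, pwin, 1 - pwin))
    },
    svm = {
      fit <- e1071::svm(train$x, ylev, kernel = "radial",
                        cost = spec$params$cost, scale = FALSE,
                        probability = TRUE)
      pr <- stats::predict(fit, test$x, probability = TRUE)
      scores <- attr(pr, "probabilities")[, "1"]
      list(predictions = as.integer(as.character(pr)),
           scores = unname(scores))
    },
    tree = {
      df <- data.frame(.y = ylev, train$x, check.names = TRUE)
      fit <- rpart::rpart(.y ~ ., df, method = "class")
      nd <- data.frame(test$x, check.names = TRUE)
      scores <- unname(stats::predict(fit, nd, type = "prob")[, "1"])
      list(predictions = as.integer(scores >= 0.5), scores = scores)
    },
    gbt = {
      dtrain <- xgboost::xgb.DMatrix(train$x,
                                     label = train$labels, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      tree_method = "hist", grow_policy = "lossguide",
                      max_depth = 0L,
                      max_leaves = spec$params$max_leaves,
                      eta = spec$params$learning_rate,
                      nthread = 1, seed = spec$seed),
        data = dtrain, nrounds = spec$params$nrounds, verbose = 0)
      scores <- stats::predict(
        fit, xgboost::xgb.DMatrix(test$x, nthread = 1))
      list(predictions = as.integer(scores >= 0.5),
           scores = unname(scores))
    }))
}
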