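test_that("confusion counts follow the positive = case convention", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(cm$TP, 1L); expect_equal(cm$FN, 1L)
  expect_equal(cm$TN, 1L); expect_equal(cm$FP, 1L)

  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$FP + perfect$FN, 0L)

  # all-positive predictor on the 141/48 test-set class sizes
  labels <- rep(c(1L, 0L), c(141L, 48L))
  cm2 <- confusion(labels, rep(1L, 189))
  expect_equal(cm2$TP, 141L); expect_equal(cm2$FP, 48L)
  expect_equal(cm2$TN + cm2$FN, 0L)

  expect_error(confusion(c(1, 0), 1), "equal length")
  expect_error(confusion(c(1, 2), c(1, 0)), "0/1")
})

test_that("metrics reproduce the k-NN selected-model row jointly", {
  # TP=139, FN=2 from '139 of the actual 141 cases'; FP, TN solved from
  # the printed accuracy/precision on the 189-row test set
  cm <- structure(list(TP = 139L, TN = 27L, FP = 21L, FN = 2L),
                  class = "confusion_matrix")
  m <- classification_metrics(cm)
  expect_equal(m$recall, 139 / 141, tolerance = 1e-12)
  expect_equal(round(m$recall, 3), 0.986)
  expect_equal(round(m$accuracy, 3), 0.878)
  expect_equal(round(m$precision, 3), 0.869)
  # the published row prints 0.923; recomputation from the counts gives
  # 0.9236, i.e. agreement at printed precision
  expect_equal(m$f1, 0.923, tolerance = 1e-3)
})

test_that("metrics agree with brute-force recomputation on random data", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    labels <- rbinom(n, 1, 0.5)
    preds <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    cm <- confusion(labels, preds)
    m <- classification_metrics(cm)
    expect_equal(m$accuracy, mean(labels == preds), tolerance = 1e-12)
    if (sum(preds) > 0)
      expect_equal(m$precision, sum(labels[preds == 1] == 1) / sum(preds),
                   tolerance = 1e-12)
    if (sum(labels) > 0)
      expect_equal(m$recall, sum(preds[labels == 1] == 1) / sum(labels),
                   tolerance = 1e-12)
  }
})

test_that("undefined ratios surface as NA, not zero", {
  all_neg <- confusion(c(1, 0, 0), c(0, 0, 0))
  m <- classification_metrics(all_neg)
  expect_true(is.na(m$precision))
  expect_false(is.na(m$recall))
  no_pos <- confusion(c(0, 0), c(0, 1))
  expect_true(is.na(classification_metrics(no_pos)$recall))
  expect_equal(classification_metrics(confusion(c(1, 0), c(1, 0)))$f1, 1)
})

test_that("metamorphic: recall ignores FP, precision ignores FN", {
  base <- structure(list(TP = 30L, TN = 20L, FP = 5L, FN = 8L),
                    class = "confusion_matrix")
  more_fp <- base; more_fp$FP <- 50L
  more_fn <- base; more_fn$FN <- 50L
  expect_equal(classification_metrics(base)$recall,
               classification_metrics(more_fp)$recall)
  expect_equal(classification_metrics(base)$precision,
               classification_metrics(more_fn)$precision)
})

test_that("rank AUC hits the separable extremes", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_rank(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_error(auc_rank(c(1, 2), c(1, 1)), "both classes")
})

test_that("rank AUC equals the pairwise oracle on random instances", {
  pairwise_auc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    total <- 0
    for (p in pos) for (q in neg)
      total <- total + (p > q) + 0.5 * (p == q)
    total / (length(pos) * length(neg))
  }
  set.seed(32)
  for (i in 1:100) {
    n <- 30
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    # discrete scores force ties in about half the trials
    scores <- if (i %% 2) rnorm(n) else sample(1:5, n, replace = TRUE)
    expect_equal(auc_rank(scores, labels), pairwise_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("rank AUC is invariant under strictly monotone transforms", {
  set.seed(33)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4); labels[1:2] <- c(0L, 1L)
  a <- auc_rank(scores, labels)
  expect_equal(auc_rank(exp(scores), labels), a, tolerance = 1e-12)
  expect_equal(auc_rank(3 * scores - 100, labels), a, tolerance = 1e-12)
  expect_equal(auc_rank(rank(scores), labels), a, tolerance = 1e-12)
})

test_that("balanced random scores give AUC near one half", {
  set.seed(34)
  aucs <- replicate(400, auc_rank(rnorm(40), rep(c(0, 1), 20)))
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("classifier specs validate kinds and hyperparameters", {
  expect_error(classifier_spec("boost"), "'arg' should be one of")
  expect_error(classifier_spec("knn", params = list(gamma = 2)),
               "unknown knn hyperparameters")
  sp <- classifier_spec("gbt", params = list(nrounds = 10L))
  expect_equal(sp$params$nrounds, 10L)
  expect_equal(sp$params$max_leaves, 31L)
})

test_that("1-NN recognizes a training point as its own neighbour", {
  sp <- std_split(make_cohort(p = 5, seed = 41)$table)
  case_row <- which(sp$train$labels == 1L)[1]
  probe <- feature_table(sp$train$x[case_row, , drop = FALSE], 1L)
  out <- fit_predict(classifier_spec("knn", params = list(k = 1L)),
                     sp$train, probe)
  expect_equal(out$predictions, 1L)
})

test_that("every classifier separates a linearly separated toy set", {
  set.seed(42)
  x <- rbind(matrix(rnorm(40, -5, 0.3), 20, 2),
             matrix(rnorm(40, 5, 0.3), 20, 2))
  colnames(x) <- c("u", "v")
  y <- rep(c(0L, 1L), each = 20)
  ord <- sample(40)
  train <- feature_table(x[ord[1:30], ], y[ord[1:30]])
  test <- feature_table(x[ord[31:40], ], y[ord[31:40]])
  for (kind in c("knn", "svm", "tree", "gbt")) {
    out <- fit_predict(classifier_spec(kind, seed = 1), train, test)
    expect_equal(mean(out$predictions == test$labels), 1.0,
                 info = kind)
    expect_gte(auc_rank(out$scores, test$labels), 0.99)
  }
})

test_that("boosted trees exploit planted informative columns", {
  gains <- vapply(1:5, function(s) {
    coh <- make_cohort(p = 8, n_cases = 60, n_controls = 40,
                       n_informative = 8, effect_size = 2, seed = s)
    sp <- std_split(coh$table, seed = s)
    out <- fit_predict(classifier_spec("gbt", seed = s), sp$train, sp$test)
    majority <- max(mean(sp$test$labels), 1 - mean(sp$test$labels))
    mean(out$predictions == sp$test$labels) - majority
  }, numeric(1))
  expect_gte(mean(gains), 0.15)
})

test_that("fit_predict is deterministic for a fixed seed", {
  sp <- std_split(make_cohort(p = 6, n_informative = 2, seed = 43)$table)
  for (kind in c("knn", "svm", "tree", "gbt")) {
    a <- fit_predict(classifier_spec(kind, seed = 5), sp$train, sp$test)
    b <- fit_predict(classifier_spec(kind, seed = 5), sp$train, sp$test)
    expect_identical(a, b, info = kind)
  }
  expect_error(fit_predict(classifier_spec("knn"), sp$train,
                           ft_mismatch <- feature_table(
                             cbind(zz = rnorm(3)), c(1, 0, 1))),
               "share feature columns")
})
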