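test_that("sigmoid transfer hits midpoint, hand value and limits", {
  expect_equal(sigmoid_transfer(0.5), 0.5)
  expect_equal(sigmoid_transfer(0.6), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(sigmoid_transfer(1e3), 1)
  expect_equal(sigmoid_transfer(-1e3), 0)
  expect_true(all(diff(sigmoid_transfer(seq(0, 1, 0.01))) > 0))
})

test_that("binarization saturates at extreme positions", {
  set.seed(1)
  for (i in 1:5) {
    expect_equal(binarize(rep(10, 20)), rep(1L, 20))
    expect_equal(binarize(rep(-10, 20)), rep(0L, 20))
  }
})

test_that("binarization at the midpoint includes features half the time", {
  set.seed(2)
  freq <- mean(replicate(1e4, binarize(rep(0.5, 4))))
  expect_equal(freq, 0.5, tolerance = 0.02)
})

test_that("random triplet position averages three random wolves", {
  pack <- matrix(rep(c(0.3, 0.9), each = 5), 5, 2)
  set.seed(3)
  expect_equal(random_triplet_position(pack), c(0.3, 0.9))

  spread <- matrix(c(0, 3, 6), 3, 1)
  set.seed(4)
  got <- random_triplet_position(spread)
  set.seed(4)
  idx <- sample.int(3, 3, replace = TRUE)
  expect_equal(got, mean(spread[idx, 1]))

  expect_error(random_triplet_position(matrix(0, 2, 3)), "at least 3")
})

test_that("fitness_spec enforces the weight and k invariants", {
  fs <- fitness_spec(alpha_weight = 0.9)
  expect_equal(fs$alpha_weight + fs$beta_weight, 1)
  expect_error(fitness_spec(induction_k = 4), "odd")
  expect_error(fitness_spec(alpha_weight = 1.2), "alpha_weight")
  expect_error(fitness_spec(holdout_fraction = 0), "holdout_fraction")
})

test_that("wrapper fitness combines error and size exactly", {
  sp <- std_split(make_cohort(p = 12, n_cases = 40, n_controls = 25,
                              n_informative = 3, seed = 5)$table)
  fs <- fitness_spec(holdout_seed = 99)
  set.seed(10)
  for (i in 1:10) {
    mask <- rbinom(12, 1, 0.6)
    if (sum(mask) == 0) mask[1] <- 1L
    r <- wrapper_fitness(mask, sp$train, fs)
    expect_equal(r$fitness,
                 fs$alpha_weight * r$error_rate +
                   fs$beta_weight * r$n_selected / r$n_total,
                 tolerance = 1e-12)
    expect_equal(r$n_selected, sum(mask))
    expect_equal(r$n_total, 12L)
  }

  # alpha_weight = 1 kills the size term
  r1 <- wrapper_fitness(rep(1L, 12), sp$train,
                        fitness_spec(alpha_weight = 1, holdout_seed = 99))
  expect_equal(r1$fitness, r1$error_rate)
})

test_that("a single perfectly separating column scores beta/n_total", {
  # one huge-effect column: ER = 0, fitness = 0.01 * (1 / n_total)
  set.seed(11)
  n <- 60
  x <- cbind(sep = c(rnorm(n / 2, 10), rnorm(n / 2, -10)),
             matrix(rnorm(n * 9), n, 10 - 1))
  colnames(x) <- c("sep", paste0("noise", 1:9))
  ft <- feature_table(x, rep(c(1, 0), each = n / 2))
  ft <- standardize_apply(ft, standardize_fit(ft))
  r <- wrapper_fitness(c(1L, rep(0L, 9)), ft,
                       fitness_spec(holdout_seed = 1))
  expect_equal(r$error_rate, 0)
  expect_equal(r$fitness, 0.01 * (1 / 10), tolerance = 1e-12)
})

test_that("the empty mask is flagged with a worst-case sentinel", {
  sp <- std_split(make_cohort(p = 5, seed = 6)$table)
  r <- wrapper_fitness(rep(0L, 5), sp$train, fitness_spec())
  expect_true(is.infinite(r$fitness))
  expect_true(r$empty)
  expect_true(is.na(r$error_rate))
})

test_that("wrapper fitness leaves the caller's RNG stream untouched", {
  sp <- std_split(make_cohort(p = 6, seed = 7)$table)
  set.seed(42); before <- .Random.seed
  wrapper_fitness(c(1L, 1L, 0L, 0L, 1L, 0L), sp$train,
                  fitness_spec(holdout_seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("parsimony pressure: more features cost more at equal error", {
  # planted signal so strong that ER = 0 for any superset of the truth
  coh <- make_cohort(p = 10, n_cases = 50, n_controls = 30,
                     n_informative = 2, effect_size = 6, seed = 8)
  sp <- std_split(coh$table)
  fs <- fitness_spec(holdout_seed = 5)
  base <- as.integer(colnames(sp$train$x) %in% coh$truth)
  wider <- base; wider[which(base == 0)[1:3]] <- 1L
  r_small <- wrapper_fitness(base, sp$train, fs)
  r_big <- wrapper_fitness(wider, sp$train, fs)
  expect_equal(r_small$error_rate, r_big$error_rate)
  expect_gt(r_big$fitness, r_small$fitness)
})

test_that("fitness increases with the error rate for a fixed mask", {
  sp <- std_split(make_cohort(p = 8, n_cases = 40, n_controls = 28,
                              n_informative = 2, seed = 9)$table)
  fs <- fitness_spec()
  mask <- rep(1L, 8)
  hold_a <- ebgwo:::with_seed(1,
    ebgwo:::draw_holdout(sp$train$labels, 0.2))
  hold_b <- ebgwo:::with_seed(2,
    ebgwo:::draw_holdout(sp$train$labels, 0.2))
  ra <- wrapper_fitness(mask, sp$train, fs, holdout = hold_a)
  rb <- wrapper_fitness(mask, sp$train, fs, holdout = hold_b)
  expect_equal(rb$fitness - ra$fitness,
               fs$alpha_weight * (rb$error_rate - ra$error_rate),
               tolerance = 1e-12)
})

test_that("selection runs are bit-reproducible under equal seeds", {
  sp <- std_split(make_cohort(p = 15, n_informative = 3, seed = 10)$table)
  cfg <- gwo_config(dim = 15, pack_size = 5, max_iter = 20, seed = 33)
  a <- select_features(sp$train, cfg)
  b <- select_features(sp$train, cfg)
  expect_identical(a$mask, b$mask)
  expect_identical(a$trace, b$trace)
  expect_identical(a$best_fitness, b$best_fitness)

  c <- select_features(sp$train,
                       gwo_config(dim = 15, pack_size = 5, max_iter = 20,
                                  seed = 34))
  expect_false(identical(a$trace, c$trace))
})

test_that("traces are monotone and the reported fitness recomputes", {
  sp <- std_split(make_cohort(p = 15, n_informative = 3, seed = 11)$table)
  fit <- select_features(sp$train,
                         gwo_config(dim = 15, pack_size = 6, max_iter = 30,
                                    seed = 7))
  expect_true(all(diff(fit$trace$best_fitness) <= 0))
  expect_gte(length(fit$selected), 1)
  expect_equal(length(fit$selected), sum(fit$mask))

  recomputed <- wrapper_fitness(fit$mask, sp$train, fit$fitness,
                                holdout = fit$holdout_idx)
  expect_equal(fit$best_fitness, recomputed$fitness, tolerance = 1e-12)
  expect_equal(fit$error_rate, recomputed$error_rate)
})

test_that("a single-feature problem selects that feature", {
  coh <- make_cohort(p = 1, n_cases = 20, n_controls = 14,
                     n_informative = 1, seed = 12)
  sp <- std_split(coh$table)
  fit <- select_features(sp$train,
                         gwo_config(dim = 1, pack_size = 4, max_iter = 10,
                                    seed = 2))
  expect_equal(unname(fit$mask), 1L)
  expect_equal(fit$selected, "f_001")
})

test_that("planted informative features dominate a small selection", {
  coh <- make_cohort(p = 20, n_cases = 60, n_controls = 40,
                     n_informative = 3, effect_size = 2, seed = 13)
  sp <- std_split(coh$table)
  fit <- select_features(sp$train,
                         gwo_config(dim = 20, pack_size = 8, max_iter = 60,
                                    seed = 3))
  expect_gte(sum(coh$truth %in% fit$selected), 2)
})

test_that("ebgwo() validates inputs and wires the matrix interface", {
  coh <- make_cohort(p = 6, seed = 14)
  sp <- std_split(coh$table)
  fit <- ebgwo(sp$train$x, sp$train$labels, pack_size = 4, max_iter = 5,
               seed = 1)
  expect_s3_class(fit, "ebgwo")
  expect_error(ebgwo(sp$train$x), "`y` is required")
  expect_error(select_features(sp$train, gwo_config(dim = 99)),
               "must equal the feature count")
  single <- sp$train; single$labels <- rep(1L, nrow(single$x))
  expect_error(select_features(single, gwo_config(dim = 6)),
               "both classes")
})

test_that("ebgwo S3 surface: print, summary, coef, plot, predict", {
  coh <- make_cohort(p = 10, n_cases = 40, n_controls = 26,
                     n_informative = 3, effect_size = 3, seed = 15)
  sp <- std_split(coh$table)
  fit <- select_features(sp$train,
                         gwo_config(dim = 10, pack_size = 5, max_iter = 15,
                                    seed = 4))
  expect_output(print(fit), "grey wolf")
  s <- summary(fit)
  expect_s3_class(s, "summary.ebgwo")
  expect_equal(s$n_selected, length(fit$selected))
  expect_output(print(s), "reduction")
  expect_equal(sum(coef(fit)), length(fit$selected))

  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))

  pred <- predict(fit, sp$test)
  expect_true(all(pred %in% c(0L, 1L)))
  expect_gt(mean(pred == sp$test$labels), 0.6)
  sc <- predict(fit, sp$test, type = "score")
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("selection results survive a JSON round trip", {
  sp <- std_split(make_cohort(p = 8, seed = 16)$table)
  fit <- select_features(sp$train,
                         gwo_config(dim = 8, pack_size = 4, max_iter = 8,
                                    seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_selection(fit, path)
  back <- read_selection(path)
  expect_equal(back$selected, fit$selected)
  expect_equal(back$mask, unname(fit$mask))
  expect_equal(back$best_fitness, fit$best_fitness)
  expect_equal(back$config$pack_size, 4)

  tr <- withr::local_tempfile(fileext = ".csv")
  write_trace(fit, tr)
  got <- read.csv(tr)
  expect_equal(names(got), c("iteration", "best_fitness", "n_selected"))
  expect_equal(nrow(got), 8)
})
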