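#' Steep sigmoid transfer function
#'
#' Maps a continuous position coordinate in the unit interval to an
#' inclusion probability: p = 1 / (1 + exp(-10 (x - 0.5))). The slope of 10
#' makes the transfer decisive away from the midpoint while x = 0.5 stays
#' maximally undecided (p = 0.5).
#'
#' @param x numeric vector of position coordinates.
#' @return inclusion probabilities in (0, 1).
#' @export
#' @examples
#' sigmoid_transfer(c(0, 0.5, 1))
sigmoid_transfer <- function(x) 1 / (1 + exp(-10 * (x - 0.5)))

#' Stochastic binarization of a continuous position
#'
#' Per dimension i, the feature is included (mask 1) when
#' `sigmoid_transfer(position[i]) >= r_i` with r_i ~ Uniform(0, 1), so the
#' transfer value acts as the inclusion probability.
#'
#' @param position numeric position vector (unit-interval encoding).
#' @return integer 0/1 mask of the same length.
#' @export
binarize <- function(position) {
  as.integer(sigmoid_transfer(position) >= stats::runif(length(position)))
}

#' Random-triplet exploration position
#'
#' Exploration-mode update: the mean of three pack positions chosen
#' uniformly at random (independent draws, so repeats are possible). Pulls
#' a wolf toward a random region of the pack's current span instead of
#' toward the leaders.
#'
#' @param positions pack_size x dim matrix of wolf positions (>= 3 rows).
#' @return numeric position vector.
#' @export
random_triplet_position <- function(positions) {
  if (!is.matrix(positions) || nrow(positions) < 3L)
    stop("need a pack of at least 3 wolves", call. = FALSE)
  idx <- sample.int(nrow(positions), 3L, replace = TRUE)
  colMeans(positions[idx, , drop = FALSE])
}

#' Wrapper fitness specification
#'
#' The wrapper fitness combines the induction classifier's validation error
#' with a feature-count penalty:
#' fitness = alpha_weight * ER + (1 - alpha_weight) * n_selected / n_total.
#' The default alpha_weight = 0.99 keeps classification error dominant while
#' still breaking ties toward smaller subsets. The induction classifier is
#' k-nearest neighbours with an odd `induction_k` (no vote ties), evaluated
#' on a stratified holdout inside the training partition that is drawn once
#' per run, making fitness a deterministic function of the mask.
#'
#' @param alpha_weight error-rate weight in [0, 1]; the size penalty gets
#'   1 - alpha_weight.
#' @param induction_k neighbour count for the induction k-NN (odd, >= 1).
#' @param holdout_fraction fraction of training rows held out for internal
#'   validation, in (0, 1). Default 0.2.
#' @param holdout_seed optional seed used when [wrapper_fitness()] must draw
#'   its own holdout (the selection loop draws one from the run seed
#'   instead).
#' @return an object of class `fitness_spec`.
#' @export
fitness_spec <- function(alpha_weight = 0.99, induction_k = 5L,
                         holdout_fraction = 0.2, holdout_seed = NULL) {
  stopifnot(alpha_weight >= 0, alpha_weight <= 1, induction_k >= 1L,
            holdout_fraction > 0, holdout_fraction < 1)
  if (induction_k %% 2L == 0L)
    stop("`induction_k` must be odd to avoid vote ties", call. = FALSE)
  structure(list(alpha_weight = alpha_weight,
                 beta_weight = 1 - alpha_weight,
                 induction_k = as.integer(induction_k),
                 holdout_fraction = holdout_fraction,
                 holdout_seed = holdout_seed),
            class = "fitness_spec")
}

# stratified holdout indices for internal validation (consumes the current
# RNG stream)
draw_holdout <- function(labels, fraction) {
  classes <- sort(unique(labels))
  counts <- apportion_test_counts(
    as.integer(table(factor(labels, levels = classes))), fraction)
  idx <- integer(0)
  for (i in seq_along(classes))
    idx <- c(idx, sample(which(labels == classes[i]), counts[i]))
  sort(idx)
}

#' Evaluate the wrapper fitness of a feature mask
#'
#' Restricts the training table to the masked columns, trains the induction
#' k-NN on the non-holdout rows, measures the error rate ER on the holdout
#' rows, and returns
#' fitness = alpha_weight * ER + beta_weight * n_selected / n_total.
#' The empty mask is assigned a `+Inf` sentinel fitness (worst possible) and
#' flagged. The classifier evaluation never consumes the caller's RNG
#' stream.
#'
#' @param mask integer/logical 0-1 vector over the table's features.
#' @param train a standardized [feature_table] containing both classes.
#' @param spec a [fitness_spec()].
#' @param holdout optional integer vector of validation row indices; when
#'   `NULL` a stratified holdout is drawn using `spec$holdout_seed`.
#' @return an object of class `fitness_result` with fields `fitness`,
#'   `error_rate`, `n_selected`, `n_total` and `empty`.
#' @export
wrapper_fitness <- function(mask, train, spec = fitness_spec(),
                            holdout = NULL) {
  stopifnot(inherits(train, "feature_table"), inherits(spec, "fitness_spec"))
  mask <- as.integer(as.logical(mask))
  if (length(mask) != ncol(train$x))
    stop("mask length must equal the feature count", call. = FALSE)
  n_total <- ncol(train$x)
  n_sel <- sum(mask)
  if (n_sel == 0L)
    return(structure(list(fitness = Inf, error_rate = NA_real_,
                          n_selected = 0L, n_total = n_total, empty = TRUE),
                     class = "fitness_result"))
  if (is.null(holdout))
    holdout <- with_seed(spec$holdout_seed,
                         draw_holdout(train$labels, spec$holdout_fraction))
  fit_lab <- train$labels[-holdout]
  val_lab <- train$labels[holdout]
  if (length(unique(fit_lab)) < 2L || length(unique(val_lab)) < 2L)
    stop("internal validation fold contains a single class; ",
         "use a different seed or holdout fraction", call. = FALSE)
  er <- rng_isolated({
    cols <- which(mask == 1L)
    pred <- class::knn(train$x[-holdout, cols, drop = FALSE],
                       train$x[holdout, cols, drop = FALSE],
                       factor(fit_lab, levels = c(0L, 1L)),
                       k = min(spec$induction_k, length(fit_lab)),
                       use.all = TRUE)
    mean(as.integer(as.character(pred)) != val_lab)
  })
  structure(list(fitness = spec$alpha_weight * er +
                   spec$beta_weight * n_sel / n_total,
                 error_rate = er, n_selected = n_sel, n_total = n_total,
                 empty = FALSE),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat("<fitness_result> fitness ", format(x$fitness, digits = 6),
      "  ER ", format(x$error_rate, digits = 4),
      "  |R|/|C| ", x$n_selected, "/", x$n_total, "\n", sep = "")
  invisible(x)
}

# run `code` without touching the caller's RNG stream (some classifier
# backends draw from it even when their result is deterministic)
rng_isolated <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Enhanced binary grey wolf optimization feature selection
#'
#' Fits a wrapper feature selector: continuous wolf positions live in the
#' unit hypercube (one coordinate per feature), are binarized through the
#' steep sigmoid transfer, and each candidate mask is scored by the
#' induction k-NN wrapper fitness. Per iteration, each non-leader wolf
#' either takes the random-triplet exploration update (probability
#' `p_explore`) or the leader-guided encircling update, and is then, with
#' probability `levy_prob`, replaced by a Levy-flight perturbation around
#' the current alpha. The alpha/beta/delta leaders are retained unchanged
#' (elitism); the best-ever mask is tracked separately so the convergence
#' trace is monotone non-increasing, and at least one feature is always
#' selected.
#'
#' @param x a [feature_table] (standardized; see [standardize_fit()]), or a
#'   numeric matrix/data frame of features.
#' @param y binary labels (0/1), required when `x` is not a
#'   `feature_table`.
#' @param pack_size wolf count (>= 4). Default 10.
#' @param max_iter iteration budget. Default 1000.
#' @param alpha_weight,induction_k,holdout_fraction wrapper-fitness
#'   parameters; see [fitness_spec()].
#' @param p_explore probability of the random-triplet exploration update.
#'   Default 0.2.
#' @param levy_prob probability of the Levy perturbation. Default 0.5.
#' @param levy_beta Levy control parameter. Default 0.5.
#' @param levy_alpha Levy step-size scale. Default 0.1.
#' @param seed integer master seed for the run; equal seeds are
#'   bit-reproducible.
#' @return an object of class `ebgwo` with components `mask` (named 0/1
#'   vector), `selected` (feature names), `best_fitness`, `error_rate`,
#'   `trace` (data frame: iteration, best_fitness, n_selected), `gwo`,
#'   `fitness` (specs), `holdout_idx`, `train`, `seed` and `call`.
#' @seealso [select_features()] for the config-object interface;
#'   [predict.ebgwo()], [plot.ebgwo()], [summary.ebgwo()].
#' @export
#' @examples
#' coh <- generate_cohort(
#'   feature_schema(data.frame(group = "f", n = 12)),
#'   cohort_spec(n_cases = 20, n_controls = 12, n_informative = 3,
#'               effect_size = 2, seed = 1))
#' std <- standardize_apply(coh$table, standardize_fit(coh$table))
#' fit <- ebgwo(std, pack_size = 6, max_iter = 25, seed = 1)
#' fit
ebgwo <- function(x, y = NULL, pack_size = 10L, max_iter = 1000L,
                  alpha_weight = 0.99, induction_k = 5L,
                  holdout_fraction = 0.2, p_explore = 0.2, levy_prob = 0.5,
                  levy_beta = 0.5, levy_alpha = 0.1, seed = NULL) {
  cl <- match.call()
  if (!inherits(x, "feature_table")) {
    if (is.null(y)) stop("`y` is required when `x` is not a feature_table",
                         call. = FALSE)
    x <- feature_table(as.matrix(x), y)
  }
  gwo <- gwo_config(dim = ncol(x$x), pack_size = pack_size,
                    max_iter = max_iter, levy_beta = levy_beta,
                    levy_alpha = levy_alpha, levy_prob = levy_prob,
                    seed = seed)
  fs <- fitness_spec(alpha_weight = alpha_weight,
                     induction_k = induction_k,
                     holdout_fraction = holdout_fraction)
  out <- ebgwo_engine(x, gwo, fs, p_explore = p_explore)
  out$call <- cl
  out
}

#' Run EBGWO selection from configuration objects
#'
#' Identical to [ebgwo()] but takes pre-built [gwo_config()] and
#' [fitness_spec()] objects, which the experiment pipeline composes from a
#' run configuration.
#'
#' @param train a standardized [feature_table] containing both classes.
#' @param gwo a [gwo_config()] with `dim` equal to the feature count; its
#'   `seed` is the run seed.
#' @param fitness a [fitness_spec()].
#' @param p_explore probability of the random-triplet exploration update.
#' @return an `ebgwo` object; see [ebgwo()].
#' @export
select_features <- function(train, gwo, fitness = fitness_spec(),
                            p_explore = 0.2) {
  out <- ebgwo_engine(train, gwo, fitness, p_explore)
  out$call <- match.call()
  out
}

# core selection loop; RNG draw order (under the run seed): internal
# holdout, pack initialization (row order), then per iteration per
# non-leader wolf: explore gate, triplet indices or 3 coefficient pairs,
# levy gate, levy normals. Fitness evaluation is RNG-isolated.
ebgwo_engine <- function(train, gwo, fs, p_explore = 0.2) {
  stopifnot(inherits(train, "feature_table"), inherits(gwo, "gwo_config"),
            inherits(fs, "fitness_spec"))
  if (gwo$dim != ncol(train$x))
    stop("gwo_config dim (", gwo$dim, ") must equal the feature count (",
         ncol(train$x), ")", call. = FALSE)
  if (length(unique(train$labels)) < 2L)
    stop("training table must contain both classes", call. = FALSE)
  stopifnot(p_explore >= 0, p_explore <= 1)
  d <- gwo$dim; np <- gwo$pack_size
  feat <- colnames(train$x)

  cache <- new.env(parent = emptyenv())
  eval_mask <- function(mask, holdout) {
    key <- paste(mask, collapse = "")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    res <- wrapper_fitness(mask, train, fs, holdout = holdout)
    assign(key, res, envir = cache)
    res
  }

  with_seed(gwo$seed, {
    holdout <- draw_holdout(train$labels, fs$holdout_fraction)
    pos <- matrix(stats::runif(np * d), np, d, byrow = TRUE)
    masks <- matrix(0L, np, d)
    fit <- numeric(np); nsel <- integer(np)
    for (i in seq_len(np)) {
      masks[i, ] <- binarize(pos[i, ])
      r <- eval_mask(masks[i, ], holdout)
      fit[i] <- r$fitness; nsel[i] <- r$n_selected
    }

    best <- list(fitness = Inf, mask = rep(0L, d), n_selected = 0L)
    note_best <- function(i) {
      if (fit[i] < best$fitness ||
          (fit[i] == best$fitness && nsel[i] < best$n_selected)) {
        best <<- list(fitness = fit[i], mask = masks[i, ],
                      n_selected = nsel[i])
      }
    }
    for (i in order(fit, nsel)) note_best(i)

    trace <- data.frame(iteration = seq_len(gwo$max_iter),
                        best_fitness = NA_real_, n_selected = NA_integer_)

    for (t in seq_len(gwo$max_iter)) {
      a <- a_schedule(t, gwo$max_iter)
      rank <- order(fit, nsel, seq_len(np))
      leaders_idx <- rank[1:3]
      leaders <- pos[leaders_idx, , drop = FALSE]
      alpha_pos <- pos[rank[1L], ]
      snapshot <- pos
      for (i in seq_len(np)) {
        if (i %in% leaders_idx) next
        xi <- if (stats::runif(1) < p_explore)
          random_triplet_position(snapshot)
        else
          leader_guided_position(snapshot[i, ], leaders, a,
                                 gwo$lower, gwo$upper)
        if (stats::runif(1) < gwo$levy_prob)
          xi <- levy_perturb(alpha_pos, gwo$levy_alpha, gwo$levy_beta,
                             gwo$lower, gwo$upper)
        pos[i, ] <- clip_box(xi, gwo$lower, gwo$upper)
        masks[i, ] <- binarize(pos[i, ])
        r <- eval_mask(masks[i, ], holdout)
        fit[i] <- r$fitness; nsel[i] <- r$n_selected
        note_best(i)
      }
      trace$best_fitness[t] <- best$fitness
      trace$n_selected[t] <- best$n_selected
    }

    if (best$n_selected == 0L) {
      # pathological: every evaluated mask was empty — fall back to the
      # single feature with the lowest univariate wrapper error
      errs <- vapply(seq_len(d), function(j) {
        m <- rep(0L, d); m[j] <- 1L
        eval_mask(m, holdout)$fitness
      }, numeric(1))
      j <- which.min(errs)
      best <- list(fitness = errs[j],
                   mask = replace(rep(0L, d), j, 1L), n_selected = 1L)
      trace$best_fitness[gwo$max_iter] <- best$fitness
      trace$n_selected[gwo$max_iter] <- 1L
    }

    final <- wrapper_fitness(best$mask, train, fs, holdout = holdout)
    structure(list(mask = stats::setNames(best$mask, feat),
                   selected = feat[best$mask == 1L],
                   best_fitness = best$fitness,
                   error_rate = final$error_rate,
                   trace = trace,
                   gwo = gwo, fitness = fs, p_explore = p_explore,
                   holdout_idx = holdout, train = train,
                   seed = gwo$seed, call = NULL),
              class = "ebgwo")
  })
}

#' @export
print.ebgwo <- function(x, ...) {
  cat("Enhanced binary grey wolf feature selection\n")
  if (!is.null(x$call)) {
    cat("Call: "); print(x$call)
  }
  cat("  features: ", length(x$selected), " selected of ",
      length(x$mask), " (reduction ",
      sprintf("%.1f%%", 100 * (1 - length(x$selected) / length(x$mask))),
      ")\n", sep = "")
  cat("  best fitness: ", format(x$best_fitness, digits = 6),
      "   wrapper error rate: ", format(x$error_rate, digits = 4),
      "\n", sep = "")
  cat("  ", x$gwo$pack_size, " wolves, ", x$gwo$max_iter,
      " iterations, seed ",
      if (is.null(x$seed)) "unset" else x$seed, "\n", sep = "")
  invisible(x)
}

#' Summarize an EBGWO selection
#'
#' @param object an `ebgwo` fit.
#' @param ... ignored.
#' @return a `summary.ebgwo` list with the selection size, fitness
#'   decomposition, and (when the table carries group tags) the per-group
#'   selected counts.
#' @export
summary.ebgwo <- function(object, ...) {
  groups <- object$train$groups
  by_group <- NULL
  if (!is.null(groups)) {
    tot <- table(groups[names(object$mask)])
    sel <- table(factor(groups[object$selected], levels = names(tot)))
    by_group <- data.frame(group = names(tot),
                           selected = as.integer(sel),
                           total = as.integer(tot))
  }
  structure(list(n_selected = length(object$selected),
                 n_total = length(object$mask),
                 reduction = 1 - length(object$selected) /
                   length(object$mask),
                 best_fitness = object$best_fitness,
                 error_rate = object$error_rate,
                 alpha_weight = object$fitness$alpha_weight,
                 by_group = by_group,
                 trace_tail = utils::tail(object$trace, 1L)),
            class = "summary.ebgwo")
}

#' @export
print.summary.ebgwo <- function(x, ...) {
  cat("EBGWO selection: ", x$n_selected, "/", x$n_total, " features (",
      sprintf("%.1f%%", 100 * x$reduction), " reduction)\n", sep = "")
  cat("fitness ", format(x$best_fitness, digits = 6), " = ",
      x$alpha_weight, " * ER(", format(x$error_rate, digits = 4),
      ") + ", format(1 - x$alpha_weight, digits = 3), " * |R|/|C|\n",
      sep = "")
  if (!is.null(x$by_group)) {
    cat("selected per feature group:\n")
    print(x$by_group, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.ebgwo <- function(object, ...) {
  stats::setNames(as.numeric(object$mask), names(object$mask))
}

#' Plot the EBGWO convergence trace
#'
#' Best-so-far wrapper fitness against iteration; a second axis line
#' reports the selected-subset size of the incumbent.
#'
#' @param x an `ebgwo` fit.
#' @param ... passed to [plot()].
#' @export
plot.ebgwo <- function(x, ...) {
  tr <- x$trace
  plot(tr$iteration, tr$best_fitness, type = "s",
       xlab = "iteration", ylab = "best wrapper fitness",
       main = "EBGWO convergence", ...)
  graphics::mtext(sprintf("final subset: %d/%d features",
                          length(x$selected), length(x$mask)),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(x)
}

#' Predict with the induction classifier on the selected subset
#'
#' Applies the fit's induction k-NN, trained on the full training table
#' restricted to the selected features, to new recordings. New data must be
#' standardized with the same parameters as the training table.
#'
#' @param object an `ebgwo` fit.
#' @param newdata a [feature_table] or numeric matrix with the training
#'   feature columns.
#' @param type `"class"` for 0/1 predictions, `"score"` for the fraction of
#'   positive neighbours.
#' @param ... ignored.
#' @return integer predictions or numeric scores.
#' @export
predict.ebgwo <- function(object, newdata,
                          type = c("class", "score"), ...) {
  type <- match.arg(type)
  xnew <- if (inherits(newdata, "feature_table")) newdata$x
          else as.matrix(newdata)
  if (!is.null(colnames(xnew)))
    xnew <- xnew[, names(object$mask), drop = FALSE]
  cols <- which(object$mask == 1L)
  res <- rng_isolated(
    class::knn(object$train$x[, cols, drop = FALSE],
               xnew[, cols, drop = FALSE],
               factor(object$train$labels, levels = c(0L, 1L)),
               k = object$fitness$induction_k, use.all = TRUE,
               prob = TRUE))
  pred <- as.integer(as.character(res))
  if (type == "class") return(pred)
  pwin <- attr(res, "prob")
  ifelse(pred == 1L, pwin, 1 - pwin)
}

#' Serialize a selection result to JSON
#'
#' @param object an `ebgwo` fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(object, path) {
  stopifnot(inherits(object, "ebgwo"))
  jsonlite::write_json(
    list(selected = object$selected,
         mask = paste(object$mask, collapse = ""),
         best_fitness = object$best_fitness,
         error_rate = object$error_rate,
         n_iterations = object$gwo$max_iter,
         seed = object$seed,
         config = list(pack_size = object$gwo$pack_size,
                       levy_beta = object$gwo$levy_beta,
                       levy_alpha = object$gwo$levy_alpha,
                       levy_prob = object$gwo$levy_prob,
                       p_explore = object$p_explore,
                       alpha_weight = object$fitness$alpha_weight,
                       induction_k = object$fitness$induction_k,
                       holdout_fraction = object$fitness$holdout_fraction)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized selection mask
#'
#' @param path JSON path written by [write_selection()].
#' @return list with `selected` names, integer `mask`, and the stored
#'   metadata.
#' @export
read_selection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$mask <- as.integer(strsplit(obj$mask, "")[[1]])
  obj
}

#' Export the convergence trace as CSV
#'
#' Two/three-column CSV: iteration, best_fitness, n_selected.
#'
#' @param object an `ebgwo` fit (or a `gwo_fit`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(object, path) {
  tr <- if (inherits(object, "ebgwo")) object$trace
        else data.frame(iteration = seq_along(object$trace),
                        best_fitness = object$trace)
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}
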