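#' Grey wolf optimizer configuration
#'
#' @param dim search-space dimension.
#' @param pack_size number of wolves (>= 4: the alpha/beta/delta leaders
#'   plus at least one omega). Default 10.
#' @param max_iter iteration budget T. Default 1000.
#' @param levy_beta Levy stability control parameter, in (0, 2]. Default 0.5.
#' @param levy_alpha Levy step-size scale (> 0). Default 0.1.
#' @param levy_prob probability that a wolf's update is followed by a Levy
#'   perturbation around the current alpha. Default 0.5.
#' @param lower,upper box bounds, recycled over dimensions. Default [0, 1].
#' @param seed integer seed; equal seeds make runs bit-reproducible.
#' @return an object of class `gwo_config`.
#' @export
gwo_config <- function(dim, pack_size = 10L, max_iter = 1000L,
                       levy_beta = 0.5, levy_alpha = 0.1, levy_prob = 0.5,
                       lower = 0, upper = 1, seed = NULL) {
  stopifnot(dim >= 1L, pack_size >= 4L, max_iter >= 1L,
            levy_beta > 0, levy_beta <= 2, levy_alpha > 0,
            levy_prob >= 0, levy_prob <= 1)
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  if (any(lower >= upper)) stop("need lower < upper", call. = FALSE)
  structure(list(dim = as.integer(dim), pack_size = as.integer(pack_size),
                 max_iter = as.integer(max_iter), levy_beta = levy_beta,
                 levy_alpha = levy_alpha, levy_prob = levy_prob,
                 lower = lower, upper = upper, seed = seed),
            class = "gwo_config")
}

#' Linear coefficient schedule
#'
#' The encircling coefficient `a` decays linearly from 2 at the first
#' iteration to 0 at the last: a(t) = 2 - 2 t / T. Large `a` favours
#' exploration (wolves can overshoot the leaders), small `a` exploitation.
#'
#' @param t current iteration, 0 <= t <= T.
#' @param T maximum iteration (>= 1).
#' @return the scalar coefficient a in [0, 2].
#' @export
a_schedule <- function(t, T) {
  stopifnot(T >= 1)
  if (any(t < 0) || any(t > T))
    stop("iteration t must satisfy 0 <= t <= T", call. = FALSE)
  2 - 2 * t / T
}

#' Draw encircling coefficient vectors
#'
#' Per dimension, A = 2 a r1 - a and C = 2 r2 with r1, r2 ~ Uniform(0, 1).
#' The r1 vector is drawn first, then r2 (a documented order that
#' record-and-replay tests rely on).
#'
#' @param a scalar schedule coefficient in [0, 2].
#' @param dim dimension.
#' @return list with numeric vectors `A` (in [-a, a]) and `C` (in [0, 2]).
#' @export
gwo_coefficients <- function(a, dim) {
  stopifnot(a >= 0, a <= 2, dim >= 1)
  r1 <- stats::runif(dim)
  r2 <- stats::runif(dim)
  list(A = 2 * a * r1 - a, C = 2 * r2)
}

# clip to the box
clip_box <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Encircling update
#'
#' One wolf's move toward a target (prey) position: D = |C * x_p - x|
#' componentwise, then x' = x_p - A * D, clipped to the box.
#'
#' @param x current position.
#' @param x_p target position (same length).
#' @param A,C coefficient vectors from [gwo_coefficients()].
#' @param lower,upper box bounds.
#' @return the updated position.
#' @export
encircle <- function(x, x_p, A, C, lower = 0, upper = 1) {
  if (length(x) != length(x_p) || length(A) != length(x) ||
      length(C) != length(x))
    stop("position and coefficient vectors must share one dimension",
         call. = FALSE)
  D <- abs(C * x_p - x)
  clip_box(x_p - A * D, lower, upper)
}

#' Leader-guided position update
#'
#' Moves a wolf toward the pack's three leaders: an encircling step toward
#' each of alpha, beta and delta with fresh coefficient draws (in that
#' order), averaged and clipped. With a = 0 every candidate collapses onto
#' its leader, so the result is the leader centroid.
#'
#' @param x current position.
#' @param leaders 3 x dim matrix of the alpha, beta, delta positions (rows
#'   in rank order).
#' @param a schedule coefficient from [a_schedule()].
#' @param lower,upper box bounds.
#' @return the updated position.
#' @export
leader_guided_position <- function(x, leaders, a, lower = 0, upper = 1) {
  if (!is.matrix(leaders) || nrow(leaders) != 3L ||
      ncol(leaders) != length(x))
    stop("`leaders` must be a 3 x length(x) matrix", call. = FALSE)
  cand <- matrix(0, 3L, length(x))
  for (l in 1:3) {
    co <- gwo_coefficients(a, length(x))
    cand[l, ] <- encircle(x, leaders[l, ], co$A, co$C, lower, upper)
  }
  clip_box(colMeans(cand), lower, upper)
}

#' Mantegna scale for Levy steps
#'
#' Closed-form sigma_u of the Mantegna construction:
#' sigma_u = \{Gamma(1+beta) sin(pi beta / 2) /
#'            [Gamma((1+beta)/2) beta 2^((beta-1)/2)]\}^(1/beta).
#' At beta = 1 this evaluates to exactly 1.
#'
#' @param beta stability control parameter in (0, 2].
#' @return the scalar sigma_u.
#' @export
levy_sigma_u <- function(beta) {
  if (beta <= 0 || beta > 2)
    stop("beta must satisfy 0 < beta <= 2", call. = FALSE)
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Sample heavy-tailed Levy steps
#'
#' Mantegna construction: per dimension, step = u / |v|^(1/beta) with
#' u ~ Normal(0, sigma_u^2) and v ~ Normal(0, 1), sigma_u from
#' [levy_sigma_u()]. The full u vector is drawn before the v vector. Small
#' beta gives heavier tails (occasional very long jumps); beta near 2
#' approaches Gaussian behaviour.
#'
#' @param beta stability control parameter in (0, 2].
#' @param dim number of independent steps.
#' @return numeric step vector of length `dim`.
#' @export
levy_sample <- function(beta, dim) {
  sigma_u <- levy_sigma_u(beta)
  u <- stats::rnorm(dim, 0, sigma_u)
  v <- stats::rnorm(dim, 0, 1)
  u / abs(v)^(1 / beta)
}

#' Levy-flight perturbation around the best position
#'
#' y' = y_best + alpha_step * Levy(beta), clipped to the box. The
#' occasional long Levy jumps push wolves out of the basin of the current
#' best, improving exploration.
#'
#' @param y_best position of the current best solution.
#' @param alpha_step step-size scale (> 0).
#' @param beta Levy control parameter in (0, 2].
#' @param lower,upper box bounds.
#' @return the perturbed, clipped position.
#' @export
levy_perturb <- function(y_best, alpha_step, beta, lower = 0, upper = 1) {
  stopifnot(alpha_step > 0)
  clip_box(y_best + alpha_step * levy_sample(beta, length(y_best)),
           lower, upper)
}

#' Minimize a function with Levy-enhanced grey wolf optimization
#'
#' Initializes a pack uniformly in the box, then iterates: rank wolves by
#' objective value to find the alpha/beta/delta leaders, move every wolf by
#' the leader-guided encircling update, and with probability `levy_prob`
#' apply a Levy perturbation around the current alpha. The best-ever
#' solution is tracked separately from the pack, so the convergence trace is
#' monotone non-increasing.
#'
#' RNG draw order per run: initialization (pack_size x dim uniforms,
#' wolves in row order), then per iteration and per wolf the three
#' leader-coefficient pairs, one levy-gate uniform, and (if gated in) the
#' Levy u/v normals.
#'
#' @param objective function mapping a dim-vector to a finite scalar.
#' @param config a [gwo_config()].
#' @return list of class `gwo_fit` with `par` (best position), `value`
#'   (best objective), and `trace` (best-so-far value per iteration, length
#'   `max_iter`).
#' @export
#' @examples
#' fit <- gwo_minimize(function(x) sum(x^2),
#'                     gwo_config(dim = 3, max_iter = 50, lower = -1,
#'                                upper = 1, seed = 1))
#' fit$value
gwo_minimize <- function(objective, config) {
  stopifnot(inherits(config, "gwo_config"), is.function(objective))
  d <- config$dim; np <- config$pack_size
  lo <- config$lower; up <- config$upper

  eval_obj <- function(x) {
    v <- objective(x)
    if (!is.finite(v))
      stop("objective returned a non-finite value at position (",
           paste(signif(x, 4), collapse = ", "), ")", call. = FALSE)
    v
  }

  with_seed(config$seed, {
    pos <- matrix(stats::runif(np * d), np, d, byrow = TRUE)
    pos <- sweep(sweep(pos, 2L, up - lo, "*"), 2L, lo, "+")
    fit <- apply(pos, 1L, eval_obj)

    best_i <- which.min(fit)
    best_par <- pos[best_i, ]; best_val <- fit[best_i]
    trace <- numeric(config$max_iter)

    for (t in seq_len(config$max_iter)) {
      a <- a_schedule(t, config$max_iter)
      rank <- order(fit)
      leaders <- pos[rank[1:3], , drop = FALSE]
      alpha_pos <- pos[rank[1L], ]
      for (i in seq_len(np)) {
        xi <- leader_guided_position(pos[i, ], leaders, a, lo, up)
        if (stats::runif(1) < config$levy_prob)
          xi <- levy_perturb(alpha_pos, config$levy_alpha,
                             config$levy_beta, lo, up)
        pos[i, ] <- xi
      }
      fit <- apply(pos, 1L, eval_obj)
      it_best <- which.min(fit)
      if (fit[it_best] < best_val) {
        best_val <- fit[it_best]; best_par <- pos[it_best, ]
      }
      trace[t] <- best_val
    }
    structure(list(par = best_par, value = best_val, trace = trace,
                   config = config),
              class = "gwo_fit")
  })
}

#' @export
print.gwo_fit <- function(x, ...) {
  cat("<gwo_fit> dim ", x$config$dim, ", pack ", x$config$pack_size,
      ", ", x$config$max_iter, " iterations\n", sep = "")
  cat("  best value: ", format(x$value, digits = 6), "\n", sep = "")
  invisible(x)
}
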