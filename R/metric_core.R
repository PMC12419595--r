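# Bilinear similarity model and the single-task baseline trainer
# ("isolated learning": one metric per kinship type, no shared structure).

#' Bilinear similarity score
#'
#' The similarity between a parent descriptor `p` and a child descriptor `c`
#' under a square metric matrix `W` is the bilinear form `t(p) %*% W %*% c`.
#' No symmetry or positive-definiteness is imposed on `W`.
#'
#' @param p,c Numeric vectors of equal length.
#' @param W Square numeric matrix matching the vector length.
#' @return A single numeric score.
#' @export
bilinear_similarity <- function(p, c, W) {
  p <- as.numeric(p); c <- as.numeric(c)
  if (length(p) != length(c)) stopf("p and c must have the same length")
  if (!is.matrix(W) || nrow(W) != length(p) || ncol(W) != length(c)) {
    stopf("W must be a %d x %d matrix", length(p), length(c))
  }
  drop(crossprod(p, W %*% c))
}

#' Hinge loss
#'
#' `max(0, 1 - y * s)` for labels `y` in \{+1, -1\} and scores `s`;
#' vectorized over both arguments.
#'
#' @param y Labels (+1 / -1).
#' @param s Similarity scores.
#' @return Numeric vector of losses.
#' @export
hinge_loss <- function(y, s) pmax(0, 1 - y * s)

#' Regularized single-task objective
#'
#' Sum of hinge losses over all pairs of a task plus a Frobenius-norm
#' penalty `lambda/2 * ||W||_F^2`.
#'
#' @param task A [task_data] object.
#' @param W Metric matrix, `d x d`.
#' @param lambda Non-negative regularization weight.
#' @return Objective value (numeric scalar).
#' @export
isolated_objective <- function(task, W, lambda) {
  stopifnot(lambda >= 0)
  s <- score_pairs(task$parent, task$child, W)
  sum(hinge_loss(task$label, s)) + lambda / 2 * frob2(W)
}

#' Full-batch sub-gradient of the single-task objective
#'
#' Analytic sub-gradient of [isolated_objective] with respect to `W`:
#' `lambda * W` minus the sum of `y_i * p_i %*% t(c_i)` over pairs with a
#' violated margin (`y_i * s_i < 1`). At a kink (`y * s == 1` exactly) the
#' regularizer-only branch is taken.
#'
#' @inheritParams isolated_objective
#' @return A `d x d` gradient matrix.
#' @export
isolated_gradient <- function(task, W, lambda) {
  s <- score_pairs(task$parent, task$child, W)
  viol <- task$label * s < 1
  G <- lambda * W
  if (any(viol)) {
    G <- G - crossprod(task$parent[viol, , drop = FALSE] * task$label[viol],
                       task$child[viol, , drop = FALSE])
  }
  G
}

#' Train a single-task bilinear metric (isolated learning baseline)
#'
#' Stochastic sub-gradient descent on [isolated_objective]: starting from the
#' identity, each iteration samples one pair uniformly at random, takes the
#' sub-gradient step `W <- W - alpha * G` with
#' `G = -y * p %*% t(c) + lambda * W` when the margin is violated
#' (`y * s < 1`) and `G = lambda * W` otherwise. The full-data objective is
#' recorded every iteration; training stops after `n_iter` iterations or as
#' soon as the objective change between consecutive iterations falls below
#' `tau` (checked from iteration 3 on).
#'
#' @param task A [task_data] object with at least one positive and one
#'   negative pair.
#' @param lambda Frobenius regularization weight (>= 0).
#' @param alpha Learning rate (> 0).
#' @param n_iter Maximum number of stochastic iterations.
#' @param tau Convergence threshold on the objective change.
#' @param seed Integer seed controlling the pair sampling; fixed seed gives
#'   bitwise-identical results.
#' @param w_init Optional starting matrix (default: identity).
#' @return A list of class `isolated_fit` with elements `W` (learned metric),
#'   `objective` (per-iteration objective trace), `sampled` (sequence of
#'   sampled pair indices) and `iterations`.
#' @export
train_isolated <- function(task, lambda = 0.01, alpha = 0.01, n_iter = 200,
                           tau = 0.1, seed = 1, w_init = NULL) {
  check_trainable(task)
  stopifnot(alpha > 0, lambda >= 0, n_iter >= 1)
  d <- task$d
  W <- if (is.null(w_init)) diag(d) else check_matrix(w_init, "w_init")
  trace <- numeric(0)
  sampled <- integer(0)
  with_seed(seed, {
    for (r in seq_len(n_iter)) {
      i <- sample.int(task$n, 1L)
      sampled[r] <- i
      p <- task$parent[i, ]; cc <- task$child[i, ]; y <- task$label[i]
      s <- drop(crossprod(p, W %*% cc))
      G <- lambda * W
      if (y * s < 1) G <- G - y * tcrossprod(p, cc)
      W <- W - alpha * G
      f <- isolated_objective(task, W, lambda)
      if (!is.finite(f)) {
        stopf("objective diverged at iteration %d (alpha = %g)", r, alpha)
      }
      trace[r] <- f
      if (r > 2 && smoothed_delta(trace, r) < tau) break
    }
  })
  structure(list(W = W, objective = trace, sampled = sampled,
                 iterations = length(trace)),
            class = "isolated_fit")
}
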