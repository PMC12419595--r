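# Multi-task objective and its alternating stochastic sub-gradient
# optimizer: every task metric decomposes as W_v = W0 + Wstar_v, the shared
# part W0 pooling gradient information across all selected tasks, the
# task-specific parts absorbing per-type deviations, and the simplex
# weights beta balancing task influence.

#' Training configuration
#'
#' Collects every hyperparameter of the multi-task trainer. `lambda`
#' regularizes the task-specific matrices, `eta` the shared matrix, `alpha`
#' is the common learning rate, `theta` the Lagrange-multiplier constant of
#' the weight update, `k` the number of auxiliary kinship types, `tau` the
#' convergence threshold on the objective change, `n_iter` the iteration
#' budget, and `s` the small constant giving the target task its dominant
#' initial weight. `svdd_c` and `svdd_gamma` parameterize the SVDD used for
#' correlation discovery and filtering; `svm_cost` is the cost of the final
#' decision-layer SVM.
#'
#' @param lambda,eta Non-negative regularization weights.
#' @param alpha Positive learning rate.
#' @param theta Lagrange-multiplier constant of the weight update.
#' @param k Number of correlated auxiliary types, 0..3.
#' @param tau Positive convergence threshold (default 0.1).
#' @param n_iter Iteration budget (default 200).
#' @param s Small positive constant for the target's initial weight.
#' @param svdd_c,svdd_gamma SVDD hyperparameters (see [fit_svdd]).
#' @param svm_cost Cost parameter of the decision-layer SVM.
#' @param seed Integer seed for all stochastic steps.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lambda = 1, eta = 1, alpha = 0.01, theta = 2000,
                         k = 2, tau = 0.1, n_iter = 200, s = 1e-6,
                         svdd_c = 1, svdd_gamma = NULL, svm_cost = 1,
                         seed = 1) {
  stopifnot(lambda >= 0, eta >= 0, alpha > 0, tau > 0, n_iter >= 1,
            s > 0, k %in% 0:3)
  structure(list(lambda = lambda, eta = eta, alpha = alpha, theta = theta,
                 k = as.integer(k), tau = tau, n_iter = as.integer(n_iter),
                 s = s, svdd_c = svdd_c, svdd_gamma = svdd_gamma,
                 svm_cost = svm_cost, seed = as.integer(seed)),
            class = "train_config")
}

new_mtl_model <- function(tasks, W0, Wstar, beta) {
  structure(list(tasks = tasks, W0 = W0, Wstar = Wstar, beta = beta),
            class = "mtl_model")
}

#' @export
print.mtl_model <- function(x, ...) {
  cat(sprintf("mtl_model: tasks [%s], d = %d\n",
              paste(x$tasks, collapse = ", "), nrow(x$W0)))
  cat("  beta:", paste(sprintf("%s=%.3g", x$tasks, x$beta), collapse = ", "),
      "\n")
  invisible(x)
}

#' Effective metric of one task
#'
#' `W0 + Wstar_v`: the shared structure plus the task-specific deviation.
#'
#' @param model An `mtl_model`.
#' @param v Task index (1 = target).
#' @return A `d x d` metric matrix.
#' @export
effective_metric <- function(model, v) {
  stopifnot(inherits(model, "mtl_model"))
  if (!(v %in% seq_along(model$tasks))) stopf("invalid task index %d", v)
  model$W0 + model$Wstar[[v]]
}

#' Multi-task similarity score
#'
#' Bilinear score of a pair under task `v`'s effective metric.
#'
#' @inheritParams bilinear_similarity
#' @inheritParams effective_metric
#' @return A single numeric score.
#' @export
mtl_similarity <- function(p, c, model, v) {
  bilinear_similarity(p, c, effective_metric(model, v))
}

#' Multi-task objective value
#'
#' `sum_v ( beta_v * sum_i hinge(y_vi, s_vi) + lambda/2 ||Wstar_v||_F^2 )
#'  + eta/2 ||W0||_F^2`, where `s_vi` is the score of pair `i` of task `v`
#' under `W0 + Wstar_v`.
#'
#' @param model An `mtl_model`.
#' @param datasets List of [task_data] aligned with `model$tasks`.
#' @param cfg A [train_config].
#' @return Objective value (numeric scalar).
#' @export
ccmtl_objective <- function(model, datasets, cfg) {
  stopifnot(length(datasets) == length(model$tasks))
  f <- cfg$eta / 2 * frob2(model$W0)
  for (v in seq_along(datasets)) {
    t <- datasets[[v]]
    s <- score_pairs(t$parent, t$child, model$W0 + model$Wstar[[v]])
    f <- f + model$beta[v] * sum(hinge_loss(t$label, s)) +
      cfg$lambda / 2 * frob2(model$Wstar[[v]])
  }
  f
}

# Data term of the stochastic sub-gradient for one sampled pair of task v:
# -beta_v * y * p %*% t(c) if the margin is violated, else zero.
sample_data_term <- function(p, c, y, beta_v, s) {
  if (y * s < 1) -beta_v * y * tcrossprod(p, c) else NULL
}

#' Single-sample sub-gradient with respect to the shared matrix
#'
#' For one sampled pair `(p, c, y)` of task `v`: `eta * W0` when the margin
#' is satisfied (`y * s >= 1`), and `-beta_v * y * p %*% t(c) + eta * W0`
#' otherwise.
#'
#' @param p,c Feature vectors of the sampled pair.
#' @param y Label (+1/-1).
#' @param v Task index of the sample.
#' @param model An `mtl_model`.
#' @param cfg A [train_config].
#' @return A `d x d` matrix.
#' @export
subgrad_w0 <- function(p, c, y, v, model, cfg) {
  s <- mtl_similarity(p, c, model, v)
  G <- cfg$eta * model$W0
  dt <- sample_data_term(p, c, y, model$beta[v], s)
  if (!is.null(dt)) G <- G + dt
  G
}

#' Single-sample sub-gradient with respect to a task-specific matrix
#'
#' As [subgrad_w0] with `lambda * Wstar_v` in place of `eta * W0`; only
#' task `v`'s matrix receives the data term.
#'
#' @inheritParams subgrad_w0
#' @return A `d x d` matrix.
#' @export
subgrad_wstar <- function(p, c, y, v, model, cfg) {
  s <- mtl_similarity(p, c, model, v)
  G <- cfg$lambda * model$Wstar[[v]]
  dt <- sample_data_term(p, c, y, model$beta[v], s)
  if (!is.null(dt)) G <- G + dt
  G
}

#' Full-batch analytic gradients of the multi-task objective
#'
#' Sub-gradients of [ccmtl_objective] with respect to the shared matrix,
#' every task-specific matrix, and every task weight (the latter is simply
#' each task's total hinge loss, since the objective is linear in `beta`).
#' Used by the finite-difference correctness checks.
#'
#' @inheritParams ccmtl_objective
#' @return List with elements `W0` (matrix), `Wstar` (list of matrices)
#'   and `beta` (numeric vector of per-task hinge sums).
#' @export
ccmtl_gradients <- function(model, datasets, cfg) {
  d <- nrow(model$W0)
  G0 <- cfg$eta * model$W0
  Gstar <- vector("list", length(datasets))
  gbeta <- numeric(length(datasets))
  for (v in seq_along(datasets)) {
    t <- datasets[[v]]
    s <- score_pairs(t$parent, t$child, model$W0 + model$Wstar[[v]])
    viol <- t$label * s < 1
    data_term <- matrix(0, d, d)
    if (any(viol)) {
      data_term <- -model$beta[v] *
        crossprod(t$parent[viol, , drop = FALSE] * t$label[viol],
                  t$child[viol, , drop = FALSE])
    }
    G0 <- G0 + data_term
    Gstar[[v]] <- cfg$lambda * model$Wstar[[v]] + data_term
    gbeta[v] <- sum(hinge_loss(t$label, s))
  }
  list(W0 = G0, Wstar = Gstar, beta = gbeta)
}

#' One task-weight update
#'
#' Computes the full-batch weight gradient `g_v = sum_i hinge_vi - theta`
#' for every task, takes the step `beta - alpha * g`, and restores
#' feasibility by clipping each coordinate to `[1e-8, 1 - 1e-8]` and
#' renormalizing to sum 1. With `theta` set above the per-task hinge sums
#' (it is a tuned hyperparameter) every raw weight stays positive and the
#' renormalized weights tilt toward the better-fitting tasks.
#'
#' @inheritParams ccmtl_objective
#' @return The model with updated `beta`.
#' @export
update_beta <- function(model, datasets, cfg) {
  if (length(model$beta) == 1L) {
    model$beta <- 1
    return(model)
  }
  g <- vapply(seq_along(datasets), function(v) {
    t <- datasets[[v]]
    s <- score_pairs(t$parent, t$child, model$W0 + model$Wstar[[v]])
    sum(hinge_loss(t$label, s)) - cfg$theta
  }, numeric(1))
  raw <- model$beta - cfg$alpha * g
  lo <- 1e-8; hi <- 1 - 1e-8
  if (all(raw <= lo)) {
    stopf("degenerate task weights: every raw weight fell below the floor; increase theta")
  }
  b <- pmin(pmax(raw, lo), hi)
  b <- b / sum(b)
  model$beta <- b
  model
}

#' Train the correlation-aware multi-task metric
#'
#' Full training pipeline for a target kinship type. Step 1 discovers the
#' correlated auxiliary types: SVDD centroids of positive-pair differences
#' ([compute_correlations]), top-K selection ([select_top_k]) and
#' reciprocal-correlation initial weights ([init_task_weights]). Step 2
#' initializes `W0` and every `Wstar_v` to the identity and alternates,
#' for up to `cfg$n_iter` rounds: sample one pair uniformly from every
#' task, update the shared matrix with the accumulated data terms of all
#' sampled pairs plus its regularizer gradient, update each task-specific
#' matrix with its own sampled pair, then update the task weights
#' ([update_beta]). The full-data objective is evaluated every round and
#' training stops early once its change falls below `cfg$tau` (checked
#' from round 3 on).
#'
#' @param target [task_data] of the kinship type to be learned.
#' @param others List of [task_data] for the remaining types (may be
#'   empty when `cfg$k = 0`).
#' @param cfg A [train_config].
#' @param freeze_w0 If `TRUE`, the shared matrix is fixed at zero and
#'   never updated; with `cfg$k = 0` and `eta = 0` this makes the trainer
#'   behaviorally identical to [train_isolated].
#' @return A list of class `ccmtl_fit`: `model` (the `mtl_model`),
#'   `profile` (the `correlation_profile`), `objective` (trace),
#'   `beta_trace` (iterations x tasks matrix), `sampled` (iterations x
#'   tasks matrix of sampled pair indices), `iterations`.
#' @export
train_ccmtl <- function(target, others = list(), cfg = train_config(),
                        freeze_w0 = FALSE) {
  check_trainable(target)
  stopifnot(inherits(cfg, "train_config"))
  if (cfg$k > length(others)) {
    stopf("k = %d auxiliary types requested but only %d provided",
          cfg$k, length(others))
  }
  names(others) <- vapply(others, `[[`, character(1), "kin_type")

  profile <- if (length(others)) {
    compute_correlations(target, others, C = cfg$svdd_c,
                         gamma = cfg$svdd_gamma, seed = cfg$seed)
  } else {
    new_correlation_profile(target$kin_type, numeric(0))
  }
  profile <- select_top_k(profile, cfg$k)
  profile <- init_task_weights(profile, cfg$s)

  datasets <- c(list(target), unname(others[profile$U]))
  task_names <- c(target$kin_type, profile$U)
  nt <- length(datasets)
  d <- target$d
  for (t in datasets) {
    if (t$d != d) stopf("feature dimensions differ across tasks")
    check_trainable(t)
  }

  W0 <- if (freeze_w0) matrix(0, d, d) else diag(d)
  Wstar <- replicate(nt, diag(d), simplify = FALSE)
  model <- new_mtl_model(task_names, W0, Wstar, unname(profile$beta0))

  trace <- numeric(0)
  beta_trace <- matrix(NA_real_, nrow = 0, ncol = nt)
  sampled <- matrix(NA_integer_, nrow = 0, ncol = nt)

  with_seed(cfg$seed, {
    for (r in seq_len(cfg$n_iter)) {
      idx <- vapply(datasets, function(t) sample.int(t$n, 1L), integer(1))
      ps <- lapply(seq_len(nt), function(v) datasets[[v]]$parent[idx[v], ])
      cs <- lapply(seq_len(nt), function(v) datasets[[v]]$child[idx[v], ])
      ys <- vapply(seq_len(nt), function(v) datasets[[v]]$label[idx[v]],
                   numeric(1))

      if (!freeze_w0) {
        G0 <- cfg$eta * model$W0
        for (v in seq_len(nt)) {
          s <- drop(crossprod(ps[[v]],
                              (model$W0 + model$Wstar[[v]]) %*% cs[[v]]))
          dt <- sample_data_term(ps[[v]], cs[[v]], ys[v], model$beta[v], s)
          if (!is.null(dt)) G0 <- G0 + dt
        }
        model$W0 <- model$W0 - cfg$alpha * G0
      }

      for (v in seq_len(nt)) {
        s <- drop(crossprod(ps[[v]],
                            (model$W0 + model$Wstar[[v]]) %*% cs[[v]]))
        Gv <- cfg$lambda * model$Wstar[[v]]
        dt <- sample_data_term(ps[[v]], cs[[v]], ys[v], model$beta[v], s)
        if (!is.null(dt)) Gv <- Gv + dt
        model$Wstar[[v]] <- model$Wstar[[v]] - cfg$alpha * Gv
      }

      model <- update_beta(model, datasets, cfg)

      f <- ccmtl_objective(model, datasets, cfg)
      if (!is.finite(f)) {
        stopf("objective diverged at iteration %d (alpha = %g)",
              r, cfg$alpha)
      }
      trace[r] <- f
      beta_trace <- rbind(beta_trace, model$beta)
      sampled <- rbind(sampled, idx)
      if (r > 2 && smoothed_delta(trace, r) < cfg$tau) break
    }
  })
  dimnames(beta_trace) <- list(NULL, task_names)
  dimnames(sampled) <- list(NULL, task_names)
  structure(list(model = model, profile = profile, objective = trace,
                 beta_trace = beta_trace, sampled = sampled,
                 iterations = length(trace)),
            class = "ccmtl_fit")
}

#' @export
print.ccmtl_fit <- function(x, ...) {
  cat(sprintf("ccmtl_fit: %d iterations, final objective %.4g\n",
              x$iterations, x$objective[x$iterations]))
  print(x$model)
  invisible(x)
}
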