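# Decision layer and evaluation machinery: SVM on the scalar similarity
# score, leakage-free 5-fold protocol, ROC, label-noise injection, K-sweep.

#' Score pairs under a metric
#'
#' Vectorized bilinear similarity: row `i` of the result is
#' `t(parent[i, ]) %*% W %*% child[i, ]`.
#'
#' @param parent,child Feature matrices (rows are pairs).
#' @param W Square metric matrix.
#' @return Numeric vector of scores.
#' @export
score_pairs <- function(parent, child, W) {
  parent <- as.matrix(parent); child <- as.matrix(child)
  if (!identical(dim(parent), dim(child)) || ncol(parent) != nrow(W)) {
    stopf("dimension mismatch between pairs and metric")
  }
  rowSums((parent %*% W) * child)
}

#' Train the scalar-score decision model
#'
#' Fits a linear SVM on the one-dimensional similarity score and
#' normalizes its orientation so that a positive weight maps higher
#' similarity to "kin". If the SVM orients negatively (or the scores are
#' degenerate), the model falls back to an exhaustive max-accuracy
#' threshold with positive orientation, or to the majority class when the
#' scores carry no information at all.
#'
#' @param scores Numeric vector of training similarity scores.
#' @param labels Labels (+1/-1), both classes present.
#' @param cost SVM cost parameter.
#' @return A list of class `decision_model` with `weight` (> 0), `bias`
#'   and a `degenerate` flag; decide with [predict.decision_model].
#' @export
train_decision <- function(scores, labels, cost = 1) {
  scores <- as.numeric(scores); labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(-1, 1)))
  if (length(unique(labels)) < 2L) {
    stopf("both classes must be present to train the decision model")
  }
  span <- max(scores) - min(scores)
  if (!is.finite(span) || span < 1e-12) {
    # uninformative scores: fall back to the majority class (ties -> -1)
    maj <- if (sum(labels == 1) > sum(labels == -1)) 1 else -1
    big <- max(abs(scores)) + 1
    return(structure(list(weight = 1, bias = maj * big, degenerate = TRUE),
                     class = "decision_model"))
  }
  fit <- e1071::svm(x = matrix(scores, ncol = 1),
                    y = factor(labels, levels = c(-1, 1)),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # align the (w, b) halfspace with the svm's own +1 predictions
  pred_svm <- as.numeric(as.character(predict(fit, matrix(scores, ncol = 1))))
  pred_wb <- ifelse(w * scores + b >= 0, 1, -1)
  if (mean(pred_svm == pred_wb) < 0.5) {
    w <- -w; b <- -b
  }
  if (w <= 0) {
    # orientation contract: higher similarity must not mean "less kin";
    # recover a positively oriented threshold by exhaustive search
    th <- best_threshold(scores, labels)
    return(structure(list(weight = 1, bias = -th, degenerate = FALSE),
                     class = "decision_model"))
  }
  structure(list(weight = w, bias = b, degenerate = FALSE),
            class = "decision_model")
}

# Max-accuracy threshold for decision sign(s - t); candidates are midpoints
# between consecutive distinct scores plus the two outer points.
best_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  acc <- vapply(cand, function(t) mean(ifelse(scores - t >= 0, 1, -1) ==
                                         labels), numeric(1))
  cand[which.max(acc)]
}

#' @export
predict.decision_model <- function(object, scores, ...) {
  ifelse(object$weight * as.numeric(scores) + object$bias >= 0, 1, -1)
}

#' ROC curve from scores
#'
#' Pools scores and true labels, sweeps the threshold over all distinct
#' score values (higher score = "kin") and returns the false/true positive
#' rates, plus the trapezoidal area under the curve.
#'
#' @param scores Numeric similarity scores.
#' @param labels True labels (+1/-1).
#' @return List with a `points` data frame (`fpr`, `tpr`, monotone
#'   non-decreasing) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == -1)
  np <- sum(y == 1); nn <- sum(y == -1)
  # collapse tied scores to their last cumulative count
  keep <- c(diff(scores[ord]) != 0, TRUE)
  pts <- data.frame(fpr = c(0, fp[keep] / nn), tpr = c(0, tp[keep] / np))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  list(points = pts, auc = auc)
}

#' Inject label noise into a task
#'
#' Flips the labels of exactly `round(rate * n)` distinct pairs chosen
#' uniformly at random (seeded). Applying the same seed twice restores the
#' original labels. Intended for training partitions only; evaluation code
#' never calls it on test folds.
#'
#' @param task A [task_data].
#' @param rate Fraction of labels to flip, in `[0, 0.5]`.
#' @param seed Integer seed.
#' @return The task with flipped labels.
#' @export
inject_label_noise <- function(task, rate, seed) {
  if (rate < 0 || rate > 0.5) stopf("noise rate must lie in [0, 0.5]")
  m <- round(rate * task$n)
  if (m == 0) return(task)
  with_seed(seed, {
    flip <- sample.int(task$n, m)
    task$label[flip] <- -task$label[flip]
  })
  task
}

#' Five-fold cross-validated verification accuracy
#'
#' For every held-out fold: restrict every task to its training folds,
#' optionally fit PCA on the pooled training descriptors of the tasks in
#' use, optionally inject label noise into the training partitions, train
#' the requested method (`"isolated"`, `"isolated_svdd"` = SVDD-filtered
#' isolated learning, or `"ccmtl"`), fit the SVM decision layer on the
#' target's training scores, and measure accuracy on the target's held-out
#' pairs (whose labels are never touched). No test-fold record enters any
#' fitting step; the report retains a per-fold audit of the record indices
#' used on each side.
#'
#' @param tasks Named list of [task_data] objects (all four types for
#'   `ccmtl`; at least the target), each carrying fold assignments.
#' @param target Kin type to evaluate.
#' @param method One of `"isolated"`, `"isolated_svdd"`, `"ccmtl"`.
#' @param cfg A [train_config]. Fold `f` trains with seed `cfg$seed + f`.
#' @param pca_dim Optional PCA dimension; `NULL` skips projection (use for
#'   features that are already low-dimensional).
#' @param noise_rate Label-noise fraction applied to every task's training
#'   partition (0 = clean).
#' @param noise_seed Base seed for noise injection.
#' @param n_folds Number of folds (default 5).
#' @return A list of class `eval_report`: `per_fold_accuracy`,
#'   `mean_accuracy`, `roc` (pooled), `auc`, `settings`, `audit`.
#' @export
cross_validate <- function(tasks, target, method = c("isolated",
                                                     "isolated_svdd",
                                                     "ccmtl"),
                           cfg = train_config(), pca_dim = NULL,
                           noise_rate = 0, noise_seed = NULL,
                           n_folds = 5) {
  method <- match.arg(method)
  if (!target %in% names(tasks)) stopf("no task named %s", target)
  for (t in tasks) {
    if (is.null(t$fold)) stopf("task %s carries no fold assignments",
                               t$kin_type)
  }
  use_tasks <- if (method == "ccmtl") tasks else tasks[target]
  noise_seed <- noise_seed %||% cfg$seed

  acc <- numeric(n_folds)
  pooled_scores <- numeric(0); pooled_labels <- numeric(0)
  audit <- vector("list", n_folds)

  for (f in seq_len(n_folds)) {
    test_idx <- which(tasks[[target]]$fold == f)
    if (!length(test_idx)) stopf("empty test fold %d for %s", f, target)
    train <- lapply(use_tasks, function(t) {
      subset_task(t, which(t$fold != f))
    })
    if (noise_rate > 0) {
      train <- lapply(seq_along(train), function(j) {
        inject_label_noise(train[[j]], noise_rate,
                           seed = noise_seed + 101L * f + j)
      })
      names(train) <- names(use_tasks)
    }
    test <- subset_task(tasks[[target]], test_idx)

    if (!is.null(pca_dim)) {
      pool <- do.call(rbind, unlist(lapply(train, function(t) {
        list(t$parent, t$child)
      }), recursive = FALSE))
      proj <- fit_pca(pool, pca_dim)
      train <- lapply(train, function(t) {
        task_data(t$kin_type, apply_pca(proj, t$parent),
                  apply_pca(proj, t$child), t$label, t$fold)
      })
      test <- task_data(test$kin_type, apply_pca(proj, test$parent),
                        apply_pca(proj, test$child), test$label, test$fold)
    }

    seed_f <- cfg$seed + f
    W <- switch(method,
      isolated = train_isolated(train[[target]], lambda = cfg$lambda,
                                alpha = cfg$alpha, n_iter = cfg$n_iter,
                                tau = cfg$tau, seed = seed_f)$W,
      isolated_svdd = {
        filtered <- filter_by_svdd(train[[target]], C = cfg$svdd_c,
                                   gamma = cfg$svdd_gamma)
        train_isolated(filtered, lambda = cfg$lambda, alpha = cfg$alpha,
                       n_iter = cfg$n_iter, tau = cfg$tau, seed = seed_f)$W
      },
      ccmtl = {
        cfg_f <- cfg; cfg_f$seed <- seed_f
        fit <- train_ccmtl(train[[target]],
                           unname(train[names(train) != target]), cfg_f)
        effective_metric(fit$model, 1)
      })

    dec <- train_decision(score_pairs(train[[target]]$parent,
                                      train[[target]]$child, W),
                          train[[target]]$label, cost = cfg$svm_cost)
    s_test <- score_pairs(test$parent, test$child, W)
    acc[f] <- mean(predict(dec, s_test) == test$label)
    pooled_scores <- c(pooled_scores, s_test)
    pooled_labels <- c(pooled_labels, test$label)
    audit[[f]] <- list(
      train = lapply(use_tasks, function(t) which(t$fold != f)),
      test = test_idx)
  }

  roc <- roc_curve(pooled_scores, pooled_labels)
  structure(list(per_fold_accuracy = acc, mean_accuracy = mean(acc),
                 roc = roc$points, auc = roc$auc,
                 settings = list(method = method, target = target,
                                 cfg = cfg, pca_dim = pca_dim,
                                 noise_rate = noise_rate),
                 audit = audit),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s on %s]: mean accuracy %.3f (folds: %s), AUC %.3f\n",
              x$settings$method, x$settings$target, x$mean_accuracy,
              paste(sprintf("%.3f", x$per_fold_accuracy), collapse = " "),
              x$auc))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(per_fold_accuracy = report$per_fold_accuracy,
         mean_accuracy = report$mean_accuracy,
         auc = report$auc,
         roc = report$roc,
         method = report$settings$method,
         target = report$settings$target),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Label-noise robustness sweep
#'
#' Repeats [cross_validate] at each noise rate with `repeats` different
#' noise seeds (training seeds are shared across rates, so the rate-0 row
#' reproduces the clean run exactly) and reports the mean accuracy and its
#' spread per rate.
#'
#' @inheritParams cross_validate
#' @param rates Noise rates, each in `[0, 0.5]`.
#' @param repeats Number of seeded repetitions per rate.
#' @return Data frame with one row per rate: `rate`, `mean_accuracy`,
#'   `sd_accuracy`, `se_accuracy`.
#' @export
noise_sweep <- function(tasks, target, method = "ccmtl",
                        rates = c(0, 0.05, 0.1, 0.15, 0.2), repeats = 10,
                        cfg = train_config(), pca_dim = NULL) {
  rows <- lapply(rates, function(rate) {
    accs <- vapply(seq_len(repeats), function(rep) {
      cross_validate(tasks, target, method, cfg, pca_dim = pca_dim,
                     noise_rate = rate,
                     noise_seed = cfg$seed + 7919L * rep)$mean_accuracy
    }, numeric(1))
    data.frame(rate = rate, mean_accuracy = mean(accs),
               sd_accuracy = sd(accs),
               se_accuracy = sd(accs) / sqrt(repeats))
  })
  do.call(rbind, rows)
}

#' Accuracy as a function of the number of auxiliary types K
#'
#' Runs [cross_validate] once per requested `K`, all else fixed; `K = 0`
#' executes the isolated-learning path by definition.
#'
#' @inheritParams cross_validate
#' @param ks Values of K to evaluate, each in 0..3.
#' @return Data frame with one row per K: `k`, `mean_accuracy`,
#'   `sd_fold`, `se_fold`.
#' @export
k_sweep <- function(tasks, target, ks = 0:3, cfg = train_config(),
                    pca_dim = NULL) {
  rows <- lapply(ks, function(k) {
    rep <- if (k == 0) {
      cross_validate(tasks, target, "isolated", cfg, pca_dim = pca_dim)
    } else {
      cfg_k <- cfg; cfg_k$k <- as.integer(k)
      cross_validate(tasks, target, "ccmtl", cfg_k, pca_dim = pca_dim)
    }
    data.frame(k = k, mean_accuracy = rep$mean_accuracy,
               sd_fold = sd(rep$per_fold_accuracy),
               se_fold = sd(rep$per_fold_accuracy) /
                 sqrt(length(rep$per_fold_accuracy)))
  })
  do.call(rbind, rows)
}
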