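test_that("pair scoring matches the elementwise bilinear oracle", {
  set.seed(51)
  P <- matrix(rnorm(12), 4, 3); C <- matrix(rnorm(12), 4, 3)
  W <- matrix(rnorm(9), 3, 3)
  expect_equal(score_pairs(P, C, diag(3)), rowSums(P * C))
  s <- score_pairs(P, C, W)
  for (i in 1:4) {
    expect_equal(s[i], bilinear_similarity(P[i, ], C[i, ], W))
  }
  expect_equal(score_pairs(P, C, 3 * W), 3 * s)
})

test_that("decision layer separates separable scores and stays oriented", {
  scores <- c(2.1, 3.5, 2.8, -1.2, -0.5, -2)
  labels <- c(1, 1, 1, -1, -1, -1)
  d <- train_decision(scores, labels)
  expect_gt(d$weight, 0)
  expect_false(d$degenerate)
  expect_equal(predict(d, scores), labels)
  # recovered threshold lies within the separating gap
  thr <- -d$bias / d$weight
  expect_gt(thr, -0.5); expect_lt(thr, 2.1)

  # anti-correlated scores: orientation contract still enforced
  d_flip <- train_decision(-scores, labels)
  expect_gt(d_flip$weight, 0)

  expect_error(train_decision(scores, rep(1, 6)), "both classes")
})

test_that("identical scores degrade to a flagged majority decision", {
  d <- train_decision(rep(1.5, 5), c(1, 1, 1, -1, -1))
  expect_true(d$degenerate)
  expect_gt(d$weight, 0)
  expect_equal(unique(predict(d, rep(1.5, 5))), 1)
})

test_that("separable accuracy is invariant to increasing score transforms", {
  scores <- c(0.1, 0.9, 1.4, -2, -0.3, -1)
  labels <- c(1, 1, 1, -1, -1, -1)
  # hard-margin regime: the learned threshold must separate whenever the
  # scores do, whatever their monotone re-expression
  acc <- function(s) {
    mean(predict(train_decision(s, labels, cost = 100), s) == labels)
  }
  expect_equal(acc(scores), 1)
  expect_equal(acc(exp(scores)), 1)
  expect_equal(acc(scores^3), 1)
})

test_that("roc curve is monotone and consistent with accuracy", {
  set.seed(9)
  scores <- c(rnorm(50, 1.5), rnorm(50, -1.5))
  labels <- rep(c(1, -1), each = 50)
  roc <- roc_curve(scores, labels)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_equal(tail(roc$points$fpr, 1), 1)
  expect_equal(tail(roc$points$tpr, 1), 1)
  expect_gt(roc$auc, 0.5)
})

test_that("label noise flips the exact count and is an involution", {
  task <- random_task(n = 100, d = 3, seed = 60)
  expect_identical(inject_label_noise(task, 0, seed = 1), task)
  noisy <- inject_label_noise(task, 0.1, seed = 5)
  expect_equal(sum(noisy$label != task$label), 10)
  restored <- inject_label_noise(noisy, 0.1, seed = 5)
  expect_identical(restored$label, task$label)
  expect_error(inject_label_noise(task, 0.6, seed = 1), "rate")
})

test_that("cross-validation partitions cleanly and reports honest means", {
  gen <- generate_tasks(synth_spec(d = 6, n_pos = 50, n_neg = 50, seed = 3))
  cfg <- train_config(k = 2, n_iter = 40, seed = 2)
  rep <- cross_validate(gen$tasks, "FS", "ccmtl", cfg)
  expect_length(rep$per_fold_accuracy, 5)
  expect_equal(rep$mean_accuracy, mean(rep$per_fold_accuracy),
               tolerance = 1e-12)
  # leakage audit: no fitted record index ever appears in the test fold
  for (f in seq_along(rep$audit)) {
    expect_length(intersect(rep$audit[[f]]$train$FS, rep$audit[[f]]$test), 0)
  }
  # oriented decision layer implies AUC above chance when accuracy is
  expect_true(rep$mean_accuracy <= 0.5 || rep$auc >= 0.5)
})

test_that("uninformative features score at chance level", {
  # children independent of parents: no kin signal at all
  set.seed(71)
  mk <- function(tt) task_data(tt, matrix(rnorm(200 * 6), 200, 6),
                               matrix(rnorm(200 * 6), 200, 6),
                               rep(c(1, -1), 100), rep_len(1:5, 200))
  tasks <- list(FS = mk("FS"))
  cfg <- train_config(n_iter = 40, k = 0, seed = 4)
  rep <- cross_validate(tasks, "FS", "isolated", cfg)
  expect_gt(rep$mean_accuracy, 0.35)
  expect_lt(rep$mean_accuracy, 0.65)
})

test_that("sweeps have the documented shape and row counts", {
  gen <- generate_tasks(synth_spec(d = 6, n_pos = 40, n_neg = 40, seed = 8))
  cfg <- train_config(n_iter = 30, seed = 5)
  ks <- k_sweep(gen$tasks, "FS", ks = c(0, 1), cfg = cfg)
  expect_equal(nrow(ks), 2)
  iso <- cross_validate(gen$tasks, "FS", "isolated", cfg)
  expect_equal(ks$mean_accuracy[1], iso$mean_accuracy)

  ns <- noise_sweep(gen$tasks, "FS", "isolated", rates = c(0, 0.2),
                    repeats = 2, cfg = cfg)
  expect_equal(nrow(ns), 2)
  clean <- cross_validate(gen$tasks, "FS", "isolated", cfg)
  expect_equal(ns$mean_accuracy[1], clean$mean_accuracy)
})

test_that("evaluation reports serialize to JSON", {
  gen <- generate_tasks(synth_spec(d = 5, n_pos = 25, n_neg = 25, seed = 2))
  cfg <- train_config(n_iter = 15, k = 0, seed = 3)
  rep <- cross_validate(gen$tasks, "FS", "isolated", cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$mean_accuracy, rep$mean_accuracy)
  expect_length(back$per_fold_accuracy, 5)
})
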