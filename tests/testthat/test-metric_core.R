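test_that("bilinear similarity matches the explicit triple product", {
  expect_equal(bilinear_similarity(c(1, 0), c(1, 0), diag(2)), 1)
  expect_equal(bilinear_similarity(c(1, 0), c(0, 1), diag(2)), 0)

  p <- c(1, 2); cc <- c(3, -1)
  W <- rbind(c(1, 0), c(2, 1))
  oracle <- 0
  for (i in 1:2) for (j in 1:2) oracle <- oracle + p[i] * W[i, j] * cc[j]
  expect_equal(bilinear_similarity(p, cc, W), oracle)

  expect_error(bilinear_similarity(c(1, 2, 3), c(1, 2), diag(2)), "length")
})

test_that("bilinear similarity is bilinear in its arguments", {
  set.seed(5)
  W <- matrix(rnorm(16), 4, 4)
  p1 <- rnorm(4); p2 <- rnorm(4); cc <- rnorm(4); a <- rnorm(1)
  expect_equal(bilinear_similarity(a * p1, cc, W),
               a * bilinear_similarity(p1, cc, W))
  expect_equal(bilinear_similarity(p1 + p2, cc, W),
               bilinear_similarity(p1, cc, W) + bilinear_similarity(p2, cc, W))
})

test_that("hinge loss takes its textbook values", {
  expect_equal(hinge_loss(1, 2), 0)
  expect_equal(hinge_loss(1, 0), 1)
  expect_equal(hinge_loss(-1, 0.5), 1.5)
  expect_equal(hinge_loss(c(1, -1), c(2, 0.5)), c(0, 1.5))
})

test_that("isolated objective agrees with term-by-term summation", {
  task <- random_task(n = 12, d = 4, seed = 2)
  W0 <- matrix(0, 4, 4)
  expect_equal(isolated_objective(task, W0, lambda = 0.5), task$n)

  set.seed(3)
  W <- matrix(rnorm(16), 4, 4)
  oracle <- 0.25 / 2 * sum(W^2)
  for (i in seq_len(task$n)) {
    s <- sum(outer(task$parent[i, ], task$child[i, ]) * W)
    oracle <- oracle + max(0, 1 - task$label[i] * s)
  }
  expect_equal(isolated_objective(task, W, lambda = 0.25), oracle)
})

test_that("perfectly separated task with unit margins has zero loss", {
  # positives score +4, negatives -4 under the identity
  p <- rbind(c(2, 0), c(2, 0), c(0, 2), c(0, 2))
  ch <- rbind(c(2, 0), c(2, 0), c(0, -2), c(0, -2))
  task <- task_data("FS", p, ch, c(1, 1, -1, -1))
  expect_equal(isolated_objective(task, diag(2), lambda = 0), 0)
})

test_that("analytic isolated sub-gradient matches central finite differences", {
  task <- random_task(n = 15, d = 4, seed = 9)
  set.seed(10)
  W <- matrix(rnorm(16) * 0.3, 4, 4)
  margins <- task$label * score_pairs(task$parent, task$child, W)
  expect_true(all(abs(margins - 1) > 1e-3))  # non-kink probe point
  G <- isolated_gradient(task, W, lambda = 0.6)
  h <- 1e-5
  for (probe in 1:20) {
    D <- matrix(rnorm(16), 4, 4); D <- D / sqrt(sum(D^2))
    fd <- (isolated_objective(task, W + h * D, 0.6) -
             isolated_objective(task, W - h * D, 0.6)) / (2 * h)
    expect_equal(sum(G * D), fd, tolerance = 1e-4)
  }
})

test_that("trainer leaves the identity untouched when all margins hold", {
  # all pairs already satisfy y * s >= 1 under W = I and lambda = 0
  p <- rbind(c(2, 0), c(0, 2), c(2, 0))
  ch <- rbind(c(2, 0), c(0, 2), c(-2, 0))
  task <- task_data("FS", p, ch, c(1, 1, -1))
  fit <- train_isolated(task, lambda = 0, alpha = 0.1, n_iter = 20,
                        tau = 1e-12, seed = 1)
  expect_identical(fit$W, diag(2))
})

test_that("isolated training is deterministic and decreases the objective", {
  task <- random_task(n = 24, d = 5, seed = 4)
  fit1 <- train_isolated(task, lambda = 0.1, alpha = 0.05, n_iter = 60,
                         tau = 1e-9, seed = 11)
  fit2 <- train_isolated(task, lambda = 0.1, alpha = 0.05, n_iter = 60,
                         tau = 1e-9, seed = 11)
  expect_identical(fit1$W, fit2$W)
  expect_identical(fit1$objective, fit2$objective)
  expect_lt(fit1$objective[fit1$iterations],
            isolated_objective(task, diag(5), 0.1))
})

test_that("training is sign-symmetric under label flip and negated start", {
  task <- random_task(n = 18, d = 4, seed = 6)
  flipped <- task_data(task$kin_type, task$parent, task$child, -task$label)
  fit_pos <- train_isolated(task, lambda = 0.2, alpha = 0.03, n_iter = 40,
                            tau = 1e-9, seed = 5)
  fit_neg <- train_isolated(flipped, lambda = 0.2, alpha = 0.03, n_iter = 40,
                            tau = 1e-9, seed = 5, w_init = -diag(4))
  expect_equal(fit_neg$W, -fit_pos$W)
  expect_equal(fit_neg$objective, fit_pos$objective)
})
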