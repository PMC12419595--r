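make_model <- function(d = 4, nt = 3, scale = 0.2, seed = 1,
                       beta = NULL) {
  set.seed(seed)
  kinmtl:::new_mtl_model(
    c("FS", "FD", "MS")[seq_len(nt)],
    matrix(rnorm(d * d) * scale, d, d),
    replicate(nt, matrix(rnorm(d * d) * scale, d, d), simplify = FALSE),
    beta %||% rep(1 / nt, nt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("multi-task similarity composes the shared and specific parts", {
  m <- make_model()
  m$Wstar[[2]] <- matrix(0, 4, 4)
  p <- rnorm(4); cc <- rnorm(4)
  expect_equal(mtl_similarity(p, cc, m, 2), bilinear_similarity(p, cc, m$W0))
  m2 <- m; m2$W0 <- matrix(0, 4, 4)
  expect_equal(mtl_similarity(p, cc, m2, 1),
               bilinear_similarity(p, cc, m2$Wstar[[1]]))
  expect_equal(mtl_similarity(p, cc, m, 1),
               bilinear_similarity(p, cc, m$W0 + m$Wstar[[1]]))
  expect_equal(effective_metric(m, 3), m$W0 + m$Wstar[[3]])
  expect_error(effective_metric(m, 5), "invalid task index")
})

test_that("multi-task objective matches the term-by-term oracle", {
  d <- 4
  datasets <- list(random_task("FS", 10, d, 31), random_task("FD", 8, d, 32),
                   random_task("MS", 12, d, 33))
  cfg <- train_config(lambda = 0.3, eta = 0.7, k = 2)
  m <- make_model(d = d, beta = c(0.5, 0.3, 0.2))

  oracle <- 0.7 / 2 * sum(m$W0^2)
  for (v in 1:3) {
    t <- datasets[[v]]
    Wv <- m$W0 + m$Wstar[[v]]
    hv <- 0
    for (i in seq_len(t$n)) {
      s <- drop(t(t$parent[i, ]) %*% Wv %*% t$child[i, ])
      hv <- hv + max(0, 1 - t$label[i] * s)
    }
    oracle <- oracle + m$beta[v] * hv + 0.3 / 2 * sum(m$Wstar[[v]]^2)
  }
  expect_equal(ccmtl_objective(m, datasets, cfg), oracle, tolerance = 1e-10)

  # all matrices zero: every hinge is 1
  mz <- m
  mz$W0 <- matrix(0, d, d)
  mz$Wstar <- replicate(3, matrix(0, d, d), simplify = FALSE)
  cfg0 <- train_config(lambda = 0, eta = 0, k = 2)
  expect_equal(ccmtl_objective(mz, datasets, cfg0),
               sum(m$beta * vapply(datasets, `[[`, numeric(1), "n")))
})

test_that("with one task the objective reduces to the isolated form", {
  d <- 4
  task <- random_task("FS", 15, d, 7)
  m <- make_model(d = d, nt = 1, beta = 1)
  cfg <- train_config(lambda = 0.4, eta = 0.9, k = 0)
  expect_equal(ccmtl_objective(m, list(task), cfg),
               isolated_objective(task, m$W0 + m$Wstar[[1]], 0) +
                 0.4 / 2 * sum(m$Wstar[[1]]^2) + 0.9 / 2 * sum(m$W0^2))
})

test_that("single-sample sub-gradients take the specified branches", {
  d <- 3
  m <- make_model(d = d, beta = c(0.5, 0.3, 0.2))
  cfg <- train_config(lambda = 0.4, eta = 0.25, k = 2)

  # force a satisfied margin: huge aligned pair
  p_big <- c(10, 0, 0); c_big <- drop(solve(m$W0 + m$Wstar[[1]], c(1, 0, 0)))
  s <- mtl_similarity(p_big, c_big, m, 1)
  if (s < 1) { c_big <- c_big * 2 / s; s <- mtl_similarity(p_big, c_big, m, 1) }
  expect_gte(s, 1)
  expect_equal(subgrad_w0(p_big, c_big, 1, 1, m, cfg), 0.25 * m$W0)
  expect_equal(subgrad_wstar(p_big, c_big, 1, 1, m, cfg), 0.4 * m$Wstar[[1]])

  # violated margin with eta = 0: pure outer product
  cfg0 <- train_config(lambda = 0, eta = 1e-12, k = 2)
  cfg0$eta <- 0
  m0 <- m
  m0$W0 <- matrix(0, d, d)
  m0$Wstar[[1]] <- matrix(0, d, d)
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  G <- subgrad_w0(e1, e2, 1, 1, m0, cfg0)
  expected <- matrix(0, d, d); expected[1, 2] <- -0.5
  expect_equal(G, expected)
  expect_equal(subgrad_wstar(e1, e2, 1, 1, m0, cfg0), expected)
})

test_that("weight update tilts away from the worst-fitting task", {
  d <- 3
  # task 1 fits perfectly, task 2 is hopeless
  good <- task_data("FS", rbind(c(2, 0, 0), c(0, 2, 0)),
                    rbind(c(2, 0, 0), c(0, -2, 0)), c(1, -1))
  bad <- task_data("FD", rbind(c(2, 0, 0), c(0, 2, 0)),
                   rbind(c(-2, 0, 0), c(0, 2, 0)), c(1, -1))
  m <- kinmtl:::new_mtl_model(c("FS", "FD"), diag(3) * 0.5,
                              list(diag(3) * 0.5, diag(3) * 0.5),
                              c(0.5, 0.5))
  cfg <- train_config(lambda = 0, eta = 0, alpha = 0.001, theta = 10, k = 1)
  m2 <- update_beta(m, list(good, bad), cfg)
  expect_lt(m2$beta[2], m$beta[2])
  expect_gt(m2$beta[1], m$beta[1])
  expect_equal(sum(m2$beta), 1, tolerance = 1e-12)
  expect_true(all(m2$beta > 0 & m2$beta < 1))

  # theta far below every hinge sum drives all raw weights under the floor
  cfg_bad <- train_config(lambda = 0, eta = 0, alpha = 1, theta = -1e9, k = 1)
  expect_error(update_beta(m, list(good, bad), cfg_bad), "degenerate")
})

test_that("analytic full-batch gradients match finite differences", {
  set.seed(77)
  d <- 6
  datasets <- list(random_task("FS", 10, d, 41), random_task("FD", 10, d, 42),
                   random_task("MS", 10, d, 43))
  m <- make_model(d = d, scale = 0.15, seed = 78, beta = c(0.4, 0.35, 0.25))
  cfg <- train_config(lambda = 0.5, eta = 0.8, k = 2)
  g <- ccmtl_gradients(m, datasets, cfg)
  f <- function(mm) ccmtl_objective(mm, datasets, cfg)
  h <- 1e-5
  for (probe in 1:10) {
    D <- matrix(rnorm(d * d), d, d); D <- D / sqrt(sum(D^2))
    mp <- m; mp$W0 <- m$W0 + h * D
    mm_ <- m; mm_$W0 <- m$W0 - h * D
    expect_equal(sum(g$W0 * D), (f(mp) - f(mm_)) / (2 * h), tolerance = 1e-4)
    v <- sample(1:3, 1)
    mp <- m; mp$Wstar[[v]] <- m$Wstar[[v]] + h * D
    mm_ <- m; mm_$Wstar[[v]] <- m$Wstar[[v]] - h * D
    expect_equal(sum(g$Wstar[[v]] * D), (f(mp) - f(mm_)) / (2 * h),
                 tolerance = 1e-4)
  }
  # the objective is linear in beta: gradient is the exact hinge sum
  for (v in 1:3) {
    mp <- m; mp$beta[v] <- m$beta[v] + h
    mm_ <- m; mm_$beta[v] <- m$beta[v] - h
    expect_equal(g$beta[v], (f(mp) - f(mm_)) / (2 * h), tolerance = 1e-6)
  }
})

test_that("multi-task training is deterministic and objective trends down", {
  gen <- generate_tasks(synth_spec(d = 8, n_pos = 40, n_neg = 40, seed = 5))
  cfg <- train_config(k = 2, n_iter = 60, tau = 1e-9, seed = 13)
  fit1 <- train_ccmtl(gen$tasks$FS, unname(gen$tasks[c("FD", "MS", "MD")]),
                      cfg)
  fit2 <- train_ccmtl(gen$tasks$FS, unname(gen$tasks[c("FD", "MS", "MD")]),
                      cfg)
  expect_identical(fit1$model, fit2$model)
  expect_identical(fit1$objective, fit2$objective)
  expect_identical(fit1$sampled, fit2$sampled)
  # stochastic descent sanity: early window median above late window median
  expect_gt(median(head(fit1$objective, 20)), median(tail(fit1$objective, 20)))
  # task order: target first, then ascending correlation
  expect_equal(fit1$model$tasks[1], "FS")
  expect_equal(fit1$model$tasks[-1], fit1$profile$U)
})

test_that("requesting more auxiliary types than provided is an error", {
  task <- random_task("FS", 10, 4, 3)
  expect_error(train_ccmtl(task, list(), train_config(k = 1)),
               "auxiliary")
})
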