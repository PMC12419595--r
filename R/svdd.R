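# Support vector data description (SVDD): a one-class boundary over
# positive-pair difference vectors, used both to locate per-type centroids
# (correlation discovery) and to filter outlying positive pairs.

rbf_kernel <- function(x, z = NULL, gamma) {
  x <- as.matrix(x)
  if (is.null(z)) z <- x else z <- as.matrix(z)
  xn <- rowSums(x * x); zn <- rowSums(z * z)
  d2 <- outer(xn, zn, "+") - 2 * tcrossprod(x, z)
  exp(-gamma * pmax(d2, 0))
}

#' Fit a support vector data description
#'
#' Solves the SVDD dual with an RBF kernel `exp(-gamma * ||x - z||^2)`:
#' minimize `t(a) %*% K %*% a - t(a) %*% diag(K)` subject to `sum(a) = 1`
#' and `0 <= a_i <= 1/(C * n)`. `C` in `(0, 1]` is parameterized as an upper
#' bound on the fraction of points allowed outside the description (the
#' nu-style reading): at `C = 1` the box forces `a_i = 1/n` exactly, so the
#' centroid is the sample mean; smaller `C` yields a tighter description
#' that caps fewer points at the bound. The reported center lives in input
#' space as the coefficient-weighted mean of the support vectors, which is
#' what the Euclidean centroid distances of the correlation step consume.
#'
#' @param x Numeric matrix (rows are points, here pair-difference vectors).
#' @param C Outlier-fraction ceiling in `(0, 1]`.
#' @param gamma RBF bandwidth (> 0); default `1/ncol(x)`.
#' @param seed Accepted for interface stability; the interior-point solver
#'   is deterministic, so the seed is not consumed.
#' @return An object of class `svdd_model` with fields `support_vectors`,
#'   `coefficients` (non-negative, summing to 1), `center` (input-space
#'   weighted mean), `radius` (kernel-space boundary distance), `C`, `gamma`.
#' @export
fit_svdd <- function(x, C = 1, gamma = NULL, seed = NULL) {
  x <- check_matrix(as.matrix(x), "x")
  n <- nrow(x)
  if (n < 2L) stopf("SVDD needs at least 2 points")
  if (!(C > 0 && C <= 1)) stopf("C must lie in (0, 1]")
  gamma <- gamma %||% (1 / ncol(x))
  if (gamma <= 0) stopf("gamma must be positive")

  K <- rbf_kernel(x, gamma = gamma)
  bound <- 1 / (C * n)

  if (n * bound <= 1 + 1e-10) {
    # box bound equals 1/n: the simplex-plus-box feasible set is the single
    # point a = 1/n, no solver needed (and the centroid is exact)
    alpha <- rep(1 / n, n)
  } else if (max(K) - min(K) < 1e-12) {
    # identical points: any feasible vector is optimal; take the uniform one
    alpha <- rep(1 / n, n)
  } else {
    sol <- tryCatch(
      kernlab::ipop(c = -diag(K), H = 2 * K,
                    A = matrix(1, 1, n), b = 1, r = 0,
                    l = rep(0, n), u = rep(min(bound, 1), n),
                    sigf = 9, maxiter = 200),
      error = function(e) {
        stopf("SVDD solver failed (C = %g, gamma = %g): %s",
              C, gamma, conditionMessage(e))
      })
    alpha <- pmin(pmax(kernlab::primal(sol), 0), bound)
    alpha <- alpha / sum(alpha)
  }

  # classify bounded support vectors against the solver's box before any
  # renormalization shifts the coefficient values
  bounded_all <- alpha >= min(bound, 1) * (1 - 1e-6)
  sv <- which(alpha > 1e-8)
  coef <- alpha[sv] / sum(alpha[sv])
  svx <- x[sv, , drop = FALSE]
  Ksv <- K[sv, sv, drop = FALSE]
  aKa <- drop(crossprod(coef, Ksv %*% coef))
  # kernel-space squared distance of each SV to the kernel center
  d2 <- 1 - 2 * drop(Ksv %*% coef) + aKa
  # in the exact dual every free SV sits exactly on the boundary; under
  # solver tolerance their distances scatter slightly, so take the largest
  # (any smaller choice would spuriously expel free SVs themselves)
  free <- !bounded_all[sv]
  r2 <- if (any(free)) max(d2[free]) else max(d2)
  center <- if (max(coef) - min(coef) < 1e-12) {
    colMeans(svx)            # uniform coefficients: exact sample mean
  } else {
    drop(crossprod(svx, coef))
  }
  structure(
    list(support_vectors = svx,
         coefficients = coef,
         center = unname(center),
         radius = sqrt(max(r2, 0)),
         aKa = aKa, C = C, gamma = gamma),
    class = "svdd_model"
  )
}

#' Input-space centroid of a fitted SVDD
#'
#' @param model An `svdd_model`.
#' @return Numeric vector: the coefficient-weighted mean of the support
#'   vectors (exactly the sample mean when the model was fit with `C = 1`).
#' @export
svdd_centroid <- function(model) {
  stopifnot(inherits(model, "svdd_model"))
  model$center
}

#' Kernel-space distance from the SVDD center
#'
#' @param model An `svdd_model`.
#' @param x Matrix (or single vector) of query points.
#' @return Numeric vector of kernel-space distances; points with distance
#'   greater than `model$radius` lie outside the description.
#' @export
svdd_distance <- function(model, x) {
  stopifnot(inherits(model, "svdd_model"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  kz <- rbf_kernel(x, model$support_vectors, gamma = model$gamma)
  d2 <- 1 - 2 * drop(kz %*% model$coefficients) + model$aKa
  d2[d2 < 1e-12] <- 0     # zap accumulation noise near the center
  sqrt(d2)
}

#' @export
print.svdd_model <- function(x, ...) {
  cat(sprintf("svdd_model: %d support vectors, radius %.4g (C = %g, gamma = %g)\n",
              nrow(x$support_vectors), x$radius, x$C, x$gamma))
  invisible(x)
}

#' Remove boundary-violating positive pairs from a task
#'
#' Fits an SVDD on the absolute difference vectors of the task's positive
#' pairs and drops the positives whose kernel-space distance to the center
#' exceeds the radius. Negative pairs pass through unchanged. This is the
#' data-refinement step behind the `isolated_svdd` baseline.
#'
#' @param task A [task_data] object with at least 2 positive pairs.
#' @inheritParams fit_svdd
#' @return The filtered [task_data].
#' @export
filter_by_svdd <- function(task, C = 1, gamma = NULL, seed = NULL) {
  pos <- which(task$label == 1)
  if (length(pos) < 2L) stopf("task %s has fewer than 2 positive pairs",
                              task$kin_type)
  diffs <- pair_difference(task$parent[pos, , drop = FALSE],
                           task$child[pos, , drop = FALSE])
  model <- fit_svdd(diffs, C = C, gamma = gamma, seed = seed)
  dist <- svdd_distance(model, diffs)
  keep <- dist <= model$radius + 1e-8 * max(model$radius, 1)
  if (!any(keep)) stopf("SVDD filtering removed every positive pair of %s",
                        task$kin_type)
  subset_task(task, sort(c(pos[keep], which(task$label == -1))))
}
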