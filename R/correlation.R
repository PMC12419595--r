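# Correlation discovery across kinship types: SVDD centroids of the
# positive-pair difference vectors give one point per type; Euclidean
# distances between centroids define the correlation vector r (smaller
# distance = stronger correlation), from which the K auxiliary tasks and
# their initial simplex weights are derived.

#' Absolute pair-difference representation
#'
#' Elementwise `|p - c|`, the summary a positive parent-child pair
#' contributes to the SVDD of its kinship type. Accepts vectors or
#' conforming matrices (rowwise pairs).
#'
#' @param p,c Numeric vectors or matrices of identical dimension.
#' @return Object of the same shape as the inputs.
#' @export
pair_difference <- function(p, c) {
  if (!identical(dim(p), dim(c)) || length(p) != length(c)) {
    stopf("p and c must have identical dimensions")
  }
  abs(p - c)
}

new_correlation_profile <- function(target, r, U = character(0),
                                    beta0 = numeric(0)) {
  structure(list(target = target, r = r, U = U, beta0 = beta0),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("correlation_profile: target %s\n", x$target))
  if (length(x$r)) {
    cat("  r:", paste(sprintf("%s=%.4g", names(x$r), x$r), collapse = ", "),
        "\n")
  }
  if (length(x$U)) cat("  U:", paste(x$U, collapse = " < "), "\n")
  if (length(x$beta0)) {
    cat("  beta0:", paste(sprintf("%s=%.3g", names(x$beta0), x$beta0),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Correlation vector between a target kinship type and the others
#'
#' For the target task and each auxiliary task, fits an SVDD on the
#' absolute difference vectors of the *positive* pairs only and takes the
#' input-space centroid; the correlation entry for auxiliary type `u` is
#' the Euclidean distance between the two centroids. Smaller values mean
#' the two types place their positive pairs in closer regions of
#' difference space, i.e. are more strongly correlated.
#'
#' @param target A [task_data] for the type of interest.
#' @param others List of [task_data] objects for the remaining types.
#' @inheritParams fit_svdd
#' @return A `correlation_profile` with the `r` vector filled (named by
#'   auxiliary kin type); `U` and `beta0` are filled by [select_top_k] and
#'   [init_task_weights].
#' @export
compute_correlations <- function(target, others, C = 1, gamma = NULL,
                                 seed = NULL) {
  stopifnot(inherits(target, "task_data"))
  centroid_of <- function(task) {
    pos <- which(task$label == 1)
    if (length(pos) < 2L) {
      stopf("task %s has fewer than 2 positive pairs", task$kin_type)
    }
    diffs <- pair_difference(task$parent[pos, , drop = FALSE],
                             task$child[pos, , drop = FALSE])
    svdd_centroid(fit_svdd(diffs, C = C, gamma = gamma, seed = seed))
  }
  cq <- centroid_of(target)
  r <- vapply(others, function(t) {
    if (t$d != target$d) stopf("feature dimensions differ across tasks")
    sqrt(sum((cq - centroid_of(t))^2))
  }, numeric(1))
  names(r) <- vapply(others, `[[`, character(1), "kin_type")
  new_correlation_profile(target$kin_type, r)
}

#' Select the K most correlated kinship types
#'
#' Sorts the correlation vector in ascending order (ties broken by the
#' canonical type order `FS < FD < MS < MD`) and keeps the first `k` types.
#'
#' @param profile A `correlation_profile` with `r` filled.
#' @param k Number of auxiliary types to keep, `0 <= k <= length(r)`.
#' @return The profile with `U` filled (ascending by `r`).
#' @export
select_top_k <- function(profile, k) {
  stopifnot(inherits(profile, "correlation_profile"))
  k <- as.integer(k)
  if (k < 0L || k > length(profile$r)) {
    stopf("k must lie in 0..%d (got %d)", length(profile$r), k)
  }
  ord <- order(profile$r, match(names(profile$r), KIN_TYPES))
  profile$U <- names(profile$r)[ord][seq_len(k)]
  profile
}

#' Initial simplex weights from reciprocal correlations
#'
#' The target task receives raw weight `1/s` for an extremely small `s`
#' (so it dominates at initialization) and each selected auxiliary type
#' `u` receives `1/r[u]`; the raw weights are normalized to sum to one.
#'
#' @param profile A `correlation_profile` after [select_top_k].
#' @param s Small positive constant (default `1e-6`); must be far below
#'   the smallest selected correlation.
#' @return The profile with `beta0` filled (named, target first, summing
#'   to 1, target weight largest).
#' @export
init_task_weights <- function(profile, s = 1e-6) {
  stopifnot(inherits(profile, "correlation_profile"), s > 0)
  if (is.null(profile$U) && length(profile$r)) {
    stopf("call select_top_k() before init_task_weights()")
  }
  rsel <- profile$r[profile$U]
  if (any(rsel == 0)) {
    stopf("degenerate correlation r = 0 for %s; perturb or drop the type",
          paste(names(rsel)[rsel == 0], collapse = ", "))
  }
  raw <- c(1 / s, 1 / rsel)
  beta0 <- raw / sum(raw)
  names(beta0) <- c(profile$target, profile$U)
  profile$beta0 <- beta0
  profile
}
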