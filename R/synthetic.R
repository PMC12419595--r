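# Synthetic multi-task kin-pair generator. Positive children arise from a
# shared linear kin map plus a task-specific deviation with additive
# noise; negatives are "wrong-family" children produced by the same map
# from an independent parent. Deviation directions can be aligned across
# chosen task groups, which plants a known correlation ranking for the
# discovery step to recover.

#' Specification of a synthetic multi-task benchmark
#'
#' @param d Feature dimension (>= 2).
#' @param n_pos,n_neg Positive / negative pairs per task (>= 1).
#' @param a0_scale Frobenius norm of the shared kin map `A0`; the default
#'   `sqrt(d)` gives it the same Frobenius mass as the identity.
#' @param dev_norms Named numeric vector (names in `KIN_TYPES`): Frobenius
#'   norm of each task's deviation from the shared map. The default makes
#'   every deviation small relative to `A0` (15 percent of its norm), the
#'   regime in which the types genuinely share structure.
#' @param dev_alignment List of character vectors; types in the same group
#'   share one deviation direction (hence near-identical positive-pair
#'   difference distributions when their norms match), types outside any
#'   group draw independent directions.
#' @param noise_sigma Standard deviation of the additive child noise.
#' @param seed Integer seed.
#' @param a0 Optional explicit shared kin map (a `d x d` matrix). When
#'   given it is used verbatim and `a0_scale` is ignored; useful for
#'   planting degenerate geometries (e.g. `a0 = diag(d)` with zero
#'   deviations and zero noise makes every positive child equal its
#'   parent).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(d = 20, n_pos = 200, n_neg = 200,
                       a0_scale = sqrt(d),
                       dev_norms = NULL,
                       dev_alignment = list(c("FS", "FD"), c("MS", "MD")),
                       noise_sigma = 0.1, seed = 1, a0 = NULL) {
  stopifnot(d >= 2, n_pos >= 1, n_neg >= 1, a0_scale > 0, noise_sigma >= 0)
  if (!is.null(a0)) {
    a0 <- check_matrix(a0, "a0")
    if (!identical(dim(a0), c(as.integer(d), as.integer(d)))) {
      stopf("a0 must be a %d x %d matrix", d, d)
    }
  }
  dev_norms <- dev_norms %||%
    structure(rep(0.15 * a0_scale, 4), names = KIN_TYPES)
  if (!all(KIN_TYPES %in% names(dev_norms)) || any(dev_norms < 0)) {
    stopf("dev_norms must name all four kin types with non-negative values")
  }
  for (g in dev_alignment) {
    if (!all(g %in% KIN_TYPES)) stopf("dev_alignment names unknown types")
  }
  structure(list(d = d, n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 a0_scale = a0_scale, dev_norms = dev_norms[KIN_TYPES],
                 dev_alignment = dev_alignment, noise_sigma = noise_sigma,
                 seed = as.integer(seed), a0 = a0),
            class = "synth_spec")
}

unit_matrix <- function(d) {
  m <- matrix(rnorm(d * d), d, d)
  m / sqrt(frob2(m))
}

#' Generate the four synthetic kinship tasks
#'
#' Draws the shared kin map `A0` and per-task deviations `Delta_v`
#' respecting the alignment groups, then per task: parents are standard
#' normal, positive children are `(A0 + Delta_v) p + sigma * eps`, and
#' negative children apply the same map to an independently drawn parent
#' (another "family"). Folds are assigned round-robin 1..5 so every fold
#' is exactly balanced. The returned ground truth includes the analytic
#' per-task mean absolute-difference vectors and the correlation ranking
#' they plant.
#'
#' @param spec A [synth_spec].
#' @return List with `tasks` (named list of four [task_data]) and `truth`
#'   (`A0`, `Delta`, `A` = per-task full maps, `diff_mean` = analytic
#'   mean |p - c| per task, `dist` = 4x4 distance matrix between those
#'   vectors, `ranking` = per-target auxiliary ordering).
#' @export
generate_tasks <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  d <- spec$d
  with_seed(spec$seed, {
    A0 <- spec$a0 %||% (unit_matrix(d) * spec$a0_scale)
    dirs <- vector("list", 4); names(dirs) <- KIN_TYPES
    for (g in spec$dev_alignment) {
      shared <- unit_matrix(d)
      for (tt in g) dirs[[tt]] <- shared
    }
    for (tt in KIN_TYPES) {
      if (is.null(dirs[[tt]])) dirs[[tt]] <- unit_matrix(d)
    }
    Delta <- lapply(KIN_TYPES, function(tt) spec$dev_norms[tt] * dirs[[tt]])
    names(Delta) <- KIN_TYPES

    tasks <- lapply(KIN_TYPES, function(tt) {
      A <- A0 + Delta[[tt]]
      p_pos <- matrix(rnorm(spec$n_pos * d), spec$n_pos, d)
      c_pos <- p_pos %*% t(A) +
        spec$noise_sigma * matrix(rnorm(spec$n_pos * d), spec$n_pos, d)
      p_neg <- matrix(rnorm(spec$n_neg * d), spec$n_neg, d)
      p_other <- matrix(rnorm(spec$n_neg * d), spec$n_neg, d)
      c_neg <- p_other %*% t(A) +
        spec$noise_sigma * matrix(rnorm(spec$n_neg * d), spec$n_neg, d)
      n <- spec$n_pos + spec$n_neg
      task_data(tt, rbind(p_pos, p_neg), rbind(c_pos, c_neg),
                c(rep(1, spec$n_pos), rep(-1, spec$n_neg)),
                rep_len(1:5, n))
    })
    names(tasks) <- KIN_TYPES
  })

  # analytic mean of |p - c| for positive pairs: p - c ~ N(0, S) with
  # S = (I - A)(I - A)' + sigma^2 I, so E|p - c|_j = sqrt(2/pi) sqrt(S_jj)
  diff_mean <- lapply(KIN_TYPES, function(tt) {
    IA <- diag(d) - (A0 + Delta[[tt]])
    sqrt(2 / pi) * sqrt(diag(tcrossprod(IA)) + spec$noise_sigma^2)
  })
  names(diff_mean) <- KIN_TYPES
  dist <- matrix(0, 4, 4, dimnames = list(KIN_TYPES, KIN_TYPES))
  for (a in KIN_TYPES) {
    for (b in KIN_TYPES) {
      dist[a, b] <- sqrt(sum((diff_mean[[a]] - diff_mean[[b]])^2))
    }
  }
  ranking <- lapply(KIN_TYPES, function(tt) {
    others <- setdiff(KIN_TYPES, tt)
    others[order(dist[tt, others], match(others, KIN_TYPES))]
  })
  names(ranking) <- KIN_TYPES

  A <- lapply(KIN_TYPES, function(tt) A0 + Delta[[tt]])
  names(A) <- KIN_TYPES
  list(tasks = tasks,
       truth = list(A0 = A0, Delta = Delta, A = A, diff_mean = diff_mean,
                    dist = dist, ranking = ranking))
}

# bilinear 8x8 -> 64x64 upsampling used to make smooth face-like blobs
upscale8 <- function(g) {
  xs <- seq(1, 8, length.out = 64)
  i0 <- pmin(floor(xs), 7); fi <- xs - i0
  row_interp <- g[i0, ] * (1 - fi) + g[i0 + 1, ] * fi
  row_interp[, i0] * rep(1 - fi, each = 64) +
    row_interp[, i0 + 1] * rep(fi, each = 64)
}

#' Generate a synthetic image fixture
#'
#' Writes seeded 64x64 grayscale PNG images of smooth random blobs --
#' parent and child of a family share a dominant low-frequency component
#' -- together with a valid pair-list CSV (`pairs.csv`) whose negatives
#' pair each parent with the next family's child. This exercises the
#' image-IO and descriptor pipeline end to end without any download; the
#' images are synthetic stand-ins, not faces.
#'
#' @param dir Output directory (created if needed).
#' @param n_pairs Positive pairs per kin type.
#' @param seed Integer seed.
#' @return Path of the written pair-list CSV, invisibly.
#' @export
generate_images <- function(dir, n_pairs = 10, seed = 1) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create directory '%s'", dir)
  }
  to_unit <- function(m) {
    rng <- range(m)
    if (diff(rng) < 1e-12) matrix(0.5, 64, 64)
    else (m - rng[1]) / diff(rng)
  }
  rows <- list()
  with_seed(seed, {
    for (tt in KIN_TYPES) {
      parents <- character(n_pairs); children <- character(n_pairs)
      for (i in seq_len(n_pairs)) {
        shared <- upscale8(matrix(rnorm(64), 8, 8))
        parent <- to_unit(shared + 0.5 * upscale8(matrix(rnorm(64), 8, 8)) +
                            0.05 * matrix(rnorm(64 * 64), 64, 64))
        child <- to_unit(shared + 0.5 * upscale8(matrix(rnorm(64), 8, 8)) +
                           0.05 * matrix(rnorm(64 * 64), 64, 64))
        parents[i] <- sprintf("%s_fam%02d_parent.png", tt, i)
        children[i] <- sprintf("%s_fam%02d_child.png", tt, i)
        png::writePNG(parent, file.path(dir, parents[i]))
        png::writePNG(child, file.path(dir, children[i]))
      }
      neg_child <- children[c(seq_len(n_pairs)[-1], 1)]
      rows[[tt]] <- data.frame(
        kin_type = tt,
        parent_path = c(parents, parents),
        child_path = c(children, neg_child),
        label = rep(c(1L, -1L), each = n_pairs),
        fold = rep_len(1:5, 2 * n_pairs))
    }
  })
  csv <- file.path(dir, "pairs.csv")
  write_pair_list(do.call(rbind, rows), csv)
  invisible(csv)
}
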