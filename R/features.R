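# Facial descriptors: block LBP (16 blocks x 256 bins = 4096) and dense
# upright SIFT on a 7x7 grid of 16x16 patches (49 x 128 = 6272), plus the
# PCA reduction applied before metric learning.

check_image64 <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) stopf("image must be a numeric matrix")
  if (nrow(img) != 64 || ncol(img) != 64) {
    stopf("expected a 64x64 image, got %dx%d", nrow(img), ncol(img))
  }
  if (any(!is.finite(img))) stopf("image contains non-finite values")
  img
}

# LBP neighbor offsets in clockwise order starting at the top-left,
# with bit weights 1, 2, 4, ..., 128.
LBP_OFFSETS <- cbind(dr = c(-1, -1, -1, 0, 1, 1, 1, 0),
                     dc = c(-1, 0, 1, 1, 1, 0, -1, -1))

lbp_codes_block <- function(block) {
  # codes for the 14x14 interior of a 16x16 block; a bit is set when the
  # neighbor is >= the center pixel
  ctr <- block[2:15, 2:15]
  code <- matrix(0L, 14, 14)
  for (k in 1:8) {
    nb <- block[2:15 + LBP_OFFSETS[k, 1], 2:15 + LBP_OFFSETS[k, 2]]
    code <- code + as.integer(2^(k - 1)) * (nb >= ctr)
  }
  code
}

#' Block LBP descriptor
#'
#' Partitions a 64x64 grayscale image into 4x4 non-overlapping blocks of
#' 16x16 pixels (row-major order) and computes, for each block, a 256-bin
#' histogram of 8-neighbor LBP codes at radius 1. A code bit is set when
#' the neighbor is greater than or equal to the center; bits are ordered
#' clockwise from the top-left neighbor. Border pixels whose neighborhood
#' leaves the block are skipped, so each histogram counts the 14x14 = 196
#' interior pixels. Histograms are L1-normalized per block by default and
#' concatenated into a 4096-dimensional vector.
#'
#' @param img 64x64 numeric matrix of intensities.
#' @param normalize L1-normalize each block histogram (default `TRUE`).
#' @return Numeric vector of length 4096.
#' @export
extract_block_lbp <- function(img, normalize = TRUE) {
  check_image64(img)
  out <- numeric(0)
  for (bi in 0:3) {
    for (bj in 0:3) {
      block <- img[bi * 16 + 1:16, bj * 16 + 1:16]
      h <- tabulate(as.vector(lbp_codes_block(block)) + 1L, nbins = 256L)
      if (normalize) h <- h / sum(h)
      out <- c(out, h)
    }
  }
  out
}

#' Dense-grid upright SIFT descriptor
#'
#' Divides a 64x64 image into 49 overlapping 16x16 patches whose top-left
#' corners lie on a 7x7 grid with stride 8. Each patch yields one upright
#' 128-dimensional SIFT descriptor (4x4 spatial cells of 4x4 pixels, 8
#' orientation bins, Gaussian spatial weighting with sigma = 8, linear
#' soft-assignment between adjacent orientation bins, L2 normalization
#' with the standard clamp-at-0.2-then-renormalize rule; a gradient-free
#' patch yields the zero vector). Descriptors are concatenated in
#' row-major grid order into a 6272-dimensional vector.
#'
#' @param img 64x64 numeric matrix of intensities.
#' @return Numeric vector of length 6272.
#' @export
extract_grid_sift <- function(img) {
  check_image64(img)
  # image-wide gradients, central differences with clamped borders
  right <- img[, c(2:64, 64)]; left <- img[, c(1, 1:63)]
  down <- img[c(2:64, 64), ]; up <- img[c(1, 1:63), ]
  gx <- (right - left) / 2
  gy <- (down - up) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)  # (-pi, pi]

  # fixed per-patch geometry
  pix <- expand.grid(i = 1:16, j = 1:16)
  cell <- (pix$i - 1) %/% 4 * 4 + (pix$j - 1) %/% 4   # 0..15 row-major cells
  gw <- exp(-((pix$i - 8.5)^2 + (pix$j - 8.5)^2) / (2 * 8^2))

  starts <- seq(1, 49, by = 8)
  out <- numeric(0)
  for (r0 in starts) {
    for (c0 in starts) {
      ridx <- r0 + pix$i - 1
      cidx <- c0 + pix$j - 1
      lin <- ridx + (cidx - 1) * 64
      m <- mag[lin] * gw
      a <- (ang[lin] + pi) / (pi / 4)   # [0, 8]
      b0 <- floor(a)
      frac <- a - b0
      bin1 <- as.integer(b0) %% 8L
      bin2 <- (bin1 + 1L) %% 8L
      idx <- c(cell * 8L + bin1, cell * 8L + bin2) + 1L
      wgt <- c(m * (1 - frac), m * frac)
      h <- numeric(128)
      agg <- rowsum(wgt, idx)
      h[as.integer(rownames(agg))] <- agg
      nrm <- sqrt(sum(h^2))
      if (nrm > 1e-12) {
        h <- pmin(h / nrm, 0.2)
        nrm2 <- sqrt(sum(h^2))
        if (nrm2 > 1e-12) h <- h / nrm2
      } else {
        h <- numeric(128)
      }
      out <- c(out, h)
    }
  }
  out
}

#' Fit a PCA projection
#'
#' Centers the training descriptors and keeps the top `pca_dim` principal
#' directions by explained variance. Each basis row's sign is fixed by
#' making its largest-magnitude coordinate positive, so the projection is
#' deterministic.
#'
#' @param x Matrix of training descriptors (rows = observations); must
#'   have at least `pca_dim` rows.
#' @param pca_dim Output dimension.
#' @return A list of class `pca_projection` with `mean` (length raw dim)
#'   and `basis` (`pca_dim` x raw dim, orthonormal rows).
#' @export
fit_pca <- function(x, pca_dim = 100) {
  x <- check_matrix(as.matrix(x), "x")
  if (nrow(x) < pca_dim) {
    stopf("need at least %d observations to fit %d components (got %d)",
          pca_dim, pca_dim, nrow(x))
  }
  if (ncol(x) < pca_dim) stopf("pca_dim exceeds the descriptor dimension")
  pr <- prcomp(x, center = TRUE, scale. = FALSE, rank. = pca_dim)
  basis <- unname(t(pr$rotation))
  for (i in seq_len(nrow(basis))) {
    j <- which.max(abs(basis[i, ]))
    if (basis[i, j] < 0) basis[i, ] <- -basis[i, ]
  }
  structure(list(mean = unname(colMeans(x)), basis = basis),
            class = "pca_projection")
}

#' Apply a fitted PCA projection
#'
#' Maps a descriptor (or rows of a matrix of descriptors) to
#' `basis %*% (x - mean)`.
#'
#' @param projection A `pca_projection` from [fit_pca].
#' @param x Numeric vector of raw dimension, or a matrix with one
#'   descriptor per row.
#' @return Reduced vector (or matrix with `pca_dim` columns).
#' @export
apply_pca <- function(projection, x) {
  stopifnot(inherits(projection, "pca_projection"))
  if (is.matrix(x)) {
    if (ncol(x) != length(projection$mean)) {
      stopf("descriptor length %d does not match projection dimension %d",
            ncol(x), length(projection$mean))
    }
    sweep(x, 2, projection$mean) %*% t(projection$basis)
  } else {
    if (length(x) != length(projection$mean)) {
      stopf("descriptor length %d does not match projection dimension %d",
            length(x), length(projection$mean))
    }
    drop(projection$basis %*% (as.numeric(x) - projection$mean))
  }
}
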