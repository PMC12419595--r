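# Shared fixtures, built in code at test time.

# generic random task with both classes present
random_task <- function(kin_type = "FS", n = 20, d = 5, seed = 1) {
  set.seed(seed)
  task_data(kin_type,
            matrix(rnorm(n * d), n, d),
            matrix(rnorm(n * d), n, d),
            rep(c(1, -1), length.out = n))
}

# task whose positive pairs all have |p - c| exactly equal to `mu`
# (child = parent - mu), so the difference centroid is `mu` itself;
# negatives are random
constant_diff_task <- function(kin_type, mu, n = 12, seed = 1) {
  set.seed(seed)
  d <- length(mu)
  p_pos <- matrix(rnorm(n * d), n, d)
  c_pos <- sweep(p_pos, 2, mu)
  p_neg <- matrix(rnorm(4 * d), 4, d)
  c_neg <- matrix(rnorm(4 * d), 4, d)
  task_data(kin_type, rbind(p_pos, p_neg), rbind(c_pos, c_neg),
            c(rep(1, n), rep(-1, 4)))
}

# brute-force per-pixel LBP oracle: explicit loops, no vectorization;
# same stated convention (clockwise from top-left, neighbor >= center,
# 14x14 block interior) as the implementation contract
lbp_oracle <- function(img, normalize = TRUE) {
  dr <- c(-1, -1, -1, 0, 1, 1, 1, 0)
  dc <- c(-1, 0, 1, 1, 1, 0, -1, -1)
  out <- numeric(0)
  for (bi in 0:3) {
    for (bj in 0:3) {
      block <- img[bi * 16 + 1:16, bj * 16 + 1:16]
      h <- numeric(256)
      for (i in 2:15) {
        for (j in 2:15) {
          code <- 0
          for (k in 1:8) {
            if (block[i + dr[k], j + dc[k]] >= block[i, j]) {
              code <- code + 2^(k - 1)
            }
          }
          h[code + 1] <- h[code + 1] + 1
        }
      }
      if (normalize) h <- h / sum(h)
      out <- c(out, h)
    }
  }
  out
}

random_image <- function(seed = 1) {
  set.seed(seed)
  matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
}

# benchmark generators shared between tests: the default shared-structure
# benchmark, plus the variant with a deliberately unrelated fourth task
# (large deviation on its own direction, used for the K sweep)
benchmark_spec <- function(seed) synth_spec(seed = seed)

unrelated_benchmark_spec <- function(seed) {
  d <- 20
  synth_spec(d = d, seed = seed,
             dev_norms = c(FS = 0.15, FD = 0.15, MS = 0.15,
                           MD = 1.5) * sqrt(d),
             dev_alignment = list(c("FS", "FD", "MS")))
}

# recovery fixture: one aligned near pair, one far-off group
recovery_spec <- function(seed) {
  d <- 20
  synth_spec(d = d, seed = seed,
             dev_norms = c(FS = 0.15, FD = 0.15, MS = 0.8,
                           MD = 0.8) * sqrt(d),
             dev_alignment = list(c("FS", "FD"), c("MS", "MD")))
}
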