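# Shared synthetic-scene builders used across test files.

# Two-stain test kernel with known ground-truth angles.
test_kernel <- function() {
  build_kernel(list(polar_to_vector(83, 59, name = "A"),
                    polar_to_vector(47, 73, name = "B")))
}
test_kernel_angles <- rbind(c(83, 59), c(47, 73))

# Nine pure-dye calibration-style scenes: non-overlapping disks on a grid,
# alternating stains, random concentrations. Suitable for kernel estimation
# (no genuine dye co-localization).
pure_dye_images <- function(kernel = test_kernel(), noise_sd = 0, size = 64) {
  lapply(1:9, function(i) {
    set.seed(100 + i)
    centers <- expand.grid(cx = size * c(0.19, 0.5, 0.81),
                           cy = size * c(0.19, 0.5, 0.81))
    objs <- lapply(seq_len(nrow(centers)), function(j) {
      if ((j + i) %% 2 == 0)
        list(cx = centers$cx[j], cy = centers$cy[j], r = size * 0.11,
             conc = c(A = runif(1, 0.3, 0.9)))
      else
        list(cx = centers$cx[j], cy = centers$cy[j], r = size * 0.11,
             conc = c(B = runif(1, 0.3, 0.7)))
    })
    sp <- scene_spec(width = size, height = size, seed = i,
                     noise_sd = noise_sd, objects = objs)
    render_stained_image(sp, kernel)$image
  })
}

# RMS contrast (1 - I) of a list of images; the signal scale used to set
# noise levels for a given SNR in dB.
contrast_rms <- function(images) {
  sqrt(mean(vapply(images, function(im) mean((1 - im)^2), numeric(1))))
}

# Dark disk on bright background (single-channel), the pellet geometry.
disk_scene <- function(height, width, cx, cy, r, fg = 0.2, bg = 0.9) {
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  g <- matrix(bg, height, width)
  g[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- fg
  g
}

disk_mask <- function(height, width, cx, cy, r) {
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  ((xs - cx)^2 + (ys - cy)^2 <= r^2) + 0
}

# Brute-force local-adaptive mask: explicit per-pixel loops over a centered
# square window with symmetric edge padding; population sd. Independent of
# the integral-image implementation.
adaptive_mask_bruteforce <- function(gray, s, gain_mu = 1.1, gain_sigma = 0.3) {
  n <- nrow(gray); m <- ncol(gray)
  lo <- (s - 1) %/% 2; hi <- s - 1 - lo
  ri <- c(if (lo > 0) lo:1, 1:n, if (hi > 0) n:(n - hi + 1))
  ci <- c(if (lo > 0) lo:1, 1:m, if (hi > 0) m:(m - hi + 1))
  pad <- gray[ri, ci, drop = FALSE]
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    w <- pad[i:(i + s - 1), j:(j + s - 1)]
    mu <- mean(w)
    sig <- sqrt(mean(w^2) - mu^2)
    out[i, j] <- (gray[i, j] > gain_mu * mu - gain_sigma * sig) + 0
  }
  out
}

# Shift-and-accumulate variant of the same oracle (vectorized; used where
# many images are checked).
adaptive_mask_shiftsum <- function(gray, s, gain_mu = 1.1, gain_sigma = 0.3) {
  n <- nrow(gray); m <- ncol(gray)
  lo <- (s - 1) %/% 2; hi <- s - 1 - lo
  ri <- c(if (lo > 0) lo:1, 1:n, if (hi > 0) n:(n - hi + 1))
  ci <- c(if (lo > 0) lo:1, 1:m, if (hi > 0) m:(m - hi + 1))
  pad <- gray[ri, ci, drop = FALSE]
  s1 <- matrix(0, n, m); s2 <- matrix(0, n, m)
  for (di in 0:(s - 1)) for (dj in 0:(s - 1)) {
    blk <- pad[di + seq_len(n), dj + seq_len(m), drop = FALSE]
    s1 <- s1 + blk
    s2 <- s2 + blk^2
  }
  mu <- s1 / (s * s)
  sig <- sqrt(pmax(s2 / (s * s) - mu^2, 0))
  (gray > gain_mu * mu - gain_sigma * sig) + 0
}

# Exhaustive-search Otsu oracle: evaluates the two-class between-class
# variance at every one of the 255 candidate cuts directly.
otsu_bruteforce <- function(gray, n_bins = 256L) {
  v <- as.vector(gray)
  bin <- pmin(floor(v * n_bins) + 1L, n_bins)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  x <- centers[bin]
  best_k <- NA_integer_; best_bc <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    g0 <- x[bin <= k]; g1 <- x[bin > k]
    if (!length(g0) || !length(g1)) next
    w0 <- length(g0) / length(x); w1 <- 1 - w0
    bc <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (bc > best_bc + 1e-15) { best_bc <- bc; best_k <- k }
  }
  best_k / n_bins
}

# Exhaustive sign-flip Wilcoxon oracle: enumerates all 2^n sign assignments
# of the rank vector and accumulates the exact distribution of V.
wilcoxon_signflip_oracle <- function(a, b,
                                     alternative = "two.sided") {
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  p_le <- mean(Vs <= V + 1e-9)
  p_ge <- mean(Vs >= V - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# Full-enumeration Friedman oracle: every combination of within-block
# permutations, vectorized over the enumeration index.
friedman_permutation_oracle <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  ranks <- t(apply(values, 1, rank))
  A <- sum(ranks^2)
  C <- n * k * (k + 1)^2 / 4
  stat_of <- function(R) {
    denom <- A - C
    if (denom <= 0) return(0)
    (k - 1) * sum((R - n * (k + 1) / 2)^2) / denom
  }
  obs <- stat_of(colSums(ranks))
  perms <- gtools_permutations(k)
  np <- nrow(perms)
  idx <- as.matrix(expand.grid(rep(list(seq_len(np)), n)))
  Rsums <- matrix(0, nrow(idx), k)
  for (d in seq_len(n)) {
    permuted <- matrix(ranks[d, ][perms], nrow = np)  # row p = ranks[d, perms[p, ]]
    Rsums <- Rsums + permuted[idx[, d], ]
  }
  denom <- A - C
  stats_all <- if (denom <= 0) rep(0, nrow(idx)) else
    (k - 1) * rowSums((Rsums - n * (k + 1) / 2)^2) / denom
  mean(stats_all >= obs - 1e-9)
}

gtools_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(rep(i, nrow(sub)), sub + (sub >= i))))
}
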