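#' Parameters of the local-adaptive cell-mask threshold
#'
#' The local region is a square window whose side depends on the
#' magnification the image was acquired at: 30 px for 10x, 60 px for 20x,
#' applied at the downscaled working resolution (width `work_width`,
#' default 512 px). The threshold rule is
#' `value > gain_mu * mu - gain_sigma * sigma` with the local mean `mu` and
#' local (population) standard deviation `sigma`, defaults 1.1 and 0.3.
#'
#' @param magnification 10 or 20 (sets `region_size` 30 or 60), ignored if
#'   `region_size` is given directly.
#' @param region_size Square window side in pixels at working resolution.
#' @param gain_mu,gain_sigma Threshold gains.
#' @param work_width Working width in pixels for the downscaled image.
#' @return List of class `adaptive_params`.
#' @export
adaptive_params <- function(magnification = 10, region_size = NULL,
                            gain_mu = 1.1, gain_sigma = 0.3, work_width = 512) {
  if (is.null(region_size)) {
    if (!magnification %in% c(10, 20))
      stop("magnification must be 10 or 20 (or give region_size directly)")
    region_size <- if (magnification == 10) 30L else 60L
  }
  if (region_size < 1 || work_width < 1)
    stop("region_size and work_width must be positive")
  structure(list(region_size = as.integer(region_size), gain_mu = gain_mu,
                 gain_sigma = gain_sigma, work_width = as.integer(work_width)),
            class = "adaptive_params")
}

# Local mean and population sd over a centered square window of side s,
# symmetric (edge-duplicating) border padding, via integral images.
local_mean_sd <- function(gray, s) {
  n <- nrow(gray); m <- ncol(gray)
  lo <- (s - 1L) %/% 2L
  hi <- s - 1L - lo
  if (s > n || s > m) stop("region_size exceeds image size at working resolution")
  ri <- c(if (lo > 0) lo:1, 1:n, if (hi > 0) n:(n - hi + 1))
  ci <- c(if (lo > 0) lo:1, 1:m, if (hi > 0) m:(m - hi + 1))
  pad <- gray[ri, ci, drop = FALSE]
  boxsum <- function(x) {
    cs <- rbind(0, apply(x, 2, cumsum))
    v <- cs[seq_len(n) + s, , drop = FALSE] - cs[seq_len(n), , drop = FALSE]
    cs2 <- cbind(0, t(apply(v, 1, cumsum)))
    cs2[, seq_len(m) + s, drop = FALSE] - cs2[, seq_len(m), drop = FALSE]
  }
  area <- s * s
  mu <- boxsum(pad) / area
  mu2 <- boxsum(pad^2) / area
  sigma <- sqrt(pmax(mu2 - mu^2, 0))
  list(mu = mu, sigma = sigma)
}

#' Local-adaptive binarization
#'
#' Core thresholding rule of the cell mask: a pixel is foreground when its
#' value exceeds `gain_mu * mu - gain_sigma * sigma`, where `mu` and
#' `sigma` are the mean and population standard deviation of a centered
#' square region around it (symmetric border padding). Operates at the
#' supplied resolution; see [adaptive_cell_mask()] for the full
#' downscale/negate/upscale pipeline.
#'
#' @param gray Single-channel matrix in `[0, 1]`.
#' @param region_size Square window side in pixels.
#' @param gain_mu,gain_sigma Threshold gains (defaults 1.1 and 0.3).
#' @return 0/1 matrix.
#' @export
local_adaptive_threshold <- function(gray, region_size, gain_mu = 1.1,
                                     gain_sigma = 0.3) {
  if (!is.matrix(gray)) stop("gray must be a single-channel matrix")
  ls <- local_mean_sd(gray, as.integer(region_size))
  (gray > gain_mu * ls$mu - gain_sigma * ls$sigma) + 0
}

#' Adaptive cell mask for bright-background cultures
#'
#' Cells are darker than the background, so the negated luminance image is
#' binarized: the image is downscaled to `params$work_width`, negated
#' (`1 - value`), thresholded with [local_adaptive_threshold()], and the
#' mask is upscaled (nearest-neighbor) back to the input dimensions.
#'
#' @param gray Single-channel luminance matrix in `[0, 1]`.
#' @param params An [adaptive_params()] object.
#' @return 0/1 matrix matching `gray` in size.
#' @export
adaptive_cell_mask <- function(gray, params = adaptive_params()) {
  if (!is.matrix(gray)) stop("gray must be a single-channel matrix")
  work <- if (ncol(gray) > params$work_width)
    resize_to_width(gray, params$work_width) else gray
  mask <- local_adaptive_threshold(1 - work, params$region_size,
                                   params$gain_mu, params$gain_sigma)
  if (!identical(dim(mask), dim(gray)))
    mask <- upscale_mask(mask, nrow(gray), ncol(gray))
  mask
}

#' Otsu's global threshold
#'
#' Maximizes the between-class variance over a 256-bin histogram of
#' `[0, 1]`; candidate thresholds are the bin boundaries `k/256`,
#' `k = 1..255`, and ties are broken toward the lowest threshold. The
#' returned value is meant to be used as `value > threshold`.
#'
#' @param gray Single-channel matrix in `[0, 1]` with at least two
#'   distinct values (a constant image has no separating threshold and is
#'   rejected).
#' @param n_bins Number of histogram bins (default 256).
#' @return Threshold value in `(0, 1)`.
#' @export
otsu_threshold <- function(gray, n_bins = 256L) {
  if (!is.matrix(gray)) stop("gray must be a single-channel matrix")
  v <- as.vector(gray)
  if (max(v) == min(v)) stop("constant image: no separating threshold exists")
  bin <- pmin(floor(v * n_bins) + 1L, n_bins)
  h <- tabulate(bin, nbins = n_bins)
  p <- h / sum(h)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(p)[-n_bins]
  m0 <- cumsum(p * centers)[-n_bins]
  mt <- sum(p * centers)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, n_bins - 1L)
  bc[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(bc)          # which.max takes the first (lowest) maximizer
  k / n_bins
}

# Merge 4-connected EBImage labels whose regions touch diagonally, giving
# 8-connected components; returns an integer label matrix.
label_components_8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  n <- nrow(lab); m <- ncol(lab)
  a <- lab[-n, -m]; b <- lab[-1, -1]    # NW-SE diagonal neighbors
  c1 <- lab[-n, -1]; d1 <- lab[-1, -m]  # NE-SW diagonal neighbors
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c1), as.vector(d1)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nl), find, 1L)
  # relabel so components are numbered by first occurrence in scan order
  relab <- match(root, unique(root))
  out <- matrix(0L, n, m)
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  out
}

#' Global-threshold pellet mask with morphological cleanup
#'
#' Segments a single dark micromass/pellet on a bright background: the
#' luminance image is downscaled to one-third of its width, negated,
#' binarized at the Otsu threshold, closed with a discrete disk of radius 4
#' (at the working scale) to fill small holes, reduced to its largest
#' 8-connected component (removing air bubbles and debris), and upscaled
#' back to the input dimensions.
#'
#' @param gray Single-channel luminance matrix in `[0, 1]`.
#' @param closing_radius Disk radius of the morphological closing, px at
#'   the working scale.
#' @param scale_divisor Width divisor for the working resolution
#'   (default 3).
#' @return 0/1 matrix matching `gray`; an image with no separable
#'   foreground yields an empty mask with a warning.
#' @export
pellet_mask <- function(gray, closing_radius = 4L, scale_divisor = 3) {
  if (!is.matrix(gray)) stop("gray must be a single-channel matrix")
  work <- resize_to_width(gray, max(1L, as.integer(round(ncol(gray) / scale_divisor))))
  neg <- 1 - work
  thr <- tryCatch(otsu_threshold(neg), error = function(e) NULL)
  if (is.null(thr)) {
    warning("pellet_mask: no separable foreground; returning an empty mask")
    return(matrix(0, nrow(gray), ncol(gray)))
  }
  bw <- (neg > thr) + 0
  if (!any(bw == 1)) {
    warning("pellet_mask: empty foreground after Otsu; returning an empty mask")
    return(matrix(0, nrow(gray), ncol(gray)))
  }
  brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, shape = "disc")
  closed <- EBImage::imageData(EBImage::closing(bw, brush))
  lab <- label_components_8(closed)
  if (max(lab) == 0L) {
    warning("pellet_mask: empty mask after closing")
    return(matrix(0, nrow(gray), ncol(gray)))
  }
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)   # first occurrence wins ties (scan order)
  mask <- (lab == keep) + 0
  upscale_mask(mask, nrow(gray), ncol(gray))
}

#' Mean-offset confluency mask for phase-contrast images
#'
#' Cells appear brighter than the background in phase contrast; a global
#' threshold of `mean(image) + 0.07` gives a consistent cell mask without
#' any resizing.
#'
#' @param gray Single-channel phase-contrast matrix in `[0, 1]`.
#' @param offset Threshold offset above the image mean (default 0.07).
#' @return 0/1 matrix.
#' @export
confluency_mask <- function(gray, offset = 0.07) {
  if (!is.matrix(gray)) stop("gray must be a single-channel matrix")
  (gray > mean(gray) + offset) + 0
}
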