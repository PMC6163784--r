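#' Polar-parametrized stain vectors
#'
#' A stain's color in optical-density (OD) RGB space is a unit vector with
#' nonnegative components (dyes absorb, never emit). The vector is
#' parametrized in physics-convention polar coordinates: `inclination`
#' (phi, degrees) is measured from the blue OD axis, `azimuth` (theta,
#' degrees) in the red-green plane from the red axis, so
#' `v = (sin(phi) cos(theta), sin(phi) sin(theta), cos(phi))`.
#' Both angles must lie in `[0, 90]` degrees for a physical stain.
#'
#' @param azimuth,inclination Angles in degrees.
#' @param name Stain label, e.g. `"OilRedO"`.
#' @return A `stain_vector`: list with `name`, `azimuth`, `inclination`,
#'   and the unit `od_vector`.
#' @examples
#' polar_to_vector(0, 0)$od_vector      # pure blue absorber: c(0, 0, 1)
#' @export
polar_to_vector <- function(azimuth, inclination, name = "stain") {
  th <- azimuth * pi / 180
  ph <- inclination * pi / 180
  v <- c(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph))
  v[abs(v) < 1e-15] <- 0
  if (any(v < 0))
    stop("angles produce a negative OD component; not a physical stain")
  v <- v / sqrt(sum(v^2))
  structure(list(name = name, azimuth = azimuth, inclination = inclination,
                 od_vector = v),
            class = "stain_vector")
}

#' @rdname polar_to_vector
#' @param od_vector Nonnegative 3-vector (any norm); normalized internally.
#' @export
vector_to_polar <- function(od_vector, name = "stain") {
  if (length(od_vector) != 3L || any(od_vector < 0))
    stop("od_vector must be a nonnegative 3-vector")
  v <- od_vector / sqrt(sum(od_vector^2))
  inclination <- acos(pmin(1, pmax(-1, v[3]))) * 180 / pi
  azimuth <- if (v[1] == 0 && v[2] == 0) 0 else atan2(v[2], v[1]) * 180 / pi
  polar_to_vector(azimuth, inclination, name = name)
}

#' Convert transmitted intensity to optical density
#'
#' Beer-Lambert with base-10 logarithm: `OD = -log10(max(I, 1e-6))`,
#' per channel. OD is additive across co-localized absorbing dyes, which is
#' what makes linear unmixing of stains valid.
#'
#' @param image Image in `[0, 1]` (any channel count).
#' @return Image of optical densities (`>= 0`).
#' @export
to_optical_density <- function(image) {
  check_image(image)
  od <- -log10(pmax(image, .EPS_OD))
  dim(od) <- dim(image)
  od
}

#' @rdname to_optical_density
#' @param od Optical-density image.
#' @export
od_to_intensity <- function(od) {
  out <- 10^(-od)
  dim(out) <- dim(od)
  out
}

#' Build a color-deconvolution kernel from stain vectors
#'
#' Assembles the 3x3 OD matrix (one stain vector per row) and its inverse,
#' the unmixing matrix. With only two stains, the third row is completed
#' with the normalized cross product of the two — a unit residual vector
#' orthogonal to their span, reported but excluded from assay ratios.
#'
#' @param stains List of 2 or 3 `stain_vector` objects.
#' @return A `stain_kernel`: list with `stains`, `stain_names`, `matrix`
#'   (3x3, rows = OD vectors), `inverse`, and `n_stains` (2 or 3; the
#'   third channel of a 2-stain kernel is the residual).
#' @export
build_kernel <- function(stains) {
  if (inherits(stains, "stain_vector")) stains <- list(stains)
  if (!length(stains) %in% 2:3)
    stop("a kernel needs 2 or 3 stain vectors")
  V <- t(vapply(stains, function(s) s$od_vector, numeric(3)))
  # reject near-collinear pairs (angle < 1 degree)
  for (i in seq_len(nrow(V) - 1)) for (j in (i + 1):nrow(V)) {
    ang <- acos(pmin(1, sum(V[i, ] * V[j, ]))) * 180 / pi
    if (ang < 1) stop("stain vectors ", i, " and ", j, " are collinear (< 1 degree apart)")
  }
  if (nrow(V) == 2L) {
    res <- c(V[1, 2] * V[2, 3] - V[1, 3] * V[2, 2],
             V[1, 3] * V[2, 1] - V[1, 1] * V[2, 3],
             V[1, 1] * V[2, 2] - V[1, 2] * V[2, 1])
    nr <- sqrt(sum(res^2))
    if (nr < 1e-12) stop("cannot complete residual vector: stains are collinear")
    V <- rbind(V, res / nr)
  }
  if (rcond(V) < 1e-6) stop("stain matrix is singular or ill-conditioned")
  structure(list(stains = stains,
                 stain_names = vapply(stains, `[[`, "", "name"),
                 matrix = V,
                 inverse = solve(V),
                 n_stains = length(stains)),
            class = "stain_kernel")
}

#' @export
print.stain_kernel <- function(x, ...) {
  cat("stain_kernel with", x$n_stains, "stain(s):\n")
  for (s in x$stains)
    cat(sprintf("  %-16s azimuth %6.2f  inclination %6.2f  OD (%.3f, %.3f, %.3f)\n",
                s$name, s$azimuth, s$inclination,
                s$od_vector[1], s$od_vector[2], s$od_vector[3]))
  if (x$n_stains == 2L)
    cat(sprintf("  %-16s (residual) OD (%.3f, %.3f, %.3f)\n", "",
                x$matrix[3, 1], x$matrix[3, 2], x$matrix[3, 3]))
  invisible(x)
}

#' Unmix an RGB image into per-stain concentration maps
#'
#' Each pixel's OD vector is multiplied by the kernel's unmixing inverse,
#' giving unitless per-stain OD amounts ("concentrations"). Negative raw
#' concentrations (noise, imperfect kernels) are clipped to 0 in the
#' returned maps; the raw values are retained for kernel diagnostics.
#'
#' @param image RGB array in `[0, 1]`.
#' @param kernel A `stain_kernel`.
#' @return A `concentration_maps`: list with `maps` (named list of
#'   matrices, clipped at 0), `raw` (pixels x 3 matrix of unclipped
#'   concentrations) and `stain_names` (third name `"residual"` for
#'   2-stain kernels).
#' @export
deconvolve <- function(image, kernel) {
  check_image(image)
  if (n_channels(image) != 3L) stop("deconvolve needs a 3-channel image")
  if (!inherits(kernel, "stain_kernel")) stop("kernel must be a stain_kernel")
  if (kernel$n_stains < 2L) stop("kernel must carry at least 2 stains")
  od <- to_optical_density(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  odm <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  # OD_i = t(V) c_i  =>  c_i = t(inverse) OD_i, i.e. raw = OD %*% inverse
  raw <- odm %*% kernel$inverse
  nm <- kernel$stain_names
  if (kernel$n_stains == 2L) nm <- c(nm, "residual")
  maps <- lapply(seq_len(3), function(k) matrix(pmax(raw[, k], 0), h, w))
  names(maps) <- nm
  structure(list(maps = maps, raw = raw, stain_names = nm,
                 n_stains = kernel$n_stains),
            class = "concentration_maps")
}

#' Compose an RGB image from concentration maps (forward model)
#'
#' Inverse of [deconvolve()]: `OD(pixel) = sum_s c_s(pixel) * v_s`, then
#' `I = 10^(-OD)` per channel. Used by the synthetic generator and in
#' round-trip validation.
#'
#' @param conc Named list of concentration matrices (one per kernel stain,
#'   in kernel order; the residual channel of a 2-stain kernel is omitted).
#' @param kernel A `stain_kernel`.
#' @return RGB array in `(0, 1]`.
#' @export
compose_stains <- function(conc, kernel) {
  h <- nrow(conc[[1]]); w <- ncol(conc[[1]])
  od <- array(0, c(h, w, 3))
  for (s in seq_along(conc)) {
    v <- kernel$matrix[s, ]
    for (ch in 1:3) od[, , ch] <- od[, , ch] + conc[[s]] * v[ch]
  }
  od_to_intensity(od)
}

#' Preset deconvolution kernels
#'
#' Package presets for the two stain pairs of the trilineage assays:
#' `"oilredo_hematoxylin"` (adipogenic: lipid dye vs. blue nuclear
#' counterstain) and `"alcianblue_nfr"` (chondrogenic: glycosaminoglycan
#' dye vs. Nuclear Fast Red). The angles are package presets — reasonable
#' starting points for [estimate_kernel()] on a user's own material, not
#' instrument-validated ground truth.
#'
#' @param name Preset name.
#' @return A `stain_kernel`.
#' @export
kernel_preset <- function(name = c("oilredo_hematoxylin", "alcianblue_nfr")) {
  name <- match.arg(name)
  switch(name,
    oilredo_hematoxylin = build_kernel(list(
      polar_to_vector(azimuth = 83, inclination = 59, name = "OilRedO"),
      polar_to_vector(azimuth = 47, inclination = 73, name = "Hematoxylin"))),
    alcianblue_nfr = build_kernel(list(
      polar_to_vector(azimuth = 35, inclination = 76, name = "AlcianBlue"),
      polar_to_vector(azimuth = 77, inclination = 65, name = "NuclearFastRed")))
  )
}

#' Read or write a kernel as a small structured text file
#'
#' YAML schema: a list of stains, each with `name`, `azimuth` and
#' `inclination` in degrees.
#'
#' @param kernel A `stain_kernel`.
#' @param path File path.
#' @return `write_kernel()` returns `path` invisibly; `read_kernel()` a
#'   `stain_kernel`.
#' @export
write_kernel <- function(kernel, path) {
  stains <- lapply(kernel$stains, function(s)
    list(name = s$name, azimuth = s$azimuth, inclination = s$inclination))
  yaml::write_yaml(list(stains = stains), path)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  y <- yaml::read_yaml(path)
  build_kernel(lapply(y$stains, function(s)
    polar_to_vector(s$azimuth, s$inclination, name = s$name)))
}

# Kernel-estimation objective: mean squared magnitude of negative raw
# concentrations, plus (2-stain kernels) the mean squared residual channel
# (two-dye material must have a vanishing residual; penalizing its
# magnitude symmetrically pins out-of-plane drift), plus lambda times the
# mean pairwise Pearson correlation of the clipped stain channels: cleanly
# separated stains are anti-correlated across a collage, and any
# cone-enlarging drift leaks one dye into the other's channel, raising the
# correlation.
kernel_objective <- function(odm, kernel, lambda = 0.1) {
  raw <- odm %*% kernel$inverse
  ns <- kernel$n_stains
  obj <- mean(pmin(raw, 0)^2)
  if (ns == 2L) obj <- obj + mean(raw[, 3]^2)
  if (ns >= 2L) {
    pos <- pmax(raw[, seq_len(ns), drop = FALSE], 0)
    cors <- c()
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
      si <- sd(pos[, i]); sj <- sd(pos[, j])
      if (si > 0 && sj > 0) cors <- c(cors, stats::cor(pos[, i], pos[, j]))
    }
    if (length(cors)) obj <- obj + lambda * mean(cors)
  }
  obj
}

#' Assemble a deterministic image collage for kernel estimation
#'
#' Tiles nine images (sampled with a fixed seed when more are supplied) into
#' a 3x3 collage after resizing each to a common tile size, so the kernel
#' search sees the pooled color statistics of a batch.
#'
#' @param images List of RGB arrays in `[0, 1]`.
#' @param tile_width Tile width in pixels (each tile is resized to this).
#' @param seed Integer seed controlling which nine images are sampled.
#' @return RGB array, the collage.
#' @export
make_collage <- function(images, tile_width = 64, seed = 1) {
  if (!length(images)) stop("need at least one image")
  set.seed(seed)
  idx <- if (length(images) >= 9) sample(length(images), 9)
         else rep_len(seq_along(images), 9)
  tiles <- lapply(images[idx], resize_to_width, target_width = tile_width)
  th <- min(vapply(tiles, function(t) dim(t)[1], 1L))
  tiles <- lapply(tiles, function(t) t[seq_len(th), , , drop = FALSE])
  rows <- lapply(0:2, function(r) {
    do.call(abind3, tiles[r * 3 + 1:3])
  })
  out <- array(0, c(3 * th, 3 * tile_width, 3))
  for (r in 1:3) out[(r - 1) * th + seq_len(th), , ] <- rows[[r]]
  out
}

# bind RGB arrays left-to-right
abind3 <- function(...) {
  parts <- list(...)
  w <- sum(vapply(parts, function(p) dim(p)[2], 1L))
  h <- dim(parts[[1]])[1]
  out <- array(0, c(h, w, 3))
  at <- 0L
  for (p in parts) {
    out[, at + seq_len(dim(p)[2]), ] <- p
    at <- at + dim(p)[2]
  }
  out
}

#' Estimate a deconvolution kernel from an image collage
#'
#' Refines the polar angles of a starting kernel by coordinate descent,
#' minimizing the mean squared magnitude of negative raw concentrations
#' plus a cross-talk penalty (`lambda` times the mean pairwise correlation
#' of the clipped stain channels). The step schedule halves from 2 degrees
#' down to `resolution` (default 0.25 degrees); angles are confined to
#' `[0, 90]`. This is a reproducible replacement for interactive
#' slider-based kernel tuning: alongside the kernel it can emit a static
#' diagnostics report ([kernel_report()]).
#'
#' @param collage_images List of RGB arrays (a collage is built from them),
#'   or a single RGB array used as the collage directly.
#' @param initial Starting `stain_kernel`.
#' @param lambda Cross-talk penalty weight.
#' @param resolution Angular resolution of the final search step, degrees.
#' @param max_sweeps Safety cap on coordinate-descent sweeps per step size.
#' @param od_pool Block-average factor applied to the optical-density image
#'   before the search (default 2). Averaging in OD space is linear in
#'   concentrations, so it suppresses sensor noise without biasing stain
#'   directions (averaging intensities would, through the logarithm).
#' @param seed Seed for the collage assembly.
#' @return A `stain_kernel` with an attached `diagnostics` attribute:
#'   objective at start/end, number of evaluations, per-stain angle deltas.
#' @export
estimate_kernel <- function(collage_images, initial, lambda = 0.1,
                            resolution = 0.25, max_sweeps = 40, od_pool = 2L,
                            seed = 1) {
  collage <- if (is.list(collage_images)) {
    make_collage(collage_images, seed = seed)
  } else collage_images
  check_image(collage)
  od <- to_optical_density(collage)
  if (od_pool > 1L) {
    nh <- max(1L, nrow(od[, , 1]) %/% od_pool)
    nw <- max(1L, ncol(od[, , 1]) %/% od_pool)
    pooled <- array(0, c(nh, nw, 3))
    for (ch in 1:3) pooled[, , ch] <- resample_channel(od[, , ch], nh, nw)
    od <- pooled
  }
  odm <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  ns <- initial$n_stains
  ang <- do.call(rbind, lapply(initial$stains, function(s) c(s$azimuth, s$inclination)))
  nm <- initial$stain_names
  mk <- function(a) {
    build_kernel(lapply(seq_len(ns), function(i)
      polar_to_vector(a[i, 1], a[i, 2], name = nm[i])))
  }
  evals <- 0L
  f <- function(a) {
    k <- tryCatch(mk(a), error = function(e) NULL)
    if (is.null(k)) return(Inf)
    evals <<- evals + 1L
    kernel_objective(odm, k, lambda)
  }
  best <- f(ang)
  start_obj <- best
  # per-stain pattern moves: axis steps plus diagonals, so coupled
  # azimuth/inclination valleys (in-plane rotations) remain descendable
  deltas <- as.matrix(expand.grid(daz = c(-1, 0, 1), dinc = c(-1, 0, 1)))
  deltas <- deltas[rowSums(abs(deltas)) > 0, , drop = FALSE]
  step <- 2
  while (step >= resolution - 1e-12) {
    for (sweep in seq_len(max_sweeps)) {
      improved <- FALSE
      for (i in seq_len(ns)) {
        for (d in seq_len(nrow(deltas))) {
          cand <- ang
          cand[i, ] <- pmin(90, pmax(0, cand[i, ] + deltas[d, ] * step))
          val <- f(cand)
          if (val < best - 1e-15) {
            best <- val; ang <- cand; improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    step <- step / 2
  }
  out <- mk(ang)
  attr(out, "diagnostics") <- list(
    objective_start = start_obj, objective_end = best, n_evaluations = evals,
    angles = ang, collage_dim = dim(collage))
  out
}

#' Write a static kernel-diagnostics report
#'
#' Replaces dynamic inspection of deconvolution results: writes one PNG per
#' stain channel (concentration map rescaled to the unit range) and a CSV
#' of per-channel pixel statistics (min, max, mean, fraction of negative
#' raw concentrations).
#'
#' @param kernel A `stain_kernel`.
#' @param image RGB array the kernel is evaluated on (e.g. the collage).
#' @param dir Output directory (created if needed).
#' @return Tibble of per-channel statistics, invisibly; files are written
#'   into `dir`.
#' @export
kernel_report <- function(kernel, image, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm <- deconvolve(image, kernel)
  stats_rows <- lapply(seq_along(cm$maps), function(k) {
    m <- cm$maps[[k]]
    raw <- cm$raw[, k]
    rng <- max(m)
    png::writePNG(if (rng > 0) m / rng else m,
                  file.path(dir, paste0("concentration_", cm$stain_names[k], ".png")))
    tibble::tibble(stain = cm$stain_names[k], min_raw = min(raw),
                   max_raw = max(raw), mean_raw = mean(raw),
                   frac_negative = mean(raw < 0))
  })
  out <- dplyr::bind_rows(stats_rows)
  write.csv(out, file.path(dir, "kernel_statistics.csv"), row.names = FALSE)
  invisible(out)
}
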