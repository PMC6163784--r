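#' Scene specification for synthetic stained microscopy
#'
#' Describes a renderable scene: compact objects (disks/ellipses) carrying
#' per-stain optical-density amounts over an optional stained background,
#' imaged under a radial quadratic vignette (`1 - strength * r^2` with `r`
#' the distance to the field center normalized by the far-corner distance)
#' and optional Gaussian intensity noise.
#'
#' @param width,height Image size in pixels.
#' @param objects List of objects; each a list with `cx`, `cy` (center,
#'   px), `r` (radius) or `rx`/`ry` (ellipse semi-axes), and `conc`, a
#'   named numeric vector of per-stain OD amounts (named by kernel stain).
#' @param background Named numeric vector of background OD amounts
#'   (default none).
#' @param vignette_strength Vignette coefficient in `[0, 1)`; 0 = flat
#'   field.
#' @param vignette_center `c(x, y)` in pixels; default image center.
#' @param noise_sd Gaussian intensity noise standard deviation.
#' @param seed Integer seed; renders are bit-identical given the spec.
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(width = 512, height = 512, objects = list(),
                       background = NULL, vignette_strength = 0,
                       vignette_center = NULL, noise_sd = 0, seed = 1) {
  for (ob in objects)
    if (any(ob$conc < 0)) stop("object stain concentrations must be >= 0")
  if (!is.null(background) && any(background < 0))
    stop("background concentrations must be >= 0")
  if (vignette_strength < 0 || vignette_strength >= 1)
    stop("vignette_strength must lie in [0, 1)")
  structure(list(width = as.integer(width), height = as.integer(height),
                 objects = objects, background = background,
                 vignette_strength = vignette_strength,
                 vignette_center = vignette_center,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Radial quadratic vignette field
#'
#' @param height,width Field size in pixels.
#' @param strength Coefficient `k` of `1 - k * r^2`; `r` is normalized so
#'   the farthest corner has `r = 1`.
#' @param center `c(x, y)` center in pixels (default image center).
#' @return Matrix in `(0, 1]`.
#' @export
vignette_field <- function(height, width, strength, center = NULL) {
  if (is.null(center)) center <- c((width + 1) / 2, (height + 1) / 2)
  x <- matrix(seq_len(width), height, width, byrow = TRUE)
  y <- matrix(seq_len(height), height, width)
  d2 <- (x - center[1])^2 + (y - center[2])^2
  corners <- rbind(c(1, 1), c(1, height), c(width, 1), c(width, height))
  maxd2 <- max((corners[, 1] - center[1])^2 + (corners[, 2] - center[2])^2)
  if (maxd2 == 0) maxd2 <- 1
  1 - strength * d2 / maxd2
}

object_mask_matrix <- function(ob, height, width) {
  rx <- if (!is.null(ob$rx)) ob$rx else ob$r
  ry <- if (!is.null(ob$ry)) ob$ry else ob$r
  x <- matrix(seq_len(width), height, width, byrow = TRUE)
  y <- matrix(seq_len(height), height, width)
  ((x - ob$cx) / rx)^2 + ((y - ob$cy) / ry)^2 <= 1
}

#' Render a stained brightfield image with known ground truth
#'
#' Forward Beer-Lambert composition: per pixel,
#' `OD = sum_s c_s * v_s` over the kernel's stains, `I = 10^(-OD)` per
#' channel, multiplied by the vignette field, plus clipped Gaussian noise.
#' The exact concentration maps, object mask and illumination field used
#' are returned, so deconvolution and segmentation results can be checked
#' against ground truth.
#'
#' @param spec A [scene_spec()].
#' @param kernel `stain_kernel` providing the stain colors; object/
#'   background concentration names must match kernel stain names.
#' @return List with `image` (RGB array), `field`, `concentrations`
#'   (named list of matrices), `object_mask` (0/1), and `spec`.
#' @export
render_stained_image <- function(spec, kernel) {
  h <- spec$height; w <- spec$width
  nm <- kernel$stain_names[seq_len(kernel$n_stains)]
  conc <- lapply(nm, function(s) matrix(0, h, w))
  names(conc) <- nm
  if (!is.null(spec$background))
    for (s in names(spec$background))
      conc[[s]] <- conc[[s]] + spec$background[[s]]
  omask <- matrix(0, h, w)
  for (ob in spec$objects) {
    inside <- object_mask_matrix(ob, h, w)
    omask[inside] <- 1
    for (s in names(ob$conc))
      conc[[s]][inside] <- conc[[s]][inside] + ob$conc[[s]]
  }
  unknown <- setdiff(c(names(spec$background),
                       unlist(lapply(spec$objects, function(o) names(o$conc)))),
                     nm)
  if (length(unknown))
    stop("concentrations refer to stains absent from the kernel: ",
         paste(unknown, collapse = ", "))
  img <- compose_stains(conc, kernel)
  field <- vignette_field(h, w, spec$vignette_strength, spec$vignette_center)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * field
  if (min(img) < 0 || max(img) > 1)
    stop("rendered intensities fall outside [0, 1] before noise")
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    img <- clip01(img + rnorm(length(img), 0, spec$noise_sd))
    dim(img) <- c(h, w, 3)
  }
  list(image = img, field = field, concentrations = conc,
       object_mask = omask, spec = spec)
}

#' Calibration pair matching a rendered scene
#'
#' The brightfield reference of a synthetic scene is its illumination
#' field (an empty slide transmits everything), the darkfield is zero.
#'
#' @param field Illumination-field matrix.
#' @param channels 1 or 3 (match the image to correct).
#' @return List with `brightfield` and `darkfield`.
#' @export
calibration_from_field <- function(field, channels = 3L) {
  if (channels == 1L)
    return(list(brightfield = field, darkfield = matrix(0, nrow(field), ncol(field))))
  bf <- array(0, c(nrow(field), ncol(field), 3))
  for (ch in 1:3) bf[, , ch] <- field
  list(brightfield = bf, darkfield = array(0, dim(bf)))
}

place_spots <- function(n, height, width, min_sep, margin, max_tries = 10000L) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("requested spot density too high for the separation constraint")
    cand <- c(runif(1, margin, width - margin), runif(1, margin, height - margin))
    if (!nrow(pts) || min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= min_sep)
      pts <- rbind(pts, cand)
  }
  pts
}

gaussian_spot_field <- function(centers, height, width, sigma, amplitude) {
  f <- matrix(0, height, width)
  if (!nrow(centers)) return(f)
  ext <- ceiling(4 * sigma)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    xs <- max(1, floor(cx - ext)):min(width, ceiling(cx + ext))
    ys <- max(1, floor(cy - ext)):min(height, ceiling(cy + ext))
    gx <- exp(-(xs - cx)^2 / (2 * sigma^2))
    gy <- exp(-(ys - cy)^2 / (2 * sigma^2))
    f[ys, xs] <- f[ys, xs] + amplitude * outer(gy, gx)
  }
  f
}

#' Render a two-channel LIVE/DEAD fluorescence image
#'
#' Viable cells are isotropic Gaussian spots in the green channel, dead
#' cells in the red channel, over a positively skewed fluorescence
#' background. Spot centers are placed by rejection sampling under a
#' minimum-separation constraint (error when the requested density cannot
#' be placed). Ground-truth counts and centers are returned.
#'
#' @param n_live,n_dead Number of green / red spots.
#' @param width,height Image size in pixels.
#' @param spot_sigma Gaussian spot standard deviation (px).
#' @param amplitude Peak spot amplitude.
#' @param min_separation Minimum center-to-center distance (default
#'   `6 * spot_sigma`, comfortably above the resolvability limit).
#' @param background_level,background_noise Background offset and
#'   half-normal noise scale.
#' @param n_specks Number of single-pixel sub-threshold-size noise specks
#'   added to each channel (component area far below any sensible
#'   `min_area`).
#' @param seed Integer seed.
#' @return List with `green`, `red` (matrices in `[0, 1]`), `n_live`,
#'   `n_dead`, `live_centers`, `dead_centers`.
#' @export
render_livedead_image <- function(n_live, n_dead, width = 512, height = 512,
                                  spot_sigma = 2, amplitude = 0.7,
                                  min_separation = 6 * spot_sigma,
                                  background_level = 0.05,
                                  background_noise = 0.015,
                                  n_specks = 0, seed = 1) {
  set.seed(seed)
  margin <- 4 * spot_sigma
  render_channel <- function(n) {
    centers <- if (n > 0) place_spots(n, height, width, min_separation, margin)
               else matrix(numeric(0), 0, 2)
    ch <- background_level + abs(rnorm(height * width, 0, background_noise)) +
      gaussian_spot_field(centers, height, width, spot_sigma, amplitude)
    if (n_specks > 0) {
      idx <- sample(height * width, n_specks)
      ch[idx] <- ch[idx] + amplitude
    }
    list(img = clip01(matrix(ch, height, width)), centers = centers)
  }
  g <- render_channel(n_live)
  r <- render_channel(n_dead)
  list(green = g$img, red = r$img, n_live = n_live, n_dead = n_dead,
       live_centers = g$centers, dead_centers = r$centers)
}

#' Experimental-group labels per culture system
#'
#' The treatment groups of the study design: monolayer cultures see all
#' nine conditions (control, single cytokines at high and low doses, both
#' combinations, activated and non-activated leukocyte co-culture); static
#' scaffold cultures drop the activated-leukocyte group; dynamic scaffold
#' cultures keep only the control, the two cytokine combinations and
#' non-activated leukocytes.
#'
#' @param system `"monolayer"`, `"static"` or `"dynamic"`.
#' @return Character vector of condition labels (first is the control).
#' @export
cohort_conditions <- function(system = c("monolayer", "static", "dynamic")) {
  system <- match.arg(system)
  all9 <- c("control", "IL1b_high", "TNFa_high", "IL1b_low", "TNFa_low",
            "IL1b_TNFa_high", "IL1b_TNFa_low", "leuko_stim", "leuko")
  switch(system,
         monolayer = all9,
         static = setdiff(all9, "leuko_stim"),
         dynamic = c("control", "IL1b_TNFa_high", "IL1b_TNFa_low", "leuko"))
}

#' Cohort specification for simulated donor-blocked experiments
#'
#' Defines a 7-donor, multi-condition, two-timepoint design with
#' multiplicative condition/day effects on a positive metric, a shared
#' lognormal donor random effect, and lognormal residual noise — the data
#' shape the nonparametric cohort statistics consume.
#'
#' @param n_donors Number of donors (blocking factor; default 7).
#' @param systems Culture systems to simulate.
#' @param days Timepoints (default days 1 and 3).
#' @param baseline Baseline metric value (positive).
#' @param condition_effects Named multiplicative effects; unnamed
#'   conditions default to 1. The control effect must be 1.
#' @param day_effects Named multiplicative effects per day (default 1).
#' @param donor_sdlog Donor random-effect scale on the log scale
#'   (default 0.3).
#' @param noise_cv Residual coefficient of variation (default 0.2);
#'   converted to `sdlog = sqrt(log(1 + cv^2))`.
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_donors = 7, systems = "monolayer", days = c(1, 3),
                        baseline = 1, condition_effects = NULL,
                        day_effects = NULL, donor_sdlog = 0.3,
                        noise_cv = 0.2, seed = 1) {
  if (baseline <= 0) stop("baseline must be positive")
  if (!is.null(condition_effects)) {
    if (any(condition_effects <= 0)) stop("condition effects must be positive")
    if ("control" %in% names(condition_effects) &&
        condition_effects[["control"]] != 1)
      stop("the control condition effect must be 1")
  }
  structure(list(n_donors = as.integer(n_donors), systems = systems,
                 days = days, baseline = baseline,
                 condition_effects = condition_effects,
                 day_effects = day_effects, donor_sdlog = donor_sdlog,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a donor-blocked cohort table
#'
#' `value = baseline * donor_effect * condition_effect * day_effect *
#' exp(N(0, sdlog))` with `sdlog = sqrt(log(1 + cv^2))`; donor effects are
#' `exp(N(0, donor_sdlog))`, shared across all of a donor's cells. With
#' all effects at 1 and zero noise every value equals the baseline.
#'
#' @param spec A [cohort_spec()].
#' @return Tidy tibble with `donor`, `culture_system`, `condition`, `day`,
#'   `value`, and the ground-truth effect columns `true_donor_effect`,
#'   `true_condition_effect`, `true_day_effect`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  donor_eff <- exp(rnorm(spec$n_donors, 0, spec$donor_sdlog))
  rows <- list()
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  for (sys in spec$systems) {
    conds <- cohort_conditions(sys)
    grid <- expand.grid(donor = seq_len(spec$n_donors), condition = conds,
                        day = spec$days, stringsAsFactors = FALSE)
    ce <- rep(1, nrow(grid))
    if (!is.null(spec$condition_effects)) {
      hit <- grid$condition %in% names(spec$condition_effects)
      ce[hit] <- unlist(spec$condition_effects[grid$condition[hit]])
    }
    de <- rep(1, nrow(grid))
    if (!is.null(spec$day_effects)) {
      hit <- as.character(grid$day) %in% names(spec$day_effects)
      de[hit] <- unlist(spec$day_effects[as.character(grid$day)[hit]])
    }
    noise <- if (sdlog > 0) exp(rnorm(nrow(grid), 0, sdlog)) else rep(1, nrow(grid))
    rows[[sys]] <- tibble::tibble(
      donor = paste0("d", grid$donor),
      culture_system = sys,
      condition = grid$condition,
      day = grid$day,
      value = spec$baseline * donor_eff[grid$donor] * ce * de * noise,
      true_donor_effect = donor_eff[grid$donor],
      true_condition_effect = ce,
      true_day_effect = de)
  }
  dplyr::bind_rows(rows)
}
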