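#' Assay-level metrics
#'
#' Each quantification function returns an `assay_metrics` tibble row with
#' the assay label and its measurands. Undefined quantities (e.g. a dye
#' ratio over an empty mask) propagate as `NA`, never as 0, so that
#' downstream statistics treat them as missing.
#'
#' @name assay_metrics
#' @keywords internal
NULL

assay_row <- function(assay, area_fraction = NA_real_, dye_ratio = NA_real_,
                      concentration_percentage = NA_real_, score = NA_real_,
                      dead_count = NA_integer_, area_px = NA_real_) {
  tibble::tibble(assay = assay, area_fraction = area_fraction,
                 area_px = area_px, dye_ratio = dye_ratio,
                 concentration_percentage = concentration_percentage,
                 score = score, dead_count = dead_count)
}

# mass of the first two stain channels inside a mask; the residual channel
# of a 2-stain kernel never enters assay ratios
stain_masses <- function(cm, mask) {
  inmask <- mask == 1
  c(a = sum(cm$maps[[1]][inmask]), b = sum(cm$maps[[2]][inmask]))
}

#' Adipogenic assay: Oil Red O / hematoxylin quantification
#'
#' Pipeline: illumination correction, adaptive cell mask on the negated
#' luminance (analysis restricted to cell regions), color deconvolution,
#' then `area_fraction` (mask area over image area), `dye_ratio`
#' (Oil Red O concentration mass over hematoxylin mass within the mask)
#' and `concentration_percentage` (Oil Red O mass over total two-stain
#' mass within the mask).
#'
#' @param image RGB array in `[0, 1]`.
#' @param brightfield,darkfield Calibration pair (see
#'   [correct_illumination()]).
#' @param kernel `stain_kernel` whose first stain is the target dye
#'   (Oil Red O) and second the counterstain (hematoxylin).
#' @param params [adaptive_params()] for the cell mask.
#' @return One-row tibble of metrics; with an empty cell mask the ratio
#'   metrics are `NA` with a warning.
#' @export
adipogenic_metrics <- function(image, brightfield, darkfield,
                               kernel = kernel_preset("oilredo_hematoxylin"),
                               params = adaptive_params()) {
  corrected <- correct_illumination(image, brightfield, darkfield)
  lum <- to_luminance(corrected)
  mask <- adaptive_cell_mask(lum, params)
  af <- mean(mask)
  if (!any(mask == 1)) {
    warning("adipogenic_metrics: empty cell mask; dye ratio is undefined")
    return(assay_row("adipogenic", area_fraction = 0, area_px = 0))
  }
  cm <- deconvolve(corrected, kernel)
  ms <- stain_masses(cm, mask)
  dr <- if (ms["b"] > 0) unname(ms["a"] / ms["b"]) else NA_real_
  cp <- if (sum(ms) > 0) unname(ms["a"] / sum(ms)) else NA_real_
  assay_row("adipogenic", area_fraction = af, area_px = sum(mask),
            dye_ratio = dr, concentration_percentage = cp)
}

#' Chondrogenic assay: pellet size and Alcian blue / Nuclear Fast Red ratio
#'
#' Pipeline: illumination correction, pellet mask (global Otsu with
#' morphological cleanup; analysis restricted to the pellet), color
#' deconvolution, then the pellet `area_fraction` (and `area_px`) as a
#' micromass-size measure and the Alcian blue to Nuclear Fast Red
#' concentration-mass ratio as a cartilaginous-matrix measure.
#'
#' @inheritParams adipogenic_metrics
#' @param kernel `stain_kernel` with the Alcian blue stain first and
#'   Nuclear Fast Red second.
#' @return One-row tibble of metrics; all `NA` with a warning when no
#'   pellet is found.
#' @export
chondrogenic_metrics <- function(image, brightfield, darkfield,
                                 kernel = kernel_preset("alcianblue_nfr")) {
  corrected <- correct_illumination(image, brightfield, darkfield)
  lum <- to_luminance(corrected)
  mask <- suppressWarnings(pellet_mask(lum))
  if (!any(mask == 1)) {
    warning("chondrogenic_metrics: no pellet found; metrics are undefined")
    return(assay_row("chondrogenic"))
  }
  cm <- deconvolve(corrected, kernel)
  ms <- stain_masses(cm, mask)
  dr <- if (ms["b"] > 0) unname(ms["a"] / ms["b"]) else NA_real_
  cp <- if (sum(ms) > 0) unname(ms["a"] / sum(ms)) else NA_real_
  assay_row("chondrogenic", area_fraction = mean(mask), area_px = sum(mask),
            dye_ratio = dr, concentration_percentage = cp)
}

#' Osteogenic assay: inverted mean brightness of a von Kossa stain
#'
#' The single-dye von Kossa stain needs no deconvolution: the score is
#' `1 - mean(luminance)` of the illumination-corrected image, so darker
#' (more mineralized) images score higher. The score lies in `[0, 1]`.
#'
#' @inheritParams adipogenic_metrics
#' @return One-row tibble with the `score`.
#' @export
osteogenic_score <- function(image, brightfield, darkfield) {
  corrected <- correct_illumination(image, brightfield, darkfield)
  lum <- if (n_channels(corrected) == 3L) to_luminance(corrected) else corrected
  assay_row("osteogenic", score = 1 - mean(lum))
}

#' Confluency of a phase-contrast image
#'
#' Area percentage of the mean-offset mask ([confluency_mask()]); luminance
#' is taken first if the input is RGB. Reported as percent in the `score`
#' column (and as a fraction in `area_fraction`).
#'
#' @param image Gray matrix or RGB array in `[0, 1]`.
#' @param offset Threshold offset above the mean (default 0.07).
#' @return One-row tibble; `score` is the confluency in percent.
#' @export
confluency <- function(image, offset = 0.07) {
  gray <- if (n_channels(image) == 3L) to_luminance(image) else image
  mask <- confluency_mask(gray, offset)
  assay_row("confluency", area_fraction = mean(mask), area_px = sum(mask),
            score = 100 * mean(mask))
}

#' Count dead cells in the red fluorescence channel
#'
#' Dead (membrane-compromised) nuclei appear as bright red spots. The
#' channel is binarized at the Otsu threshold, 8-connected components are
#' labeled, components smaller than `min_area` pixels are discarded as
#' noise, and the remaining components are counted. Viable (green) cells
#' are too variable in morphology for this approach and are not counted.
#'
#' @param red_channel Single-channel matrix in `[0, 1]`.
#' @param min_area Minimum component area in pixels (default 10).
#' @param min_intensity Absolute threshold floor (default 0.2): Otsu always
#'   splits a histogram, so on a spot-free frame it would binarize the
#'   background noise; flooring the threshold keeps empty frames empty.
#' @return One-row tibble with `dead_count`. A saturated frame (foreground
#'   above 50% of the image) is rejected as unanalyzable.
#' @export
count_dead_cells <- function(red_channel, min_area = 10L, min_intensity = 0.2) {
  if (!is.matrix(red_channel)) stop("red_channel must be a single-channel matrix")
  thr <- tryCatch(otsu_threshold(red_channel), error = function(e) NULL)
  if (is.null(thr)) return(assay_row("livedead", dead_count = 0L))
  bw <- (red_channel > max(thr, min_intensity)) + 0
  if (mean(bw) > 0.5)
    stop("count_dead_cells: foreground exceeds half of the image; ",
         "saturated or unanalyzable frame")
  lab <- label_components_8(bw)
  if (max(lab) == 0L) return(assay_row("livedead", dead_count = 0L))
  sizes <- tabulate(lab[lab > 0])
  assay_row("livedead", dead_count = sum(sizes >= min_area),
            area_fraction = mean(bw))
}

#' Histology repopulation score
#'
#' Blinded scoring of hematoxylin/eosin sections of cell-seeded scaffolds,
#' three categories summed to a 0-10 total: cell distribution at the seeded
#' surface (0-4: none, single cells, monolayer, partial multilayer,
#' constant multilayer), cell integration within the scaffold (0-3: none,
#' <10%, 10-50%, >50% of cells integrated), and cell distribution at the
#' opposite surface (0-3, same percentage bands).
#'
#' @param surface Integer 0-4.
#' @param integration,opposite Integers 0-3.
#' @return List of class `histology_score` with the three category scores
#'   and their `total`.
#' @examples
#' total_histology_score(4, 3, 3)$total  # maximum: 10
#' @export
total_histology_score <- function(surface, integration, opposite) {
  chk <- function(x, hi, nm) {
    if (length(x) != 1L || is.na(x) || x %% 1 != 0 || x < 0 || x > hi)
      stop(nm, " must be an integer in 0..", hi)
    as.integer(x)
  }
  surface <- chk(surface, 4L, "surface")
  integration <- chk(integration, 3L, "integration")
  opposite <- chk(opposite, 3L, "opposite")
  structure(list(surface_distribution = surface, integration = integration,
                 opposite_surface = opposite,
                 total = surface + integration + opposite),
            class = "histology_score")
}
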