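adipo_scene <- function(oro = 0.8, hema = 0.2, vignette = 0) {
  objs <- list(
    list(cx = 40, cy = 40, r = 18, conc = c(OilRedO = oro, Hematoxylin = hema)),
    list(cx = 110, cy = 60, r = 15, conc = c(OilRedO = oro, Hematoxylin = hema)),
    list(cx = 70, cy = 110, r = 16, conc = c(OilRedO = oro, Hematoxylin = hema)))
  scene_spec(width = 160, height = 160, objects = objs,
             vignette_strength = vignette)
}

test_that("adipogenic dye ratio reflects the composed OD mixture", {
  k <- kernel_preset("oilredo_hematoxylin")
  r <- render_stained_image(adipo_scene(), k)
  calib <- calibration_from_field(r$field)
  m <- adipogenic_metrics(r$image, calib$brightfield, calib$darkfield, k,
                          adaptive_params(region_size = 21, work_width = 160))
  expect_equal(m$dye_ratio, 4, tolerance = 0.05)
  expect_gt(m$area_fraction, 0)
  expect_equal(m$concentration_percentage, 0.8, tolerance = 0.05)
  # doubling the Oil Red O amount doubles the ratio
  r2 <- render_stained_image(adipo_scene(oro = 1.6), k)
  m2 <- adipogenic_metrics(r2$image, calib$brightfield, calib$darkfield, k,
                           adaptive_params(region_size = 21, work_width = 160))
  expect_equal(m2$dye_ratio / m$dye_ratio, 2, tolerance = 0.05)
})

test_that("a blank adipogenic image reports empty mask and missing ratio", {
  blank <- array(1, c(64, 64, 3))
  calib <- calibration_from_field(matrix(1, 64, 64))
  expect_warning(
    m <- adipogenic_metrics(blank, calib$brightfield, calib$darkfield,
                            kernel_preset("oilredo_hematoxylin"),
                            adaptive_params(region_size = 9, work_width = 64)),
    "empty")
  expect_equal(m$area_fraction, 0)
  expect_true(is.na(m$dye_ratio))
})

test_that("dye ratio is invariant under a vignette captured by calibration", {
  k <- kernel_preset("oilredo_hematoxylin")
  flat <- render_stained_image(adipo_scene(vignette = 0), k)
  vig <- render_stained_image(adipo_scene(vignette = 0.4), k)
  p <- adaptive_params(region_size = 21, work_width = 160)
  cf <- calibration_from_field(flat$field)
  cv <- calibration_from_field(vig$field)
  mf <- adipogenic_metrics(flat$image, cf$brightfield, cf$darkfield, k, p)
  mv <- adipogenic_metrics(vig$image, cv$brightfield, cv$darkfield, k, p)
  expect_equal(mv$dye_ratio, mf$dye_ratio, tolerance = 0.01)
})

chondro_scene <- function(r = 55, alcian = 0.5, nfr = 0.5, with_bubble = FALSE) {
  objs <- list(list(cx = 90, cy = 84, r = r,
                    conc = c(AlcianBlue = alcian, NuclearFastRed = nfr)))
  if (with_bubble)
    objs <- c(objs, list(list(cx = 15, cy = 15, r = 4,
                              conc = c(AlcianBlue = 2.5, NuclearFastRed = 2.5))))
  scene_spec(width = 180, height = 168, objects = objs)
}

test_that("chondrogenic metrics recover pellet area and dye symmetry", {
  k <- kernel_preset("alcianblue_nfr")
  r <- render_stained_image(chondro_scene(), k)
  calib <- calibration_from_field(r$field)
  m <- chondrogenic_metrics(r$image, calib$brightfield, calib$darkfield, k)
  expect_equal(m$area_fraction, pi * 55^2 / (180 * 168), tolerance = 0.02)
  # equal OD of both dyes: ratio 1 by symmetry
  expect_equal(m$dye_ratio, 1, tolerance = 0.05)
  # an air-bubble artifact must not move the metrics
  rb <- render_stained_image(chondro_scene(with_bubble = TRUE), k)
  mb <- chondrogenic_metrics(rb$image, calib$brightfield, calib$darkfield, k)
  expect_equal(mb$area_fraction, m$area_fraction, tolerance = 0.01)
  expect_equal(mb$dye_ratio, m$dye_ratio, tolerance = 0.01)
})

test_that("chondrogenic metrics are missing when no pellet exists", {
  blank <- array(1, c(60, 60, 3))
  calib <- calibration_from_field(matrix(1, 60, 60))
  expect_warning(
    m <- chondrogenic_metrics(blank, calib$brightfield, calib$darkfield),
    "no pellet")
  expect_true(is.na(m$area_fraction) && is.na(m$dye_ratio))
})

test_that("von Kossa score is one minus mean corrected luminance", {
  calib <- calibration_from_field(matrix(1, 10, 10))
  black <- array(0, c(10, 10, 3)); white <- array(1, c(10, 10, 3))
  expect_equal(osteogenic_score(black, calib$brightfield, calib$darkfield)$score, 1)
  expect_equal(osteogenic_score(white, calib$brightfield, calib$darkfield)$score, 0)
  half <- array(rep(c(0, 1), each = 50), c(10, 10, 3))
  expect_equal(osteogenic_score(half, calib$brightfield, calib$darkfield)$score, 0.5)
  # strictly decreasing in mean brightness
  scores <- vapply(c(0.2, 0.4, 0.6, 0.8), function(v)
    osteogenic_score(array(v, c(10, 10, 3)),
                     calib$brightfield, calib$darkfield)$score, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("confluency reports the mask percentage", {
  g <- matrix(rep(c(0, 1), each = 50), 10, 10)
  expect_equal(confluency(g)$score, 50)
  expect_equal(confluency(matrix(0.3, 10, 10))$score, 0)
  # synthetic monolayer with known 30% bright coverage
  set.seed(31)
  h <- 128; w <- 128
  img <- matrix(0.1 + runif(h * w, 0, 0.02), h, w)
  n_on <- round(0.3 * h * w)
  on <- sample(h * w, n_on)
  img[on] <- 0.7 + runif(n_on, 0, 0.02)
  expect_equal(confluency(img)$score, 30, tolerance = 3)
})

test_that("dead-cell counting matches planted ground truth", {
  ld <- render_livedead_image(0, 25, width = 256, height = 256, seed = 41)
  expect_equal(count_dead_cells(ld$red)$dead_count, 25)
  blank <- render_livedead_image(0, 0, width = 128, height = 128, seed = 42)
  expect_equal(count_dead_cells(blank$red)$dead_count, 0)
  # sub-min_area specks are rejected
  sp <- render_livedead_image(0, 25, width = 256, height = 256,
                              n_specks = 40, seed = 43)
  expect_equal(count_dead_cells(sp$red)$dead_count, 25)
  # saturated frames are rejected as unanalyzable
  sat <- matrix(0.1, 64, 64); sat[1:40, ] <- 0.9
  expect_error(count_dead_cells(sat), "unanalyzable|foreground")
})

test_that("histology scores sum within their category ranges", {
  expect_equal(total_histology_score(4, 3, 3)$total, 10)
  expect_equal(total_histology_score(0, 0, 0)$total, 0)
  expect_equal(total_histology_score(2, 1, 1)$total, 4)
  expect_error(total_histology_score(5, 0, 0), "surface")
  expect_error(total_histology_score(1, 4, 0), "integration")
  expect_error(total_histology_score(1, 1, -1), "opposite")
  expect_error(total_histology_score(1.5, 1, 1))
})
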