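test_that("polar angles and OD vectors round-trip", {
  expect_equal(polar_to_vector(0, 0)$od_vector, c(0, 0, 1))
  expect_equal(polar_to_vector(45, 90)$od_vector, c(sqrt(2) / 2, sqrt(2) / 2, 0))
  set.seed(7)
  for (i in 1:1000) {
    az <- runif(1, 0, 90); inc <- runif(1, 0, 90)
    sv <- polar_to_vector(az, inc)
    expect_equal(sqrt(sum(sv$od_vector^2)), 1, tolerance = 1e-9)
    back <- vector_to_polar(sv$od_vector)
    # azimuth is undefined at the pole; skip the degenerate direction
    if (inc > 1e-6) expect_equal(back$azimuth, az, tolerance = 1e-9)
    expect_equal(back$inclination, inc, tolerance = 1e-9)
  }
  expect_error(polar_to_vector(135, 45), "negative")
})

test_that("optical density is the base-10 Beer-Lambert transform", {
  expect_equal(to_optical_density(matrix(1, 2, 2)), matrix(0, 2, 2))
  expect_equal(to_optical_density(matrix(0.1, 1, 1))[1, 1], 1)
  set.seed(8)
  img <- array(runif(60, 0.01, 1), c(4, 5, 3))
  expect_lt(max(abs(od_to_intensity(to_optical_density(img)) - img)), 1e-9)
})

test_that("kernels assemble, complete, and invert correctly", {
  id <- build_kernel(list(vector_to_polar(c(1, 0, 0), "r"),
                          vector_to_polar(c(0, 1, 0), "g"),
                          vector_to_polar(c(0, 0, 1), "b")))
  expect_equal(id$inverse, diag(3), tolerance = 1e-12)
  # 2-stain kernel: residual is unit-norm and orthogonal to both stains
  k2 <- build_kernel(list(vector_to_polar(c(1, 0, 0), "r"),
                          vector_to_polar(c(0, 1, 0), "g")))
  expect_equal(sum(k2$matrix[3, ]^2), 1, tolerance = 1e-12)
  expect_equal(sum(k2$matrix[3, ] * k2$matrix[1, ]), 0, tolerance = 1e-12)
  expect_equal(sum(k2$matrix[3, ] * k2$matrix[2, ]), 0, tolerance = 1e-12)
  # random independent triples invert
  set.seed(9)
  for (i in 1:20) {
    k <- build_kernel(list(polar_to_vector(runif(1, 5, 40), runif(1, 40, 85)),
                           polar_to_vector(runif(1, 50, 85), runif(1, 40, 85)),
                           polar_to_vector(runif(1, 30, 60), runif(1, 5, 30))))
    expect_lt(max(abs(k$matrix %*% k$inverse - diag(3))), 1e-9)
  }
  expect_error(build_kernel(list(polar_to_vector(45, 60),
                                 polar_to_vector(45.5, 60))), "collinear")
})

test_that("deconvolution unmixes composed mixtures exactly", {
  k <- test_kernel()
  # single pixel with known mixture
  od <- 0.7 * k$matrix[1, ] + 0.3 * k$matrix[2, ]
  px <- array(10^(-od), c(1, 1, 3))
  cm <- deconvolve(px, k)
  expect_equal(cm$raw[1, ], c(0.7, 0.3, 0), tolerance = 1e-6,
               ignore_attr = TRUE)
  # blank white image has zero concentrations
  blank <- deconvolve(array(1, c(4, 4, 3)), k)
  expect_true(all(abs(blank$raw) < 1e-9))
  # full-image round trip
  set.seed(10)
  ca <- matrix(runif(256, 0, 0.9), 16, 16)
  cb <- matrix(runif(256, 0, 0.6), 16, 16)
  img <- compose_stains(list(A = ca, B = cb), k)
  cm <- deconvolve(img, k)
  expect_lt(sqrt(mean((cm$maps$A - ca)^2)), 1e-6)
  expect_lt(sqrt(mean((cm$maps$B - cb)^2)), 1e-6)
  # clipped maps are nonnegative, raw values retained
  expect_true(all(cm$maps$residual >= 0))
})

test_that("deconvolution is linear in optical density before clipping", {
  k <- test_kernel()
  set.seed(12)
  od1 <- array(runif(48, 0, 0.5), c(4, 4, 3))
  od2 <- array(runif(48, 0, 0.5), c(4, 4, 3))
  a <- 0.6; b <- 0.3
  raw_of <- function(od) deconvolve(od_to_intensity(od), k)$raw
  lhs <- raw_of(a * od1 + b * od2)
  rhs <- a * raw_of(od1) + b * raw_of(od2)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("kernel files and reports round-trip", {
  k <- kernel_preset("alcianblue_nfr")
  f <- tempfile(fileext = ".yml")
  write_kernel(k, f)
  k2 <- read_kernel(f)
  expect_equal(k2$matrix, k$matrix, tolerance = 1e-12)
  expect_identical(k2$stain_names, k$stain_names)
  unlink(f)
  d <- file.path(tempdir(), "kreport")
  stats <- kernel_report(k, pure_dye_images(test_kernel())[[1]], d)
  expect_true(file.exists(file.path(d, "kernel_statistics.csv")))
  expect_true(all(file.exists(file.path(d, paste0(
    "concentration_", c(k$stain_names, "residual"), ".png")))))
  expect_named(stats, c("stain", "min_raw", "max_raw", "mean_raw", "frac_negative"))
  unlink(d, recursive = TRUE)
})

test_that("kernel estimation recovers true angles and beats rotated kernels", {
  truth <- test_kernel()
  imgs <- pure_dye_images(truth)
  init <- build_kernel(list(polar_to_vector(87, 55, "A"),
                            polar_to_vector(43, 77, "B")))
  est <- estimate_kernel(imgs, init)
  ang <- attr(est, "diagnostics")$angles
  expect_lt(max(abs(ang - test_kernel_angles)), 1)
  # a deliberately rotated kernel produces more negative concentrations
  collage <- make_collage(imgs, seed = 1)
  rot <- build_kernel(list(polar_to_vector(83, 44, "A"),
                           polar_to_vector(47, 88, "B")))
  neg_of <- function(k) sum(deconvolve(collage, k)$raw < -1e-9)
  expect_lt(neg_of(est), neg_of(rot))
  # clipped concentration mass from the true kernel is tiny
  cm <- deconvolve(collage, truth)
  clipped <- sum(abs(cm$raw[cm$raw < 0])) / sum(abs(cm$raw))
  expect_lt(clipped, 0.001)
})

test_that("a blank collage leaves the initial kernel unchanged", {
  blanks <- replicate(3, array(1, c(64, 64, 3)), simplify = FALSE)
  init <- kernel_preset("oilredo_hematoxylin")
  est <- estimate_kernel(blanks, init)
  expect_equal(attr(est, "diagnostics")$angles,
               do.call(rbind, lapply(init$stains,
                                     function(s) c(s$azimuth, s$inclination))),
               ignore_attr = TRUE)
})

test_that("collage assembly is deterministic and tiles nine inputs", {
  imgs <- pure_dye_images()
  c1 <- make_collage(imgs, tile_width = 32, seed = 4)
  c2 <- make_collage(imgs, tile_width = 32, seed = 4)
  expect_identical(c1, c2)
  expect_identical(dim(c1), c(96L, 96L, 3L))
})
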