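#' Image containers and validation helpers
#'
#' Grayscale images are numeric matrices, RGB images are
#' `height x width x 3` arrays, values nominally in `[0, 1]`.
#' These helpers validate and interrogate that representation.
#'
#' @param image A matrix (grayscale) or 3-d array (RGB).
#' @return `n_channels()` returns 1 or 3; `check_image()` returns the
#'   image invisibly after validation.
#' @keywords internal
n_channels <- function(image) {
  d <- dim(image)
  if (is.matrix(image)) return(1L)
  if (length(d) == 3L && d[3] == 3L) return(3L)
  stop("image must be a matrix (gray) or a height x width x 3 array (RGB)")
}

#' @rdname n_channels
#' @keywords internal
check_image <- function(image) {
  nc <- n_channels(image)
  d <- dim(image)
  if (d[1] < 1L || d[2] < 1L) stop("image must have height >= 1 and width >= 1")
  if (!is.numeric(image)) stop("image must be numeric")
  invisible(image)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

same_geometry <- function(a, b) {
  identical(dim(a)[1:2], dim(b)[1:2]) && n_channels(a) == n_channels(b)
}

#' Flat-field illumination correction from a calibration pair
#'
#' Corrects uneven illumination and fixed sensor offsets using an empty-slide
#' brightfield reference and a blocked-light darkfield reference:
#' `corrected = (original - darkfield) / (brightfield - darkfield)`,
#' applied per pixel and per channel. The denominator is floored at `1e-6`
#' and the result is clipped to `[0, 1]`.
#'
#' @param image Image to correct (gray matrix or RGB array, values in `[0,1]`).
#' @param brightfield,darkfield Calibration images matching `image` in
#'   dimensions and channel count. `brightfield` must exceed `darkfield`
#'   somewhere; a pair with `brightfield <= darkfield` everywhere is an
#'   invalid calibration and is rejected.
#' @return Corrected image of the same shape, values in `[0, 1]`.
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' identical(correct_illumination(img, matrix(1, 8, 8), matrix(0, 8, 8)), img)
#' @export
correct_illumination <- function(image, brightfield, darkfield) {
  check_image(image); check_image(brightfield); check_image(darkfield)
  if (!same_geometry(image, brightfield) || !same_geometry(image, darkfield))
    stop("image, brightfield and darkfield must share dimensions and channels")
  denom <- brightfield - darkfield
  if (all(denom <= 0))
    stop("invalid calibration: brightfield does not exceed darkfield anywhere")
  denom <- pmax(denom, .EPS_DENOM)
  out <- clip01((image - darkfield) / denom)
  dim(out) <- dim(image)
  out
}

#' Convert an RGB image to luminance
#'
#' Rec. 601 luma weighting: `0.299 R + 0.587 G + 0.114 B`. A grayscale
#' input is returned unchanged with a message (so pipelines can accept
#' either form).
#'
#' @param image RGB array or gray matrix, values in `[0, 1]`.
#' @return Single-channel matrix in `[0, 1]`.
#' @export
to_luminance <- function(image) {
  check_image(image)
  if (n_channels(image) == 1L) {
    message("to_luminance: input is already single-channel; returned unchanged")
    return(image)
  }
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# 1-D area-average resampling operator: rows are output cells, columns input
# cells; entry = overlap length between output cell i (width n_in/n_out in
# input coordinates) and input cell j, normalized so rows sum to 1.
area_resample_operator <- function(n_in, n_out) {
  scale <- n_in / n_out
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1L
    j1 <- min(ceiling(hi), n_in)
    js <- j0:j1
    w <- pmin(hi, js) - pmax(lo, js - 1)
    w <- pmax(w, 0)
    A[i, js] <- w / sum(w)
  }
  A
}

resample_channel <- function(ch, new_h, new_w) {
  Ah <- area_resample_operator(nrow(ch), new_h)
  Aw <- area_resample_operator(ncol(ch), new_w)
  Ah %*% ch %*% t(Aw)
}

#' Resize an image to a target width, preserving aspect ratio
#'
#' Area-average (anti-aliased) resampling; the new height is
#' `round(target_width / width * height)`. Upscaling is allowed but flagged
#' with a warning since the intended use is downscaling to a working
#' resolution (e.g. 512 px for adaptive cell masks, one-third width for
#' pellet masks).
#'
#' @param image Gray matrix or RGB array in `[0, 1]`.
#' @param target_width Target width in pixels (`>= 1`).
#' @return Resized image, values clipped to `[0, 1]`.
#' @export
resize_to_width <- function(image, target_width) {
  check_image(image)
  target_width <- as.integer(target_width)
  if (target_width < 1L) stop("target_width must be >= 1")
  w <- dim(image)[2]
  if (target_width == w) return(image)
  if (target_width > w)
    warning("resize_to_width: upscaling beyond the native width")
  h <- dim(image)[1]
  new_h <- max(1L, as.integer(round(target_width / w * h)))
  if (n_channels(image) == 1L) {
    out <- clip01(resample_channel(image, new_h, target_width))
  } else {
    out <- array(0, c(new_h, target_width, 3L))
    for (c in 1:3) out[, , c] <- clip01(resample_channel(image[, , c], new_h, target_width))
  }
  out
}

#' Upscale a binary mask with nearest-neighbor semantics
#'
#' Used to bring masks computed at a working resolution back to the source
#' image's dimensions while staying strictly binary.
#'
#' @param mask 0/1 (or logical) matrix.
#' @param target_height,target_width Output dimensions in pixels.
#' @return 0/1 matrix of the requested size.
#' @export
upscale_mask <- function(mask, target_height, target_width) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  v <- as.vector(mask)
  if (!all(v %in% c(0, 1))) stop("mask must be strictly binary (0/1 or logical)")
  mask <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ri <- pmin(nrow(mask), floor((seq_len(target_height) - 0.5) * nrow(mask) / target_height) + 1L)
  ci <- pmin(ncol(mask), floor((seq_len(target_width) - 0.5) * ncol(mask) / target_width) + 1L)
  mask[ri, ci, drop = FALSE]
}

#' Read a microscopy image as a `[0, 1]` array
#'
#' TIFF and PNG, 8- or 16-bit, grayscale or RGB. Integer sample values are
#' rescaled to `[0, 1]` by the reader (division by the dtype maximum); an
#' alpha channel, if present, is dropped.
#'
#' @param path File path; format chosen by extension (`.tif`, `.tiff`, `.png`).
#' @return Gray matrix or `h x w x 3` array in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext)
  )
  d <- dim(img)
  if (length(d) == 3L && d[3] >= 4L) img <- img[, , 1:3, drop = FALSE]
  if (length(d) == 3L && dim(img)[3] == 1L) img <- img[, , 1]
  clip01(img)
}

#' Write an image to TIFF or PNG
#'
#' Values are clipped to `[0, 1]`; TIFF is written at 16 bits per sample,
#' PNG at 8.
#'
#' @param image Gray matrix or RGB array in `[0, 1]`.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_image(image)
  img <- clip01(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    png = png::writePNG(img, path),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}
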