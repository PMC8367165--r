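#' Construct a wound image
#'
#' Wraps an 8-bit RGB raster together with optional acquisition metadata.
#' Pixels are stored as a `height x width x 3` numeric array on the 0--255
#' scale; the coordinate convention throughout the package is 0-based pixel
#' coordinates with the origin at the top-left corner, `x` growing rightward
#' (columns) and `y` growing downward (rows).
#'
#' @param pixels numeric array `height x width x 3` with values in `[0, 255]`.
#' @param patient_id,wound_location optional opaque identifier strings.
#' @param timestamp optional ISO-8601 datetime string.
#' @return An object of class `wound_image` with fields `pixels`, `width`,
#'   `height` and the metadata.
#' @export
wound_image <- function(pixels, patient_id = NA_character_,
                        wound_location = NA_character_,
                        timestamp = NA_character_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be a height x width x 3 array", call. = FALSE)
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    stop("image must have width >= 1 and height >= 1", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  structure(
    list(pixels = pixels, width = d[2], height = d[1],
         patient_id = patient_id, wound_location = wound_location,
         timestamp = timestamp),
    class = "wound_image"
  )
}

#' @export
print.wound_image <- function(x, ...) {
  cat(sprintf("<wound_image> %d x %d px", x$width, x$height))
  if (!is.na(x$patient_id)) cat(", patient", x$patient_id)
  if (!is.na(x$timestamp)) cat(", taken", x$timestamp)
  cat("\n")
  invisible(x)
}

#' Read a wound image from a PNG or JPEG file
#'
#' @param path file path to an 8-bit RGB PNG or JPEG.
#' @param ... metadata passed on to [wound_image()].
#' @return A `wound_image`.
#' @export
read_wound_image <- function(path, ...) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {                      # grayscale file
    a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  } else if (dim(a)[3] >= 3L) {
    a <- a[, , 1:3, drop = FALSE]                  # drop alpha if present
  } else {
    stop("unsupported channel layout in ", path, call. = FALSE)
  }
  # EBImage stores x (width) as the first margin; transpose to row = y
  px <- aperm(a, c(2, 1, 3)) * 255
  px[px < 0] <- 0; px[px > 255] <- 255
  wound_image(px, ...)
}

#' Write a wound image (or grayscale grid) to a PNG file
#'
#' @param image a `wound_image` or a numeric matrix of intensities in
#'   `[0, 255]` (written as a grayscale PNG, useful for debugging).
#' @param path output path; the format is taken from the file extension.
#' @return `path`, invisibly.
#' @export
write_wound_image <- function(image, path) {
  if (inherits(image, "wound_image")) {
    a <- aperm(image$pixels, c(2, 1, 3)) / 255
    img <- EBImage::Image(a, colormode = "Color")
  } else {
    img <- EBImage::Image(t(image) / 255, colormode = "Grayscale")
  }
  EBImage::writeImage(img, path)
  invisible(path)
}

#' Convert an RGB wound image to grayscale
#'
#' Uses the ITU-R BT.601 luma weights `0.299 R + 0.587 G + 0.114 B`, the
#' default of the common imaging libraries, so scores are comparable across
#' toolchains.
#'
#' @param image a `wound_image`.
#' @return A numeric matrix (`height x width`) of intensities in `[0, 255]`.
#' @export
to_grayscale <- function(image) {
  stopifnot(inherits(image, "wound_image"))
  px <- image$pixels
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

# Replicate-pad a matrix by `r` pixels on every side (edge clamp).
pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

#' Discrete Laplacian of a grayscale image
#'
#' Convolves with the 4-connected 3x3 stencil
#' `[[0,1,0],[1,-4,1],[0,1,0]]` using replicate (edge-clamp) border
#' handling, the most common discrete form of the operator. The response is
#' a signed real grid of the same dimensions: zero on constant and linear
#' regions, large where intensity changes rapidly (edges, fine detail).
#'
#' @param gray numeric matrix of intensities (at least 3x3).
#' @return Numeric matrix of the same dimensions.
#' @export
laplacian <- function(gray) {
  if (!is.matrix(gray) || !is.numeric(gray))
    stop("`gray` must be a numeric matrix", call. = FALSE)
  h <- nrow(gray); w <- ncol(gray)
  if (h < 3L || w < 3L)
    stop("image must be at least 3x3 for the Laplacian stencil", call. = FALSE)
  p <- pad_replicate(gray, 1L)
  i <- 2:(h + 1); j <- 2:(w + 1)
  p[i - 1, j] + p[i + 1, j] + p[i, j - 1] + p[i, j + 1] - 4 * p[i, j]
}

#' Variance-of-Laplacian sharpness score
#'
#' The focus measure driving the quality gate: the population variance of
#' the Laplacian response over the selected pixels. Sharp images have
#' rapid local intensity changes, hence a widely spread Laplacian; blur
#' attenuates high spatial frequencies and shrinks the variance toward
#' zero. The score is invariant to constant intensity offsets and scales
#' with the square of intensity gain; it is resolution-dependent, so images
#' are scored at native resolution (no resizing).
#'
#' @param gray numeric matrix of intensities.
#' @param roi optional logical matrix of the same dimensions selecting the
#'   region of interest (e.g. the color checker); `NULL` scores all pixels.
#'   At least 2 pixels must be selected.
#' @return A list of class `sharpness_score` with `value` (variance,
#'   intensity squared, `>= 0`) and `n_pixels`.
#' @export
variance_of_laplacian <- function(gray, roi = NULL) {
  lap <- laplacian(gray)
  if (!is.null(roi)) {
    if (!is.logical(roi) || !identical(dim(roi), dim(gray)))
      stop("`roi` must be a logical matrix aligned with `gray`", call. = FALSE)
    v <- lap[roi]
  } else {
    v <- as.vector(lap)
  }
  n <- length(v)
  if (n < 2L)
    stop("region of interest selects fewer than 2 pixels", call. = FALSE)
  structure(list(value = sum((v - mean(v))^2) / n, n_pixels = n),
            class = "sharpness_score")
}

#' @export
print.sharpness_score <- function(x, ...) {
  cat(sprintf("<sharpness_score> variance of Laplacian = %.2f over %d px\n",
              x$value, x$n_pixels))
  invisible(x)
}
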