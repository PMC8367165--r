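#' Detection configuration
#'
#' Tuning knobs for [detect_checker()]. The sticker is square (30 x 30 mm),
#' so candidate quadrilaterals are screened by area fraction, aspect ratio
#' and, optionally, by the internal 6x6 patch structure.
#'
#' @param min_area_fraction minimum quadrilateral area as a fraction of the
#'   image area, in `(0, 1)`. At holder distance the sticker comfortably
#'   exceeds the default 0.02.
#' @param max_aspect_ratio maximum long/short side ratio (`>= 1`); default
#'   1.3 tolerates moderate perspective on a square marker.
#' @param grid_check if `TRUE`, verify the 6x6 patch structure by sampling
#'   patch-center colors inside the rectified quadrilateral and requiring
#'   them to be diverse. Structure, not colorimetry, is tested.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(min_area_fraction = 0.02,
                             max_aspect_ratio = 1.3,
                             grid_check = TRUE) {
  if (!is.numeric(min_area_fraction) || length(min_area_fraction) != 1L ||
      min_area_fraction <= 0 || min_area_fraction >= 1)
    stop("`min_area_fraction` must be a number in (0, 1)", call. = FALSE)
  if (!is.numeric(max_aspect_ratio) || length(max_aspect_ratio) != 1L ||
      max_aspect_ratio < 1)
    stop("`max_aspect_ratio` must be >= 1", call. = FALSE)
  if (!is.logical(grid_check) || length(grid_check) != 1L || is.na(grid_check))
    stop("`grid_check` must be TRUE or FALSE", call. = FALSE)
  structure(list(min_area_fraction = min_area_fraction,
                 max_aspect_ratio = max_aspect_ratio,
                 grid_check = grid_check),
            class = "detection_config")
}

## ---- geometry helpers (0-based pixel coordinates, x right, y down) ----

# Order the rows of a 4x2 corner matrix clockwise (in image coordinates,
# y down) starting from the corner nearest the top-left.
order_corners <- function(p) {
  cx <- mean(p[, 1]); cy <- mean(p[, 2])
  # with y downward, increasing atan2 angle walks clockwise on screen
  ang <- atan2(p[, 2] - cy, p[, 1] - cx)
  p <- p[order(ang), , drop = FALSE]
  start <- which.min(p[, 1] + p[, 2])
  p[((seq_len(4) + start - 2) %% 4) + 1, , drop = FALSE]
}

# Minimum-area enclosing rectangle of a point set, by rotating calipers
# over the convex hull edges. Returns corners (4x2, clockwise from
# top-left), area, and side lengths.
min_area_rect <- function(pts) {
  hull <- pts[chull(pts[, 1], pts[, 2]), , drop = FALSE]
  nh <- nrow(hull)
  if (nh < 3L) return(NULL)
  best <- NULL
  for (k in seq_len(nh)) {
    e <- hull[(k %% nh) + 1, ] - hull[k, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len; v <- c(-u[2], u[1])
    s <- hull %*% cbind(u, v)
    w1 <- max(s[, 1]) - min(s[, 1]); w2 <- max(s[, 2]) - min(s[, 2])
    area <- w1 * w2
    if (is.null(best) || area < best$area) {
      cs <- rbind(c(min(s[, 1]), min(s[, 2])), c(max(s[, 1]), min(s[, 2])),
                  c(max(s[, 1]), max(s[, 2])), c(min(s[, 1]), max(s[, 2])))
      best <- list(corners = cs %*% rbind(u, v), area = area,
                   sides = sort(c(w1, w2)))
    }
  }
  best$corners <- order_corners(best$corners)
  best
}

# Logical mask (h x w) of pixel centers inside a convex quadrilateral given
# as a 4x2 clockwise corner matrix in 0-based coordinates.
quad_mask <- function(corners, width, height) {
  xs <- matrix(rep(0:(width - 1), each = height), nrow = height)
  ys <- matrix(rep(0:(height - 1), times = width), nrow = height)
  inside <- matrix(TRUE, height, width)
  for (k in 1:4) {
    a <- corners[k, ]; b <- corners[(k %% 4) + 1, ]
    # clockwise with y down => interior has non-negative cross product
    cr <- (b[1] - a[1]) * (ys - a[2]) - (b[2] - a[2]) * (xs - a[1])
    inside <- inside & (cr >= 0)
  }
  inside
}

# Shoelace area of a polygon (4x2 matrix).
polygon_area <- function(p) {
  n <- nrow(p); j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# Shrink a convex quadrilateral toward its centroid by `margin` pixels.
shrink_quad <- function(corners, margin) {
  c0 <- colMeans(corners)
  t(apply(corners, 1, function(p) {
    d <- p - c0; len <- sqrt(sum(d^2))
    if (len <= margin) c0 else p - d / len * margin
  }))
}

# Bilinear map from the unit square to a quadrilateral (clockwise from
# top-left); u rightward along the top edge, v downward.
quad_point <- function(corners, u, v) {
  p <- (1 - u) * (1 - v) * corners[1, ] + u * (1 - v) * corners[2, ] +
    u * v * corners[3, ] + (1 - u) * v * corners[4, ]
  p
}

# Mean RGB color sampled in a small neighborhood of a point (0-based coords).
sample_color <- function(px, x, y) {
  h <- dim(px)[1]; w <- dim(px)[2]
  rows <- pmin(pmax(round(y) + 1 + (-1:1), 1), h)
  cols <- pmin(pmax(round(x) + 1 + (-1:1), 1), w)
  vapply(1:3, function(ch) mean(px[rows, cols, ch]), numeric(1))
}

# Diversity of the 36 patch-center colors inside the rectified quad:
# mean pairwise Euclidean RGB distance. A flat or smoothly shaded region
# (e.g. skin) scores low; a patch grid scores high.
grid_dispersion <- function(px, corners) {
  centers <- expand.grid(i = 0:5, j = 0:5)
  cols <- t(mapply(function(i, j) {
    p <- quad_point(corners, (i + 0.5) / 6, (j + 0.5) / 6)
    sample_color(px, p[1], p[2])
  }, centers$i, centers$j))
  mean(stats::dist(cols))
}

## ---- detection -------------------------------------------------------

# Foreground mask: pixels that stand out from the dominant background,
# either in luma or in chroma. The background estimate is the image-wide
# median, robust as long as the background covers most of the frame.
foreground_mask <- function(px, gray) {
  chroma <- pmax(px[, , 1], px[, , 2], px[, , 3]) -
    pmin(px[, , 1], px[, , 2], px[, , 3])
  bg <- median(gray)
  (abs(gray - bg) > 20) | (chroma > 30)
}

#' Locate the color reference sticker in an image
#'
#' Detects the square 36-patch color reference sticker by rectangular
#' morphology: a foreground map is segmented into connected components,
#' each component is fitted with its minimum-area enclosing rectangle, and
#' candidates are kept when the component fills the rectangle (the
#' rectangularity test that separates the square sticker from rounded
#' anatomy), the aspect ratio is near square, the rectangle exceeds the
#' configured size threshold and, optionally, the interior shows the 6x6
#' patch structure. Among passing candidates the largest area wins; ties
#' are broken by the top-left corner position (y, then x) so detection is
#' deterministic.
#'
#' @param image a `wound_image`.
#' @param config a [detection_config()].
#' @return A list of class `checker_detection` with fields `found`;
#'   `corners` (4x2 matrix, clockwise from top-left, 0-based pixel
#'   coordinates) or `NULL`; `area_fraction` or `NULL`; `roi` (logical mask
#'   of the filled quadrilateral) or `NULL`; and `area_only_rejection`,
#'   `TRUE` when at least one shape-passing candidate failed only the size
#'   threshold (used to report a "checker too small" reason upstream).
#' @export
detect_checker <- function(image, config = detection_config()) {
  stopifnot(inherits(image, "wound_image"), inherits(config, "detection_config"))
  px <- image$pixels
  gray <- to_grayscale(image)
  h <- image$height; w <- image$width
  npix <- as.numeric(h) * w

  fg <- foreground_mask(px, gray)
  # close small gaps (patch borders, noise holes) without moving the outline
  fg <- EBImage::closing(EBImage::Image(t(fg)), EBImage::makeBrush(5, "disc"))
  labels <- t(EBImage::imageData(EBImage::bwlabel(fg)))
  nlab <- max(labels)
  if (nlab == 0)
    return(empty_detection(FALSE))

  counts <- tabulate(labels[labels > 0], nbins = nlab)
  candidates <- list()
  area_only_rejection <- FALSE
  for (lab in which(counts >= 25)) {
    idx <- which(labels == lab)
    ys <- (idx - 1) %% h         # 0-based row
    xs <- (idx - 1) %/% h        # 0-based col
    # +-0.5: treat pixels as unit squares so the rectangle hugs pixel edges
    pts <- cbind(c(xs - 0.5, xs + 0.5, xs + 0.5, xs - 0.5),
                 c(ys - 0.5, ys - 0.5, ys + 0.5, ys + 0.5))
    rect <- min_area_rect(pts)
    if (is.null(rect) || rect$sides[1] < 4) next
    rectangularity <- counts[lab] / rect$area
    aspect <- rect$sides[2] / rect$sides[1]
    if (rectangularity < 0.85 || aspect > config$max_aspect_ratio) next
    if (rect$area / npix < config$min_area_fraction) {
      area_only_rejection <- TRUE
      next
    }
    if (config$grid_check && grid_dispersion(px, rect$corners) < 30) next
    candidates[[length(candidates) + 1L]] <- rect
  }

  if (length(candidates) == 0L)
    return(empty_detection(area_only_rejection))

  areas <- vapply(candidates, function(c.) c.$area, numeric(1))
  tl_y <- vapply(candidates, function(c.) c.$corners[1, 2], numeric(1))
  tl_x <- vapply(candidates, function(c.) c.$corners[1, 1], numeric(1))
  best <- candidates[[order(-areas, tl_y, tl_x)[1]]]

  structure(list(
    found = TRUE,
    corners = best$corners,
    area_fraction = polygon_area(best$corners) / npix,
    roi = quad_mask(best$corners, w, h),
    area_only_rejection = area_only_rejection
  ), class = "checker_detection")
}

empty_detection <- function(area_only_rejection) {
  structure(list(found = FALSE, corners = NULL, area_fraction = NULL,
                 roi = NULL, area_only_rejection = area_only_rejection),
            class = "checker_detection")
}

#' @export
print.checker_detection <- function(x, ...) {
  if (x$found) {
    cat(sprintf("<checker_detection> found, area fraction %.4f\n",
                x$area_fraction))
  } else {
    cat("<checker_detection> not found\n")
  }
  invisible(x)
}

#' Sharpness of the detected color checker region (CCS)
#'
#' The color checker sharpness: the variance-of-Laplacian score restricted
#' to the detected sticker quadrilateral. The quadrilateral is shrunk
#' inward by `margin` pixels before scoring so that the sticker's outer
#' boundary -- whose Laplacian energy reflects contrast against the
#' background, not focus -- does not dominate the score or make it
#' sensitive to one-pixel localization differences.
#'
#' @param image a `wound_image`.
#' @param detection a `checker_detection` with `found = TRUE`, or any list
#'   carrying 4x2 `corners` (e.g. scene ground truth).
#' @param margin inward shrink of the scored quadrilateral, in pixels.
#' @return A `sharpness_score`.
#' @export
checker_roi_sharpness <- function(image, detection, margin = 2) {
  stopifnot(inherits(image, "wound_image"))
  if (!is.null(detection$found) && !isTRUE(detection$found))
    stop("checker was not detected in this image; no region to score",
         call. = FALSE)
  if (is.null(detection$corners))
    stop("detection carries no corner coordinates", call. = FALSE)
  inner <- shrink_quad(detection$corners, margin)
  roi <- quad_mask(inner, image$width, image$height)
  variance_of_laplacian(to_grayscale(image), roi)
}

#' Write a debug overlay with the detected quadrilateral
#'
#' Draws the detected corners and edges onto the image and writes a PNG.
#'
#' @param image a `wound_image`.
#' @param detection a `checker_detection` with `found = TRUE`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_detection_overlay <- function(image, detection, path) {
  stopifnot(isTRUE(detection$found))
  px <- image$pixels
  co <- detection$corners
  for (k in 1:4) {
    a <- co[k, ]; b <- co[(k %% 4) + 1, ]
    n <- max(2L, ceiling(sqrt(sum((b - a)^2))))
    t. <- seq(0, 1, length.out = n)
    xs <- pmin(pmax(round(a[1] + t. * (b[1] - a[1])), 0), image$width - 1)
    ys <- pmin(pmax(round(a[2] + t. * (b[2] - a[2])), 0), image$height - 1)
    px[cbind(ys + 1, xs + 1, 1)] <- 0
    px[cbind(ys + 1, xs + 1, 2)] <- 255
    px[cbind(ys + 1, xs + 1, 3)] <- 0
  }
  write_wound_image(wound_image(px), path)
}
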