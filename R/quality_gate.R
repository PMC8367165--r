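#' Quality gate configuration
#'
#' @param detection a [detection_config()].
#' @param sharpness_threshold minimum color checker sharpness (variance of
#'   Laplacian over the sticker region) required to accept an image; the
#'   default was calibrated on the bundled synthetic scene suite as the
#'   midpoint between the median score of unblurred scenes and scenes
#'   blurred at sigma = 4 (see [calibrate_sharpness_threshold()]).
#' @return A list of class `quality_config`.
#' @export
quality_config <- function(detection = detection_config(),
                           sharpness_threshold = default_sharpness_threshold) {
  if (!inherits(detection, "detection_config"))
    stop("`detection` must be a detection_config", call. = FALSE)
  if (!is.numeric(sharpness_threshold) || length(sharpness_threshold) != 1L ||
      is.na(sharpness_threshold) || sharpness_threshold < 0)
    stop("`sharpness_threshold` must be a nonnegative number", call. = FALSE)
  structure(list(detection = detection,
                 sharpness_threshold = sharpness_threshold),
            class = "quality_config")
}

# Frozen output of calibrate_sharpness_threshold(n_scenes = 20, seed = 20) at
# the default scene geometry; regenerate with that call if the renderer or
# palette changes.
default_sharpness_threshold <- 483

#' Calibrate the default sharpness threshold from synthetic scenes
#'
#' Renders `n_scenes` randomized scenes at blur sigma 0 (sharp, should pass)
#' and sigma 4 (clearly blurred, should fail), scores the checker region of
#' each from ground truth, and returns the midpoint between the two median
#' scores -- a threshold that separates the two populations.
#'
#' @param n_scenes scenes per blur level.
#' @param seed RNG seed for scene placement.
#' @return A list with `threshold`, `median_sharp`, `median_blurred`.
#' @export
calibrate_sharpness_threshold <- function(n_scenes = 20, seed = 20) {
  score_at <- function(sigma) {
    vapply(seq_len(n_scenes), function(k) {
      sc <- random_scene_spec(seed = seed + k, blur_sigma = sigma)
      sg <- render_scene(sc)
      checker_roi_sharpness(sg$image, sg$ground_truth)$value
    }, numeric(1))
  }
  m0 <- median(score_at(0)); m4 <- median(score_at(4))
  list(threshold = (m0 + m4) / 2, median_sharp = m0, median_blurred = m4)
}

#' Accept/retake decision for a wound image
#'
#' Combines sticker detection and region sharpness into the decision the
#' acquisition-time feedback is based on: the image passes when the color
#' reference sticker is found and the sharpness of its region strictly
#' exceeds the configured threshold. Failures carry machine-readable
#' reasons: `checker_not_found`, `checker_too_small` (a square candidate
#' was present but below the size threshold), `blurry`.
#'
#' @param image a `wound_image`.
#' @param config a [quality_config()].
#' @return A list of class `quality_decision` with `pass`, `reasons`
#'   (character vector, empty on pass), `sharpness` (a `sharpness_score`,
#'   or `NULL` when the checker was not found) and `detection`.
#' @export
assess_quality <- function(image, config = quality_config()) {
  stopifnot(inherits(image, "wound_image"), inherits(config, "quality_config"))
  det <- detect_checker(image, config$detection)
  if (!det$found) {
    reason <- if (isTRUE(det$area_only_rejection)) "checker_too_small"
              else "checker_not_found"
    return(structure(list(pass = FALSE, reasons = reason, sharpness = NULL,
                          detection = det), class = "quality_decision"))
  }
  sharp <- checker_roi_sharpness(image, det)
  pass <- sharp$value > config$sharpness_threshold
  structure(list(pass = pass,
                 reasons = if (pass) character(0) else "blurry",
                 sharpness = sharp, detection = det),
            class = "quality_decision")
}

#' @export
print.quality_decision <- function(x, ...) {
  if (x$pass) {
    cat(sprintf("<quality_decision> PASS (sharpness %.1f)\n",
                x$sharpness$value))
  } else {
    cat(sprintf("<quality_decision> RETAKE [%s]%s\n",
                paste(x$reasons, collapse = ", "),
                if (!is.null(x$sharpness))
                  sprintf(" (sharpness %.1f)", x$sharpness$value) else ""))
  }
  invisible(x)
}
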