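# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' The synthetic 36-patch reference palette
#'
#' A fixed 36x3 matrix of 8-bit RGB rows: the 24 classic photographic
#' calibration colors plus 6 skin shades and 6 wound shades (fibrin,
#' granulation, necrosis, epithelium, slough, deep red). The commercial
#' sticker's exact palette is unpublished; this constant is the package's
#' documented stand-in, chosen for visual diversity, and detection tests
#' verify patch structure, never colorimetry.
#'
#' @return A 36x3 numeric matrix, rows in row-major grid order (6 columns
#'   per row of the rendered sticker).
#' @export
checker_palette <- function() {
  m <- rbind(
    c(243, 243, 242), c(175, 54, 60), c(70, 148, 73), c(56, 61, 150),
    c(187, 86, 149), c(231, 199, 31),
    c(214, 126, 44), c(8, 133, 161), c(94, 60, 108), c(157, 188, 64),
    c(193, 90, 99), c(103, 189, 170),
    c(115, 82, 68), c(194, 150, 130), c(98, 122, 157), c(87, 108, 67),
    c(133, 128, 177), c(224, 163, 46),
    c(80, 91, 166), c(200, 200, 200), c(160, 160, 160), c(122, 122, 121),
    c(85, 85, 85), c(52, 52, 52),
    c(231, 194, 171), c(219, 170, 148), c(203, 146, 121), c(177, 120, 95),
    c(148, 92, 71), c(117, 68, 52),
    c(222, 205, 160), c(178, 72, 66), c(77, 45, 38), c(233, 180, 172),
    c(196, 178, 128), c(139, 28, 34)
  )
  colnames(m) <- c("r", "g", "b")
  m
}

#' Specify a synthetic wound scene
#'
#' Describes one renderable scene: a flat background (a stand-in for the
#' holder's bottom plate), an optional elliptical skin blob with a darker
#' wound core, and an optional square 6x6-patch color reference sticker at
#' a given pose, degraded by Gaussian blur (optical defocus), a constant
#' illumination offset and additive Gaussian sensor noise.
#'
#' @param image_size `c(width, height)` in pixels.
#' @param checker_center `c(x, y)` center of the sticker, 0-based pixel
#'   coordinates.
#' @param checker_side side length of the square sticker, pixels.
#' @param checker_rotation in-plane rotation, degrees.
#' @param blur_sigma Gaussian blur standard deviation, pixels (`>= 0`).
#' @param illumination_offset constant added to every channel.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param include_checker,include_wound_blob toggles for the two objects.
#' @param wound_center,wound_axes geometry of the skin ellipse.
#' @param seed RNG seed controlling the noise realization.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(480, 360),
                       checker_center = c(340, 180),
                       checker_side = 110,
                       checker_rotation = 8,
                       blur_sigma = 0,
                       illumination_offset = 0,
                       noise_sd = 0,
                       include_checker = TRUE,
                       include_wound_blob = TRUE,
                       wound_center = c(130, 190),
                       wound_axes = c(85, 60),
                       seed = 1L) {
  if (blur_sigma < 0 || noise_sd < 0)
    stop("`blur_sigma` and `noise_sd` must be nonnegative", call. = FALSE)
  spec <- structure(
    list(image_size = image_size, checker_center = checker_center,
         checker_side = checker_side, checker_rotation = checker_rotation,
         blur_sigma = blur_sigma, illumination_offset = illumination_offset,
         noise_sd = noise_sd, include_checker = include_checker,
         include_wound_blob = include_wound_blob, wound_center = wound_center,
         wound_axes = wound_axes, seed = as.integer(seed)),
    class = "scene_spec")
  if (include_checker) {
    th <- checker_rotation * pi / 180
    half <- checker_side / 2 * (abs(cos(th)) + abs(sin(th)))
    if (checker_center[1] - half < 0 || checker_center[2] - half < 0 ||
        checker_center[1] + half > image_size[1] - 1 ||
        checker_center[2] + half > image_size[2] - 1)
      stop("checker does not fit inside the frame", call. = FALSE)
  }
  spec
}

#' Randomized scene specification
#'
#' Draws sticker pose and size from ranges that emulate the hand-held
#' variability left after the smartphone holder fixes distance and lighting:
#' the sticker lands in the right half of the frame (the wound occupies the
#' left), at 90--130 px side (area fraction 0.047--0.098 of a 480x360
#' frame) and up to +-20 degrees rotation.
#'
#' @param seed RNG seed; determines pose and noise.
#' @param ... overrides passed on to [scene_spec()] (e.g. `blur_sigma`,
#'   `noise_sd`, `include_checker`).
#' @return A `scene_spec`.
#' @export
random_scene_spec <- function(seed, ...) {
  pose <- with_local_seed(seed, list(
    center = c(runif(1, 305, 390), runif(1, 115, 245)),
    side = runif(1, 90, 130),
    rot = runif(1, -20, 20),
    wound = c(runif(1, 95, 130), runif(1, 130, 230))
  ))
  args <- list(checker_center = pose$center, checker_side = pose$side,
               checker_rotation = pose$rot, wound_center = pose$wound,
               seed = seed)
  do.call(scene_spec, modifyList(args, list(...)))
}

# Separable Gaussian blur with replicate borders, applied per channel.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  conv1 <- function(x, along_rows) {
    n <- if (along_rows) nrow(x) else ncol(x)
    out <- 0
    for (o in -r:r) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      out <- out + k[o + r + 1] * (if (along_rows) x[idx, , drop = FALSE]
                                   else x[, idx, drop = FALSE])
    }
    out
  }
  conv1(conv1(m, TRUE), FALSE)
}

#' Render a synthetic wound scene with ground truth
#'
#' Deterministically renders the scene described by a [scene_spec()]:
#' identical spec and seed give bit-identical pixels. The returned ground
#' truth carries the exact sticker corner coordinates (clockwise from
#' top-left, 0-based), the sticker's area fraction, and the region-of-
#' interest mask actually used to paint the sticker, so detection and
#' sharpness code can be scored against geometry that is true by
#' construction.
#'
#' @param spec a `scene_spec`.
#' @return A list with `image` (a `wound_image`) and `ground_truth` (fields
#'   `found`, `corners`, `area_fraction`, `roi`, `blur_sigma`; corners and
#'   mask are `NULL` when the scene has no checker).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$image_size[1]; h <- spec$image_size[2]
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), times = w), nrow = h)
  px <- array(70, dim = c(h, w, 3))   # holder plate background

  if (spec$include_wound_blob) {
    dx <- (xs - spec$wound_center[1]) / spec$wound_axes[1]
    dy <- (ys - spec$wound_center[2]) / spec$wound_axes[2]
    skin <- dx^2 + dy^2 <= 1
    # smooth radial shading so the blob is not flat
    shade <- 1 - 0.15 * pmin(dx^2 + dy^2, 1)
    for (ch in 1:3) {
      base <- c(205, 160, 140)[ch]
      m <- px[, , ch]; m[skin] <- (base * shade)[skin]; px[, , ch] <- m
    }
    core <- (dx / 0.35)^2 + (dy / 0.35)^2 <= 1
    for (ch in 1:3) {
      m <- px[, , ch]; m[core] <- c(150, 60, 50)[ch]; px[, , ch] <- m
    }
  }

  gt <- list(found = FALSE, corners = NULL, area_fraction = NULL,
             roi = NULL, blur_sigma = spec$blur_sigma)
  if (spec$include_checker) {
    s <- spec$checker_side
    th <- spec$checker_rotation * pi / 180
    u <- cos(th) * (xs - spec$checker_center[1]) +
      sin(th) * (ys - spec$checker_center[2])
    v <- -sin(th) * (xs - spec$checker_center[1]) +
      cos(th) * (ys - spec$checker_center[2])
    inside <- abs(u) <= s / 2 & abs(v) <= s / 2
    ci <- pmin(pmax(floor((u + s / 2) / s * 6), 0), 5)
    cj <- pmin(pmax(floor((v + s / 2) / s * 6), 0), 5)
    patch <- cj * 6 + ci + 1
    pal <- checker_palette()
    for (ch in 1:3) {
      m <- px[, , ch]
      m[inside] <- pal[patch[inside], ch]
      px[, , ch] <- m
    }
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, byrow = TRUE)
    half <- s / 2
    local_corners <- rbind(c(-half, -half), c(half, -half),
                           c(half, half), c(-half, half))
    corners <- t(t(local_corners %*% rot) + spec$checker_center)
    gt <- list(found = TRUE, corners = order_corners(corners),
               area_fraction = s^2 / (as.numeric(w) * h),
               roi = inside, blur_sigma = spec$blur_sigma)
  }

  for (ch in 1:3) px[, , ch] <- gaussian_blur(px[, , ch], spec$blur_sigma)
  px <- px + spec$illumination_offset
  if (spec$noise_sd > 0) {
    noise <- with_local_seed(spec$seed,
                             array(rnorm(h * w * 3, sd = spec$noise_sd),
                                   dim = c(h, w, 3)))
    px <- px + noise
  }
  px[px < 0] <- 0; px[px > 255] <- 255

  list(image = wound_image(px), ground_truth = gt)
}

#' Specify a synthetic two-arm home-imaging cohort
#'
#' Emulates the study protocol the analysis layer expects: two device
#' groups (`feedback` and `basic`), assessments scheduled every third day,
#' 16 assigned assessment days, a fixed number of images per performed
#' assessment, and per-group distributions for sticker detection, sharpness
#' (log-normal, which keeps scores positive and is parameterized directly
#' from a median and quartiles), subjective usability and assessment
#' duration (linear in assessment index plus Gaussian noise).
#'
#' Defaults reproduce the study's observed operating point: 8 feedback and
#' 7 basic patients, detection probabilities 191/199 and 158/183, usability
#' 180/199 and 155/183, sharpness medians 894 and 700 with quartiles
#' (710, 999) and (549, 867), and a skip probability giving about 25
#' images per patient.
#'
#' @param n_patients named count vector `c(feedback = , basic = )`.
#' @param assessments_per_patient assigned assessment days (protocol: 16).
#' @param images_per_assessment images saved per performed assessment.
#' @param skip_prob probability a scheduled assessment day is skipped.
#' @param detection_prob,usable_prob named per-group probabilities.
#' @param ccs_median,ccs_q25,ccs_q75 named per-group sharpness summaries
#'   that parameterize the log-normal sharpness law.
#' @param duration_intercept,duration_slope,duration_noise_sd assessment
#'   duration model, seconds (slope per assessment index).
#' @param start_date first scheduled assessment date.
#' @param seed RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = c(feedback = 8, basic = 7),
                        assessments_per_patient = 16,
                        images_per_assessment = 2,
                        skip_prob = 0.2,
                        detection_prob = c(feedback = 191 / 199,
                                           basic = 158 / 183),
                        usable_prob = c(feedback = 180 / 199,
                                        basic = 155 / 183),
                        ccs_median = c(feedback = 894, basic = 700),
                        ccs_q25 = c(feedback = 710, basic = 549),
                        ccs_q75 = c(feedback = 999, basic = 867),
                        duration_intercept = 55,
                        duration_slope = -0.8,
                        duration_noise_sd = 8,
                        start_date = "2019-06-01",
                        seed = 1L) {
  groups <- c("feedback", "basic")
  for (p in list(skip_prob, detection_prob, usable_prob)) {
    if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]",
                                 call. = FALSE)
  }
  if (!all(groups %in% names(n_patients)) || any(n_patients < 1))
    stop("`n_patients` must name feedback and basic counts >= 1",
         call. = FALSE)
  if (assessments_per_patient < 1 || images_per_assessment < 1)
    stop("counts must be >= 1", call. = FALSE)
  structure(as.list(environment()), class = "cohort_spec")
}

# Log-normal sdlog implied by a pair of quartiles.
lognormal_sdlog <- function(q25, q75) log(q75 / q25) / (2 * qnorm(0.75))

#' Generate a synthetic assessment cohort
#'
#' Draws one assessment-record table from a [cohort_spec()]: per-group
#' Bernoulli sticker detection, log-normal sharpness for detected stickers,
#' Bernoulli usability labels, and durations linear in assessment index.
#' Reproducible: identical spec (including its seed) yields an identical
#' table.
#'
#' @param spec a `cohort_spec`.
#' @return A tibble with one row per image: `patient_id`, `group`,
#'   `assessment_index`, `timestamp`, `image_path`, `checker_detected`,
#'   `usable_label`, `ccs` (`NA` when the sticker was not detected),
#'   `duration_s` (the assessment's duration, repeated across its images).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c("feedback", "basic")
  day0 <- as.Date(spec$start_date)
  with_local_seed(spec$seed, {
    rows <- list()
    for (g in groups) {
      meanlog <- log(spec$ccs_median[[g]])
      sdlog <- lognormal_sdlog(spec$ccs_q25[[g]], spec$ccs_q75[[g]])
      for (p in seq_len(spec$n_patients[[g]])) {
        pid <- sprintf("%s%02d", toupper(substr(g, 1, 1)), p)
        for (idx in seq_len(spec$assessments_per_patient)) {
          if (runif(1) < spec$skip_prob) next
          dur <- max(5, spec$duration_intercept +
                       spec$duration_slope * idx +
                       rnorm(1, sd = spec$duration_noise_sd))
          stamp <- sprintf("%sT%02d:%02d:00",
                           format(day0 + (idx - 1) * 3), 8 + idx %% 10,
                           sample(0:59, 1))
          n_img <- spec$images_per_assessment
          det <- runif(n_img) < spec$detection_prob[[g]]
          rows[[length(rows) + 1L]] <- tibble::tibble(
            patient_id = pid, group = g, assessment_index = idx,
            timestamp = stamp, image_path = NA_character_,
            checker_detected = det,
            usable_label = runif(n_img) < spec$usable_prob[[g]],
            ccs = ifelse(det, rlnorm(n_img, meanlog, sdlog), NA_real_),
            duration_s = dur)
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}
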