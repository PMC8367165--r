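test_that("scene rendering is bit-identical for identical spec and seed", {
  spec <- scene_spec(blur_sigma = 0.5, noise_sd = 5, seed = 33)
  a <- render_scene(spec); b <- render_scene(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$ground_truth$corners, b$ground_truth$corners)
  # a different seed changes pixels but not geometry
  spec2 <- scene_spec(blur_sigma = 0.5, noise_sd = 5, seed = 34)
  c. <- render_scene(spec2)
  expect_false(identical(a$image$pixels, c.$image$pixels))
  expect_identical(a$ground_truth$corners, c.$ground_truth$corners)
})

test_that("ground-truth geometry follows from the spec", {
  sg <- render_scene(scene_spec(image_size = c(1200, 900),
                                checker_center = c(600, 450),
                                checker_side = 120, checker_rotation = 0,
                                include_wound_blob = FALSE))
  expect_equal(sg$ground_truth$area_fraction, 120^2 / (1200 * 900))
  co <- sg$ground_truth$corners
  expect_equal(co[1, ], c(540, 390))   # clockwise from top-left
  expect_equal(co[3, ], c(660, 510))
  expect_equal(dim(sg$image$pixels), c(900, 1200, 3))
  # the ROI mask paints exactly the sticker pixels
  expect_equal(sum(sg$ground_truth$roi), 121^2)  # side+1 pixel centers
})

test_that("checker-free scenes carry no ground-truth corners", {
  sg <- render_scene(scene_spec(include_checker = FALSE))
  expect_false(sg$ground_truth$found)
  expect_null(sg$ground_truth$corners)
})

test_that("a sticker that does not fit the frame is a spec error", {
  expect_error(scene_spec(checker_center = c(20, 20), checker_side = 110),
               "fit inside")
})

test_that("rendered blur ordering is recovered end to end", {
  # detection + ROI sharpness must reproduce the generator's blur ranking
  sigmas <- c(0, 0.5, 1, 2)
  ccs <- vapply(sigmas, function(s) {
    sg <- render_scene(random_scene_spec(seed = 60, blur_sigma = s,
                                         noise_sd = 2))
    det <- detect_checker(sg$image)
    expect_true(det$found)
    checker_roi_sharpness(sg$image, det)$value
  }, numeric(1))
  expect_equal(cor(sigmas, ccs, method = "spearman"), -1)
})

test_that("cohort generation is reproducible and honors probabilities", {
  spec <- cohort_spec(seed = 44)
  a <- generate_cohort(spec); b <- generate_cohort(spec)
  expect_identical(a, b)

  # degenerate Bernoulli: every sticker detected
  all_det <- cohort_spec(detection_prob = c(feedback = 1, basic = 1),
                         seed = 45)
  co <- generate_cohort(all_det)
  expect_true(all(co$checker_detected))
  expect_equal(group_summary(co, "feedback")$ccdr, 1)
  expect_true(all(!is.na(co$ccs)))

  expect_error(cohort_spec(detection_prob = c(feedback = 1.2, basic = 0.5)),
               "probabilities")
})

test_that("cohort CCDR concentrates near the generating probabilities", {
  hits <- vapply(1:5, function(k) {
    co <- generate_cohort(cohort_spec(seed = 500 + k))
    c(group_summary(co, "feedback")$ccdr, group_summary(co, "basic")$ccdr)
  }, numeric(2))
  # binomial sd at ~180-200 images is ~0.026 per replicate, ~0.012 for the
  # 5-replicate mean: 0.05 is a sound band for the mean, 4 sd per replicate
  expect_lt(abs(mean(hits[1, ]) - 191 / 199), 0.05)
  expect_lt(abs(mean(hits[2, ]) - 158 / 183), 0.05)
  expect_true(all(abs(hits[1, ] - 191 / 199) < 0.104))
  expect_true(all(abs(hits[2, ] - 158 / 183) < 0.104))
})

test_that("duration trend recovers the generating slope", {
  hit <- vapply(1:10, function(k) {
    co <- generate_cohort(cohort_spec(seed = 700 + k))
    assess <- unique(co[, c("patient_id", "assessment_index", "duration_s")])
    fit <- lm(duration_s ~ assessment_index, data = assess)
    ci <- coef(fit)[2] + c(-2, 2) * summary(fit)$coefficients[2, 2]
    ci[1] <= -0.8 && -0.8 <= ci[2]
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})
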