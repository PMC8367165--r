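test_that("ccdr is the detected-over-total ratio with guarded edges", {
  expect_equal(ccdr(191, 199), 191 / 199)
  expect_equal(round(ccdr(191, 199), 2), 0.96)
  expect_equal(round(ccdr(158, 183), 2), 0.86)
  expect_equal(ccdr(0, 50), 0)
  expect_error(ccdr(1, 0), "zero images")
  expect_error(ccdr(5, 4), "n_total")
})

test_that("group summaries pool counts and quantiles correctly", {
  rec <- make_records(c(TRUE, TRUE, TRUE, FALSE),
                      ccs = c(700, NA, 800, NA))
  s <- group_summary(rec, "feedback")
  expect_equal(s$ccdr, 0.75)
  expect_equal(s$n_images, 4)
  expect_equal(s$n_detected, 3)

  # degenerate quantiles: a single sharpness value
  s1 <- group_summary(make_records(TRUE, ccs = 700), "feedback")
  expect_equal(s1$ccs_median, 700)
  expect_equal(s1$ccs_q25, 700)
  expect_equal(s1$ccs_q75, 700)

  expect_error(group_summary(rec, "basic"), "no records")
})

test_that("usable ratio counts labeled images only", {
  rec <- make_records(rep(TRUE, 10),
                      usable = c(rep(TRUE, 6), rep(FALSE, 2), NA, NA))
  expect_equal(group_summary(rec, "feedback")$usable_ratio, 0.75)
})

test_that("per-patient summaries match a naive group-by oracle", {
  co <- generate_cohort(cohort_spec(seed = 11))
  pp <- per_patient_summaries(co)
  oracle <- naive_patient_summary(co)
  oracle <- oracle[match(pp$patient_id, oracle$patient_id), ]
  expect_equal(pp$ccdr, oracle$ccdr)
  expect_equal(pp$ccs_median, oracle$ccs_median)
  # group CCDR pools counts, not per-patient means
  g <- group_summary(co, "feedback")
  fb <- pp[pp$group == "feedback", ]
  expect_equal(g$ccdr, sum(fb$n_detected) / sum(fb$n_images))
})

test_that("compliance ratio divides performed by assigned days, capped at 1", {
  expect_equal(compliance_ratio(16, 16), 1)
  expect_equal(compliance_ratio(20, 16), 1)     # over-performing caps at 1
  expect_equal(compliance_ratio(8, 16), 0.5)
  expect_error(compliance_ratio(3, 0), "assigned_days")
  expect_error(compliance_ratio(-1, 16), "performed_days")
})

test_that("duration outliers beyond 3 scaled MADs are removed", {
  expect_equal(filter_duration_outliers(numeric(0)),
               list(kept = numeric(0), removed = numeric(0)))

  # degenerate MAD: all equal, everything survives
  f <- filter_duration_outliers(c(40, 40, 40, 40))
  expect_equal(f$kept, c(40, 40, 40, 40))
  expect_length(f$removed, 0)

  # median 42, MAD 1, bound 3 * 1.4826: only 400 exceeds it
  f <- filter_duration_outliers(c(40, 41, 42, 43, 400))
  expect_equal(f$removed, 400)
  expect_equal(f$kept, c(40, 41, 42, 43))
})

test_that("outlier filter partitions the input and stays stable on resample", {
  set.seed(7)
  for (k in 1:10) {
    x <- rnorm(50, 100, 10)
    f <- filter_duration_outliers(x)
    expect_equal(sort(c(f$kept, f$removed)), sort(x))
    # symmetric data: a second pass removes little or nothing more
    f2 <- filter_duration_outliers(f$kept)
    expect_lte(length(f2$removed), length(f$removed))
  }
})

test_that("rank-sum test agrees with wilcox.test on both branches", {
  set.seed(3)
  # small tie-free samples: exact branch
  for (k in 1:10) {
    a <- runif(sample(3:9, 1)); b <- runif(sample(3:9, 1)) + runif(1, -1, 1)
    ours <- rank_sum_test(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # large samples: normal approximation with continuity correction
  a <- rnorm(80); b <- rnorm(90, 0.3)
  ours <- rank_sum_test(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  # tied data engage the tie correction
  at <- rep(1:4, each = 5); bt <- rep(2:5, each = 5)
  expect_equal(rank_sum_test(at, bt)$p_value,
               suppressWarnings(wilcox.test(at, bt, correct = TRUE)$p.value),
               tolerance = 1e-10)
})

test_that("rank-sum test is symmetric and sane on exchangeable input", {
  x <- c(3, 1, 5, 2, 4); y <- c(2, 5, 1, 4, 3)
  r <- rank_sum_test(x, y)
  expect_lt(abs(r$statistic), 0.5)
  expect_gt(r$p_value, 0.9)

  set.seed(12)
  a <- rnorm(12); b <- rnorm(15, 1)
  r1 <- rank_sum_test(a, b); r2 <- rank_sum_test(b, a)
  expect_equal(r1$statistic, -r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)

  # full separation at n = 8 per group is decisively significant
  expect_lt(rank_sum_test(1:8, 11:18)$p_value, 0.01)
  expect_error(rank_sum_test(numeric(0), 1:3), "at least one")
})

test_that("duration trend recovers lines and rejects degenerate input", {
  tr <- duration_trend(data.frame(assessment_index = c(1, 2),
                                  duration_s = c(60, 50)))
  expect_equal(tr$slope, -10)
  expect_equal(tr$intercept, 70)

  const <- data.frame(assessment_index = 1:10, duration_s = rep(42, 10))
  expect_equal(duration_trend(const)$slope, 0)

  expect_error(duration_trend(data.frame(assessment_index = c(2, 2),
                                         duration_s = c(10, 20))),
               "distinct")

  # closed-form OLS oracle on a seeded noisy line
  set.seed(9)
  idx <- rep(1:16, 3)
  dur <- 55 - 0.8 * idx + rnorm(48, sd = 4)
  tr <- duration_trend(data.frame(assessment_index = idx, duration_s = dur))
  beta <- sum((idx - mean(idx)) * (dur - mean(dur))) / sum((idx - mean(idx))^2)
  expect_equal(tr$slope, beta, tolerance = 1e-12)
  expect_equal(tr$intercept, mean(dur) - beta * mean(idx), tolerance = 1e-12)
})

test_that("quality_report assembles the full analysis", {
  co <- generate_cohort(cohort_spec(seed = 21))
  rep <- quality_report(co)
  expect_setequal(rep$groups$group, c("feedback", "basic"))
  expect_true(all(rep$groups$ccdr >= 0 & rep$groups$ccdr <= 1))
  expect_true(all(rep$compliance$ratio <= 1))
  expect_s3_class(rep$ccs_test_pooled, "rank_sum_result")
  expect_true(all(c("feedback", "basic") %in% names(rep$duration_trends)))
  expect_true(is.finite(rep$duration_trends$feedback$slope))
})
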