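#' Color checker detection ratio (CCDR)
#'
#' The fraction of collected images in which the color reference sticker
#' was detected: `n_detected / n_total`.
#'
#' @param n_detected count of images with the sticker detected.
#' @param n_total total count of images collected (`>= 1`).
#' @return A number in `[0, 1]`.
#' @export
ccdr <- function(n_detected, n_total) {
  if (n_total == 0) stop("CCDR is undefined for zero images", call. = FALSE)
  if (n_detected < 0 || n_detected > n_total)
    stop("`n_detected` must lie in [0, n_total]", call. = FALSE)
  n_detected / n_total
}

#' Patient compliance with the assessment schedule
#'
#' Performed assessment days divided by assigned days, capped at 1: a
#' patient who assessed on more days than the protocol asked for is fully
#' compliant, not more.
#'
#' @param performed_days days on which at least one image was saved.
#' @param assigned_days protocol-assigned assessment days (default 16,
#'   every third day over 8 weeks).
#' @return A ratio in `[0, 1]`.
#' @export
compliance_ratio <- function(performed_days, assigned_days = 16) {
  if (assigned_days < 1)
    stop("`assigned_days` must be >= 1", call. = FALSE)
  if (performed_days < 0)
    stop("`performed_days` must be >= 0", call. = FALSE)
  min(performed_days / assigned_days, 1)
}

#' Remove assessment-duration outliers
#'
#' Flags durations more than 3 scaled median absolute deviations from the
#' median (scaled MAD = 1.4826 x MAD, the consistency constant that makes
#' the MAD estimate the standard deviation under normality). When all
#' values are equal the MAD is zero and only exact-median values survive
#' the bound; the filter is not idempotent in general since the median and
#' MAD are recomputed on the kept values.
#'
#' @param durations numeric vector of positive durations (may be empty).
#' @return A list with `kept` and `removed`, both preserving input order.
#' @export
filter_duration_outliers <- function(durations) {
  if (length(durations) == 0)
    return(list(kept = numeric(0), removed = numeric(0)))
  med <- median(durations)
  bound <- 3 * mad(durations)          # mad() applies the 1.4826 constant
  out <- abs(durations - med) > bound
  list(kept = durations[!out], removed = durations[out])
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Compares two groups via pooled midranks. For small tie-free samples
#' (both below 50) the p-value uses the exact rank-sum distribution;
#' otherwise the normal approximation with tie correction and a continuity
#' correction, two-sided in both cases. The reported statistic is the
#' corrected z-score (0 for exchangeable samples, sign flips when the
#' samples are swapped).
#'
#' @param a,b numeric vectors, both nonempty.
#' @return A list of class `rank_sum_result`: `statistic` (z), `p_value`,
#'   `n_a`, `n_b`, `method` ("exact" or "normal approximation").
#' @export
rank_sum_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0)
    stop("both samples must contain at least one value", call. = FALSE)
  n <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])             # rank sum of sample a
  u <- w - na * (na + 1) / 2           # Mann-Whitney U
  ties <- table(r)
  has_ties <- any(ties > 1)

  mu <- na * nb / 2
  sigma2 <- (na * nb / 12) * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
  d <- u - mu
  cc <- if (sigma2 > 0) sign(d) * 0.5 else 0
  z <- if (sigma2 > 0) (d - cc) / sqrt(sigma2) else 0

  if (!has_ties && na < 50 && nb < 50) {
    p <- if (u > mu) 2 * (1 - pwilcox(u - 1, na, nb)) else 2 * pwilcox(u, na, nb)
    method <- "exact"
  } else {
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  structure(list(statistic = z, p_value = min(1, p), n_a = na, n_b = nb,
                 method = method),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("<rank_sum_result> z = %.3f, p = %.4g (%s; n = %d vs %d)\n",
              x$statistic, x$p_value, x$method, x$n_a, x$n_b))
  invisible(x)
}

#' Linear trend of assessment duration over time
#'
#' Ordinary least-squares fit of duration against assessment index, used
#' to judge whether patients become faster with practice.
#'
#' @param records a data frame with columns `assessment_index` and
#'   `duration_s`, or a two-column matrix/data frame in that order.
#' @return A list of class `trend_fit` with `slope` (seconds per
#'   assessment) and `intercept` (seconds).
#' @export
duration_trend <- function(records) {
  records <- as.data.frame(records)
  if (!all(c("assessment_index", "duration_s") %in% names(records)))
    names(records)[1:2] <- c("assessment_index", "duration_s")
  records <- records[complete.cases(records[, c("assessment_index",
                                                "duration_s")]), ]
  if (length(unique(records$assessment_index)) < 2)
    stop("need at least 2 distinct assessment indices to fit a trend",
         call. = FALSE)
  fit <- lm(duration_s ~ assessment_index, data = records)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1])),
            class = "trend_fit")
}

# Quantile summary with linear interpolation between order statistics
# (R's default type 7).
q3 <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(c(q25 = NA_real_, median = NA_real_,
                               q75 = NA_real_))
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q25 = q[1], median = q[2], q75 = q[3])
}

summarize_records <- function(records, label_cols) {
  qs <- q3(records$ccs)
  lab <- records$usable_label[!is.na(records$usable_label)]
  tibble::tibble(
    !!!label_cols,
    n_images = nrow(records),
    n_detected = sum(records$checker_detected),
    ccdr = ccdr(sum(records$checker_detected), nrow(records)),
    ccs_median = qs[["median"]], ccs_q25 = qs[["q25"]], ccs_q75 = qs[["q75"]],
    usable_ratio = if (length(lab)) mean(lab) else NA_real_
  )
}

#' Quality summary for one device group
#'
#' Pools all records of the group: CCDR over all images, quartiles of the
#' available sharpness scores, and the subjectively-usable ratio among
#' labeled images.
#'
#' @param records an assessment-record tibble (see [generate_cohort()] or
#'   [read_manifest()]).
#' @param group `"feedback"` or `"basic"`.
#' @return A one-row tibble: `group`, `n_images`, `n_detected`, `ccdr`,
#'   `ccs_median`, `ccs_q25`, `ccs_q75`, `usable_ratio`.
#' @export
group_summary <- function(records, group) {
  sub <- records[records$group == group, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no records for group '", group, "'", call. = FALSE)
  summarize_records(sub, list(group = group))
}

#' Per-patient quality summaries
#'
#' The same summary as [group_summary()], computed within each patient;
#' the study compared the distributions of these per-patient values
#' between groups.
#'
#' @param records an assessment-record tibble.
#' @return A tibble with one row per patient, columns as in
#'   [group_summary()] plus `patient_id`.
#' @export
per_patient_summaries <- function(records) {
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  records |>
    dplyr::group_by(.data$patient_id, .data$group) |>
    dplyr::group_map(function(sub, key) {
      summarize_records(sub, list(patient_id = key$patient_id,
                                  group = key$group))
    }) |>
    dplyr::bind_rows()
}

#' Per-patient compliance from assessment records
#'
#' Counts distinct calendar dates with at least one saved image per
#' patient and applies [compliance_ratio()].
#'
#' @param records an assessment-record tibble with `timestamp` column.
#' @param assigned_days protocol-assigned days (default 16).
#' @return A tibble: `patient_id`, `group`, `performed_days`,
#'   `assigned_days`, `ratio`.
#' @export
compliance_table <- function(records, assigned_days = 16) {
  records |>
    dplyr::group_by(.data$patient_id, .data$group) |>
    dplyr::summarise(
      performed_days = dplyr::n_distinct(substr(.data$timestamp, 1, 10)),
      .groups = "drop") |>
    dplyr::mutate(assigned_days = assigned_days,
                  ratio = pmin(.data$performed_days / assigned_days, 1))
}

#' Full study quality/feasibility report
#'
#' Assembles the analysis layer over an assessment-record table: group and
#' per-patient summaries, the rank-sum comparison of sharpness between
#' groups (both pooled per-image scores and per-patient medians),
#' compliance, and per-group duration trends after per-patient outlier
#' filtering (durations counted once per assessment).
#'
#' @param records an assessment-record tibble.
#' @param assigned_days protocol-assigned assessment days.
#' @return A list of class `quality_report` with components `groups`,
#'   `patients`, `ccs_test_pooled`, `ccs_test_per_patient`, `compliance`,
#'   `duration_trends`, `durations_removed`.
#' @export
quality_report <- function(records, assigned_days = 16) {
  groups <- intersect(c("feedback", "basic"), unique(records$group))
  group_tbl <- dplyr::bind_rows(lapply(groups, group_summary,
                                       records = records))
  patients <- per_patient_summaries(records)

  ccs_test_pooled <- ccs_test_pp <- NULL
  if (length(groups) == 2) {
    pooled <- split(records$ccs[!is.na(records$ccs)],
                    records$group[!is.na(records$ccs)])
    ccs_test_pooled <- rank_sum_test(pooled$feedback, pooled$basic)
    pp <- split(patients$ccs_median, patients$group)
    if (all(lengths(pp) > 0))
      ccs_test_pp <- rank_sum_test(pp$feedback, pp$basic)
  }

  # one duration per assessment; outliers filtered within patient
  assess <- records |>
    dplyr::distinct(.data$patient_id, .data$group, .data$assessment_index,
                    .data$duration_s) |>
    dplyr::filter(!is.na(.data$duration_s))
  kept_list <- list(); n_removed <- 0L
  for (pid in unique(assess$patient_id)) {
    sub <- assess[assess$patient_id == pid, , drop = FALSE]
    keep <- abs(sub$duration_s - median(sub$duration_s)) <=
      3 * mad(sub$duration_s)
    kept_list[[pid]] <- sub[keep, , drop = FALSE]
    n_removed <- n_removed + sum(!keep)
  }
  kept <- dplyr::bind_rows(kept_list)
  trends <- lapply(setNames(groups, groups), function(g) {
    sub <- kept[kept$group == g, , drop = FALSE]
    if (length(unique(sub$assessment_index)) < 2) return(NULL)
    tr <- duration_trend(sub)
    list(slope = tr$slope, intercept = tr$intercept,
         median_duration = median(sub$duration_s), n = nrow(sub))
  })

  structure(list(groups = group_tbl, patients = patients,
                 ccs_test_pooled = ccs_test_pooled,
                 ccs_test_per_patient = ccs_test_pp,
                 compliance = compliance_table(records, assigned_days),
                 duration_trends = trends,
                 durations_removed = n_removed),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n\nGroup summaries:\n")
  print(as.data.frame(x$groups), row.names = FALSE, digits = 3)
  if (!is.null(x$ccs_test_pooled)) {
    cat("\nPooled CCS comparison: "); print(x$ccs_test_pooled)
  }
  cat("\nCompliance (median ratio):",
      sprintf("%.2f", median(x$compliance$ratio)), "\n")
  invisible(x)
}
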