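make_field <- function(speeds, D = 0.1, valid = TRUE) {
  n <- length(speeds)
  side <- ceiling(sqrt(n))
  ux <- matrix(0, side, side); ux[seq_len(n)] <- speeds
  transport_field(matrix(D, side, side), ux, matrix(0, side, side),
                  valid_mask = matrix(valid, side, side))
}

test_that("region summaries are plain means/medians over valid pixels", {
  f <- make_field(c(1, 2, 3, 4))
  m <- matrix(FALSE, 2, 2); m[] <- TRUE
  s <- summarize_region(f, region_mask(m, "tumor"), "P01", "s1")
  expect_equal(s$mean_speed, 2.5)
  expect_equal(s$median_speed, 2.5)
  expect_identical(s$n_valid, 4L)
  expect_identical(s$region, "tumor")

  ## invalid pixels are excluded whatever value they store
  f2 <- make_field(c(1, 2, 3, 99))
  f2$valid_mask[2, 2] <- FALSE
  f2$velocity_x[2, 2] <- 1e6  # must not leak into the summary
  s2 <- summarize_region(f2, region_mask(m, "tumor"))
  expect_equal(s2$mean_speed, 2)
  expect_identical(s2$n_valid, 3L)

  f3 <- make_field(1:4, valid = FALSE)
  expect_error(summarize_region(f3, region_mask(m, "tumor")),
               "no valid pixels")
})

test_that("tumor-ring phantom summaries recover the true regime means", {
  spec <- phantom_spec("tumor_ring", shape = c(48, 48), D = 0.2,
                       D_out = 0.1, ring_speed_in = 0.05,
                       ring_speed_out = 0.15)
  ph <- simulate_phantom(spec, frame_times = 0:4, pre_contrast_count = 1,
                         micro_dt = 1, advection = "gradient")
  sub <- subtract_background(ph$stack)
  both <- region_mask(ph$tumor_mask$mask | ph$ring_mask$mask, "roi")
  fit <- estimate_transport(sub, both)
  st <- summarize_region(fit, ph$tumor_mask)
  sr <- summarize_region(fit, ph$ring_mask)
  expect_lt(abs(st$mean_speed - 0.05), 1e-4)
  expect_lt(abs(sr$mean_speed - 0.15), 1e-4)
  expect_lt(abs(st$mean_D - 0.2), 1e-4)
  expect_lt(abs(sr$mean_D - 0.1), 1e-4)
})

test_that("patient aggregation is the unweighted slice mean", {
  sl <- do.call(rbind, lapply(1:3, function(k)
    data.frame(patient_id = "P01", slice_id = paste0("s", k),
               region = "tumor", mean_speed = k, median_speed = k + 0.5,
               mean_D = 0.1 * k, median_D = 0.1 * k, n_valid = 10L,
               units = "px_frame")))
  p <- aggregate_patient(sl)
  expect_equal(p$mean_speed, 2)
  expect_equal(p$median_speed, 2.5)
  expect_identical(p$n_slices, 3L)
  ## single slice: identity
  p1 <- aggregate_patient(sl[1, ])
  expect_equal(p1$mean_speed, 1)
  ## permutation invariance in slice order
  p2 <- aggregate_patient(sl[c(3, 1, 2), ])
  expect_equal(p2, p)
  ## inter-slice spread diagnostic: (3 - 1)/2 = 100%
  expect_equal(p$slice_spread_pct, 100)
  ## mixed regions/patients rejected
  bad <- sl; bad$region[2] <- "parenchyma"
  expect_error(aggregate_patient(bad), "mix")
})

test_that("correlate matches the covariance-formula oracle", {
  expect_equal(correlate(c(1, 2, 3), c(2, 4, 6))$r, 1.0)
  expect_equal(correlate(c(1, 2, 3, 4), c(4, 3, 2, 1))$r, -1.0)
  res <- correlate(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  ## hand oracle: r = 0.8, p from t = r sqrt(n-2)/sqrt(1-r^2) on 3 df
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  t_or <- 0.8 * sqrt(3) / sqrt(1 - 0.64)
  expect_equal(res$p, 2 * pt(-t_or, 3), tolerance = 1e-12)
  expect_identical(res$n, 5L)

  ## from-scratch covariance oracle on random vectors
  set.seed(12)
  for (rep in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    r_or <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(correlate(x, y)$r, r_or, tolerance = 1e-12)
  }
  ## NA pairs dropped, n reported
  expect_identical(correlate(c(1, 2, 3, NA), c(2, 1, 3, 4))$n, 3L)
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlate(1:2, 2:3), "at least 3")
})

test_that("paired comparisons handle degenerate inputs explicitly", {
  a <- c(1, 2, 3, 4, 5, 6)
  same <- compare_regions_paired(a, a)
  expect_equal(same$t$statistic, 0)
  expect_equal(same$t$p, 1)
  expect_true(is.na(same$wilcoxon$p))
  expect_match(same$wilcoxon$note, "all paired differences")

  shift <- compare_regions_paired(a, a + 10)
  expect_identical(shift$t$statistic, -Inf)
  expect_equal(shift$t$p, 0)  # constant differences: p -> 0
  ## the Wilcoxon headline is bounded below by its exact null at n = 6
  expect_lt(shift$headline_p, 0.05)

  set.seed(3)
  x <- rnorm(12); y <- x + rnorm(12, 1, 0.1)
  both <- compare_regions_paired(x, y, primary = "t")
  expect_equal(both$headline_p, both$t$p)
  expect_lt(both$t$p, 0.001)
})

test_that("the primary paired test is calibrated under the null", {
  set.seed(2024)
  rej <- mean(replicate(200, {
    a <- rnorm(14, 1, 0.1); b <- rnorm(14, 1, 0.1)
    compare_regions_paired(a, b)$headline_p <= 0.05
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
})

test_that("two-group comparisons report Welch and Mann-Whitney", {
  set.seed(8)
  v <- c(rnorm(10, 0), rnorm(10, 2))
  g <- rep(c("F", "M"), each = 10)
  res <- compare_groups(v, g)
  expect_lt(res$welch$p, 0.01)
  expect_lt(res$mann_whitney$p, 0.01)
  expect_error(compare_groups(v, rep("F", 20)), "two levels")
})

test_that("cohort tables left-join clinical covariates by patient id", {
  ps <- data.frame(patient_id = c("P01", "P02", "P03"), region = "tumor",
                   mean_speed = c(1, 2, 3), median_speed = c(1, 2, 3),
                   mean_D = 0.1, median_D = 0.1, n_slices = 2L,
                   slice_spread_pct = 5, resection_stage = "pre",
                   units = "px_frame")
  cl <- data.frame(patient_id = c("P01", "P02", "P03"),
                   age_years = c(50, 60, 70),
                   survival_days = c(300, 400, 500))
  tab <- build_cohort_table(ps, cl)
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$age_years, c(50, 60, 70))
  ## unmatched patient retained with NA covariates, with a warning
  expect_warning(tab2 <- build_cohort_table(
    rbind(ps, within(ps[1, ], patient_id <- "P99")), cl),
    "P99")
  expect_true(is.na(tab2$age_years[tab2$patient_id == "P99"]))
  expect_error(build_cohort_table(ps, rbind(cl, cl[1, ])), "duplicate")
  ## CSV path input
  p <- file.path(tempdir(), "clinical.csv")
  write.csv(cl, p, row.names = FALSE)
  expect_identical(nrow(build_cohort_table(ps, p)), 3L)
})

test_that("cohort stats cover the expected analysis families", {
  set.seed(5)
  co <- simulate_cohort(cohort_spec(seed = 6))
  ps <- do.call(rbind, lapply(seq_len(nrow(co)), function(i) {
    rbind(
      data.frame(patient_id = co$patient_id[i], region = "tumor",
                 mean_speed = co$tumor_mean_speed[i],
                 median_speed = co$tumor_mean_speed[i],
                 mean_D = 0.1 + 0.01 * rnorm(1), median_D = 0.1,
                 n_slices = 6L, slice_spread_pct = 10,
                 resection_stage = "pre", units = "um_s"),
      data.frame(patient_id = co$patient_id[i], region = "parenchyma",
                 mean_speed = co$tumor_mean_speed[i] + rnorm(1, 0, 0.05),
                 median_speed = co$tumor_mean_speed[i],
                 mean_D = 0.1, median_D = 0.1, n_slices = 6L,
                 slice_spread_pct = 10, resection_stage = "pre",
                 units = "um_s"))
  }))
  tab <- build_cohort_table(
    ps, co[, !names(co) %in% c("tumor_mean_speed", "resection_stage")])
  rep <- cohort_stats(tab)
  for (nm in c("tumor_vs_parenchyma_speed", "speed_tumor_vs_parenchyma_corr",
               "speed_vs_age", "speed_vs_survival", "speed_vs_weight",
               "D_vs_survival", "age_vs_survival", "speed_by_sex",
               "speed_by_mgmt_status", "speed_by_egfr_amplified"))
    expect_true(nm %in% names(rep), label = nm)
  expect_gt(rep$speed_vs_survival$r, 0)
  expect_lt(rep$speed_vs_age$r, 0)
  expect_true("bh_adjusted" %in% names(rep))
  ## too-small cohorts skip correlations with a reason
  few <- tab[tab$patient_id %in% c("P01", "P02"), ]
  rep2 <- cohort_stats(few)
  expect_match(rep2$correlations$skipped, "need")
})
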