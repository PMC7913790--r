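#' Summarize transport within a region
#'
#' Mean and median speed and diffusion coefficient over the valid pixels of
#' one region on one slice. Invalid pixels never contribute, whatever value
#' their storage slots hold.
#'
#' @param field a [transport_field()].
#' @param mask a [region_mask()].
#' @param patient_id,slice_id identifiers carried into the output.
#' @param region region label; defaults to the mask's label.
#' @return A one-row `data.frame`: `patient_id`, `slice_id`, `region`,
#'   `mean_speed`, `median_speed`, `mean_D`, `median_D`, `n_valid`,
#'   `units`.
#' @export
summarize_region <- function(field, mask, patient_id = "", slice_id = "",
                             region = mask$label) {
  stopifnot(inherits(field, "transport_field"),
            inherits(mask, "region_mask"))
  if (!identical(dim(mask$mask), dim(field)))
    stop("mask shape does not match the field")
  sel <- mask$mask & field$valid_mask
  if (!any(sel))
    stop("region '", region, "' contains no valid pixels")
  sp <- velocity_magnitude(field)[sel]
  D <- field$diffusion_map[sel]
  data.frame(patient_id = patient_id, slice_id = as.character(slice_id),
             region = region,
             mean_speed = mean(sp), median_speed = median(sp),
             mean_D = mean(D), median_D = median(D),
             n_valid = sum(sel), units = field$units,
             stringsAsFactors = FALSE)
}

#' Aggregate slice summaries to a patient summary
#'
#' Unweighted mean over slices of each slice statistic for one patient and
#' one region (several slices through the tumor are analyzed and averaged
#' to a per-patient value). Also reports the relative spread of the slice
#' mean speeds, `(max - min) / mean` in percent, as an inter-slice
#' variability diagnostic.
#'
#' @param summaries `data.frame` of [summarize_region()] rows sharing one
#'   patient, region and units.
#' @param resection_stage `"pre"` or `"post"`, carried into the output.
#' @return A one-row `data.frame` with mean-of-slice statistics,
#'   `n_slices` and `slice_spread_pct`.
#' @export
aggregate_patient <- function(summaries, resection_stage = "pre") {
  s <- as.data.frame(summaries)
  if (nrow(s) < 1L) stop("no slice summaries")
  for (col in c("patient_id", "region", "units"))
    if (length(unique(s[[col]])) != 1L)
      stop("slice summaries mix values of '", col, "'")
  data.frame(
    patient_id = s$patient_id[1L], region = s$region[1L],
    mean_speed = mean(s$mean_speed),
    median_speed = mean(s$median_speed),
    mean_D = mean(s$mean_D), median_D = mean(s$median_D),
    n_slices = nrow(s),
    slice_spread_pct = if (nrow(s) > 1L)
      100 * (max(s$mean_speed) - min(s$mean_speed)) / mean(s$mean_speed)
    else 0,
    resection_stage = resection_stage, units = s$units[1L],
    stringsAsFactors = FALSE)
}

#' Correlate two per-patient quantities
#'
#' Pearson correlation (two-sided, with p from the t transform on n - 2
#' degrees of freedom) between paired per-patient values; pairs with
#' missing entries are dropped and the effective n reported. Spearman is
#' available as an option.
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list: `r`, `p`, `n`, `conf_int` (95%, Pearson only),
#'   `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs (got ", n, ")")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance in one variable")
  ct <- suppressWarnings(cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = n,
       conf_int = if (method == "pearson") unname(ct$conf.int),
       method = method)
}

#' Paired comparison of two per-patient measurements
#'
#' For questions such as "does flow differ between tumor and parenchyma"
#' or "does resection change flow", both the paired t-test and the Wilcoxon
#' signed-rank test are computed; the configured primary test (Wilcoxon by
#' default, which is robust at the small n of imaging cohorts) supplies the
#' headline p-value. Degenerate inputs are reported explicitly: identical
#' vectors give t = 0, p = 1 and an undefined Wilcoxon; constant nonzero
#' differences give an infinite t with p = 0.
#'
#' @param a,b paired numeric vectors.
#' @param primary `"wilcoxon"` or `"t"`.
#' @return A list: `headline_p`, `primary`, `n`, and per-test sublists
#'   `t` and `wilcoxon` (`statistic`, `p`, `note`).
#' @export
compare_regions_paired <- function(a, b, primary = c("wilcoxon", "t")) {
  primary <- match.arg(primary)
  if (length(a) != length(b)) stop("'a' and 'b' must be paired")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3L) stop("need at least 3 complete pairs (got ", n, ")")
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      tt <- list(statistic = 0, p = 1, note = "all differences zero")
    } else {
      tt <- list(statistic = sign(d[1L]) * Inf, p = 0,
                 note = "constant nonzero differences")
    }
  } else {
    ht <- t.test(a, b, paired = TRUE)
    tt <- list(statistic = unname(ht$statistic), p = ht$p.value,
               note = NA_character_)
  }
  if (all(d == 0)) {
    wt <- list(statistic = NA_real_, p = NA_real_,
               note = "undefined: all paired differences are zero")
  } else {
    hw <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
    wt <- list(statistic = unname(hw$statistic), p = hw$p.value,
               note = NA_character_)
  }
  headline <- if (primary == "wilcoxon") wt$p else tt$p
  list(headline_p = headline, primary = primary, n = n, t = tt,
       wilcoxon = wt)
}

#' Two-group comparison of a per-patient quantity
#'
#' For dichotomous covariates (sex, MGMT methylation, EGFR amplification):
#' Welch's t-test as the primary test with the Mann-Whitney U test as the
#' reported alternative.
#'
#' @param values numeric vector.
#' @param group factor-like vector with exactly two levels.
#' @return A list: `headline_p`, `groups`, `n`, and sublists `welch` and
#'   `mann_whitney`.
#' @export
compare_groups <- function(values, group) {
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]; group <- factor(group[keep])
  if (nlevels(group) != 2L)
    stop("'group' must have exactly two levels")
  if (min(table(group)) < 2L)
    stop("need at least 2 observations per group")
  ht <- t.test(values ~ group)
  hw <- suppressWarnings(wilcox.test(values ~ group))
  list(headline_p = ht$p.value, groups = levels(group),
       n = length(values),
       welch = list(statistic = unname(ht$statistic), p = ht$p.value),
       mann_whitney = list(statistic = unname(hw$statistic),
                           p = hw$p.value))
}

#' Join patient summaries with clinical covariates
#'
#' Left-joins per-patient flow summaries to a clinical table on
#' `patient_id`. Unmatched patients are retained with `NA` covariates and
#' reported in a warning; duplicated clinical ids are an error. The
#' clinical table (CSV path or data.frame) uses the documented header:
#' `patient_id, age_years, sex, weight_kg, survival_days, mgmt_status,
#' egfr_amplified` (extra columns pass through).
#'
#' @param patient_summaries `data.frame` of [aggregate_patient()] rows.
#' @param clinical CSV path or `data.frame`.
#' @return The joined cohort `data.frame`, one row per patient per stage.
#' @export
build_cohort_table <- function(patient_summaries, clinical) {
  if (is.character(clinical)) clinical <- read.csv(clinical)
  if (!"patient_id" %in% names(clinical))
    stop("clinical table lacks a 'patient_id' column")
  if (anyDuplicated(clinical$patient_id))
    stop("duplicate patient ids in the clinical table: ",
         paste(unique(clinical$patient_id[
           duplicated(clinical$patient_id)]), collapse = ", "))
  unmatched <- setdiff(patient_summaries$patient_id, clinical$patient_id)
  if (length(unmatched))
    warning("no clinical record for: ", paste(unmatched, collapse = ", "),
            " (retained with NA covariates)")
  merge(patient_summaries, clinical, by = "patient_id", all.x = TRUE,
        sort = TRUE)
}

#' Cohort-level statistics report
#'
#' Runs the cohort analyses on a joined table of tumor and parenchyma
#' patient summaries: paired tumor-vs-parenchyma comparisons of speed and
#' D, tumor-parenchyma cross-correlations, correlations of tumor flow with
#' age, weight and survival (and D with survival), two-group tests for
#' sex/MGMT/EGFR, and - when both resection stages are present - the paired
#' pre/post comparison and pre-vs-post correlation. Each result carries the
#' test name, statistic, p and n. No multiplicity correction is applied to
#' the panel; a Benjamini-Hochberg summary over the correlation p-values is
#' attached separately.
#'
#' @param cohort `data.frame` from [build_cohort_table()] containing rows
#'   for regions `"tumor"` and (optionally) `"parenchyma"`.
#' @param min_n minimum patients for correlation analyses.
#' @return A nested list report; skipped analyses carry a `skipped` reason.
#' @export
cohort_stats <- function(cohort, min_n = 3L) {
  rep <- list()
  pre <- cohort[cohort$resection_stage == "pre", , drop = FALSE]
  tum <- pre[pre$region == "tumor", , drop = FALSE]
  par <- pre[pre$region == "parenchyma", , drop = FALSE]
  both <- merge(tum, par, by = "patient_id", suffixes = c("_t", "_p"))
  try_stat <- function(expr) tryCatch(expr, error = function(e)
    list(skipped = conditionMessage(e)))
  if (nrow(both) >= min_n) {
    rep$tumor_vs_parenchyma_speed <- try_stat(
      compare_regions_paired(both$mean_speed_t, both$mean_speed_p))
    rep$tumor_vs_parenchyma_D <- try_stat(
      compare_regions_paired(both$mean_D_t, both$mean_D_p))
    rep$speed_tumor_vs_parenchyma_corr <- try_stat(
      correlate(both$mean_speed_t, both$mean_speed_p))
    rep$D_tumor_vs_parenchyma_corr <- try_stat(
      correlate(both$mean_D_t, both$mean_D_p))
  } else {
    rep$tumor_vs_parenchyma <- list(
      skipped = paste0("only ", nrow(both),
                       " patients with both regions (need ", min_n, ")"))
  }
  if (nrow(tum) >= min_n) {
    for (cov in c("age_years", "weight_kg", "survival_days")) {
      if (cov %in% names(tum))
        rep[[paste0("speed_vs_", sub("_.*", "", cov))]] <- try_stat(
          correlate(tum$mean_speed, tum[[cov]]))
    }
    if ("survival_days" %in% names(tum))
      rep$D_vs_survival <- try_stat(
        correlate(tum$mean_D, tum$survival_days))
    if (all(c("age_years", "survival_days") %in% names(tum)))
      rep$age_vs_survival <- try_stat(
        correlate(tum$age_years, tum$survival_days))
    for (g in c("sex", "mgmt_status", "egfr_amplified")) {
      if (g %in% names(tum))
        rep[[paste0("speed_by_", g)]] <- try_stat(
          compare_groups(tum$mean_speed, tum[[g]]))
    }
  } else {
    rep$correlations <- list(
      skipped = paste0("only ", nrow(tum), " patients (need ", min_n, ")"))
  }
  post <- cohort[cohort$resection_stage == "post" &
                   cohort$region == "tumor", , drop = FALSE]
  if (nrow(post)) {
    pp <- merge(tum, post, by = "patient_id",
                suffixes = c("_pre", "_post"))
    if (nrow(pp) >= min_n) {
      rep$pre_vs_post_speed <- try_stat(
        compare_regions_paired(pp$mean_speed_pre, pp$mean_speed_post))
      rep$pre_vs_post_corr <- try_stat(
        correlate(pp$mean_speed_pre, pp$mean_speed_post))
      rep$pre_post_n <- nrow(pp)
    } else {
      rep$pre_vs_post <- list(
        skipped = paste0("only ", nrow(pp),
                         " patients with both stages (need ", min_n, ")"))
    }
  }
  ps <- vapply(rep, function(x) {
    if (!is.null(x[["p"]])) x[["p"]]
    else if (!is.null(x[["headline_p"]])) x[["headline_p"]]
    else NA_real_
  }, 0)
  ps <- ps[is.finite(ps)]
  if (length(ps))
    rep$bh_adjusted <- as.list(setNames(p.adjust(ps, "BH"), names(ps)))
  rep
}
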