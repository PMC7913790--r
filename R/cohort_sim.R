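#' Synthetic cohort specification
#'
#' Describes a cohort of patients with a built-in correlation structure
#' between mean tumor flow speed, age and survival, plus independent
#' clinical covariates. The default correlation signs emulate the pattern
#' reported for glioblastoma cohorts: faster interstitial flow associates
#' with longer survival, older age with slower flow, and older age with
#' shorter survival. Velocity, age and survival are drawn jointly from a
#' multivariate normal with the target correlation matrix.
#'
#' @param n_patients cohort size.
#' @param vel_mean,vel_sd per-patient mean tumor speed (um/s). Interstitial
#'   flow in and around tumors is of order 0.1-10 um/s; 1 +/- 0.25 um/s is
#'   a realistic, comfortably positive choice.
#' @param age_mean,age_sd patient age (years).
#' @param surv_mean,surv_sd overall survival (days); glioblastoma median
#'   survival is 12-15 months.
#' @param weight_mean,weight_sd body weight (kg), uncorrelated with flow.
#' @param r_vel_surv,r_vel_age,r_age_surv target Pearson correlations; the
#'   implied 3 x 3 correlation matrix must be positive semi-definite.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 14, vel_mean = 1.0, vel_sd = 0.25,
                        age_mean = 60, age_sd = 10, surv_mean = 450,
                        surv_sd = 150, weight_mean = 80, weight_sd = 15,
                        r_vel_surv = 0.6, r_vel_age = -0.6,
                        r_age_surv = -0.6, seed = 1L) {
  r <- c(r_vel_surv, r_vel_age, r_age_surv)
  if (any(abs(r) > 1)) stop("target correlations must lie in [-1, 1]")
  R <- matrix(c(1, r_vel_age, r_vel_surv,
                r_vel_age, 1, r_age_surv,
                r_vel_surv, r_age_surv, 1), 3L, 3L)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("target correlation matrix is not positive semi-definite")
  structure(
    list(n_patients = as.integer(n_patients), vel_mean = vel_mean,
         vel_sd = vel_sd, age_mean = age_mean, age_sd = age_sd,
         surv_mean = surv_mean, surv_sd = surv_sd,
         weight_mean = weight_mean, weight_sd = weight_sd,
         corr = R, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Simulate a patient cohort table
#'
#' Draws `(speed, age, survival)` per patient from the multivariate normal
#' implied by a [cohort_spec()], plus independent weight, sex, MGMT
#' methylation and EGFR amplification covariates. Survival is rounded to
#' whole days.
#'
#' @param spec a [cohort_spec()].
#' @return A `data.frame` with one row per patient: `patient_id`,
#'   `tumor_mean_speed` (um/s), `age_years`, `survival_days`, `weight_kg`,
#'   `sex`, `mgmt_status`, `egfr_amplified`, `resection_stage`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  mu <- c(spec$vel_mean, spec$age_mean, spec$surv_mean)
  sds <- c(spec$vel_sd, spec$age_sd, spec$surv_sd)
  Sigma <- diag(sds) %*% spec$corr %*% diag(sds)
  z <- MASS::mvrnorm(n, mu, Sigma)
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    tumor_mean_speed = z[, 1L],
    age_years = z[, 2L],
    survival_days = round(z[, 3L]),
    weight_kg = rnorm(n, spec$weight_mean, spec$weight_sd),
    sex = sample(c("F", "M"), n, replace = TRUE),
    mgmt_status = sample(c("methylated", "unmethylated"), n, replace = TRUE),
    egfr_amplified = sample(c(TRUE, FALSE), n, replace = TRUE),
    resection_stage = "pre",
    stringsAsFactors = FALSE)
}
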