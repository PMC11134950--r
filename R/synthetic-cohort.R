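#' Specification for a simulated survival cohort
#'
#' Describes a cohort whose overall survival follows a proportional-hazards
#' model on eight collagen features and a slate of clinical covariates
#' (age group, sex, TNM stage, differentiation, perineural invasion,
#' lymphovascular invasion, tumor location). Event times are exponential
#' with hazard `baseline_hazard * exp(linear predictor)`; censoring is
#' independent uniform on `[0, T_max]` with `T_max` calibrated to the
#' requested censoring fraction.
#'
#' @param n_patients number of patients (>= 2).
#' @param rois_per_patient ROIs imaged per patient (bookkeeping for
#'   image-level simulation).
#' @param feature_means,feature_sds length-8 vectors of feature means/SDs.
#' @param true_beta length-8 vector of log-hazard coefficients on the
#'   (mean-centred) features.
#' @param clinical_beta named numeric vector of log-hazard coefficients on
#'   clinical indicator variables; recognised names are `age_gt50`,
#'   `sex_male`, `tnm_high`, `diff_II`, `diff_III`, `pni_yes`, `lvi_yes`,
#'   `loc_body_tail`, `loc_other`. Unnamed covariates default to 0.
#' @param baseline_hazard events per month at the covariate means.
#' @param censoring_rate target fraction censored, in `[0, 1)`.
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        rois_per_patient = 2,
                        feature_means = c(0.3, 60, 80, 5, 0.9, 0.8, 40, 0.3),
                        feature_sds = c(0.1, 15, 15, 1, 0.05, 0.3, 10, 0.1),
                        true_beta = rep(0, 8),
                        clinical_beta = numeric(0),
                        baseline_hazard = 0.05,
                        censoring_rate = 0.3,
                        seed = 1L) {
  spec <- list(
    n_patients = as.integer(n_patients),
    rois_per_patient = as.integer(rois_per_patient),
    feature_means = feature_means,
    feature_sds = feature_sds,
    true_beta = true_beta,
    clinical_beta = clinical_beta,
    baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  check_that(spec$n_patients >= 2, "n_patients must be >= 2")
  check_that(length(spec$feature_means) == 8 && length(spec$feature_sds) == 8,
             "feature_means and feature_sds must have length 8")
  check_that(length(spec$true_beta) == 8, "true_beta must have length 8")
  check_that(spec$baseline_hazard > 0, "baseline_hazard must be > 0")
  check_that(spec$censoring_rate >= 0 && spec$censoring_rate < 1,
             "censoring_rate must lie in [0, 1)")
  invisible(spec)
}

# marginal frequencies of the clinical covariates in the simulated cohort
clinical_marginals <- function() {
  list(
    age_group = c("<=50" = 0.195, ">50" = 0.805),
    sex = c("Female" = 0.369, "Male" = 0.631),
    tnm = c("<=IIA" = 0.416, ">=IIB" = 0.584),
    differentiation = c("I" = 0.188, "II" = 0.416, "III" = 0.396),
    pni = c("No" = 0.235, "Yes" = 0.765),
    lvi = c("No" = 0.839, "Yes" = 0.161),
    location = c("Head" = 0.718, "Body/tail" = 0.248, "Other" = 0.034)
  )
}

# indicator matrix for the recognised clinical effects
clinical_design <- function(df) {
  cbind(
    age_gt50 = as.numeric(df$age_group == ">50"),
    sex_male = as.numeric(df$sex == "Male"),
    tnm_high = as.numeric(df$tnm == ">=IIB"),
    diff_II = as.numeric(df$differentiation == "II"),
    diff_III = as.numeric(df$differentiation == "III"),
    pni_yes = as.numeric(df$pni == "Yes"),
    lvi_yes = as.numeric(df$lvi == "Yes"),
    loc_body_tail = as.numeric(df$location == "Body/tail"),
    loc_other = as.numeric(df$location == "Other")
  )
}

#' Simulate a patient cohort with proportional-hazards survival
#'
#' @param spec a [cohort_spec()].
#' @return a data.frame with columns `patient_id`, `fea1`..`fea8`, the
#'   clinical covariates, `os_months`, `event` (1 = death, 0 = censored),
#'   and an attribute `"linear_predictor"` holding the true log-hazard of
#'   each patient.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_patients
    fea <- vapply(1:8, function(j) {
      stats::rnorm(n, spec$feature_means[j], spec$feature_sds[j])
    }, numeric(n))
    colnames(fea) <- paste0("fea", 1:8)

    marg <- clinical_marginals()
    clin <- data.frame(lapply(marg, function(p) {
      factor(sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
    }), check.names = FALSE, stringsAsFactors = FALSE)

    lp <- drop(sweep(fea, 2, spec$feature_means) %*% spec$true_beta)
    if (length(spec$clinical_beta)) {
      X <- clinical_design(clin)
      bad <- setdiff(names(spec$clinical_beta), colnames(X))
      check_that(length(bad) == 0,
                 paste("unknown clinical_beta names:", paste(bad, collapse = ", ")))
      for (nm in names(spec$clinical_beta)) {
        lp <- lp + spec$clinical_beta[[nm]] * X[, nm]
      }
    }
    rate <- spec$baseline_hazard * exp(lp)
    t_event <- stats::rexp(n, rate = rate)

    if (spec$censoring_rate > 0) {
      t_max <- calibrate_censoring(rate, spec$censoring_rate)
      t_cens <- stats::runif(n, 0, t_max)
      event <- as.integer(t_event <= t_cens)
      os <- pmin(t_event, t_cens)
    } else {
      event <- rep(1L, n)
      os <- t_event
    }
    os <- pmax(os, 1e-6)

    out <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      fea,
      clin,
      os_months = os,
      event = event,
      stringsAsFactors = FALSE
    )
    attr(out, "linear_predictor") <- lp
    out
  })
}

# Choose T_max so that uniform censoring on [0, T_max] yields the target
# expected censoring fraction given the patients' exponential rates:
# P(censored | rate r) = (1 - exp(-r * c)) / (r * c).
calibrate_censoring <- function(rates, target) {
  f <- function(cc) mean((1 - exp(-rates * cc)) / (rates * cc)) - target
  upper <- 10 / min(rates)
  while (f(upper) > 0 && upper < 1e12) upper <- upper * 10
  stats::uniroot(f, lower = 1e-8, upper = upper, tol = 1e-10)$root
}
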