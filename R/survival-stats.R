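#' Cox proportional-hazards regression
#'
#' Fits Cox models of overall survival with Efron tie handling and Wald
#' confidence intervals. In univariate mode each covariate is fitted alone;
#' in multivariate mode all covariates enter one model.
#'
#' @param cohort data.frame with `os_months`, `event` and the covariates.
#' @param covariates character vector of covariate column names.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param conf_level confidence level for the hazard-ratio intervals.
#' @return an object of class `cox_result`: list with `table` (data.frame
#'   with columns `covariate`, `term`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `mode`) and, for multivariate mode, `fit` (the `coxph` object).
#' @export
cox_fit <- function(cohort, covariates,
                    mode = c("multivariate", "univariate"),
                    conf_level = 0.95) {
  mode <- match.arg(mode)
  check_that(all(c("os_months", "event") %in% names(cohort)),
             "cohort must contain os_months and event")
  check_that(all(covariates %in% names(cohort)),
             paste("covariates absent from cohort:",
                   paste(setdiff(covariates, names(cohort)), collapse = ", ")))
  check_that(sum(cohort$event) >= 10, "need at least 10 events")
  for (cv in covariates) {
    check_that(!anyNA(cohort[[cv]]), paste("missing values in", cv))
  }

  one_fit <- function(cvs) {
    fml <- stats::as.formula(paste(
      "survival::Surv(os_months, event) ~",
      paste(cvs, collapse = " + ")
    ))
    fit <- tryCatch(
      survival::coxph(fml, data = cohort, ties = "efron"),
      error = function(e) stop("Cox fit failed for ", paste(cvs, collapse = "+"),
                               ": ", conditionMessage(e), call. = FALSE)
    )
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      stop("singular design: covariate term(s) ",
           paste(names(cf)[is.na(cf)], collapse = ", "),
           " are aliased", call. = FALSE)
    }
    if (any(abs(cf) > 15)) {
      stop("monotone likelihood (complete separation) for term(s) ",
           paste(names(cf)[abs(cf) > 15], collapse = ", "), call. = FALSE)
    }
    fit
  }

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  row_of <- function(fit, cv) {
    sm <- summary(fit)$coefficients
    terms <- rownames(sm)
    data.frame(
      covariate = cv,
      term = terms,
      hr = exp(sm[, "coef"]),
      ci_low = exp(sm[, "coef"] - z * sm[, "se(coef)"]),
      ci_high = exp(sm[, "coef"] + z * sm[, "se(coef)"]),
      p = sm[, "Pr(>|z|)"],
      mode = mode,
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  }

  if (mode == "univariate") {
    tab <- do.call(rbind, lapply(covariates, function(cv) {
      row_of(one_fit(cv), cv)
    }))
    fit <- NULL
  } else {
    fit <- one_fit(covariates)
    sm <- summary(fit)$coefficients
    asg <- attr(stats::model.matrix(fit), "assign")
    cov_of_term <- covariates[asg]
    tab <- do.call(rbind, lapply(seq_len(nrow(sm)), function(i) {
      data.frame(covariate = cov_of_term[i], term = rownames(sm)[i],
                 hr = exp(sm[i, "coef"]),
                 ci_low = exp(sm[i, "coef"] - z * sm[i, "se(coef)"]),
                 ci_high = exp(sm[i, "coef"] + z * sm[i, "se(coef)"]),
                 p = sm[i, "Pr(>|z|)"], mode = mode,
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }
  structure(list(table = tab, fit = fit, mode = mode,
                 covariates = covariates),
            class = "cox_result")
}

#' Kaplan-Meier curves and log-rank test for two risk groups
#'
#' @param cohort data.frame with `os_months` and `event`.
#' @param group_labels factor/character vector of length `nrow(cohort)`
#'   with exactly two levels.
#' @return an object of class `km_result`: list with `curves` (data.frame
#'   `group`, `time`, `surv`, `n_risk`), `logrank_p`, `hr` (second level
#'   vs first), and the underlying `survfit`.
#' @export
km_logrank <- function(cohort, group_labels) {
  g <- factor(group_labels)
  check_that(nlevels(g) == 2, "exactly two groups are required")
  check_that(all(table(g) > 0), "each group must contain patients")
  d <- data.frame(os_months = cohort$os_months, event = cohort$event, g = g)
  check_that(sum(d$event) >= 1, "no events in either group")
  sf <- survival::survfit(survival::Surv(os_months, event) ~ g, data = d)
  sd <- survival::survdiff(survival::Surv(os_months, event) ~ g, data = d)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(survival::Surv(os_months, event) ~ g, data = d)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(
    group = sub("^g=", "", strata),
    time = sf$time,
    surv = sf$surv,
    n_risk = sf$n.risk,
    stringsAsFactors = FALSE
  )
  structure(list(curves = curves, logrank_p = p,
                 hr = unname(exp(stats::coef(cx))), survfit = sf),
            class = "km_result")
}

#' Kaplan-Meier survival estimate at a time point
#' @param times,events survival data.
#' @param at evaluation time.
#' @return estimated S(at).
#' @export
km_at <- function(times, events, at) {
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  s <- summary(sf, times = at, extend = TRUE)
  as.numeric(s$surv)
}

#' ROC analysis with the Youden-index cutoff
#'
#' Empirical ROC of a continuous score against a binary outcome, with
#' trapezoidal AUC and DeLong 95% confidence interval. The optimal cutoff
#' maximizes the Youden index J = sensitivity + specificity - 1; ties are
#' broken toward the cutoff with higher specificity. Higher scores are
#' treated as predicting the positive class.
#'
#' @param scores numeric vector.
#' @param outcome binary vector (0/1 or logical).
#' @return an object of class `roc_result`: list with `auc`, `auc_ci`,
#'   `cutoff`, `youden_j`, `sensitivity`, `specificity` (at the cutoff),
#'   and `curve` (data.frame `threshold`, `sensitivity`, `specificity`).
#' @export
roc_youden <- function(scores, outcome) {
  y <- as.integer(outcome > 0)
  check_that(length(unique(y)) == 2, "both outcome classes must be present")
  r <- pROC::roc(response = y, predictor = scores,
                 direction = "<", levels = c(0, 1), quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  crv <- data.frame(threshold = r$thresholds,
                    sensitivity = r$sensitivities,
                    specificity = r$specificities)
  j <- crv$sensitivity + crv$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(crv$specificity[best])]
  structure(
    list(auc = as.numeric(pROC::auc(r)),
         auc_ci = c(low = ci[1], high = ci[3]),
         cutoff = crv$threshold[best],
         youden_j = j[best],
         sensitivity = crv$sensitivity[best],
         specificity = crv$specificity[best],
         curve = crv),
    class = "roc_result"
  )
}

#' Assign risk groups from a score and cutoff
#'
#' Higher score than the cutoff means high risk (higher score corresponds
#' to worse prognosis).
#' @param scores numeric vector.
#' @param cutoff threshold (e.g. from [roc_youden()]).
#' @return factor with levels `low`, `high`.
#' @export
assign_risk_group <- function(scores, cutoff) {
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Correlation of features (or a score) with overall survival
#'
#' @param cohort data.frame with `os_months`.
#' @param columns columns to correlate with OS (default `fea1`..`fea8`).
#' @param method `"spearman"` or `"pearson"`.
#' @return data.frame with `column`, `estimate`, `p`.
#' @export
feature_os_correlation <- function(cohort, columns = paste0("fea", 1:8),
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  check_that(nrow(cohort) >= 3, "need at least 3 patients")
  do.call(rbind, lapply(columns, function(cl) {
    x <- cohort[[cl]]
    check_that(stats::sd(x, na.rm = TRUE) > 0,
               paste("zero variance in", cl))
    ct <- suppressWarnings(
      stats::cor.test(x, cohort$os_months, method = method)
    )
    data.frame(column = cl, estimate = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
}
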