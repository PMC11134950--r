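#' Build nomogram point scales from a multivariate Cox model
#'
#' Converts a fitted multivariate Cox model into the familiar 0-100 point
#' scales: each covariate level (or numeric value) contributes
#' `100 * beta * (x - x_ref) / max_range` points, where `x_ref` is the
#' level of that covariate with the lowest contribution to the linear
#' predictor and `max_range` is the widest linear-predictor span of any
#' single covariate, so the most influential covariate spans exactly
#' 0-100 points. Total points map monotonically to the Cox linear
#' predictor and hence to predicted survival at the requested horizons via
#' the baseline cumulative hazard.
#'
#' @param cox a multivariate `cox_result` from [cox_fit()].
#' @param cohort the data the model was fitted on (supplies observed
#'   covariate ranges).
#' @param horizons_months survival horizons for the points-to-survival
#'   mapping (default 12 and 36 months: 1- and 3-year OS).
#' @return an object of class `nomogram_model`: list with `point_tables`
#'   (per covariate: value/level and points), `points_per_lp` (linear
#'   predictor units per point), `lp_ref`, `horizons_months`,
#'   `baseline_cumhaz` and the Cox fit.
#' @export
build_nomogram <- function(cox, cohort, horizons_months = c(12, 36)) {
  stopifnot(inherits(cox, "cox_result"))
  check_that(cox$mode == "multivariate" && !is.null(cox$fit),
             "a multivariate cox_result with its fit is required")
  fit <- cox$fit
  mm <- stats::model.matrix(fit, data = cohort)
  asg <- attr(mm, "assign")
  cf <- stats::coef(fit)

  # per-covariate linear-predictor contribution range over the cohort
  contribs <- lapply(unique(asg), function(a) {
    cols <- which(asg == a)
    drop(mm[, cols, drop = FALSE] %*% cf[cols])
  })
  names(contribs) <- cox$covariates[unique(asg)]
  ranges <- vapply(contribs, function(v) diff(range(v)), numeric(1))
  max_range <- max(ranges)
  check_that(is.finite(max_range), "degenerate model: no covariate range")
  lp_per_point <- max_range / 100

  point_tables <- lapply(seq_along(contribs), function(i) {
    cv <- names(contribs)[i]
    x <- cohort[[cv]]
    base <- min(contribs[[i]])
    if (is.numeric(x)) {
      vals <- range(x)
      pts <- (range(contribs[[i]]) - base) / lp_per_point
      data.frame(covariate = cv, value = as.character(vals), points = pts,
                 stringsAsFactors = FALSE)
    } else {
      lv <- levels(factor(x))
      pt <- vapply(lv, function(l) {
        mean(contribs[[i]][x == l]) - base
      }, numeric(1)) / lp_per_point
      data.frame(covariate = cv, value = lv, points = unname(pt),
                 stringsAsFactors = FALSE)
    }
  })
  lp_ref <- sum(vapply(contribs, min, numeric(1)))

  bh <- survival::basehaz(fit, centered = FALSE)
  structure(
    list(point_tables = do.call(rbind, point_tables),
         points_per_lp = 1 / lp_per_point,
         lp_per_point = lp_per_point,
         lp_ref = lp_ref,
         horizons_months = horizons_months,
         baseline_cumhaz = bh,
         fit = fit),
    class = "nomogram_model"
  )
}

#' Total nomogram points for patients
#' @param nomo a `nomogram_model`.
#' @param cohort data.frame of patients.
#' @return numeric vector of total points.
#' @export
nomogram_points <- function(nomo, cohort) {
  lp <- predict_lp(nomo$fit, cohort)
  (lp - nomo$lp_ref) / nomo$lp_per_point
}

# uncentred Cox linear predictor (reference = all-zero covariates)
predict_lp <- function(fit, newdata) {
  as.numeric(stats::predict(fit, newdata = newdata, type = "lp",
                            reference = "zero"))
}

#' Predicted survival probability at a horizon from a Cox model
#'
#' `S(t | x) = exp(-H0(t) * exp(lp(x)))` with the Efron baseline
#' cumulative hazard `H0` at reference (all-zero) covariates.
#'
#' @param nomo a `nomogram_model` (or pass a `cox_result` via
#'   [build_nomogram()] first).
#' @param cohort patients to predict for.
#' @param horizon_months evaluation time; must not exceed the last
#'   observed follow-up time.
#' @return numeric vector of survival probabilities.
#' @export
predict_survival <- function(nomo, cohort, horizon_months) {
  stopifnot(inherits(nomo, "nomogram_model"))
  bh <- nomo$baseline_cumhaz
  check_that(horizon_months <= max(bh$time),
             "horizon lies beyond the last observed follow-up time")
  h0 <- stats::approx(bh$time, bh$hazard, xout = horizon_months,
                      method = "constant", rule = 2, f = 0)$y
  lp <- predict_lp(nomo$fit, cohort)
  exp(-h0 * exp(lp))
}

#' Calibration of predicted survival against observed survival
#'
#' Bins patients by predicted survival probability at the horizon into
#' quantile bins and compares the mean prediction in each bin with the
#' Kaplan-Meier estimate at the horizon within that bin.
#'
#' @param predicted numeric vector of predicted S(horizon), one per
#'   patient.
#' @param cohort data.frame with `os_months`, `event`.
#' @param horizon_months evaluation time; must not exceed the last event
#'   time.
#' @param n_bins number of quantile bins (default 4).
#' @return data.frame with `bin`, `n`, `predicted`, `observed`.
#' @export
calibration_curve <- function(predicted, cohort, horizon_months,
                              n_bins = 4) {
  check_that(length(predicted) == nrow(cohort),
             "one prediction per patient is required")
  check_that(horizon_months <= max(cohort$os_months[cohort$event == 1]),
             "horizon lies beyond the last event time")
  qs <- stats::quantile(predicted, probs = seq(0, 1, length.out = n_bins + 1))
  qs <- unique(qs)
  bins <- if (length(qs) > 2) {
    cut(predicted, breaks = qs, include.lowest = TRUE)
  } else {
    factor(rep(1, length(predicted)))
  }
  out <- lapply(levels(droplevels(bins)), function(b) {
    ix <- which(bins == b)
    data.frame(
      bin = b, n = length(ix),
      predicted = mean(predicted[ix]),
      observed = km_at(cohort$os_months[ix], cohort$event[ix],
                       horizon_months)
    )
  })
  do.call(rbind, out)
}
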