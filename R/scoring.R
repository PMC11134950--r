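#' Published Feature-score coefficients
#'
#' The fixed linear weights combining the eight collagen features into the
#' Feature-score, applied to raw (unstandardized) feature values with zero
#' intercept.
#'
#' @return an object of class `score_coefficients`.
#' @export
published_score_coefficients <- function() {
  structure(
    list(
      weights = c(fea1 = -7.7656606, fea2 = -44.6439289, fea3 = 0.309178,
                  fea4 = 0.8884292, fea5 = -1.1665562, fea6 = 10.1583025,
                  fea7 = -0.1356464, fea8 = 0.6020531),
      intercept = 0,
      provenance = "published",
      penalty = NA_real_,
      standardization = NULL
    ),
    class = "score_coefficients"
  )
}

#' Compute the Feature-score
#'
#' Linear combination of the eight collagen features with the given
#' coefficient set. Refit coefficients carry the training-cohort
#' standardization, which is applied to the features before weighting;
#' published coefficients are applied to raw feature values.
#'
#' @param features a named numeric vector with entries `fea1`..`fea8`, or a
#'   data.frame/matrix with those columns (one score per row).
#' @param coeffs a `score_coefficients` object (default: published set).
#' @return numeric score(s).
#' @export
compute_feature_score <- function(features,
                                  coeffs = published_score_coefficients()) {
  stopifnot(inherits(coeffs, "score_coefficients"))
  feas <- paste0("fea", 1:8)
  if (is.data.frame(features) || is.matrix(features)) {
    m <- as.matrix(features[, intersect(feas, colnames(features)), drop = FALSE])
  } else {
    m <- matrix(features[intersect(feas, names(features))], nrow = 1,
                dimnames = list(NULL, intersect(feas, names(features))))
  }
  absent <- setdiff(feas, colnames(m))
  check_that(length(absent) == 0,
             paste("missing feature(s):", paste(absent, collapse = ", ")))
  m <- m[, feas, drop = FALSE]
  if (anyNA(m)) {
    bad <- feas[colSums(is.na(m)) > 0]
    stop("missing feature value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(coeffs$standardization)) {
    m <- sweep(sweep(m, 2, coeffs$standardization$center), 2,
               coeffs$standardization$scale, "/")
  }
  drop(m %*% coeffs$weights) + coeffs$intercept
}

#' Refit score coefficients by cross-validated ridge Cox regression
#'
#' Fits a ridge-penalized Cox partial-likelihood model of overall survival
#' on the z-scored eight features, choosing the penalty that maximizes the
#' mean cross-validated partial likelihood over `penalty_grid`. Fold
#' assignment is deterministic given `seed`.
#'
#' @param cohort data.frame with columns `fea1`..`fea8`, `os_months`,
#'   `event`.
#' @param penalty_grid ridge penalties (glmnet `lambda`) to search.
#' @param k_folds number of cross-validation folds.
#' @param seed integer seed for fold assignment.
#' @return a `score_coefficients` object with `provenance = "refit"`,
#'   weights on the z-score scale, and the standardization used.
#' @export
fit_ridge_cv <- function(cohort,
                         penalty_grid = 10^seq(3, -3, length.out = 31),
                         k_folds = 5, seed = 1L) {
  feas <- paste0("fea", 1:8)
  check_that(all(c(feas, "os_months", "event") %in% names(cohort)),
             "cohort must contain fea1..fea8, os_months, event")
  ok <- stats::complete.cases(cohort[, c(feas, "os_months", "event")])
  cohort <- cohort[ok, , drop = FALSE]
  check_that(nrow(cohort) >= 2 * k_folds,
             "need at least 2 * k_folds complete patients")
  x <- as.matrix(cohort[, feas])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature(s): ", paste(feas[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  ctr <- colMeans(x)
  xz <- sweep(sweep(x, 2, ctr), 2, sds, "/")
  y <- survival::Surv(cohort$os_months, cohort$event)
  lam <- sort(penalty_grid, decreasing = TRUE)
  foldid <- with_seed(seed, sample(rep_len(seq_len(k_folds), nrow(xz))))
  cvfit <- glmnet::cv.glmnet(xz, y, family = "cox", alpha = 0,
                             lambda = lam, foldid = foldid,
                             standardize = FALSE)
  w <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  names(w) <- feas
  beta_path <- as.matrix(cvfit$glmnet.fit$beta)
  structure(
    list(weights = w,
         intercept = 0,
         provenance = "refit",
         penalty = cvfit$lambda.min,
         standardization = list(center = ctr, scale = sds),
         path = data.frame(lambda = cvfit$glmnet.fit$lambda,
                           l2_norm = sqrt(colSums(beta_path^2)))),
    class = "score_coefficients"
  )
}
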