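#' Fit a Gaussian mixture model to image intensities
#'
#' Fits a univariate Gaussian mixture to the pixel intensity distribution
#' by expectation-maximization on the intensity histogram (intensity-only
#' features; no spatial terms). Initialization is k-means on the pixel
#' intensities under the given seed; EM stops when the relative change in
#' log-likelihood falls below `tol` or after `max_iter` iterations.
#' Components are reported sorted by ascending mean, so the first component
#' is always the background (dimmest) class.
#'
#' A small variance floor (0.25 squared intensity units) keeps the fit
#' stable on (near-)discrete intensity distributions, where an unfloored
#' component would collapse onto a single value.
#'
#' @param image integer matrix of 12-bit intensities.
#' @param n_components number of mixture components (>= 2), default 2:
#'   collagen versus background.
#' @param seed integer seed for the k-means initialization.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return an object of class `shg_gmm`: list with `n_components`, `means`,
#'   `variances`, `weights` (sorted by mean), `converged`, `log_lik`,
#'   `n_iter`, `seed`.
#' @export
fit_gmm <- function(image, n_components = 2, seed = 1L,
                    tol = 1e-4, max_iter = 200) {
  stopifnot(is.matrix(image) || is.numeric(image))
  vals <- as.numeric(image)
  check_that(all(vals >= 0 & vals <= 4095), "intensities must lie in [0, 4095]")
  check_that(n_components >= 2, "n_components must be >= 2")
  if (length(unique(vals)) < 2) {
    stop("degenerate input: image is constant, cannot fit a mixture",
         call. = FALSE)
  }

  # histogram representation: unique values with counts
  tb <- table(vals)
  x <- as.numeric(names(tb))
  w <- as.numeric(tb)
  n <- sum(w)
  var_floor <- 0.25

  init <- with_seed(seed, stats::kmeans(vals, centers = n_components,
                                        nstart = 3, iter.max = 50))
  mu <- as.numeric(init$centers)
  pr <- as.numeric(init$size) / length(vals)
  sg2 <- pmax(var_floor, as.numeric(init$withinss) / pmax(1, init$size))

  loglik <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(n_components), function(k) {
      pr[k] * stats::dnorm(x, mu[k], sqrt(sg2[k]))
    }, numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(w * log(tot))
    resp <- dens / tot
    nk <- colSums(w * resp)
    pr <- nk / n
    mu <- colSums(w * resp * x) / nk
    sg2 <- pmax(var_floor, vapply(seq_len(n_components), function(k) {
      sum(w * resp[, k] * (x - mu[k])^2) / nk[k]
    }, numeric(1)))
    if (is.finite(loglik) && abs(ll - loglik) <= tol * abs(loglik)) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
  }
  if (!converged) {
    warning("EM did not converge within ", max_iter, " iterations")
  }

  ord <- order(mu)
  structure(
    list(n_components = as.integer(n_components),
         means = mu[ord], variances = sg2[ord], weights = pr[ord],
         converged = converged, log_lik = loglik, n_iter = iter,
         seed = as.integer(seed)),
    class = "shg_gmm"
  )
}

#' Segment collagen foreground with a fitted mixture model
#'
#' Assigns every pixel to the mixture component with the highest posterior
#' probability; the collagen mask is the union of all components except the
#' lowest-mean (background) component. Connected foreground objects smaller
#' than `min_object_px` pixels are removed by default to stabilize
#' downstream fiber tracing.
#'
#' @param image integer matrix of 12-bit intensities.
#' @param model an `shg_gmm` from [fit_gmm()].
#' @param min_object_px remove foreground components smaller than this
#'   (set 0 to disable).
#' @param min_separation minimum Fisher-type separation
#'   `(mu_fg - mu_bg) / sqrt((var_fg + var_bg) / 2)` between the brightest
#'   and dimmest components for any foreground to be declared; below it the
#'   mixture is considered a split of pure background (no collagen class)
#'   and the mask is empty. Set 0 to disable.
#' @return logical matrix of the same shape (TRUE = collagen).
#' @export
segment_collagen <- function(image, model, min_object_px = 5,
                             min_separation = 3) {
  stopifnot(inherits(model, "shg_gmm"), is.matrix(image))
  k <- model$n_components
  sep <- (model$means[k] - model$means[1]) /
    sqrt((model$variances[k] + model$variances[1]) / 2)
  if (sep < min_separation) {
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  post <- posterior_by_intensity(model)
  lab <- apply(post, 1, which.max)
  mask <- matrix(lab[as.integer(image) + 1L] > 1L, nrow(image), ncol(image))
  if (min_object_px > 0 && any(mask)) {
    lbl <- EBImage::bwlabel(EBImage::Image(mask * 1))
    lbl <- matrix(as.integer(lbl), nrow(mask), ncol(mask))
    sizes <- tabulate(lbl)
    drop <- which(sizes < min_object_px)
    if (length(drop)) mask[lbl %in% drop] <- FALSE
  }
  mask
}

# posterior probability of each component at every intensity 0..4095
posterior_by_intensity <- function(model) {
  x <- 0:4095
  dens <- vapply(seq_len(model$n_components), function(k) {
    model$weights[k] * stats::dnorm(x, model$means[k],
                                    sqrt(model$variances[k]))
  }, numeric(length(x)))
  tot <- rowSums(dens)
  tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
  dens / tot
}

#' Pixel accuracy of a mask against ground truth
#' @param mask,truth logical matrices of equal shape.
#' @return fraction of pixels agreeing.
#' @export
mask_accuracy <- function(mask, truth) {
  stopifnot(all(dim(mask) == dim(truth)))
  mean((mask > 0) == (truth > 0))
}
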