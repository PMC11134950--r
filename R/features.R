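#' Collagen proportionate area (fea1)
#'
#' Fraction of image pixels classified as collagen.
#' @param mask logical matrix.
#' @return fraction in `[0, 1]`.
#' @export
area_fraction <- function(mask) {
  stopifnot(is.matrix(mask))
  mean(mask > 0)
}

#' Fiber number (fea2)
#'
#' Number of retained fibers per tile. If `pixel_size_um` is given and
#' `per_mm2 = TRUE`, the count is normalized to fibers per square
#' millimetre instead.
#' @param network a `fiber_network`.
#' @param per_mm2 report fibers per mm^2 rather than the raw count.
#' @param pixel_size_um physical pixel size in micrometres (required for
#'   `per_mm2`).
#' @return count (or density).
#' @export
fiber_count <- function(network, per_mm2 = FALSE, pixel_size_um = NULL) {
  n <- length(network$fibers)
  if (per_mm2) {
    check_that(!is.null(pixel_size_um) && pixel_size_um > 0,
               "pixel_size_um required for per-area fiber count")
    area_mm2 <- network$image_area * (pixel_size_um / 1000)^2
    return(n / area_mm2)
  }
  n
}

#' Mean fiber length (fea3)
#'
#' Mean per-fiber skeleton path length (sum of consecutive Euclidean
#' vertex steps), pixels.
#' @param network a `fiber_network`.
#' @return mean length, or `NA` for an empty network.
#' @export
fiber_length_mean <- function(network) {
  if (!length(network$fibers)) return(NA_real_)
  mean(vapply(network$fibers, `[[`, numeric(1), "path_length"))
}

#' Mean fiber width (fea4)
#'
#' Per-fiber width is twice the mean distance-transform value along the
#' fiber's skeleton vertices; fea4 averages it over fibers. Pixels.
#' @param network a `fiber_network`.
#' @return mean width, or `NA` for an empty network.
#' @export
fiber_width_mean <- function(network) {
  if (!length(network$fibers)) return(NA_real_)
  w <- vapply(network$fibers, `[[`, numeric(1), "mean_width")
  if (all(is.na(w))) return(NA_real_)
  mean(w, na.rm = TRUE)
}

#' Mean fiber straightness (fea5)
#'
#' Per-fiber straightness is the Euclidean distance between its endpoints
#' divided by its path length, in `(0, 1]`; closed loops (coincident
#' endpoints) are excluded with a warning.
#' @param network a `fiber_network`.
#' @return mean straightness, or `NA` if no valid fiber.
#' @export
fiber_straightness_mean <- function(network) {
  if (!length(network$fibers)) return(NA_real_)
  st <- vapply(network$fibers, function(f) {
    v <- f$vertices
    if (f$path_length <= 0) return(NA_real_)
    sqrt(sum((v[1, ] - v[nrow(v), ])^2)) / f$path_length
  }, numeric(1))
  loops <- !is.na(st) & st == 0
  if (any(loops)) {
    warning(sum(loops), " closed-loop fiber(s) excluded from straightness")
    st[loops] <- NA_real_
  }
  if (all(is.na(st))) return(NA_real_)
  mean(pmin(1, st), na.rm = TRUE)
}

#' Cross-link density (fea6)
#'
#' Number of cross-link points divided by the number of fibers.
#' @param network a `fiber_network` with cross-links detected.
#' @return cross-links per fiber, or `NA` for an empty network.
#' @export
crosslink_density <- function(network) {
  if (!length(network$fibers)) return(NA_real_)
  nrow(network$crosslinks) / length(network$fibers)
}

#' Mean cross-link spacing (fea7)
#'
#' Along each fiber, cross-link points are located at their nearest fiber
#' vertex and the geodesic (along-path) distances between consecutive
#' cross-links are collected; fea7 is the mean gap over all fibers with at
#' least two cross-links. Pixels.
#' @param network a `fiber_network` with cross-links detected.
#' @param match_tol maximum distance between a cross-link and a fiber
#'   vertex for the cross-link to be assigned to that fiber, pixels.
#' @return mean spacing, or `NA` if no fiber carries two cross-links.
#' @export
crosslink_spacing_mean <- function(network, match_tol = 2) {
  if (!length(network$fibers) || nrow(network$crosslinks) < 2) {
    return(NA_real_)
  }
  xl <- network$crosslinks
  gaps <- numeric(0)
  for (f in network$fibers) {
    v <- f$vertices
    if (nrow(v) < 2) next
    cum <- c(0, cumsum(sqrt(rowSums(diff(v)^2))))
    pos <- numeric(0)
    for (i in seq_len(nrow(xl))) {
      d2 <- (v[, 1] - xl[i, 1])^2 + (v[, 2] - xl[i, 2])^2
      j <- which.min(d2)
      if (d2[j] <= match_tol^2) pos <- c(pos, cum[j])
    }
    if (length(pos) >= 2) gaps <- c(gaps, diff(sort(pos)))
  }
  if (!length(gaps)) return(NA_real_)
  mean(gaps)
}

#' Collagen fiber orientation index (fea8)
#'
#' Quantifies collagen alignment from the 2D Fourier power spectrum. The
#' input (mask or raw intensity) is mean-centred, apodized with a Hann
#' window, and transformed; the DC term is removed and the spectrum is
#' restricted to a radial band. Power is attributed to the fiber axis
#' perpendicular to each frequency vector and summarized by the axial
#' (doubled-angle) circular order parameter
#' `R = |sum p * exp(2i * theta)| / sum p` in `[0, 1]`:
#' 1 for perfectly parallel fibers, 0 for an isotropic texture.
#'
#' @param x numeric or logical matrix (mask or intensity image).
#' @param r_min,r_max radial band limits as fractions of the image side.
#' @return order parameter in `[0, 1]`, or `NA` for constant input.
#' @export
orientation_index <- function(x, r_min = 0.02, r_max = 0.45) {
  stopifnot(is.matrix(x))
  x <- x * 1.0
  if (max(x) == min(x)) return(NA_real_)
  nr <- nrow(x); nc <- ncol(x)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xw <- (x - mean(x)) * (hann(nr) %o% hann(nc))
  P <- Mod(stats::fft(xw))^2
  # centred frequency coordinates
  fr <- ifelse(seq_len(nr) - 1 > nr / 2, seq_len(nr) - 1 - nr, seq_len(nr) - 1)
  fc <- ifelse(seq_len(nc) - 1 > nc / 2, seq_len(nc) - 1 - nc, seq_len(nc) - 1)
  U <- matrix(fr, nr, nc)
  V <- matrix(fc, nr, nc, byrow = TRUE)
  rad <- sqrt((U / nr)^2 + (V / nc)^2)
  band <- rad >= r_min & rad <= r_max
  if (!any(band)) return(NA_real_)
  p <- P[band]
  if (sum(p) <= 0) return(NA_real_)
  # frequency angle + 90 deg = fiber axis; doubling makes it axial
  theta_fiber <- atan2(U[band], V[band]) + pi / 2
  z <- sum(p * exp(2i * theta_fiber)) / sum(p)
  Mod(z)
}

#' Assemble the eight collagen features for one ROI
#'
#' @param mask logical collagen mask.
#' @param network `fiber_network` extracted from the mask.
#' @param image optional raw intensity matrix; used for fea8 when
#'   `orientation_on = "image"`.
#' @param orientation_on compute fea8 on the `"mask"` (default) or the raw
#'   `"image"`.
#' @param per_mm2 normalize fea2 per mm^2 (needs `pixel_size_um`).
#' @param pixel_size_um physical pixel size, micrometres.
#' @return named numeric vector `fea1`..`fea8`; undefined features are `NA`.
#' @export
compute_feature_vector <- function(mask, network, image = NULL,
                                   orientation_on = c("mask", "image"),
                                   per_mm2 = FALSE, pixel_size_um = NULL) {
  orientation_on <- match.arg(orientation_on)
  stopifnot(inherits(network, "fiber_network"))
  ori_src <- if (orientation_on == "image") {
    check_that(!is.null(image), "raw image required for orientation_on = 'image'")
    image
  } else {
    mask
  }
  v <- c(
    fea1 = area_fraction(mask),
    fea2 = as.numeric(fiber_count(network, per_mm2, pixel_size_um)),
    fea3 = fiber_length_mean(network),
    fea4 = fiber_width_mean(network),
    fea5 = fiber_straightness_mean(network),
    fea6 = crosslink_density(network),
    fea7 = crosslink_spacing_mean(network),
    fea8 = orientation_index(ori_src)
  )
  v
}

#' Average ROI feature vectors into patient-level features
#'
#' Per-feature arithmetic mean over the ROIs where the feature is defined;
#' a feature is missing for the patient only when it is missing in every
#' ROI.
#'
#' @param roi_features a list of named feature vectors (as returned by
#'   [compute_feature_vector()]), or a data.frame/matrix with columns
#'   `fea1`..`fea8`.
#' @return named numeric vector `fea1`..`fea8`.
#' @export
aggregate_patient <- function(roi_features) {
  if (is.list(roi_features) && !is.data.frame(roi_features)) {
    check_that(length(roi_features) >= 1, "at least one ROI is required")
    m <- do.call(rbind, roi_features)
  } else {
    m <- as.matrix(roi_features)
  }
  check_that(nrow(m) >= 1, "at least one ROI is required")
  feas <- paste0("fea", 1:8)
  check_that(all(feas %in% colnames(m)),
             "ROI features must contain columns fea1..fea8")
  out <- colMeans(m[, feas, drop = FALSE], na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}
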