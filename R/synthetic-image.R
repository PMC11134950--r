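#' Specification for a synthetic SHG-like fibrous image
#'
#' Collects the parameters controlling a phantom second-harmonic-generation
#' tile: how many fibers to draw, their length/width distributions, how wavy
#' and how aligned they are, whether they may cross, and the foreground /
#' background intensity model on the 12-bit scale.
#'
#' @param n_fibers number of fibers to draw (>= 0).
#' @param length_mean,length_sd fiber centerline length, pixels.
#' @param width_mean,width_sd fiber width, pixels (`width_mean >= 1`).
#' @param waviness dimensionless >= 0; 0 draws perfectly straight fibers.
#'   It scales the per-step heading perturbation of the random-walk
#'   centerline.
#' @param orientation_mean mean fiber axis, degrees in `[0, 180)`.
#' @param orientation_kappa von Mises concentration of the axial orientation
#'   distribution (0 = isotropic; `Inf` = all fibers parallel).
#' @param crossing_allowed if `FALSE`, fibers are placed with rejection
#'   sampling so that strokes stay at least `min_gap` pixels apart.
#' @param fg_intensity_mean,bg_intensity_mean mean fiber / background
#'   intensity, 12-bit units in `[0, 4095]`, foreground strictly brighter.
#' @param noise_sd additive Gaussian noise, 12-bit units.
#' @param seed integer seed; identical specs give byte-identical images.
#' @param size image side in pixels (square tile), default 512.
#' @param min_gap minimum stroke separation when `crossing_allowed = FALSE`.
#' @return an object of class `fiber_spec`.
#' @export
fiber_spec <- function(n_fibers,
                       length_mean = 120, length_sd = 25,
                       width_mean = 5, width_sd = 1,
                       waviness = 0.2,
                       orientation_mean = 0, orientation_kappa = 2,
                       crossing_allowed = TRUE,
                       fg_intensity_mean = 1500,
                       bg_intensity_mean = 150,
                       noise_sd = 80,
                       seed = 1L,
                       size = 512L,
                       min_gap = 3) {
  spec <- list(
    n_fibers = as.integer(n_fibers),
    length_mean = length_mean, length_sd = length_sd,
    width_mean = width_mean, width_sd = width_sd,
    waviness = waviness,
    orientation_mean = orientation_mean,
    orientation_kappa = orientation_kappa,
    crossing_allowed = isTRUE(crossing_allowed),
    fg_intensity_mean = fg_intensity_mean,
    bg_intensity_mean = bg_intensity_mean,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    size = as.integer(size),
    min_gap = min_gap
  )
  class(spec) <- "fiber_spec"
  validate_fiber_spec(spec)
  spec
}

validate_fiber_spec <- function(spec) {
  check_that(spec$n_fibers >= 0, "n_fibers must be >= 0")
  check_that(spec$length_mean > 0, "length_mean must be > 0")
  check_that(spec$width_mean >= 1, "width_mean must be >= 1")
  check_that(spec$waviness >= 0, "waviness must be >= 0")
  check_that(spec$orientation_mean >= 0 && spec$orientation_mean < 180,
             "orientation_mean must lie in [0, 180)")
  check_that(spec$orientation_kappa >= 0, "orientation_kappa must be >= 0")
  check_that(spec$fg_intensity_mean > spec$bg_intensity_mean,
             "fg_intensity_mean must exceed bg_intensity_mean")
  for (f in c("fg_intensity_mean", "bg_intensity_mean")) {
    check_that(spec[[f]] >= 0 && spec[[f]] <= 4095,
               sprintf("%s must lie in [0, 4095]", f))
  }
  check_that(spec$noise_sd >= 0, "noise_sd must be >= 0")
  check_that(spec$size >= 16, "size must be >= 16 pixels")
  invisible(spec)
}

# Pixel indices covered by a polyline dilated to the given radius.
# vertices: n x 2 matrix of (row, col) continuous coordinates, 1-based.
rasterize_polyline <- function(vertices, radius, nr, nc) {
  if (nrow(vertices) == 0) return(integer(0))
  # resample densely along the path so the stamped disks overlap
  pts <- vertices
  if (nrow(vertices) > 1) {
    segs <- diff(vertices)
    steps <- sqrt(rowSums(segs^2))
    dense <- vector("list", nrow(segs))
    for (i in seq_len(nrow(segs))) {
      k <- max(1L, ceiling(steps[i] / 0.5))
      t <- seq(0, 1, length.out = k + 1L)[-1L]
      dense[[i]] <- cbind(vertices[i, 1] + t * segs[i, 1],
                          vertices[i, 2] + t * segs[i, 2])
    }
    pts <- rbind(vertices[1, , drop = FALSE], do.call(rbind, dense))
  }
  r_int <- ceiling(radius)
  off <- expand.grid(dr = -r_int:r_int, dc = -r_int:r_int)
  off <- off[off$dr^2 + off$dc^2 <= radius^2 + 1e-9, , drop = FALSE]
  rr <- rep(round(pts[, 1]), each = nrow(off)) + off$dr
  cc <- rep(round(pts[, 2]), each = nrow(off)) + off$dc
  keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  unique((cc[keep] - 1L) * nr + rr[keep])
}

# Random-walk centerline grown symmetrically from a center point.
# Returns an n x 2 matrix of (row, col) coordinates.
walk_centerline <- function(center, theta, length, waviness,
                            step = 2, box = NULL) {
  n_half <- max(1L, floor(length / 2 / step))
  grow <- function(heading0) {
    pos <- center
    heading <- heading0
    out <- matrix(NA_real_, n_half, 2)
    k <- 0L
    for (i in seq_len(n_half)) {
      heading <- heading + stats::rnorm(1, 0, 0.15 * waviness)
      cand <- pos + step * c(sin(heading), cos(heading))
      if (!is.null(box) &&
          (cand[1] < box[1] || cand[1] > box[2] ||
           cand[2] < box[3] || cand[2] > box[4])) break
      pos <- cand
      k <- i
      out[i, ] <- pos
    }
    out[seq_len(k), , drop = FALSE]
  }
  fwd <- grow(theta)
  bwd <- grow(theta + pi)
  rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
        matrix(center, 1, 2),
        fwd)
}

#' Generate a synthetic SHG-like fiber image with ground truth
#'
#' Draws fibers as smoothed random-walk polylines (step ~2 px, per-step
#' heading perturbation scaled by `waviness`), dilates each to its sampled
#' width, and composes a 12-bit intensity image with additive Gaussian
#' noise. Orientations are drawn from a von Mises distribution on the
#' half-circle (axial data, period 180 degrees).
#'
#' @param spec a [fiber_spec()].
#' @return a list with elements
#'   \describe{
#'     \item{image}{integer matrix, values in `[0, 4095]`.}
#'     \item{truth}{ground truth: `fiber_centerlines` (list of (row, col)
#'       matrices), `fiber_widths`, `fiber_lengths` (path length of each
#'       centerline, pixels), `true_orientations` (degrees in `[0,180)`),
#'       `true_mask` (logical matrix) and `true_crossings` (matrix of
#'       (row, col) crossing coordinates).}
#'   }
#' @export
generate_fiber_image <- function(spec) {
  validate_fiber_spec(spec)
  with_seed(spec$seed, {
    n <- spec$size
    mask <- matrix(FALSE, n, n)
    territory <- matrix(FALSE, n, n)
    centerlines <- vector("list", spec$n_fibers)
    widths <- numeric(spec$n_fibers)
    lengths <- numeric(spec$n_fibers)
    orientations <- numeric(spec$n_fibers)

    if (spec$n_fibers > 0) {
      mu_axial <- spec$orientation_mean * pi / 180
      thetas <- (rvonmises(spec$n_fibers, 2 * mu_axial,
                           spec$orientation_kappa) / 2) %% pi
      for (i in seq_len(spec$n_fibers)) {
        L <- max(8, stats::rnorm(1, spec$length_mean, spec$length_sd))
        w <- max(1, stats::rnorm(1, spec$width_mean, spec$width_sd))
        radius <- w / 2
        margin <- ceiling(radius) + 2
        box <- c(margin, n - margin + 1, margin, n - margin + 1)
        placed <- FALSE
        for (try in 1:300) {
          # keep the likely extent of the fiber inside the tile; after many
          # failures fall back on border clipping alone
          relax <- if (try > 200) 0 else 1
          inset_r <- min(relax * abs(sin(thetas[i])) * L / 2,
                         (n - 2 * margin) / 2 - 1)
          inset_c <- min(relax * abs(cos(thetas[i])) * L / 2,
                         (n - 2 * margin) / 2 - 1)
          center <- c(stats::runif(1, margin + inset_r, n - margin - inset_r),
                      stats::runif(1, margin + inset_c, n - margin - inset_c))
          cl <- walk_centerline(center, thetas[i], L, spec$waviness,
                                step = 2, box = box)
          if (nrow(cl) < 3) next
          if (!spec$crossing_allowed) {
            claim <- rasterize_polyline(cl, radius + spec$min_gap / 2, n, n)
            if (any(territory[claim])) next
            territory[claim] <- TRUE
          }
          px <- rasterize_polyline(cl, radius, n, n)
          mask[px] <- TRUE
          centerlines[[i]] <- cl
          widths[i] <- w
          lengths[i] <- sum(sqrt(rowSums(diff(cl)^2)))
          orientations[i] <- (thetas[i] * 180 / pi) %% 180
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("could not place fiber ", i,
               " without crossings; lower n_fibers or the image density",
               call. = FALSE)
        }
      }
    }

    crossings <- find_centerline_crossings(centerlines, widths)
    img <- spec$bg_intensity_mean +
      (spec$fg_intensity_mean - spec$bg_intensity_mean) * mask
    if (spec$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    }
    img <- matrix(as.integer(pmin(4095, pmax(0, round(img)))), n, n)

    list(
      image = img,
      truth = list(
        fiber_centerlines = centerlines,
        fiber_widths = widths,
        fiber_lengths = lengths,
        true_orientations = orientations,
        true_mask = mask,
        true_crossings = crossings
      )
    )
  })
}

# Ground-truth crossings: pairs of centerlines whose strokes overlap.
# Returns a matrix of (row, col) coordinates, one per contact cluster.
find_centerline_crossings <- function(centerlines, widths) {
  n <- length(centerlines)
  hits <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- centerlines[[i]]
        b <- centerlines[[j]]
        if (is.null(a) || is.null(b)) next
        tol <- (widths[i] + widths[j]) / 2
        d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
        idx <- which(d2 <= tol^2, arr.ind = TRUE)
        if (nrow(idx) > 0) {
          # one representative contact point per touching pair
          pt <- (a[idx[1, 1], ] + b[idx[1, 2], ]) / 2
          hits[[length(hits) + 1L]] <- pt
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  }
  out <- do.call(rbind, hits)
  colnames(out) <- c("row", "col")
  out
}
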