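#' Skeletonize a collagen mask
#'
#' Thins a binary collagen mask to a one-pixel-wide, topology-preserving
#' medial axis (Zhang-Suen thinning) and samples the Euclidean distance
#' transform of the mask on the skeleton pixels. The distance is measured
#' from the pixel center to the mask boundary (distance to the nearest
#' background pixel minus half a pixel), so a solid bar 5 px tall has
#' skeleton distance 2.5 px and local width `2 * distance = 5` px.
#'
#' @param mask logical matrix (TRUE = collagen foreground).
#' @return a list of class `shg_skeleton` with `skeleton_mask` (logical
#'   matrix) and `distance_map` (numeric matrix, NA off the skeleton,
#'   >= 0.5 on it).
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  skel <- prune_to_unit_width(thin_zhang_suen(mask))
  dm <- matrix(NA_real_, nrow(mask), ncol(mask))
  if (any(skel)) {
    edt <- EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean")
    edt <- matrix(as.numeric(edt), nrow(mask), ncol(mask))
    dm[skel] <- pmax(0.5, edt[skel] - 0.5)
  }
  structure(list(skeleton_mask = skel, distance_map = dm),
            class = "shg_skeleton")
}

# Zhang-Suen thinning, vectorized over the whole matrix.
# Neighbours P2..P9 clockwise starting at north; works on logical matrices.
thin_zhang_suen <- function(m) {
  m <- m > 0
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- lapply(list(
        c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
        c(1, 0), c(1, -1), c(0, -1), c(-1, -1)
      ), function(o) shift_matrix(m, o[1], o[2], fill = FALSE))
      # p[[1]]=P2 (N), p[[2]]=P3 (NE), ..., p[[8]]=P9 (NW)
      b <- Reduce(`+`, p)
      a <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) {
        nxt <- if (k == 8) 1 else k + 1
        a <- a + (!p[[k]] & p[[nxt]])
      }
      if (sub == 1) {
        c1 <- !(p[[1]] & p[[3]] & p[[5]])   # P2*P4*P6 == 0
        c2 <- !(p[[3]] & p[[5]] & p[[7]])   # P4*P6*P8 == 0
      } else {
        c1 <- !(p[[1]] & p[[3]] & p[[7]])   # P2*P4*P8 == 0
        c2 <- !(p[[1]] & p[[5]] & p[[7]])   # P2*P6*P8 == 0
      }
      del <- m & b >= 2 & b <= 6 & a == 1 & c1 & c2
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Sequentially delete 8-simple pixels (foreground neighbours form a single
# 8-connected component, pixel is not an endpoint). Zhang-Suen leaves
# diagonal strokes as two-pixel staircases; this pass reduces them to unit
# width without changing topology.
prune_to_unit_width <- function(m) {
  offs <- neighbour_offsets()
  # adjacency between ring positions (as pixels in the 3x3 neighbourhood)
  ring_adj <- abs(outer(offs[, 1], offs[, 1], "-")) <= 1 &
    abs(outer(offs[, 2], offs[, 2], "-")) <= 1
  diag(ring_adj) <- FALSE
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    changed <- FALSE
    for (lin in which(m)) {
      r <- (lin - 1L) %% nr + 1L
      cc <- (lin - 1L) %/% nr + 1L
      rr <- r + offs[, 1]; ccn <- cc + offs[, 2]
      ok <- rr >= 1 & rr <= nr & ccn >= 1 & ccn <= nc
      fg <- logical(8)
      fg[ok] <- m[cbind(rr[ok], ccn[ok])]
      b <- sum(fg)
      if (b < 2 || b > 6) next
      # (8,4)-simple point needs a 4-adjacent background pixel, or its
      # deletion would open a background hole (e.g. a plus-sign centre);
      # off-image counts as background
      orth <- c(2L, 4L, 5L, 7L)
      if (sum(ok[orth]) == 4L && all(fg[orth])) next
      # count connected components among foreground ring pixels
      ids <- which(fg)
      comp <- seq_along(ids)
      for (i in seq_along(ids)) {
        for (j in seq_along(ids)) {
          if (i < j && ring_adj[ids[i], ids[j]]) {
            old <- comp[j]; comp[comp == old] <- comp[i]
          }
        }
      }
      if (length(unique(comp)) == 1L) {
        m[lin] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}
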