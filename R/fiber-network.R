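#' Extract a fiber network from a skeleton
#'
#' Decomposes the one-pixel skeleton into individual fibers. Skeleton
#' pixels with three or more neighbours form junction clusters; the chains
#' between junctions/endpoints are traced into ordered vertex lists, spur
#' branches shorter than `spur_length` are pruned, and at each junction the
#' two branches whose directions continue most smoothly (deviation below
#' `continuation_angle`) are joined into a single fiber
#' (`junction_mode = "join"`). With `junction_mode = "split"` every chain
#' terminates at junctions. Fibers shorter than `min_fiber_length` are
#' discarded. Cross-link points are then detected with
#' [detect_crosslinks()].
#'
#' @param skel an `shg_skeleton` from [skeletonize_mask()].
#' @param min_fiber_length minimum retained fiber path length, pixels.
#' @param spur_length spur branches shorter than this are pruned, pixels.
#' @param continuation_angle maximum deviation from straight continuation
#'   at a junction, degrees.
#' @param junction_mode `"join"` (default) or `"split"`.
#' @return an object of class `fiber_network`: list with `fibers` (each a
#'   list with `vertices` (n x 2 matrix, (row, col)), `path_length`,
#'   `mean_width`), `crosslinks` (m x 2 matrix), and `image_area` (pixels^2).
#' @export
extract_fiber_network <- function(skel,
                                  min_fiber_length = 10,
                                  spur_length = 5,
                                  continuation_angle = 45,
                                  junction_mode = c("join", "split")) {
  junction_mode <- match.arg(junction_mode)
  stopifnot(inherits(skel, "shg_skeleton"))
  sm <- skel$skeleton_mask
  area <- as.numeric(nrow(sm)) * ncol(sm)
  empty <- structure(
    list(fibers = list(),
         crosslinks = matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("row", "col"))),
         image_area = area),
    class = "fiber_network"
  )
  if (!any(sm)) return(empty)

  coords <- which(sm, arr.ind = TRUE)
  n <- nrow(coords)
  idmat <- matrix(0L, nrow(sm), ncol(sm))
  idmat[sm] <- seq_len(n)

  # adjacency lists over the 8-neighbourhood
  offs <- neighbour_offsets()
  adj <- vector("list", n)
  pairs_a <- integer(0); pairs_b <- integer(0)
  for (k in seq_len(nrow(offs))) {
    sh <- shift_matrix(idmat, offs[k, 1], offs[k, 2], fill = 0L)
    hit <- sm & sh > 0L
    if (any(hit)) {
      pairs_a <- c(pairs_a, idmat[hit])
      pairs_b <- c(pairs_b, sh[hit])
    }
  }
  if (length(pairs_a)) {
    for (i in seq_len(n)) adj[[i]] <- integer(0)
    sp <- split(pairs_b, pairs_a)
    adj[as.integer(names(sp))] <- lapply(sp, sort)
  } else {
    adj <- replicate(n, integer(0), simplify = FALSE)
  }
  deg <- lengths(adj)
  is_junction <- deg >= 3L

  # junction clusters: connected components among junction pixels
  jcluster <- integer(n)
  jreps <- list()
  if (any(is_junction)) {
    todo <- which(is_junction)
    cl <- 0L
    seen <- logical(n)
    for (s in todo) {
      if (seen[s]) next
      cl <- cl + 1L
      queue <- s
      members <- integer(0)
      seen[s] <- TRUE
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        members <- c(members, v)
        nb <- adj[[v]]
        nb <- nb[is_junction[nb] & !seen[nb]]
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
      jcluster[members] <- cl
      cen <- colMeans(coords[members, , drop = FALSE])
      d2 <- (coords[members, 1] - cen[1])^2 + (coords[members, 2] - cen[2])^2
      jreps[[cl]] <- members[which.min(d2)]
    }
  }

  # chains: ordered walks over non-junction pixels
  chains <- trace_chains(adj, coords, is_junction)

  # attach chain ends to junction clusters (0 = free end)
  end_cluster <- matrix(0L, length(chains), 2)
  for (k in seq_along(chains)) {
    ch <- chains[[k]]
    for (e in 1:2) {
      endpix <- if (e == 1) ch[[1]] else ch[[length(ch)]]
      jn <- adj[[endpix]]
      jn <- jn[is_junction[jn]]
      if (length(jn)) {
        d2 <- (coords[jn, 1] - coords[endpix, 1])^2 +
          (coords[jn, 2] - coords[endpix, 2])^2
        end_cluster[k, e] <- jcluster[jn[which.min(d2)]]
      }
    }
  }

  chain_len <- vapply(chains, function(ch) {
    if (length(ch) < 2) return(0)
    sum(sqrt(rowSums(diff(coords[ch, , drop = FALSE])^2)))
  }, numeric(1))

  # prune spurs: short chains dangling off a junction
  spur <- chain_len < spur_length &
    ((end_cluster[, 1] > 0) + (end_cluster[, 2] > 0)) == 1L
  keep <- which(!spur)
  chains <- chains[keep]
  end_cluster <- end_cluster[keep, , drop = FALSE]
  chain_len <- chain_len[keep]

  # branch joining at junctions
  pairing <- matrix(0L, length(chains), 2)  # partner slot id per chain end
  slot_id <- function(k, e) 2L * (k - 1L) + e
  slot_partner <- integer(2L * length(chains))
  if (junction_mode == "join" && length(jreps)) {
    for (cl in seq_along(jreps)) {
      rep_xy <- coords[jreps[[cl]], ]
      br <- which(end_cluster == cl, arr.ind = TRUE)  # (chain, end)
      if (nrow(br) < 2) next
      dirs <- matrix(NA_real_, nrow(br), 2)
      for (b in seq_len(nrow(br))) {
        ch <- chains[[br[b, 1]]]
        e <- br[b, 2]
        d <- min(4L, length(ch) - 1L)
        probe <- if (e == 1) ch[[1L + d]] else ch[[length(ch) - d]]
        v <- coords[probe, ] - rep_xy
        nv <- sqrt(sum(v^2))
        dirs[b, ] <- if (nv > 0) v / nv else c(0, 0)
      }
      cand <- list()
      for (a in seq_len(nrow(br) - 1)) {
        for (b in (a + 1):nrow(br)) {
          if (br[a, 1] == br[b, 1]) next  # don't join a chain to itself
          cosang <- sum(dirs[a, ] * dirs[b, ])
          dev <- 180 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi
          if (dev <= continuation_angle) {
            cand[[length(cand) + 1L]] <- c(
              a, b, dev, chain_len[br[a, 1]] + chain_len[br[b, 1]]
            )
          }
        }
      }
      if (length(cand)) {
        cm <- do.call(rbind, cand)
        ord <- order(cm[, 3], -cm[, 4])
        used <- logical(nrow(br))
        for (r in ord) {
          a <- cm[r, 1]; b <- cm[r, 2]
          if (used[a] || used[b]) next
          sa <- slot_id(br[a, 1], br[a, 2])
          sb <- slot_id(br[b, 1], br[b, 2])
          if (slot_partner[sa] || slot_partner[sb]) next
          slot_partner[sa] <- sb
          slot_partner[sb] <- sa
          used[a] <- used[b] <- TRUE
        }
      }
    }
  }

  # assemble fibers by following pairings through junctions
  fibers <- list()
  visited <- logical(length(chains))
  for (k0 in seq_along(chains)) {
    if (visited[k0]) next
    # walk backwards from (k0, end 1) to the first chain of this fiber
    k <- k0; enter <- 1L
    steps <- 0L
    repeat {
      p <- slot_partner[slot_id(k, enter)]
      if (p == 0L) break
      k2 <- (p + 1L) %/% 2L
      e2 <- if (p %% 2L == 1L) 1L else 2L
      k <- k2
      enter <- if (e2 == 1L) 2L else 1L
      steps <- steps + 1L
      if ((k == k0 && enter == 1L) || steps > 2L * length(chains)) break
    }
    visited_local <- logical(length(chains))
    # now walk rightward from (k, start at end `enter`)
    verts <- integer(0)
    cur <- k; from <- enter
    repeat {
      visited_local[cur] <- TRUE
      ch <- chains[[cur]]
      if (from == 2L) ch <- rev(ch)
      # insert junction representative between chains
      exit_end <- if (from == 1L) 2L else 1L
      entry_cl <- end_cluster[cur, from]
      if (length(verts) == 0 && entry_cl > 0) {
        verts <- c(jreps[[entry_cl]])
      }
      verts <- c(verts, ch)
      exit_cl <- end_cluster[cur, exit_end]
      p <- slot_partner[slot_id(cur, exit_end)]
      if (p == 0L) {
        if (exit_cl > 0) verts <- c(verts, jreps[[exit_cl]])
        break
      }
      if (exit_cl > 0) verts <- c(verts, jreps[[exit_cl]])
      k2 <- (p + 1L) %/% 2L
      e2 <- if (p %% 2L == 1L) 1L else 2L
      if (visited_local[k2]) break  # closed loop
      cur <- k2; from <- e2
    }
    visited <- visited | visited_local
    verts <- verts[!duplicated(verts) | c(TRUE, diff(verts) != 0)]
    vm <- coords[verts, , drop = FALSE]
    fibers[[length(fibers) + 1L]] <- make_fiber(vm, skel$distance_map)
  }

  # drop short fibers, canonical endpoint ordering
  plen <- vapply(fibers, `[[`, numeric(1), "path_length")
  fibers <- fibers[plen >= min_fiber_length]
  fibers <- lapply(fibers, canonical_fiber)

  net <- structure(list(fibers = fibers,
                        crosslinks = empty$crosslinks,
                        image_area = area),
                   class = "fiber_network")
  detect_crosslinks(net)
}

make_fiber <- function(vm, distance_map) {
  pl <- if (nrow(vm) < 2) 0 else sum(sqrt(rowSums(diff(vm)^2)))
  dvals <- distance_map[vm]
  list(
    vertices = unname(vm),
    path_length = pl,
    mean_width = if (all(is.na(dvals))) NA_real_ else
      2 * mean(dvals, na.rm = TRUE)
  )
}

canonical_fiber <- function(f) {
  v <- f$vertices
  a <- v[1, ]; b <- v[nrow(v), ]
  if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])) {
    f$vertices <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  }
  f
}

# Order non-junction pixels into chains by walking along the skeleton.
trace_chains <- function(adj, coords, is_junction) {
  n <- length(adj)
  in_chain <- !is_junction
  visited <- logical(n)
  chains <- list()
  # prefer starting from chain pixels with <=1 chain neighbour (chain ends)
  chain_deg <- vapply(seq_len(n), function(i) {
    if (!in_chain[i]) return(99L)
    sum(in_chain[adj[[i]]])
  }, integer(1))
  order_start <- c(which(in_chain & chain_deg <= 1L),
                   which(in_chain & chain_deg > 1L))
  for (s in order_start) {
    if (visited[s] || !in_chain[s]) next
    path <- integer(0)
    cur <- s
    repeat {
      visited[cur] <- TRUE
      path <- c(path, cur)
      nb <- adj[[cur]]
      nb <- nb[in_chain[nb] & !visited[nb]]
      if (!length(nb)) break
      if (length(nb) > 1) {
        # prefer orthogonal neighbours to traverse thinning triangles
        d2 <- (coords[nb, 1] - coords[cur, 1])^2 +
          (coords[nb, 2] - coords[cur, 2])^2
        nb <- nb[order(d2)]
      }
      cur <- nb[[1]]
    }
    chains[[length(chains) + 1L]] <- path
  }
  chains
}

#' Detect cross-link points in a fiber network
#'
#' A cross-link is a vertex shared by at least two fibers. Shared
#' coordinates closer than `merge_tol` pixels are merged into a single
#' cross-link (junction pixel clusters on thick crossings would otherwise
#' be double-counted); the reported coordinate is the cluster centroid,
#' rounded to the nearest pixel.
#'
#' @param network a `fiber_network`.
#' @param merge_tol merge radius in pixels.
#' @return the network with its `crosslinks` field populated.
#' @export
detect_crosslinks <- function(network, merge_tol = 2) {
  stopifnot(inherits(network, "fiber_network"))
  fibers <- network$fibers
  if (length(fibers) < 2) {
    network$crosslinks <- matrix(numeric(0), 0, 2,
                                 dimnames = list(NULL, c("row", "col")))
    return(network)
  }
  keys <- lapply(fibers, function(f) {
    unique(paste(f$vertices[, 1], f$vertices[, 2]))
  })
  tab <- table(unlist(keys))
  shared <- names(tab)[tab >= 2]
  if (!length(shared)) {
    network$crosslinks <- matrix(numeric(0), 0, 2,
                                 dimnames = list(NULL, c("row", "col")))
    return(network)
  }
  xy <- do.call(rbind, lapply(strsplit(shared, " "), as.numeric))
  cl <- cluster_points(xy, merge_tol)
  cent <- do.call(rbind, lapply(split(seq_len(nrow(xy)), cl), function(ix) {
    round(colMeans(xy[ix, , drop = FALSE]))
  }))
  colnames(cent) <- c("row", "col")
  network$crosslinks <- unname(cent)
  colnames(network$crosslinks) <- c("row", "col")
  network
}

# single-linkage clustering of points with distance threshold
cluster_points <- function(xy, tol) {
  m <- nrow(xy)
  cl <- seq_len(m)
  if (m > 1) {
    d <- as.matrix(stats::dist(xy))
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (d[i, j] <= tol) {
          old <- cl[j]; new <- cl[i]
          cl[cl == old] <- new
        }
      }
    }
  }
  match(cl, unique(cl))
}
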