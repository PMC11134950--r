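# Shared fixtures: hand-built masks and networks, plus an independent
# brute-force cross-link oracle.

rot90m <- function(m) t(m)[, nrow(m):1]

# fiber_network from explicit vertex matrices (row, col)
hand_network <- function(vms, area = 64 * 64) {
  fibers <- lapply(vms, function(vm) {
    vm <- as.matrix(vm)
    list(vertices = unname(vm),
         path_length = if (nrow(vm) < 2) 0 else
           sum(sqrt(rowSums(diff(vm)^2))),
         mean_width = NA_real_)
  })
  structure(list(fibers = fibers,
                 crosslinks = matrix(numeric(0), 0, 2),
                 image_area = area),
            class = "fiber_network")
}

# Independent cross-link oracle: scan all pairs of fibers for shared
# vertices, then count clusters of shared points closer than merge_tol
# using a union-find unrelated to the package implementation.
brute_crosslink_count <- function(network, merge_tol = 2) {
  keys <- lapply(network$fibers, function(f) {
    unique(paste(round(f$vertices[, 1]), round(f$vertices[, 2])))
  })
  shared <- character(0)
  nf <- length(keys)
  if (nf >= 2) {
    for (i in seq_len(nf - 1)) {
      for (j in (i + 1):nf) {
        shared <- c(shared, intersect(keys[[i]], keys[[j]]))
      }
    }
  }
  shared <- unique(shared)
  if (!length(shared)) return(0L)
  xy <- do.call(rbind, lapply(strsplit(shared, " "), as.numeric))
  parent <- seq_len(nrow(xy))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(xy))) {
    for (j in seq_len(nrow(xy))) {
      if (i < j && sqrt(sum((xy[i, ] - xy[j, ])^2)) <= merge_tol) {
        parent[find(j)] <<- find(i)
      }
    }
  }
  length(unique(vapply(seq_len(nrow(xy)), find, integer(1))))
}

# thick X mask: two strokes crossing at ~90 degrees
x_mask <- function(n = 80) {
  x <- matrix(FALSE, n, n)
  for (i in 0:(n - 21)) {
    x[10 + i, 10 + i] <- TRUE
    x[n - 10 - i, 10 + i] <- TRUE
  }
  xd <- x
  for (o in list(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))) {
    xd <- xd | collascore:::shift_matrix(x, o[1], o[2], FALSE)
  }
  xd
}

# T mask: horizontal bar with a stem meeting it at a right angle
t_mask <- function() {
  tm <- matrix(FALSE, 80, 80)
  tm[20:22, 10:69] <- TRUE
  tm[20:60, 39:41] <- TRUE
  tm
}

# 3 horizontal x 3 vertical bars
grid_mask <- function(n = 200, at = c(50, 100, 150), half = 1, margin = 30) {
  g <- matrix(FALSE, n, n)
  for (c0 in at) {
    g[margin:(n - margin), (c0 - half):(c0 + half)] <- TRUE
    g[(c0 - half):(c0 + half), margin:(n - margin)] <- TRUE
  }
  g
}

net_of_mask <- function(m, ...) {
  extract_fiber_network(skeletonize_mask(m), ...)
}

total_path_length <- function(net) {
  if (!length(net$fibers)) return(0)
  sum(vapply(net$fibers, `[[`, numeric(1), "path_length"))
}
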