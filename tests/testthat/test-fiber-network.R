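test_that("skeleton of a solid bar is its medial line with analytic distance", {
  m <- matrix(FALSE, 64, 128)
  m[30:34, 10:109] <- TRUE  # 5 px tall, 100 px long
  sk <- skeletonize_mask(m)
  px <- which(sk$skeleton_mask, arr.ind = TRUE)
  expect_equal(unique(px[, 1]), 32)  # single medial row
  interior <- px[, 2] > 20 & px[, 2] < 100
  expect_equal(unique(sk$distance_map[sk$skeleton_mask][interior]), 2.5)
  expect_true(all(sk$skeleton_mask[!m] == FALSE))  # skeleton inside mask
})

test_that("empty masks skeletonize to empty skeletons and networks", {
  sk <- skeletonize_mask(matrix(FALSE, 32, 32))
  expect_equal(sum(sk$skeleton_mask), 0)
  net <- extract_fiber_network(sk)
  expect_length(net$fibers, 0)
  expect_equal(nrow(net$crosslinks), 0)
})

test_that("a plus-sign mask skeletonizes to one 4-way junction", {
  p <- matrix(FALSE, 64, 64)
  p[30:32, 10:54] <- TRUE
  p[10:54, 30:32] <- TRUE
  sk <- skeletonize_mask(p)
  sm <- sk$skeleton_mask
  offs <- collascore:::neighbour_offsets()
  nb <- Reduce(`+`, lapply(seq_len(nrow(offs)), function(k) {
    collascore:::shift_matrix(sm, offs[k, 1], offs[k, 2], FALSE)
  }))
  # exactly one junction pixel neighbourhood, containing a 4-way pixel
  jmask <- sm & nb >= 3
  expect_true(any(nb[sm] == 4))
  lbl <- EBImage::bwlabel(EBImage::Image(jmask * 1))
  expect_equal(max(as.integer(lbl)), 1)
})

test_that("a single straight path becomes one ordered fiber", {
  m <- matrix(FALSE, 32, 64)
  m[16, 5:60] <- TRUE
  net <- net_of_mask(m)
  expect_length(net$fibers, 1)
  v <- net$fibers[[1]]$vertices
  expect_equal(v[, 1], rep(16, nrow(v)))
  expect_equal(v[, 2], 5:60)  # ordered along the path
  expect_equal(net$fibers[[1]]$path_length, 55)
})

test_that("branches continue straight through an X and split at a T", {
  nx <- net_of_mask(x_mask())
  expect_length(nx$fibers, 2)
  expect_equal(nrow(nx$crosslinks), 1)
  # each fiber passes through the junction: straightness near 1
  st <- vapply(nx$fibers, function(f) {
    v <- f$vertices
    sqrt(sum((v[1, ] - v[nrow(v), ])^2)) / f$path_length
  }, numeric(1))
  expect_true(all(st > 0.95))

  nt <- net_of_mask(t_mask())
  expect_length(nt$fibers, 2)
  lens <- sort(vapply(nt$fibers, `[[`, numeric(1), "path_length"))
  expect_lt(lens[1], lens[2])  # stem shorter than the bar
  expect_equal(nrow(nt$crosslinks), 1)

  # split mode cuts the X into four branches instead
  nxs <- net_of_mask(x_mask(), junction_mode = "split")
  expect_length(nxs$fibers, 4)
})

test_that("cross-link counts match the brute-force shared-vertex oracle", {
  # two parallel fibers: none
  np <- net_of_mask({
    p <- matrix(FALSE, 64, 64)
    p[10:12, 5:60] <- TRUE
    p[40:42, 5:60] <- TRUE
    p
  })
  expect_equal(nrow(np$crosslinks), 0)
  expect_equal(brute_crosslink_count(np), 0)

  nx <- net_of_mask(x_mask())
  expect_equal(nrow(nx$crosslinks), 1)
  expect_equal(brute_crosslink_count(nx), 1)

  ng <- net_of_mask(grid_mask())
  expect_length(ng$fibers, 6)
  expect_equal(nrow(ng$crosslinks), 9)
  expect_equal(brute_crosslink_count(ng), 9)

  # random small scenes: implementation equals the oracle
  for (sd in 1:5) {
    g <- generate_fiber_image(fiber_spec(n_fibers = 6, size = 64,
                                         length_mean = 40, length_sd = 5,
                                         width_mean = 3, width_sd = 0,
                                         noise_sd = 0, seed = sd))
    net <- net_of_mask(g$truth$true_mask)
    expect_equal(nrow(net$crosslinks), brute_crosslink_count(net))
  }
})

test_that("fiber vertices cover the retained skeleton", {
  m <- grid_mask()
  sk <- skeletonize_mask(m)
  net <- extract_fiber_network(sk)
  covered <- unique(do.call(rbind, lapply(net$fibers, `[[`, "vertices")))
  key <- function(x) paste(x[, 1], x[, 2])
  # every fiber vertex is a skeleton pixel ...
  skel_px <- which(sk$skeleton_mask, arr.ind = TRUE)
  expect_true(all(key(covered) %in% key(skel_px)))
  # ... and every non-junction skeleton pixel belongs to some fiber
  # (junction clusters are represented by their central pixel)
  offs <- collascore:::neighbour_offsets()
  nb <- Reduce(`+`, lapply(seq_len(nrow(offs)), function(k) {
    collascore:::shift_matrix(sk$skeleton_mask, offs[k, 1], offs[k, 2], FALSE)
  }))
  chain_px <- which(sk$skeleton_mask & nb <= 2, arr.ind = TRUE)
  expect_true(all(key(chain_px) %in% key(covered)))
})

test_that("rotating the mask by 90 degrees preserves the network summary", {
  for (sd in 1:3) {
    g <- generate_fiber_image(fiber_spec(
      n_fibers = 10, size = 192, crossing_allowed = FALSE, noise_sd = 0,
      waviness = 0.3, length_mean = 100, length_sd = 10,
      width_mean = 5, width_sd = 0.5, orientation_kappa = 4, seed = sd
    ))
    n1 <- net_of_mask(g$truth$true_mask)
    n2 <- net_of_mask(rot90m(g$truth$true_mask))
    expect_equal(length(n1$fibers), length(n2$fibers))
    expect_equal(nrow(n1$crosslinks), nrow(n2$crosslinks))
    expect_lt(abs(total_path_length(n1) - total_path_length(n2)) /
                total_path_length(n1), 0.01)
  }
})

test_that("well-separated noise-free fibers are recovered exactly", {
  for (sd in 1:4) {
    g <- generate_fiber_image(fiber_spec(
      n_fibers = 12, size = 384, crossing_allowed = FALSE, noise_sd = 0,
      waviness = 0, length_mean = 150, length_sd = 15,
      width_mean = 5, width_sd = 0, orientation_kappa = 8,
      orientation_mean = 40, seed = sd
    ))
    net <- net_of_mask(g$truth$true_mask)
    expect_equal(length(net$fibers), 12)
  }
})
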