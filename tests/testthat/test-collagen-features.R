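test_that("area fraction is exact arithmetic", {
  expect_equal(area_fraction(matrix(TRUE, 8, 8)), 1)
  expect_equal(area_fraction(matrix(FALSE, 8, 8)), 0)
  m <- matrix(FALSE, 512, 512)
  m[1:128, ] <- TRUE  # 65,536 foreground pixels
  expect_equal(area_fraction(m), 0.25)
})

test_that("fiber count, length and width follow their definitions", {
  empty <- hand_network(list())
  expect_equal(fiber_count(empty), 0)
  expect_true(is.na(fiber_length_mean(empty)))
  expect_true(is.na(fiber_width_mean(empty)))

  two <- hand_network(list(cbind(1, 1:51), cbind(3, 1:151)))
  expect_equal(fiber_count(two), 2)
  expect_equal(fiber_length_mean(two), 100)  # mean of 50 and 150

  # per-area mode
  expect_equal(fiber_count(two, per_mm2 = TRUE, pixel_size_um = 1000),
               2 / (64 * 64))

  # widths from the distance transform of solid bars
  bar <- matrix(FALSE, 64, 128)
  bar[30:34, 10:109] <- TRUE
  n1 <- net_of_mask(bar)
  w1 <- fiber_width_mean(n1)
  expect_gte(w1, 4); expect_lte(w1, 6)

  bars <- matrix(FALSE, 96, 128)
  bars[20:23, 10:119] <- TRUE   # 4 px tall
  bars[60:67, 10:119] <- TRUE   # 8 px tall
  n2 <- net_of_mask(bars)
  w2 <- fiber_width_mean(n2)
  expect_gte(w2, 5); expect_lte(w2, 7)
})

test_that("straightness is chord over path, with the L-path closed form", {
  straight <- hand_network(list(cbind(5, 1:101)))
  expect_equal(fiber_straightness_mean(straight), 1)

  L <- rbind(cbind(0:30, 0), cbind(30, 1:40))  # legs 30 and 40, unit steps
  expect_equal(fiber_straightness_mean(hand_network(list(L))), 50 / 70,
               tolerance = 1e-12)

  loop <- rbind(cbind(0, 0:10), cbind(0:10, 10), cbind(10, 10:0),
                cbind(10:0, 0))
  expect_warning(s <- fiber_straightness_mean(hand_network(list(loop))),
                 "closed-loop")
  expect_true(is.na(s))
})

test_that("cross-link density and spacing follow their definitions", {
  par2 <- net_of_mask({
    p <- matrix(FALSE, 64, 64); p[10:12, 5:60] <- TRUE; p[40:42, 5:60] <- TRUE
    p
  })
  expect_equal(crosslink_density(par2), 0)

  nx <- net_of_mask(x_mask())
  expect_equal(crosslink_density(nx), 0.5)   # 2 fibers, 1 cross-link

  ng <- net_of_mask(grid_mask())
  expect_equal(crosslink_density(ng), 1.5)   # 6 fibers, 9 cross-links

  # hand-built: cross-links at path positions 10, 40, 100 on one fiber
  f <- cbind(1, 0:100 + 1)
  net <- hand_network(list(f))
  net$crosslinks <- rbind(c(1, 11), c(1, 41), c(1, 101))
  expect_equal(crosslink_spacing_mean(net), 45)  # mean of 30 and 60

  net1 <- hand_network(list(f))
  net1$crosslinks <- rbind(c(1, 41))
  expect_true(is.na(crosslink_spacing_mean(net1)))  # single cross-link

  # grid: vertical bars at columns 50, 100, 150 -> spacing 50 along rows
  gaps <- crosslink_spacing_mean(ng)
  expect_equal(gaps, 50, tolerance = 0.05)
})

test_that("orientation index separates aligned from isotropic textures", {
  st <- matrix(FALSE, 256, 256)
  for (r in seq(10, 250, by = 12)) st[r:(r + 2), ] <- TRUE
  expect_gte(orientation_index(st), 0.9)
  expect_lt(abs(orientation_index(st) - orientation_index(rot90m(st))), 0.02)

  iso <- mean(vapply(1:10, function(sd) {
    g <- generate_fiber_image(fiber_spec(n_fibers = 40, size = 256,
                                         orientation_kappa = 0,
                                         noise_sd = 0, seed = sd))
    orientation_index(g$truth$true_mask)
  }, numeric(1)))
  expect_lte(iso, 0.2)

  expect_true(is.na(orientation_index(matrix(1, 32, 32))))
})

test_that("feature vectors assemble with missing propagation and ranges", {
  emptym <- matrix(FALSE, 64, 64)
  sk <- skeletonize_mask(emptym)
  net <- extract_fiber_network(sk)
  fv <- compute_feature_vector(emptym, net)
  expect_equal(unname(fv["fea1"]), 0)
  expect_equal(unname(fv["fea2"]), 0)
  expect_true(all(is.na(fv[paste0("fea", 3:8)])))

  g <- generate_fiber_image(fiber_spec(
    n_fibers = 10, size = 256, crossing_allowed = FALSE, noise_sd = 0,
    waviness = 0, orientation_kappa = Inf, orientation_mean = 0,
    length_mean = 120, length_sd = 10, width_mean = 5, width_sd = 0, seed = 3
  ))
  sk <- skeletonize_mask(g$truth$true_mask)
  net <- extract_fiber_network(sk)
  fv <- compute_feature_vector(g$truth$true_mask, net)
  expect_gte(fv[["fea5"]], 0.98)   # straight fibers
  expect_gte(fv[["fea8"]], 0.9)    # aligned fibers
  expect_true(fv[["fea1"]] >= 0 && fv[["fea1"]] <= 1)
  expect_true(fv[["fea5"]] > 0 && fv[["fea5"]] <= 1)
  expect_true(fv[["fea8"]] >= 0 && fv[["fea8"]] <= 1)
  expect_true(all(fv[c("fea2", "fea3", "fea4", "fea6")] >= 0, na.rm = TRUE))
})

test_that("patient aggregation averages ROIs and skips missing values", {
  v1 <- c(fea1 = 0.2, fea2 = 10, fea3 = 50, fea4 = 5, fea5 = 0.9,
          fea6 = 0.5, fea7 = NA, fea8 = 0.4)
  v2 <- c(fea1 = 0.4, fea2 = 20, fea3 = 70, fea4 = 7, fea5 = 0.8,
          fea6 = 1.5, fea7 = 80, fea8 = 0.6)
  agg <- aggregate_patient(list(v1, v2))
  expect_equal(unname(agg["fea1"]), 0.3)
  expect_equal(unname(agg["fea7"]), 80)   # missing-skip rule
  expect_equal(aggregate_patient(list(v1)), v1)  # single ROI identity
  expect_error(aggregate_patient(list()), "ROI")
  agg_allna <- aggregate_patient(list(v1, v1))
  expect_true(is.na(agg_allna["fea7"]))   # missing in all ROIs stays missing
})

test_that("features respond monotonically to the generator dials", {
  mean_feat <- function(feat, ...) {
    mean(vapply(1:6, function(sd) {
      g <- generate_fiber_image(fiber_spec(..., noise_sd = 0, seed = sd))
      sk <- skeletonize_mask(g$truth$true_mask)
      net <- extract_fiber_network(sk)
      suppressWarnings(
        compute_feature_vector(g$truth$true_mask, net)[[feat]]
      )
    }, numeric(1)), na.rm = TRUE)
  }
  # fea1 grows with fiber count
  f1 <- vapply(c(5, 15, 30), function(nf) {
    mean_feat("fea1", n_fibers = nf, size = 128)
  }, numeric(1))
  expect_true(all(diff(f1) > 0))
  # fea5 falls as waviness grows
  f5 <- vapply(c(0, 0.6, 1.5), function(wv) {
    mean_feat("fea5", n_fibers = 8, size = 192, waviness = wv,
              crossing_allowed = FALSE, orientation_kappa = 2,
              length_mean = 90)
  }, numeric(1))
  expect_true(all(diff(f5) < 0))
  # fea8 rises with orientation concentration
  f8 <- vapply(c(0, 4, 32), function(k) {
    mean_feat("fea8", n_fibers = 25, size = 192, orientation_kappa = k)
  }, numeric(1))
  expect_true(all(diff(f8) > 0))
})
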