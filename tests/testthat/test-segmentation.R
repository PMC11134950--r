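test_that("a two-point intensity mixture is recovered in closed form", {
  img <- matrix(c(rep(100L, 512), rep(3000L, 512)), 32, 32)
  m <- fit_gmm(img, n_components = 2, seed = 1)
  expect_lt(abs(m$means[1] - 100), 1)
  expect_lt(abs(m$means[2] - 3000), 1)
  expect_lt(max(abs(m$weights - 0.5)), 0.01)
  expect_true(m$converged)

  mask <- segment_collagen(img, m, min_object_px = 0)
  expect_identical(mask, matrix(img == 3000, 32, 32))
})

test_that("constant images are rejected and fits are deterministic", {
  expect_error(fit_gmm(matrix(7L, 32, 32), 2, seed = 1), "degenerate|constant")
  g <- generate_fiber_image(fiber_spec(n_fibers = 20, size = 128, seed = 4))
  expect_identical(fit_gmm(g$image, 2, seed = 1)$means,
                   fit_gmm(g$image, 2, seed = 1)$means)
})

test_that("component ordering makes the foreground choice stable", {
  g <- generate_fiber_image(fiber_spec(n_fibers = 20, size = 128, seed = 3))
  m1 <- fit_gmm(g$image, 2, seed = 1)
  m2 <- fit_gmm(g$image, 2, seed = 99)  # different k-means initialization
  expect_true(all(diff(m1$means) > 0))
  expect_identical(segment_collagen(g$image, m1),
                   segment_collagen(g$image, m2))
})

test_that("posterior assignment equals an intensity threshold (n=2)", {
  g <- generate_fiber_image(fiber_spec(n_fibers = 20, size = 256,
                                       noise_sd = 80, seed = 1))
  m <- fit_gmm(g$image, 2, seed = 1)
  post <- collascore:::posterior_by_intensity(m)
  lab <- apply(post, 1, which.max)
  runs <- rle(lab)
  # brute force over all 4096 intensities: a single bg -> fg crossing
  expect_identical(runs$values, c(1L, 2L))
  tstar <- sum(runs$lengths[1])  # first foreground intensity
  mask <- segment_collagen(g$image, m, min_object_px = 0)
  expect_identical(mask, matrix(g$image >= tstar, nrow(g$image), ncol(g$image)))
})

test_that("synthetic masks are segmented accurately, degrading with noise", {
  acc_at <- function(noise_sd) {
    mean(vapply(1:10, function(sd) {
      g <- generate_fiber_image(fiber_spec(
        n_fibers = 20, size = 256, noise_sd = noise_sd,
        fg_intensity_mean = 1500, bg_intensity_mean = 150, seed = sd
      ))
      m <- fit_gmm(g$image, 2, seed = 1)
      mask_accuracy(segment_collagen(g$image, m), g$truth$true_mask)
    }, numeric(1)))
  }
  accs <- vapply(c(20, 80, 160, 300), acc_at, numeric(1))
  expect_gte(accs[2], 0.98)            # noise_sd = 80
  expect_true(all(diff(accs) <= 1e-6)) # non-increasing in noise
})

test_that("the EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")  # Mclust resolves helpers unqualified
  g <- generate_fiber_image(fiber_spec(n_fibers = 20, size = 128,
                                       noise_sd = 60, seed = 2))
  m <- fit_gmm(g$image, 2, seed = 1)
  ref <- mclust::Mclust(as.numeric(g$image), G = 2, modelNames = "V",
                        verbose = FALSE)
  expect_equal(sort(m$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.01)
  expect_equal(sort(m$weights), sort(as.numeric(ref$parameters$pro)),
               tolerance = 0.01)
})

test_that("all-background images yield almost no false foreground", {
  # a collagen/background model from a typical fiber image, applied to
  # background-only tiles
  gref <- generate_fiber_image(fiber_spec(n_fibers = 20, size = 128,
                                          noise_sd = 30, seed = 99))
  mref <- fit_gmm(gref$image, 2, seed = 1)
  fracs <- vapply(1:5, function(sd) {
    g <- generate_fiber_image(fiber_spec(n_fibers = 0, size = 128,
                                         noise_sd = 30, seed = sd))
    mean(segment_collagen(g$image, mref))
  }, numeric(1))
  expect_lt(mean(fracs), 0.01)

  # a mixture fitted on pure background has no separated collagen class,
  # so the separation guard returns an empty mask
  g0 <- generate_fiber_image(fiber_spec(n_fibers = 0, size = 128,
                                        noise_sd = 30, seed = 1))
  m0 <- fit_gmm(g0$image, 2, seed = 1)
  expect_equal(mean(segment_collagen(g0$image, m0)), 0)
})
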