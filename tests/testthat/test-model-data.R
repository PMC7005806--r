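# Synthetic model generators: face models 1-4, streak-noise formula,
# tear rasterization, 3D brain/field fixtures, determinism.

test_that("fixed face model has the documented geometry and is deterministic", {
  m <- make_fixed_model()
  expect_identical(dim(m$image), c(400L, 400L))
  masks <- m$region_masks
  # pairwise disjoint, all inside the face disk
  total <- Reduce(`+`, lapply(masks, function(x) x + 0L))
  expect_true(max(total) == 1L)
  disk <- masks$face | masks$eyebrows | masks$eyes | masks$mouth
  expect_true(all(which(masks$mouth) %in% which(disk)))
  expect_identical(make_fixed_model()$image, m$image)
  expect_true(sum(masks$eyes & masks$mouth) == 0)
})

test_that("model 1 warps image and masks consistently", {
  f <- make_fixed_model()
  zero <- structure(list(field = zero_field(c(400, 400, 1)),
                         amplitude = 0, smoothness = 1, seed = 0L),
                    class = "SyntheticDeformation")
  m0 <- make_model1(f, zero)
  expect_equal(m0$image, f$image, tolerance = 1e-12)
  expect_identical(m0$region_masks, f$region_masks)

  d <- make_crying_deformation(mouth_amp = 8, rand_amp = 0, seed = 1)
  m1 <- make_model1(f, d)
  # warped masks stay pairwise disjoint under nearest-neighbor warping
  total <- Reduce(`+`, lapply(m1$region_masks, function(x) x + 0L))
  expect_true(max(total) == 1L)
  # mouth centroid moves by the deformation's value at the centroid
  cm <- function(msk) colMeans(which(msk, arr.ind = TRUE)) - 1
  c0 <- cm(f$region_masks$mouth)
  c1 <- cm(m1$region_masks$mouth)
  expected <- interp_field(d$field, c(c0, 0))[1:2]
  expect_lt(max(abs((c1 - c0) - expected)), 1)
})

test_that("histogram texturing matches the supplied distributions", {
  f <- make_fixed_model()
  # degenerate histogram: the region becomes the constant value
  h <- rep(0, 256); h[101] <- 1  # gray value 100
  m <- texture_from_histograms(f, list(mouth = h), seed = 3)
  expect_true(all(m$image[m$region_masks$mouth] == 100))
  expect_equal(m$image[!m$region_masks$mouth],
               f$image[!m$region_masks$mouth])
  # empirical histogram close in total variation on a region >= 1e4 px
  hist2 <- list(face = surrogate_histograms()$eyes)
  expect_gt(sum(f$region_masks$face), 1e4)
  m2 <- texture_from_histograms(f, hist2, seed = 4)
  vals <- as.integer(m2$image[m2$region_masks$face])
  emp <- tabulate(vals + 1L, 256) / length(vals)
  expect_lt(0.5 * sum(abs(emp - hist2$face)), 0.05)
  expect_identical(texture_from_histograms(f, hist2, seed = 4)$image,
                   m2$image)
  bad <- rep(0, 256)
  expect_error(texture_from_histograms(f, list(mouth = bad)),
               "not normalizable")
})

test_that("streak noise follows y = v (sin(pi c / w) + A - 1) / A", {
  img <- matrix(140, 41, 41)
  out <- add_streak_noise(img, w = 20, A = 7, axis = 2)
  # at c = 10 (sin = 1) the value passes through unchanged
  expect_equal(out[1, 11], 140)
  # at c = 0 and c = 20 (sin = 0) the value is attenuated to v (A-1)/A
  expect_equal(out[1, 1], 120)
  expect_equal(out[5, 21], 120)
  # zero pixels stay zero anywhere
  img0 <- matrix(0, 5, 5)
  expect_true(all(add_streak_noise(img0, 20, 7) == 0))
  # direct evaluation over a random image
  set.seed(9)
  v <- matrix(runif(25, 0, 255), 5, 5)
  got <- add_streak_noise(v, w = 13, A = 4, axis = 1)
  cc <- row(v) - 1
  expect_equal(got, pmin(pmax(v * (sin(pi / 13 * cc) + 3) / 4, 0), 255))
  expect_error(add_streak_noise(img, w = 20, A = 1), "A must be > 1")
  # literal reading uses the pixel value as the sin argument
  lit <- add_streak_noise(matrix(140, 1, 1), w = 20, A = 7,
                          literal = TRUE)
  expect_equal(lit[1, 1], 140 * (sin(pi / 20 * 140) + 6) / 7)
})

test_that("tear rasterization counts pixels by center inclusion", {
  f <- make_fixed_model()
  # right triangle (0,0),(10,0),(0,10): area 50, edge-inclusive count
  m <- add_tear(f, rbind(c(0, 0), c(10, 0), c(0, 10)))
  n_zeroed <- sum(m$tear)
  # brute-force recount with the same inclusion rule
  cnt <- 0L
  for (x in 0:10) for (y in 0:10) if (x + y <= 10) cnt <- cnt + 1L
  expect_identical(n_zeroed, cnt)
  expect_true(all(m$image[m$tear] == 0))
  # triangle fully outside the image changes nothing
  m2 <- add_tear(f, rbind(c(-30, -30), c(-10, -30), c(-20, -10)))
  expect_equal(m2$image, f$image)
  expect_error(add_tear(f, rbind(c(0, 0), c(5, 5), c(10, 10))),
               "degenerate")
})

test_that("model chain keeps prior region masks unchanged stage to stage", {
  ch <- suppressWarnings(make_model_chain(seed = 1))
  expect_identical(ch$model2$region_masks, ch$model1$region_masks)
  expect_identical(ch$model3$region_masks, ch$model2$region_masks)
  expect_identical(ch$model4$region_masks, ch$model3$region_masks)
  # tear overlaps only the image, recorded separately
  expect_true(sum(ch$model4$tear) > 0)
})

test_that("synthetic fields are scaled, invertible and deterministic", {
  f <- make_synthetic_field(c(48, 48, 48), 2, 8, seed = 2)
  expect_equal(max(field_norm(f$field)), 2, tolerance = 1e-6)
  expect_gt(field_jacobian_min(f$field), 0)
  f2 <- make_synthetic_field(c(48, 48, 48), 2, 8, seed = 2)
  expect_identical(f$field$components, f2$field$components)
  z <- make_synthetic_field(c(16, 16, 16), 0, 4, seed = 1)
  expect_equal(max(field_norm(z$field)), 0)
  expect_error(make_synthetic_field(c(16, 16, 16), 9, 8), "amplitude")
  # fixed-point inversion residual below 0.1 voxel
  g <- invert_field(f$field)
  expect_lt(max(field_norm(compose_fields(f$field, g))), 0.1)
})

test_that("synthetic brain pairs are labeled, backgrounded, reproducible", {
  syn <- make_synthetic_brain(c(32, 32, 32), n_regions = 4, seed = 5)
  lab <- syn$labels$data
  expect_gt(mean(lab == 0L), 0.3)
  expect_true(all(1:4 %in% unique(as.vector(lab))))
  syn2 <- make_synthetic_brain(c(32, 32, 32), n_regions = 4, seed = 5)
  expect_identical(syn2$labels$data, lab)
  expect_identical(syn2$volume$data, syn$volume$data)
  expect_error(make_synthetic_brain(c(16, 16, 16)), "shape")
})
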