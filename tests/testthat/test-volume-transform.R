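# High-resolution mapping algebra and block-wise warping: micro-oracles
# for the scaled affine, trilinear field interpolation and point mapping;
# ROI containment; oracle equivalence of blockwise vs dense warps;
# reslicing.

test_that("scaled affines commute with coordinate scaling", {
  expect_equal(scale_affine(affine_transform(), 17)$matrix, diag(4))
  Mt <- affine_transform(rbind(cbind(diag(3), 0), c(2, -1, 3, 1)))
  expect_equal(scale_affine(Mt, 8)$matrix[4, 1:3], c(16, -8, 24))
  set.seed(61)
  M <- affine_transform(rbind(cbind(diag(3) + matrix(stats::rnorm(9, sd = 0.2), 3), 0),
                              c(stats::rnorm(3, sd = 5), 1)))
  Mp <- scale_affine(M, 32)
  p <- matrix(stats::runif(300, -20, 50), 100, 3)
  err <- max(abs(affine_apply(Mp, 32 * p) - 32 * affine_apply(M, p)))
  expect_lt(err, 1e-6)
  expect_error(scale_affine(M, 0), "scale")
})

test_that("field interpolation matches an independent expansion", {
  f <- make_synthetic_field(c(12, 13, 14), 2, 3, seed = 62)$field
  # grid nodes return stored vectors exactly
  expect_equal(interp_field(f, c(3, 4, 5)),
               cbind(f$components[[1]][4, 5, 6],
                     f$components[[2]][4, 5, 6],
                     f$components[[3]][4, 5, 6]))
  # cell center = mean of the 8 corner vectors
  got <- interp_field(f, c(2.5, 3.5, 4.5))
  expect_equal(got[1, 1], mean(f$components[[1]][3:4, 4:5, 5:6]),
               tolerance = 1e-12)
  # 1000 random queries against the scalar 8-corner oracle
  set.seed(63)
  q <- cbind(stats::runif(1000, 0, 11), stats::runif(1000, 0, 12),
             stats::runif(1000, 0, 13))
  got <- interp_field(f, q)
  for (i in 1:3)
    expect_lt(max(abs(got[, i] - trilinear_oracle(f$components[[i]], q))),
              1e-12)
  expect_error(interp_field(f, c(NaN, 0, 0)), "NaN")
})

test_that("map_point equals the low-resolution mapping scaled by s", {
  set.seed(64)
  M <- affine_transform(rbind(cbind(diag(3) + matrix(stats::rnorm(9, sd = 0.1), 3), 0),
                              c(stats::rnorm(3), 1)))
  f <- make_synthetic_field(c(20, 20, 20), 2, 6, seed = 65)$field
  s <- 4
  m <- high_res_mapping(scale_affine(M, s), f, s, c(77, 77, 77))
  P <- matrix(stats::runif(300, 0, 76), 100, 3)
  lowres <- affine_apply(M, P / s) + interp_field(f, P / s)
  expect_lt(max(abs(map_point(m, P) - s * lowres)), 1e-9)
  # identity mapping, constant field
  mid <- high_res_mapping(affine_transform(), zero_field(c(20, 20, 20)),
                          s, c(77, 77, 77))
  expect_equal(map_point(mid, P), P, ignore_attr = TRUE)
  cf <- displacement_field(array(1, c(20, 20, 20)),
                           array(-2, c(20, 20, 20)),
                           array(0.5, c(20, 20, 20)))
  mc <- high_res_mapping(affine_transform(), cf, s, c(77, 77, 77))
  expect_equal(map_point(mc, P),
               P + rep(s * c(1, -2, 0.5), each = nrow(P)),
               ignore_attr = TRUE)
})

test_that("block plans tile and ROIs contain every sampled source", {
  g <- plan_blocks(c(100, 100, 100), 64)
  expect_identical(g$n_blocks, c(2L, 2L, 2L))
  expect_identical(nrow(block_indices(g)), 8L)
  g1 <- plan_blocks(c(64, 64, 64), 64)
  expect_identical(g1$n_blocks, c(1L, 1L, 1L))
  expect_error(plan_blocks(c(64, 64, 64), 4), ">= 8")

  # identity mapping: ROI covers the block extent (plus margin)
  mid <- high_res_mapping(affine_transform(), zero_field(c(40, 40, 40)),
                          1, c(40, 40, 40))
  ext <- list(lo = c(8L, 8L, 8L), hi = c(16L, 16L, 16L))
  roi0 <- roi_for_block(ext, mid, margin = 0, src_shape = c(40, 40, 40))
  expect_identical(roi0$lo, c(8L, 8L, 8L))
  expect_identical(roi0$hi, c(16L, 16L, 16L))
  # exhaustive containment for a random smooth mapping, margin 2 s
  s <- 2
  f <- make_synthetic_field(c(20, 20, 20), 2, 6, seed = 66)$field
  m <- high_res_mapping(affine_transform(), f, s, c(32, 32, 32))
  ext2 <- list(lo = c(0L, 0L, 0L), hi = c(32L, 32L, 32L))
  roi <- roi_for_block(ext2, m, margin = 2 * s,
                       src_shape = c(64, 64, 64))
  S <- map_point(m, grid_coords(c(32, 32, 32)))
  inside <- S[, 1] >= roi$lo[1] & S[, 1] < roi$hi[1] &
    S[, 2] >= roi$lo[2] & S[, 2] < roi$hi[2] &
    S[, 3] >= roi$lo[3] & S[, 3] < roi$hi[3]
  src_ok <- S[, 1] >= 0 & S[, 1] <= 63 & S[, 2] >= 0 & S[, 2] <= 63 &
    S[, 3] >= 0 & S[, 3] <= 63
  expect_true(all(inside[src_ok]))
})

test_that("blockwise transform equals the dense warp on one block", {
  src_vol <- rand_volume(c(48, 48, 48), seed = 67)
  st <- create_block_store(c(48, 48, 48), 16, "uint8", root = tempfile())
  ingest_volume(st, src_vol)
  f <- make_synthetic_field(c(24, 24, 24), 2, 8, seed = 68)$field
  m <- high_res_mapping(affine_transform(), f, 2, c(48, 48, 48))
  ext <- list(lo = c(16L, 0L, 16L), hi = c(32L, 16L, 32L))
  res <- transform_block(ext, st, m, "nearest")
  dense <- warp_volume_dense(src_vol, m, "nearest")
  expect_identical(res$data + 0,
                   dense$data[17:32, 1:16, 17:32] + 0)
  # identity mapping reproduces the source bit-exactly
  mid <- high_res_mapping(affine_transform(), zero_field(c(24, 24, 24)),
                          2, c(48, 48, 48))
  r2 <- transform_block(ext, st, mid, "nearest")
  expect_identical(r2$data + 0, src_vol$data[17:32, 1:16, 17:32] + 0)
})

test_that("whole-volume blockwise output is identical for 1 or 4 workers", {
  src_vol <- rand_volume(c(40, 40, 40), seed = 69)
  st <- create_block_store(c(40, 40, 40), 16, "uint8", root = tempfile())
  ingest_volume(st, src_vol)
  f <- make_synthetic_field(c(40, 40, 40), 2, 8, seed = 70)$field
  m <- high_res_mapping(affine_transform(), f, 1, c(40, 40, 40))
  out1 <- create_block_store(c(40, 40, 40), 16, "uint8", root = tempfile())
  out4 <- create_block_store(c(40, 40, 40), 16, "uint8", root = tempfile())
  s1 <- transform_volume(st, m, out1, "nearest", workers = 1)
  s4 <- transform_volume(st, m, out4, "nearest", workers = 4)
  expect_identical(assemble_volume(out1)$data, assemble_volume(out4)$data)
  expect_identical(s1$blocks_total, 27L)
  # and matches the dense warp exactly
  dense <- warp_volume_dense(src_vol, m, "nearest")
  expect_identical(assemble_volume(out1)$data + 0, dense$data + 0)
})

test_that("brain-mask skipping leaves out-of-brain blocks unwritten", {
  src_vol <- rand_volume(c(40, 40, 40), seed = 71)
  st <- create_block_store(c(40, 40, 40), 16, "uint8", root = tempfile())
  ingest_volume(st, src_vol)
  mask <- array(FALSE, c(40, 40, 40))
  mask[1:20, 1:20, 1:20] <- TRUE
  m <- high_res_mapping(affine_transform(), zero_field(c(40, 40, 40)),
                        1, c(40, 40, 40))
  out <- create_block_store(c(40, 40, 40), 16, "uint8", root = tempfile())
  stats <- transform_volume(st, m, out, "nearest", brain_mask = mask)
  expect_gt(stats$blocks_skipped, 0)
  expect_lte(stats$blocks_skipped, stats$blocks_total)
  asm <- assemble_volume(out)$data
  expect_identical(asm[1:20, 1:20, 1:20] + 0,
                   src_vol$data[1:20, 1:20, 1:20] + 0)
  # skipped blocks read back as fill
  expect_true(all(asm[33:40, 33:40, 33:40] == 0))
})

test_that("reslicing along each axis restacks to the original volume", {
  v <- rand_volume(c(12, 10, 8), seed = 72)
  st <- create_block_store(c(12, 10, 8), 8, "uint8", root = tempfile())
  ingest_volume(st, v)
  for (axis in c("x", "y", "z")) {
    d <- tempfile()
    paths <- reslice(st, axis, d)
    ax <- match(axis, c("x", "y", "z"))
    expect_identical(length(paths), dim(v$data)[ax])
    slices <- lapply(paths, function(p) tiff::readTIFF(p, as.is = TRUE))
    restack <- array(unlist(slices), c(dim(slices[[1]]), length(slices)))
    perm <- switch(ax, c(2, 3, 1), c(1, 3, 2), c(1, 2, 3))
    expect_identical(aperm(restack, order(perm)) + 0L, v$data + 0L)
  }
  # a single voxel lands on the documented slice and pixel
  v2 <- volume3d(array(0L, c(8, 8, 8)))
  v2$data[4, 5, 6] <- 200L
  st2 <- create_block_store(c(8, 8, 8), 8, "uint8", root = tempfile())
  ingest_volume(st2, v2)
  p <- reslice(st2, "z", tempfile())
  sl <- tiff::readTIFF(p[6], as.is = TRUE)
  expect_identical(which(sl != 0), 4L + 8L * 4L)
  # incomplete stores are reported with the missing index
  st3 <- create_block_store(c(16, 16, 16), 8, "uint8", root = tempfile())
  expect_error(reslice(st3, "z", tempfile()), "missing block")
})
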