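# Feature encoding, affine and diffeomorphic registration, field algebra.

test_that("feature encodings are faithful to the labels", {
  lab <- array(0L, c(16, 16, 16))
  lab[8, 8, 8] <- 1L
  lab[1:4, , ] <- 2L
  lv <- label_volume(lab, names = c("1" = "spot", "2" = "slab"))
  # raw one-hot equals the indicator
  fi <- encode_features(lv, regions = "spot", sigma = 0)
  expect_equal(fi$channels[[1]], array(as.numeric(lab == 1L), dim(lab)))
  # channel order follows the supplied region list
  fi2 <- encode_features(lv, regions = c("slab", "spot"), sigma = 0)
  expect_identical(fi2$region_ids, c(2L, 1L))
  # signed distance of a half-space boundary is +-k at k voxels
  fd <- encode_features(lv, regions = "slab", encoding = "distance",
                        cap = 10)
  ch <- fd$channels[[1]]
  expect_equal(ch[4, 8, 8], 1)   # 1 voxel inside
  expect_equal(ch[2, 8, 8], 3)
  expect_equal(ch[5, 8, 8], -1)  # 1 voxel outside
  expect_equal(ch[8, 8, 8], -4)
  expect_error(encode_features(lv, regions = "missing_region"),
               "absent")
})

test_that("affine registration recovers translation and scale", {
  syn <- make_synthetic_brain(c(48, 48, 48), n_regions = 4, seed = 11)
  ff <- encode_features(syn$labels, sigma = 2)
  cfg <- registration_config(levels = c(4, 2), iters_per_level = c(60, 40))
  # identity: fixed == moving
  M0 <- register_affine(ff, ff, cfg)
  expect_lt(max(abs(M0$matrix - diag(4))), 1e-3)
  # translation by (5, -3, 2): pull-back map must recover -(5, -3, 2)
  Mt <- affine_transform(rbind(cbind(diag(3), 0), c(5, -3, 2, 1)))
  mov <- apply_transform_lowres(syn$labels, Mt)
  Mhat <- register_affine(ff, encode_features(mov, sigma = 2), cfg)
  expect_lt(max(abs(Mhat$matrix[4, 1:3] - c(-5, 3, -2))), 0.5)
  expect_lt(max(abs(Mhat$matrix[1:3, 1:3] - diag(3))), 0.02)
  # isotropic 1.1x scale about the center
  ctr <- c(23.5, 23.5, 23.5)
  A <- diag(3) / 1.1
  Ms <- affine_transform(rbind(cbind(A, 0), c(ctr - ctr %*% A, 1)))
  mov2 <- apply_transform_lowres(syn$labels, Ms)
  Mhat2 <- register_affine(ff, encode_features(mov2, sigma = 2), cfg)
  expect_equal(mean(diag(Mhat2$matrix)[1:3]), 1.1, tolerance = 0.02)
})

test_that("field composition and inversion obey their algebra", {
  d <- c(24, 24, 24)
  f <- make_synthetic_field(d, 2, 8, seed = 21)$field
  g <- make_synthetic_field(d, 1.5, 8, seed = 22)$field
  z <- zero_field(d)
  # compose(0, g) = g ; constant fields add
  cz <- compose_fields(z, g)
  expect_equal(cz$components, g$components, tolerance = 1e-12)
  ca <- displacement_field(array(1.5, d), array(-0.5, d), array(2, d))
  cb <- displacement_field(array(-0.25, d), array(1, d), array(0.5, d))
  cc <- compose_fields(ca, cb)
  expect_equal(cc$components[[1]], array(1.25, d), tolerance = 1e-9)
  expect_equal(cc$components[[2]], array(0.5, d), tolerance = 1e-9)
  # associativity for smooth small fields (away from the clamped border)
  h <- make_synthetic_field(d, 1, 8, seed = 23)$field
  lhs <- compose_fields(compose_fields(f, g), h)
  rhs <- compose_fields(f, compose_fields(g, h))
  inner <- 5:20
  dmax <- max(abs(lhs$components[[1]][inner, inner, inner] -
                    rhs$components[[1]][inner, inner, inner]),
              abs(lhs$components[[2]][inner, inner, inner] -
                    rhs$components[[2]][inner, inner, inner]))
  expect_lt(dmax, 1e-2)
  # inversion: invert(0) = 0, invert(const a) = -a, residual small
  expect_equal(invert_field(z)$components, z$components)
  ia <- invert_field(ca)
  expect_equal(ia$components[[1]], array(-1.5, d), tolerance = 1e-6)
  inv <- invert_field(f, iters = 50, tol = 0.01)
  expect_lt(max(field_norm(compose_fields(f, inv))), 0.05)
  expect_lte(attr(inv, "iterations"), 50)
})

test_that("low-resolution warps behave on identity, shift and labels", {
  v <- rand_volume(c(20, 20, 20), seed = 31)
  out <- apply_transform_lowres(v)
  expect_equal(out$data, v$data, tolerance = 1e-12, ignore_attr = TRUE)
  # integer translation with nearest is an exact shifted copy
  Mt <- affine_transform(rbind(cbind(diag(3), 0), c(3, 0, 0, 1)))
  lab <- label_volume(v$data %% 5L)
  sh <- apply_transform_lowres(lab, Mt)
  expect_identical(sh$data[1:17, , ], lab$data[4:20, , ])
  expect_true(all(sh$data[18:20, , ] == 0L))
  # nearest-neighbor label warps never invent labels
  f <- make_synthetic_field(c(20, 20, 20), 2, 6, seed = 32)$field
  w <- apply_transform_lowres(lab, field = f)
  expect_true(all(unique(as.vector(w$data)) %in%
                    c(0L, unique(as.vector(lab$data)))))
})

test_that("diffeomorphic registration is inert on identical inputs", {
  syn <- make_synthetic_brain(c(32, 32, 32), n_regions = 3, seed = 41)
  ff <- encode_features(syn$labels, sigma = 2)
  res <- register_diffeomorphic(ff, ff,
                                cfg = registration_config(
                                  levels = c(2, 1),
                                  iters_per_level = c(10, 5)))
  expect_lt(max(field_norm(res$phi1)), 0.1)
  expect_lt(max(field_norm(res$phi2)), 0.1)
})

test_that("known-field recovery meets the desk-scale accuracy bar", {
  h <- recovery_harness()
  res <- h$result
  truth <- h$truth$field
  fg <- h$syn$labels$data > 0L
  epe <- sqrt((res$phi1$components[[1]] - truth$components[[1]])^2 +
                (res$phi1$components[[2]] - truth$components[[2]])^2 +
                (res$phi1$components[[3]] - truth$components[[3]])^2)
  expect_lt(stats::median(epe[fg]), 1.0)
  warped <- apply_transform_lowres(h$moving, res$M, res$phi2)
  for (id in 1:5)
    expect_gte(dice(warped$data == id, h$syn$labels$data == id), 0.90)
  # energy non-increasing over accepted iterations within each level
  for (lv in split(res$energy_trace$energy, res$energy_trace$level))
    expect_true(all(diff(lv) <= 1e-12))
})

test_that("registration is symmetric between A->B and B->A", {
  syn <- make_synthetic_brain(c(32, 32, 32), n_regions = 3, seed = 51)
  t1 <- make_synthetic_field(c(32, 32, 32), 2, 8, seed = 52)
  mov <- apply_transform_lowres(syn$labels, field = t1$field)
  fa <- encode_features(syn$labels, sigma = 2)
  fb <- encode_features(mov, sigma = 2)
  cfg <- registration_config(levels = c(2, 1), iters_per_level = c(40, 20))
  ab <- register_diffeomorphic(fa, fb, cfg = cfg)
  ba <- register_diffeomorphic(fb, fa, cfg = cfg)
  dn <- field_norm(displacement_field(
    ab$phi1$components[[1]] - ba$phi2$components[[1]],
    ab$phi1$components[[2]] - ba$phi2$components[[2]],
    ab$phi1$components[[3]] - ba$phi2$components[[3]]))
  fg <- syn$labels$data > 0L
  expect_lt(stats::median(dn[fg]), 1.0)
})
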