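# Shared fixtures and independent oracles for the test suite. Expensive
# harnesses (the 64^3 field-recovery registration, the 2D face-model
# registrations) are computed once per run and memoized here.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fun) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- fun()
  fixture_cache[[key]]
}

# Independent trilinear expansion: plain scalar loop over the 8 corner
# weights, written without reference to the package's vectorized sampler.
trilinear_oracle <- function(comp, q) {
  d <- dim(comp)
  vapply(seq_len(nrow(q)), function(i) {
    x <- min(max(q[i, 1], 0), d[1] - 1)
    y <- min(max(q[i, 2], 0), d[2] - 1)
    z <- min(max(q[i, 3], 0), d[3] - 1)
    x0 <- min(floor(x), d[1] - 2); y0 <- min(floor(y), d[2] - 2)
    z0 <- min(floor(z), d[3] - 2)
    if (d[1] == 1) x0 <- 0
    if (d[2] == 1) y0 <- 0
    if (d[3] == 1) z0 <- 0
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    acc <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      ix <- min(x0 + cx, d[1] - 1); iy <- min(y0 + cy, d[2] - 1)
      iz <- min(z0 + cz, d[3] - 1)
      w <- (if (cx == 1) fx else 1 - fx) *
        (if (cy == 1) fy else 1 - fy) *
        (if (cz == 1) fz else 1 - fz)
      acc <- acc + w * comp[ix + 1, iy + 1, iz + 1]
    }
    acc
  }, 0.0)
}

# Small random uint8 volume.
rand_volume <- function(shape, seed = 1L, max_val = 255L) {
  set.seed(seed)
  volume3d(array(sample(0:max_val, prod(shape), TRUE), shape))
}

# The 64^3 known-field recovery harness shared by the registration,
# inverse-consistency and duality tests: fixed synthetic brain, known
# smooth field t (amplitude 3 voxels, sigma 8), moving = pull-back warp
# of the fixed labels by t, so the recovered phi1 should approximate t.
recovery_harness <- function() {
  memo("recovery", function() {
    syn <- make_synthetic_brain(c(64, 64, 64), n_regions = 5L, seed = 7L)
    truth <- make_synthetic_field(c(64, 64, 64), 3, 8, seed = 8L)
    moving <- apply_transform_lowres(syn$labels, field = truth$field)
    ff <- encode_features(syn$labels, sigma = 2)
    mf <- encode_features(moving, sigma = 2)
    res <- register_diffeomorphic(ff, mf, cfg = registration_config())
    list(syn = syn, truth = truth, moving = moving, result = res)
  })
}

# The 2D face-model chain plus registrations of models 1-4 to the fixed
# model through the regional-feature path.
face_harness <- function() {
  memo("faces", function() {
    chain <- suppressWarnings(make_model_chain(seed = 1L))
    fixl <- face_label_volume(chain$fixed)
    ff <- encode_features(fixl, sigma = 2)
    acfg <- registration_config(levels = c(4, 2),
                                iters_per_level = c(40, 20))
    dcfg <- registration_config(levels = c(4, 2, 1),
                                iters_per_level = c(50, 25, 10))
    regs <- lapply(paste0("model", 1:4), function(mn) {
      m <- chain[[mn]]
      ml <- face_label_volume(m, exclude = m$tear)
      mf <- encode_features(ml, sigma = 2)
      M <- register_affine(ff, mf, acfg)
      # model 4: the optimizer stretches the remaining mouth over the
      # torn notch; the resulting locally-large half-field triggers the
      # inversion-residual warning there (the tear is not "fixed", as
      # expected) without affecting the intact regions
      res <- suppressWarnings(register_diffeomorphic(ff, mf, M, dcfg))
      warped <- apply_transform_lowres(ml, res$M, res$phi2)
      dsc <- vapply(1:4, function(id)
        dice(warped$data == id, fixl$data == id), 0.0)
      names(dsc) <- c("face", "eyebrows", "eyes", "mouth")
      list(result = res, dice = dsc)
    })
    names(regs) <- paste0("model", 1:4)
    list(chain = chain, fixl = fixl, regs = regs)
  })
}

# Simulated rater study on a 64x64 disk truth: each rater marks a true
# foreground pixel with probability `sens` and a background pixel with
# probability `1 - spec`.
simulate_raters <- function(n_raters = 8L, sens = 0.90, spec = 0.95,
                            seed = 42L) {
  set.seed(seed)
  n <- 64L
  g <- expand.grid(x = seq_len(n) - 1, y = seq_len(n) - 1)
  truth <- matrix((g$x - 31.5)^2 + (g$y - 31.5)^2 <= 20^2, n, n)
  masks <- lapply(seq_len(n_raters), function(j) {
    m <- matrix(FALSE, n, n)
    m[truth] <- stats::runif(sum(truth)) < sens
    m[!truth] <- stats::runif(sum(!truth)) >= spec
    m
  })
  list(truth = truth, masks = masks)
}
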