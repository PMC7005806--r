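# Linear (12-parameter affine) registration on feature channels with a
# coarse-to-fine multiresolution strategy. The estimated affine maps
# fixed-space voxel coordinates to moving-space coordinates (pull-back),
# so applying it to the moving image aligns it onto the fixed lattice.

#' Registration configuration
#'
#' @param levels multiresolution shrink factors, descending (e.g.
#'   `c(4, 2, 1)`).
#' @param iters_per_level iteration budget per level (recycled).
#' @param update_sigma fluid-like Gaussian smoothing of each demons update
#'   (voxels).
#' @param field_sigma elastic-like smoothing of the accumulated fields
#'   (voxels).
#' @param step maximum update norm per iteration (voxels).
#' @param metric similarity for the affine stage: `"ssd"` (default; the
#'   feature channels are mono-modal by construction) or `"mi"` (mutual
#'   information, 32-bin histograms, for gray-image use).
#' @param seed RNG seed recorded for provenance (the default optimization
#'   path is deterministic).
#' @return named list of class `RegistrationConfig`.
#' @export
registration_config <- function(levels = c(4, 2, 1),
                                iters_per_level = c(80, 50, 25),
                                update_sigma = 2, field_sigma = 1,
                                step = 1, metric = c("ssd", "mi"),
                                seed = 0L) {
  metric <- match.arg(metric)
  if (is.unsorted(rev(levels)) || any(levels < 1))
    stop("levels must be descending shrink factors >= 1")
  if (update_sigma < 0 || field_sigma < 0) stop("sigmas must be >= 0")
  if (step <= 0) stop("step must be > 0")
  structure(list(levels = as.integer(levels),
                 iters_per_level = rep(as.integer(iters_per_level),
                                       length.out = length(levels)),
                 update_sigma = update_sigma, field_sigma = field_sigma,
                 step = step, metric = metric, seed = as.integer(seed)),
            class = "RegistrationConfig")
}

#' Estimate a 12-parameter affine between feature images
#'
#' Minimizes the summed per-channel SSD (or maximizes summed mutual
#' information) between the fixed channels and the affinely warped moving
#' channels, coarse-to-fine over `cfg$levels`, initialized from the
#' channel-mass centroid offset. Deterministic given the inputs.
#'
#' @param fixed,moving [encode_features()] outputs with identical channel
#'   sets.
#' @param cfg [registration_config()].
#' @return [affine_transform()] mapping fixed voxel coordinates to moving
#'   voxel coordinates.
#' @export
register_affine <- function(fixed, moving, cfg = registration_config()) {
  check_channels(fixed, moving)
  mass_f <- channel_mass(fixed)
  mass_m <- channel_mass(moving)
  if (mass_f$total == 0 || mass_m$total == 0)
    stop("convergence error: a feature image has no support")
  # map(q) = (q - c) A + c + t around the fixed image center c, with
  # A = I + P / R: the 9 linear parameters are scaled by the half-extent
  # R so every parameter moves boundary points by about one voxel per
  # unit, matching the 3 translation parameters (full-res voxels).
  dim_full <- dim(fixed$channels[[1]])
  R <- mean(dim_full[dim_full > 1]) / 2
  par <- c(rep(0, 9), mass_m$centroid - mass_f$centroid)
  levels <- cfg$levels
  # a lattice too coarse to constrain 12 parameters is skipped (the
  # centroid init already absorbs gross translation)
  usable <- vapply(levels, function(f)
    min((dim_full %/% f)[dim_full > 1]) >= 24 || f == min(levels), TRUE)
  levels <- levels[usable]
  iters <- cfg$iters_per_level[usable]
  for (li in seq_along(levels)) {
    f <- levels[li]
    ff <- if (f > 1) downsample_features(fixed, f) else fixed
    mf <- if (f > 1) downsample_features(moving, f) else moving
    d <- dim(ff$channels[[1]])
    ctr <- (d - 1) / 2
    g <- grid_coords(d)
    # cap evaluation cost: deterministic stride subsample of the lattice
    stride <- max(1L, ceiling((nrow(g) / 50000)^(1 / 3)))
    keep <- g[, 1] %% stride == 0 & g[, 2] %% stride == 0 &
      g[, 3] %% stride == 0
    g <- g[keep, , drop = FALSE]
    gc_ <- sweep(g, 2, ctr)
    fvals <- lapply(ff$channels, function(ch) as.vector(ch)[keep])
    obj <- function(p) {
      A <- diag(3) + matrix(p[1:9], 3, 3, byrow = TRUE) / R
      src <- gc_ %*% A + rep(ctr + p[10:12] / f, each = nrow(gc_))
      total <- 0
      for (ci in seq_along(fvals)) {
        w <- sample_array(mf$channels[[ci]], src, "linear")
        total <- total + if (cfg$metric == "ssd") sum((fvals[[ci]] - w)^2)
        else -mutual_information(fvals[[ci]], w)
      }
      total / length(fvals)
    }
    opt <- stats::optim(par, obj, method = "BFGS",
                        control = list(maxit = iters[li], reltol = 1e-10))
    par <- opt$par
  }
  A <- diag(3) + matrix(par[1:9], 3, 3, byrow = TRUE) / R
  t <- par[10:12]
  ctr_full <- (dim_full - 1) / 2
  # expand (q - c) A + c + t into homogeneous row-vector form
  M <- rbind(cbind(A, 0), c(ctr_full - ctr_full %*% A + t, 1))
  affine_transform(M)
}

mutual_information <- function(a, b, bins = 32L) {
  ia <- pmin(pmax(findInterval(a, seq(min(a), max(a),
                                      length.out = bins + 1L),
                               all.inside = TRUE), 1L), bins)
  ib <- pmin(pmax(findInterval(b, seq(min(b), max(b),
                                      length.out = bins + 1L),
                               all.inside = TRUE), 1L), bins)
  joint <- tabulate(ia + bins * (ib - 1L), bins * bins) / length(a)
  px <- rowSums(matrix(joint, bins)); py <- colSums(matrix(joint, bins))
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] /
                        (outer(px, py)[nz] + .Machine$double.xmin)))
}

check_channels <- function(fixed, moving) {
  stopifnot(inherits(fixed, "FeatureImage"), inherits(moving, "FeatureImage"))
  if (!identical(fixed$region_ids, moving$region_ids))
    stop("fixed and moving feature images must share one channel set")
}

channel_mass <- function(fi) {
  d <- dim(fi$channels[[1]])
  g <- grid_coords(d)
  w <- Reduce(`+`, lapply(fi$channels, function(ch) pmax(as.vector(ch), 0)))
  tot <- sum(w)
  list(total = tot,
       centroid = if (tot > 0) colSums(g * w) / tot else c(0, 0, 0))
}
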