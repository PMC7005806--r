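# 3D synthetic fixtures: label/gray volume pairs related by a known smooth
# invertible deformation, used as ground truth for registration-recovery
# and block-warping tests.

#' Random smooth invertible displacement field
#'
#' Gaussian-smoothed white noise per component, rescaled so the maximum
#' vector norm equals `amplitude`; invertibility is checked numerically
#' via the finite-difference Jacobian determinant of `id + field`.
#'
#' @param shape lattice shape (length 3; a z-extent of 1 yields a 2D field
#'   with zero z-component).
#' @param amplitude maximum displacement norm in voxels; must not exceed
#'   `smoothness` (heuristic invertibility bound).
#' @param smoothness Gaussian sigma in voxels.
#' @param seed RNG seed.
#' @param on_fail `"error"` or `"retry"` (up to 5 reseeded attempts) when
#'   the Jacobian check fails.
#' @return Object of class `SyntheticDeformation`: `field`
#'   ([displacement_field()]), `amplitude`, `smoothness`, `seed`.
#' @export
make_synthetic_field <- function(shape, amplitude, smoothness, seed = 1L,
                                 on_fail = c("error", "retry")) {
  on_fail <- match.arg(on_fail)
  shape <- as.integer(shape)
  if (amplitude > smoothness)
    stop("amplitude must be <= smoothness for heuristic invertibility")
  # generate noise on a lattice padded by the kernel radius and crop
  # after smoothing, so boundary voxels are averaged over as many
  # independent samples as interior ones (no edge variance inflation)
  r <- max(1L, ceiling(3 * smoothness))
  pad <- c(r, r, if (shape[3] == 1L) 0L else r)
  pshape <- shape + 2L * pad
  crop <- function(a) a[(pad[1] + 1):(pad[1] + shape[1]),
                        (pad[2] + 1):(pad[2] + shape[2]),
                        (pad[3] + 1):(pad[3] + shape[3]), drop = FALSE]
  for (try in 0:4) {
    restore <- local_rng(seed + try * 1000L)
    comps <- lapply(1:3, function(i) array(stats::rnorm(prod(pshape)), pshape))
    restore()
    if (shape[3] == 1L) comps[[3]][] <- 0
    sig <- c(smoothness, smoothness, if (shape[3] == 1L) 0 else smoothness)
    if (amplitude == 0) {
      comps <- lapply(comps, function(a) array(0, shape))
    } else {
      comps <- lapply(comps, function(a)
        array(crop(smooth_gauss(a, sigma = sig)), shape))
      mx <- max(sqrt(comps[[1]]^2 + comps[[2]]^2 + comps[[3]]^2))
      comps <- lapply(comps, function(a) a * (amplitude / mx))
    }
    fld <- displacement_field(comps[[1]], comps[[2]], comps[[3]])
    if (amplitude == 0 || field_jacobian_min(fld) > 0)
      return(structure(list(field = fld, amplitude = amplitude,
                            smoothness = smoothness, seed = seed),
                       class = "SyntheticDeformation"))
    if (on_fail == "error")
      stop("Jacobian check failed for amplitude ", amplitude,
           ", smoothness ", smoothness)
  }
  stop("Jacobian check failed after 5 attempts")
}

#' Minimum Jacobian determinant of id + field
#'
#' Finite-difference Jacobian of the mapping `x -> x + phi(x)` over the
#' whole lattice; a strictly positive minimum certifies local
#' invertibility and orientation preservation.
#'
#' @param f [displacement_field()].
#' @return numeric scalar, the minimum determinant.
#' @export
field_jacobian_min <- function(f) {
  cm <- f$components
  d <- field_shape(f)
  J <- vector("list", 9)
  for (i in 1:3) for (ax in 1:3) {
    g <- grad_axis(cm[[i]], ax)
    if (i == ax) g <- g + 1
    J[[(i - 1) * 3 + ax]] <- g  # J[[i,ax]] = d(x_i + phi_i)/d x_ax
  }
  det3 <- J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
    J[[4]] * (J[[2]] * J[[9]] - J[[3]] * J[[8]]) +
    J[[7]] * (J[[2]] * J[[6]] - J[[3]] * J[[5]])
  min(det3)
}

#' Synthetic brain-like volume and label pair
#'
#' A smooth ellipsoidal outline containing `n_regions - 1` nested blob
#' regions, each with a distinct label and gray texture; deterministic per
#' seed. Label 0 is background (> 30% of the volume by construction),
#' label 1 the outline shell, labels `2..n_regions` the blobs.
#'
#' @param shape volume shape, each axis >= 32.
#' @param n_regions total number of labeled regions (>= 3).
#' @param seed RNG seed.
#' @param voxel_size micrometre triple.
#' @return list with elements `volume` ([volume3d()], gray values 0-255)
#'   and `labels` ([label_volume()]).
#' @export
make_synthetic_brain <- function(shape = c(64, 64, 64), n_regions = 5L,
                                 seed = 1L, voxel_size = c(10, 10, 10)) {
  shape <- as.integer(shape)
  if (any(shape < 32L)) stop("shape must be >= 32 per axis")
  if (n_regions < 3L) stop("n_regions must be >= 3")
  restore <- local_rng(seed)
  on.exit(restore())
  g <- grid_coords(shape)
  ctr <- (shape - 1) / 2
  semi <- 0.42 * shape
  r2 <- ((g[, 1] - ctr[1]) / semi[1])^2 + ((g[, 2] - ctr[2]) / semi[2])^2 +
    ((g[, 3] - ctr[3]) / semi[3])^2
  lab <- ifelse(r2 <= 1, 1L, 0L)
  n_blob <- n_regions - 1L
  # blob centers spread on a jittered ring inside the ellipsoid
  ang <- seq(0, 2 * pi, length.out = n_blob + 1L)[seq_len(n_blob)] +
    stats::runif(n_blob, -0.2, 0.2)
  for (b in seq_len(n_blob)) {
    bc <- ctr + 0.45 * semi * c(cos(ang[b]), sin(ang[b]),
                                stats::runif(1, -0.5, 0.5))
    bs <- stats::runif(3, 0.14, 0.2) * shape
    br2 <- ((g[, 1] - bc[1]) / bs[1])^2 + ((g[, 2] - bc[2]) / bs[2])^2 +
      ((g[, 3] - bc[3]) / bs[3])^2
    lab[br2 <= 1 & lab == 1L] <- b + 1L
  }
  missing <- setdiff(seq_len(n_regions), unique(lab))
  if (length(missing)) stop("internal: region(s) empty: ",
                            paste(missing, collapse = ","))
  means <- c(10, 60, seq(120, 240, length.out = n_blob))
  gray <- means[lab + 1L] + stats::rnorm(length(lab), 0, 6)
  gray[lab == 0L] <- pmax(gray[lab == 0L], 0)
  gray <- round(pmin(pmax(gray, 0), 255))
  nm <- structure(c("outline", paste0("blob_", seq_len(n_blob))),
                  names = as.character(seq_len(n_regions)))
  list(volume = volume3d(array(gray, shape), voxel_size),
       labels = label_volume(array(lab, shape), names = nm,
                             voxel_size = voxel_size))
}

#' Warp a label volume by a known synthetic deformation
#'
#' Companion to [make_synthetic_brain()] for recovery harnesses: treats
#' the deformation's field as the forward (push) field and resamples
#' gray/label data through its fixed-point inverse, so a region centered
#' at `p` lands near `p + t(p)`.
#'
#' @param v [volume3d()] or [label_volume()].
#' @param deform `SyntheticDeformation`.
#' @return warped object of the same class.
#' @export
warp_by_deformation <- function(v, deform) {
  inv <- invert_field(deform$field)
  apply_transform_lowres(v, affine_transform(), inv)
}
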