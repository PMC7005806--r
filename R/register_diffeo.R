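# Symmetric compositional diffeomorphic registration on feature channels.
#
# Two half-way pull-back fields are maintained: u1 warps the (affinely
# pre-aligned) moving channels toward the midpoint and u2 warps the fixed
# channels toward the same midpoint, so the two images meet half-way. Per
# iteration a demons-like force is computed from the channel residuals,
# smoothed (fluid regularization), capped, and composed into both
# half-fields in opposite directions; the accumulated fields are then
# smoothed (elastic regularization). The returned pair is
#   phi2 (inverse field): pull-back, out(q) = moving([q] x M + phi2(q));
#   phi1 (direct field):  push-forward for points,
#                         fixed = [p] x M^-1 + phi1(p).
# Both are obtained from the half-fields by fixed-point inversion and
# composition, which keeps them inverse-consistent by construction.

#' Compose two displacement fields
#'
#' `(f o g)(x) = g(x) + f(x + g(x))`: the mapping applies `g` first, then
#' `f` (`T_{f o g} = T_f . T_g` for `T_u(x) = x + u(x)`). `f` is sampled
#' trilinearly with clamp-to-edge.
#'
#' @param f,g [displacement_field()]s on one lattice.
#' @return composed [displacement_field()].
#' @export
compose_fields <- function(f, g) {
  d <- field_shape(f)
  if (!identical(d, field_shape(g)))
    stop("fields must share one lattice")
  base <- grid_coords(d)
  pts <- base + cbind(as.vector(g$components[[1]]),
                      as.vector(g$components[[2]]),
                      as.vector(g$components[[3]]))
  pts <- clamp_pts(pts, d)
  displacement_field(
    g$components[[1]] + array(sample_array(f$components[[1]], pts), d),
    g$components[[2]] + array(sample_array(f$components[[2]], pts), d),
    g$components[[3]] + array(sample_array(f$components[[3]], pts), d))
}

clamp_pts <- function(pts, d) {
  cbind(pmin(pmax(pts[, 1], 0), d[1] - 1),
        pmin(pmax(pts[, 2], 0), d[2] - 1),
        pmin(pmax(pts[, 3], 0), d[3] - 1))
}

#' Invert a displacement field by fixed-point iteration
#'
#' Iterates `g <- -(f o g)` evaluated as `g_{n+1}(x) = -f(x + g_n(x))`
#' until the composition residual `max |(f o g)(x)|` drops below `tol` or
#' the iteration budget is exhausted (then a warning reports the
#' residual). Exact for fields whose magnitude is small relative to their
#' smoothness.
#'
#' @param f [displacement_field()].
#' @param iters maximum iterations.
#' @param tol target residual in voxels.
#' @return [displacement_field()] `g` with attributes `residual` and
#'   `iterations`.
#' @export
invert_field <- function(f, iters = 50L, tol = 0.01) {
  d <- field_shape(f)
  base <- grid_coords(d)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  res <- Inf
  for (it in seq_len(iters)) {
    pts <- clamp_pts(base + cbind(as.vector(gx), as.vector(gy),
                                  as.vector(gz)), d)
    nx <- -array(sample_array(f$components[[1]], pts), d)
    ny <- -array(sample_array(f$components[[2]], pts), d)
    nz <- -array(sample_array(f$components[[3]], pts), d)
    res <- max(abs(nx - gx), abs(ny - gy), abs(nz - gz))
    gx <- nx; gy <- ny; gz <- nz
    if (res < tol) break
  }
  g <- displacement_field(gx, gy, gz)
  resid <- max(field_norm(compose_fields(f, g)))
  if (resid > tol)
    warning("field inversion residual ", signif(resid, 3),
            " voxels exceeds tol ", tol)
  attr(g, "residual") <- resid
  attr(g, "iterations") <- it
  g
}

#' Warp a volume by affine + displacement field at working resolution
#'
#' Pull-back resampling: `out(q) = v([q] x M + phi(q))` on the field's
#' lattice (or the volume's own lattice when `field` is `NULL`). Gray
#' volumes use trilinear interpolation, label volumes nearest-neighbor;
#' out-of-bounds samples are 0. This whole-volume warp is also the
#' reference ("oracle") against which the block-wise high-resolution
#' transform is validated.
#'
#' @param v [volume3d()] or [label_volume()].
#' @param M [affine_transform()] (fixed -> moving voxel coordinates).
#' @param field optional [displacement_field()] (phi2, pull-back).
#' @param interp override interpolation (`"linear"` or `"nearest"`).
#' @return warped object of the same class as `v`.
#' @export
apply_transform_lowres <- function(v, M = affine_transform(), field = NULL,
                                   interp = NULL) {
  is_label <- inherits(v, "LabelVolume")
  if (is.null(interp)) interp <- if (is_label) "nearest" else "linear"
  out_shape <- if (is.null(field)) dim(v$data) else field_shape(field)
  g <- grid_coords(out_shape)
  src <- affine_apply(M, g)
  if (!is.null(field))
    src <- src + cbind(as.vector(field$components[[1]]),
                       as.vector(field$components[[2]]),
                       as.vector(field$components[[3]]))
  vals <- sample_array(v$data, src, method = interp, fill = 0)
  a <- array(vals, out_shape)
  if (is_label)
    label_volume(a, names = v$names, voxel_size = v$voxel_size)
  else volume3d(a, v$voxel_size)
}

#' Symmetric diffeomorphic registration of feature images
#'
#' @param fixed,moving [encode_features()] outputs with identical channel
#'   sets on one lattice.
#' @param init [affine_transform()] applied to the moving image first
#'   (from [register_affine()]); identity by default.
#' @param cfg [registration_config()].
#' @return Object of class `RegistrationResult`: `M` (the init affine),
#'   `phi1` (direct field, push-forward for points), `phi2` (inverse
#'   field, pull-back for images), `energy_trace` (data.frame with
#'   columns `level`, `energy`: the mean squared channel residual of each
#'   accepted iteration, non-increasing within a level).
#' @export
register_diffeomorphic <- function(fixed, moving, init = affine_transform(),
                                   cfg = registration_config()) {
  check_channels(fixed, moving)
  d <- dim(fixed$channels[[1]])
  # pre-align moving channels onto the fixed lattice
  mov_aligned <- lapply(moving$channels, function(ch)
    warp_channel(ch, affine_apply(init, grid_coords(d)), d))
  u1 <- u2 <- NULL
  trace <- NULL
  for (li in seq_along(cfg$levels)) {
    f <- cfg$levels[li]
    fix_l <- lapply(fixed$channels, function(ch)
      if (f > 1) downsample_mean(ch, f) else ch)
    mov_l <- lapply(mov_aligned, function(ch)
      if (f > 1) downsample_mean(ch, f) else ch)
    dl <- dim(fix_l[[1]])
    if (is.null(u1)) {
      u1 <- zero_field(dl); u2 <- zero_field(dl)
    } else {
      u1 <- resample_field(u1, dl); u2 <- resample_field(u2, dl)
    }
    res <- demons_level(fix_l, mov_l, u1, u2, cfg,
                        iters = cfg$iters_per_level[li])
    u1 <- res$u1; u2 <- res$u2
    trace <- rbind(trace, data.frame(level = f, energy = res$trace))
    if (res$diverged)
      stop("convergence error: energy diverged; trace: ",
           paste(signif(res$trace, 4), collapse = ", "))
  }
  u1_inv <- invert_field(u1)
  u2_inv <- invert_field(u2)
  v <- compose_fields(u1, u2_inv)      # fixed -> moving (pre-affine)
  v_inv <- compose_fields(u2, u1_inv)  # moving -> fixed
  L <- init$matrix[1:3, 1:3]
  phi2 <- displacement_field(
    v$components[[1]] * L[1, 1] + v$components[[2]] * L[2, 1] +
      v$components[[3]] * L[3, 1],
    v$components[[1]] * L[1, 2] + v$components[[2]] * L[2, 2] +
      v$components[[3]] * L[3, 2],
    v$components[[1]] * L[1, 3] + v$components[[2]] * L[2, 3] +
      v$components[[3]] * L[3, 3])
  # phi1 lives on the moving lattice: phi1(p) = v_inv([p] x M^-1)
  Minv <- affine_invert(init)
  back <- clamp_pts(affine_apply(Minv, grid_coords(d)), d)
  phi1 <- displacement_field(
    array(sample_array(v_inv$components[[1]], back), d),
    array(sample_array(v_inv$components[[2]], back), d),
    array(sample_array(v_inv$components[[3]], back), d))
  structure(list(M = init, phi1 = phi1, phi2 = phi2,
                 energy_trace = trace),
            class = "RegistrationResult")
}

#' @export
print.RegistrationResult <- function(x, ...) {
  cat("RegistrationResult:", nrow(x$energy_trace),
      "accepted iterations, final energy",
      signif(utils::tail(x$energy_trace$energy, 1), 5), "\n")
  invisible(x)
}

warp_channel <- function(ch, pts, out_shape) {
  array(sample_array(ch, pts, "linear"), out_shape)
}

resample_field <- function(u, new_shape) {
  old <- field_shape(u)
  sc <- ifelse(old > 1, (new_shape - 1) / pmax(old - 1, 1), 1)
  displacement_field(resample_shape(u$components[[1]], new_shape) * sc[1],
                     resample_shape(u$components[[2]], new_shape) * sc[2],
                     resample_shape(u$components[[3]], new_shape) * sc[3])
}

demons_level <- function(fix_l, mov_l, u1, u2, cfg, iters,
                         patience = 8L) {
  d <- dim(fix_l[[1]])
  base <- grid_coords(d)
  sigu <- sig3(cfg$update_sigma, d)
  sigf <- sig3(cfg$field_sigma, d)
  step <- cfg$step
  trace <- numeric()
  bad <- 0L
  e_prev <- Inf
  prev_u1 <- u1; prev_u2 <- u2
  for (it in seq_len(iters + 1L)) {
    # one warp pass serves both the energy check of the current state
    # and, if accepted, the force computation
    p1 <- clamp_field_pts(base, u1, d)
    p2 <- clamp_field_pts(base, u2, d)
    wm <- lapply(mov_l, function(ch) array(sample_array(ch, p1), d))
    wf <- lapply(fix_l, function(ch) array(sample_array(ch, p2), d))
    e <- sum(vapply(seq_along(fix_l), function(ci)
      sum((wf[[ci]] - wm[[ci]])^2), 0.0)) / (length(fix_l) * prod(d))
    if (e > e_prev) {
      # reject the last update: rewind and shorten the step
      u1 <- prev_u1; u2 <- prev_u2
      bad <- bad + 1L
      step <- step / 2
      if (step < 1e-3 || bad >= patience) break
      next
    }
    trace <- c(trace, e)
    e_prev <- e
    prev_u1 <- u1; prev_u2 <- u2
    bad <- 0L
    if (it > iters) break
    num <- list(array(0, d), array(0, d), array(0, d))
    den <- array(0, d)
    dsum <- array(0, d)
    for (ci in seq_along(fix_l)) {
      di <- wf[[ci]] - wm[[ci]]
      dsum <- dsum + di^2
      for (ax in 1:3) {
        gax <- (grad_axis(wm[[ci]], ax) + grad_axis(wf[[ci]], ax)) / 2
        num[[ax]] <- num[[ax]] + di * gax
        den <- den + gax^2
      }
    }
    den <- den + dsum + 1e-12
    delta <- lapply(num, function(nax) smooth_gauss(nax / den, sigu))
    nmax <- max(sqrt(delta[[1]]^2 + delta[[2]]^2 + delta[[3]]^2))
    if (nmax > step)
      delta <- lapply(delta, function(a) a * (step / nmax))
    half <- displacement_field(delta[[1]] / 2, delta[[2]] / 2,
                               delta[[3]] / 2)
    nhalf <- displacement_field(-delta[[1]] / 2, -delta[[2]] / 2,
                                -delta[[3]] / 2)
    u1 <- smooth_field(compose_fields(u1, half), sigf)
    u2 <- smooth_field(compose_fields(u2, nhalf), sigf)
  }
  list(u1 = prev_u1, u2 = prev_u2, trace = trace,
       diverged = length(trace) == 0L)
}

sig3 <- function(s, d) c(s, s, if (d[3] == 1L) 0 else s)

clamp_field_pts <- function(base, u, d) {
  clamp_pts(base + cbind(as.vector(u$components[[1]]),
                         as.vector(u$components[[2]]),
                         as.vector(u$components[[3]])), d)
}

smooth_field <- function(u, sig) {
  displacement_field(smooth_gauss(u$components[[1]], sig),
                     smooth_gauss(u$components[[2]], sig),
                     smooth_gauss(u$components[[3]], sig))
}
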