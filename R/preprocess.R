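# Volume preparation before registration: multiplicative illumination /
# brightness correction, isotropic resampling to the working resolution,
# and automatic outline (sample silhouette) extraction.

#' Preprocessing configuration
#'
#' @param background_sigma Gaussian sigma (pixels) of the per-slice
#'   low-pass background estimate used for illumination correction.
#' @param target_voxel target isotropic voxel size in micrometres.
#' @param threshold_block local-mean adaptive threshold window (pixels).
#' @param morph_radius ball radius (voxels) of the morphological
#'   opening/closing applied to the outline mask.
#' @return named list of class `PreprocessConfig`.
#' @export
preprocess_config <- function(background_sigma = 25, target_voxel = 10,
                              threshold_block = 31L, morph_radius = 2L) {
  if (any(c(background_sigma, target_voxel, threshold_block,
            morph_radius) <= 0))
    stop("all preprocessing parameters must be positive")
  structure(list(background_sigma = background_sigma,
                 target_voxel = target_voxel,
                 threshold_block = as.integer(threshold_block),
                 morph_radius = as.integer(morph_radius)),
            class = "PreprocessConfig")
}

#' Multiplicative illumination / brightness correction
#'
#' Each slice is divided by a Gaussian-smoothed estimate of its own
#' background (illumination gain is multiplicative in optical microscopy)
#' and rescaled to preserve the slice mean; all-zero slices pass through
#' unchanged. Output is clipped to the input's value range.
#'
#' @param v [volume3d()], non-negative.
#' @param cfg [preprocess_config()].
#' @return corrected [volume3d()].
#' @export
correct_illumination <- function(v, cfg = preprocess_config()) {
  stopifnot(inherits(v, "Volume3D"))
  if (min(v$data) < 0) stop("volume must be non-negative")
  a <- v$data
  d <- dim(a)
  vmax <- max(a)
  for (k in seq_len(d[3])) {
    sl <- a[, , k]
    mu <- mean(sl)
    if (mu == 0) next
    bg <- smooth_gauss(array(sl, c(d[1], d[2], 1L)),
                       c(cfg$background_sigma, cfg$background_sigma, 0))[, , 1]
    bg[bg < mu * 1e-3] <- mu * 1e-3
    corr <- sl / bg
    corr <- corr * (mu / mean(corr))
    a[, , k] <- pmin(pmax(corr, 0), vmax)
  }
  volume3d(a, v$voxel_size)
}

#' Resample a volume onto an isotropic grid
#'
#' Trilinear resampling; the new shape is `round(shape * voxel_size /
#' target)` and the physical field of view is preserved (index i maps to
#' physical `i * voxel_size`).
#'
#' @param v [volume3d()] or [label_volume()] (labels use nearest).
#' @param target isotropic voxel size in micrometres.
#' @return resampled object of the same class, voxel size
#'   `(target, target, target)`.
#' @export
resample_isotropic <- function(v, target) {
  if (target <= 0) stop("target voxel size must be > 0")
  d <- dim(v$data)
  new_shape <- as.integer(round(d * v$voxel_size / target))
  if (any(new_shape < 1L))
    stop("target voxel size ", target, " collapses a dimension to 0")
  if (all(new_shape == d) && all(v$voxel_size == target)) return(v)
  is_label <- inherits(v, "LabelVolume")
  g <- grid_coords(new_shape)
  sc <- target / v$voxel_size
  pts <- cbind(g[, 1] * sc[1], g[, 2] * sc[2], g[, 3] * sc[3])
  vals <- sample_array(v$data, pts,
                       method = if (is_label) "nearest" else "linear")
  a <- array(vals, new_shape)
  if (is_label) label_volume(a, names = v$names, voxel_size = rep(target, 3))
  else volume3d(a, rep(target, 3))
}

#' Extract the sample outline mask
#'
#' Per-slice local-mean adaptive threshold (window `threshold_block`,
#' offset 0), 3D hole filling (background flood from the volume border),
#' morphological opening then closing with a ball of radius
#' `morph_radius`, keeping the largest connected component.
#'
#' @param v preprocessed [volume3d()].
#' @param cfg [preprocess_config()].
#' @return binary [label_volume()] (label 1 = `outline`); empty
#'   foreground yields an empty mask with a warning.
#' @export
extract_outline <- function(v, cfg = preprocess_config()) {
  stopifnot(inherits(v, "Volume3D"))
  a <- v$data
  d <- dim(a)
  mask <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    sl <- array(a[, , k], c(d[1], d[2], 1L))
    r <- min(cfg$threshold_block %/% 2L, d[1] - 1L, d[2] - 1L)
    loc <- box_mean(sl, c(r, r, 0L))
    mask[, , k] <- sl > loc
  }
  if (!any(mask)) {
    warning("empty foreground: returning empty outline mask")
    return(label_volume(array(0L, d), names = c("1" = "outline"),
                        voxel_size = v$voxel_size))
  }
  mask <- fill_holes_3d(mask)
  mask <- morph_open(mask, cfg$morph_radius)
  mask <- morph_close(mask, cfg$morph_radius)
  mask <- largest_component(mask)
  label_volume(array(as.integer(mask), d), names = c("1" = "outline"),
               voxel_size = v$voxel_size)
}

# Box (moving-average) filter with replicate edges, radius r per axis.
box_mean <- function(arr, r) {
  for (ax in 1:3) {
    if (r[ax] <= 0 || dim(arr)[ax] == 1L) next
    k <- rep(1 / (2 * r[ax] + 1), 2 * r[ax] + 1)
    arr <- conv_axis(arr, k, ax)
  }
  arr
}

# Fill interior holes: background connected to the border (6-connectivity)
# stays background, enclosed background becomes foreground.
fill_holes_3d <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  seed <- array(FALSE, d)
  seed[1, , ] <- bg[1, , ]; seed[d[1], , ] <- bg[d[1], , ]
  seed[, 1, ] <- seed[, 1, ] | bg[, 1, ]; seed[, d[2], ] <- seed[, d[2], ] | bg[, d[2], ]
  seed[, , 1] <- seed[, , 1] | bg[, , 1]; seed[, , d[3]] <- seed[, , d[3]] | bg[, , d[3]]
  seed <- flood_grow(seed, bg)
  mask | (bg & !seed)
}

# Morphological reconstruction by iterative 6-neighbor dilation within a
# mask; converges in at most diameter iterations.
flood_grow <- function(seed, mask) {
  repeat {
    grown <- seed |
      shift_axis(seed, 1, 1L) | shift_axis(seed, 1, -1L) |
      shift_axis(seed, 2, 1L) | shift_axis(seed, 2, -1L) |
      shift_axis(seed, 3, 1L) | shift_axis(seed, 3, -1L)
    grown <- grown & mask
    if (identical(grown, seed)) return(seed)
    seed <- grown
  }
}

ball_offsets <- function(r) {
  o <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  o[rowSums(o^2) <= r^2 + 1e-9, , drop = FALSE]
}

shift3 <- function(arr, by) {
  for (ax in 1:3) if (by[ax] != 0L) arr <- shift_axis_zero(arr, ax, by[ax])
  arr
}

# Shift with FALSE/0 boundary (content moves by +by).
shift_axis_zero <- function(arr, ax, by) {
  d <- dim(arr)
  out <- array(if (is.logical(arr)) FALSE else 0, d)
  n <- d[ax]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  ix <- function(a, i) switch(ax, a[i, , , drop = FALSE],
                              a[, i, , drop = FALSE], a[, , i, drop = FALSE])
  asn <- function(i, val) switch(ax, out[i, , ] <<- val,
                                 out[, i, ] <<- val, out[, , i] <<- val)
  asn(dst, ix(arr, src))
  out
}

morph_erode <- function(mask, r) {
  off <- ball_offsets(r)
  out <- mask
  for (i in seq_len(nrow(off))) {
    if (all(off[i, ] == 0)) next
    out <- out & shift3(mask, off[i, ])
  }
  out
}

morph_dilate <- function(mask, r) {
  off <- ball_offsets(r)
  out <- mask
  for (i in seq_len(nrow(off))) {
    if (all(off[i, ] == 0)) next
    out <- out | shift3(mask, off[i, ])
  }
  out
}

morph_open <- function(mask, r) morph_dilate(morph_erode(mask, r), r)
morph_close <- function(mask, r) morph_erode(morph_dilate(mask, r), r)

# Largest 6-connected foreground component.
largest_component <- function(mask) {
  remaining <- mask
  best <- NULL; best_n <- 0L
  while (any(remaining)) {
    first <- which(remaining)[1]
    seed <- array(FALSE, dim(mask)); seed[first] <- TRUE
    comp <- flood_grow(seed, remaining)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
  }
  if (is.null(best)) mask else best
}
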