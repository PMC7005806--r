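# Vectorised numeric primitives shared by the registration and warping
# modules: trilinear / nearest sampling, separable Gaussian smoothing,
# central-difference gradients, block-mean downsampling and a squared
# Euclidean distance transform. All coordinates are 0-based voxel indices.

#' Sample a 3D array at continuous 0-based coordinates
#'
#' Trilinear interpolation gathers the 8 cell corners with weights
#' `(1-x0)(1-y0)(1-z0) ... x0*y0*z0` where `(x0, y0, z0)` are the relative
#' coordinates within the voxel box; nearest assigns half-integer
#' boundaries to the lower index. Coordinates outside `[0, dim-1]` return
#' `fill` (trilinear: any corner support outside returns fill only if the
#' query point itself is outside; edge queries clamp onto the boundary
#' cell).
#'
#' @param arr 3D numeric array.
#' @param pts N x 3 matrix of 0-based continuous coordinates.
#' @param method `"linear"` or `"nearest"`.
#' @param fill value returned for out-of-bounds queries.
#' @return numeric vector of length N.
#' @export
sample_array <- function(arr, pts, method = c("linear", "nearest"),
                         fill = 0) {
  method <- match.arg(method)
  pts <- rbind3(pts)
  d <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1
  inside[is.na(inside)] <- FALSE
  out <- rep(as.numeric(fill), nrow(pts))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  if (method == "nearest") {
    # half-integer coordinates resolve to the lower index
    ix <- ceiling(x - 0.5); iy <- ceiling(y - 0.5); iz <- ceiling(z - 0.5)
    out[inside] <- arr[1 + ix + d[1] * (iy + d[2] * iz)]
    return(out)
  }
  x0 <- pmin(pmax(floor(x), 0), max(d[1] - 2, 0))
  y0 <- pmin(pmax(floor(y), 0), max(d[2] - 2, 0))
  z0 <- pmin(pmax(floor(z), 0), max(d[3] - 2, 0))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  if (d[1] == 1L) fx <- 0
  if (d[2] == 1L) fy <- 0
  if (d[3] == 1L) fz <- 0
  sx <- if (d[1] > 1L) 1 else 0
  sy <- if (d[2] > 1L) 1 else 0
  sz <- if (d[3] > 1L) 1 else 0
  i000 <- 1 + x0 + d[1] * (y0 + d[2] * z0)
  dx <- sx; dy <- sy * d[1]; dz <- sz * d[1] * d[2]
  v <- arr[i000] * (1 - fx) * (1 - fy) * (1 - fz) +
    arr[i000 + dy] * (1 - fx) * fy * (1 - fz) +
    arr[i000 + dz] * (1 - fx) * (1 - fy) * fz +
    arr[i000 + dy + dz] * (1 - fx) * fy * fz +
    arr[i000 + dx] * fx * (1 - fy) * (1 - fz) +
    arr[i000 + dx + dy] * fx * fy * (1 - fz) +
    arr[i000 + dx + dz] * fx * (1 - fy) * fz +
    arr[i000 + dx + dy + dz] * fx * fy * fz
  out[inside] <- v
  out
}

# Grid of all 0-based voxel coordinates of a shape, as an N x 3 matrix in
# column-major (x fastest) order, matching as.vector() of an array.
grid_coords <- function(shape) {
  cbind(
    rep.int(seq_len(shape[1]) - 1, shape[2] * shape[3]),
    rep.int(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[3]),
    rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2])
  )
}

# Separable Gaussian smoothing with replicate-edge padding.
# sigma: length-3 (voxels); a zero sigma skips that axis. Kernel radius
# ceil(3 sigma).
smooth_gauss <- function(arr, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  d <- dim(arr)
  for (ax in 1:3) {
    if (sigma[ax] <= 0 || d[ax] == 1L) next
    r <- max(1L, ceiling(3 * sigma[ax]))
    k <- stats::dnorm(seq(-r, r), sd = sigma[ax])
    k <- k / sum(k)
    arr <- conv_axis(arr, k, ax)
  }
  arr
}

# Convolve along one axis with kernel k (odd length), replicate padding.
conv_axis <- function(arr, k, ax) {
  d <- dim(arr)
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  dp <- dim(a)
  m <- matrix(a, nrow = dp[1])
  r <- (length(k) - 1L) / 2L
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
              m[rep(nrow(m), r), , drop = FALSE])
  f <- stats::filter(mp, k, sides = 2)
  m2 <- matrix(f[(r + 1L):(r + dp[1]), ], nrow = dp[1])
  a2 <- array(m2, dp)
  aperm(a2, order(perm))
}

# Central-difference gradient along one axis, replicate edges, per-voxel
# units.
grad_axis <- function(arr, ax) {
  d <- dim(arr)
  n <- d[ax]
  if (n == 1L) return(array(0, d))
  hi <- shift_axis(arr, ax, 1L)
  lo <- shift_axis(arr, ax, -1L)
  g <- (hi - lo) / 2
  # one-sided at the two boundary planes
  idx <- function(i) slice_index(d, ax, i)
  g[idx(1L)] <- (arr[idx(2L)] - arr[idx(1L)])
  g[idx(n)] <- (arr[idx(n)] - arr[idx(n - 1L)])
  g
}

# Shift array content by `by` along axis ax with replicate boundary:
# result[i] = arr[clamp(i + by)].
shift_axis <- function(arr, ax, by) {
  d <- dim(arr)
  i <- pmin(pmax(seq_len(d[ax]) + by, 1L), d[ax])
  switch(ax,
         arr[i, , , drop = FALSE],
         arr[, i, , drop = FALSE],
         arr[, , i, drop = FALSE])
}

slice_index <- function(d, ax, i) {
  a <- array(FALSE, d)
  switch(ax,
         a[i, , ] <- TRUE,
         a[, i, ] <- TRUE,
         a[, , i] <- TRUE)
  a
}

# Block-mean downsampling by integer factor per axis (trims remainder).
downsample_mean <- function(arr, f) {
  if (length(f) == 1L) f <- rep(f, 3L)
  f <- pmax(1L, as.integer(f))
  d <- dim(arr)
  nd <- pmax(1L, d %/% f)
  f <- ifelse(nd * f > d, 1L, f)  # axis too short to downsample
  nd <- pmax(1L, d %/% f)
  a <- arr[seq_len(nd[1] * f[1]), seq_len(nd[2] * f[2]),
           seq_len(nd[3] * f[3]), drop = FALSE]
  dim(a) <- c(f[1], nd[1], f[2], nd[2], f[3], nd[3])
  a <- apply(a, c(2, 4, 6), mean)
  array(a, nd)
}

# Trilinear resampling of an array onto a new shape such that the old
# lattice [0, d-1] maps linearly onto [0, nd-1].
resample_shape <- function(arr, new_shape, method = "linear") {
  d <- dim(arr)
  sc <- ifelse(new_shape > 1, (d - 1) / (new_shape - 1), 0)
  g <- grid_coords(new_shape)
  pts <- cbind(g[, 1] * sc[1], g[, 2] * sc[2], g[, 3] * sc[3])
  array(sample_array(arr, pts, method = method), new_shape)
}

# Squared Euclidean distance (in voxels, anisotropy via w = per-axis
# spacing) from every voxel to the nearest TRUE voxel of `mask`.
# Felzenszwalb-Huttenlocher separable lower-envelope transform.
edt_squared <- function(mask, w = c(1, 1, 1)) {
  d <- dim(mask)
  INF <- sum((d * w)^2) * 4 + 1
  g <- array(ifelse(mask, 0, INF), d)
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(g, perm)
    dp <- dim(a)
    m <- matrix(a, nrow = dp[1])
    m <- apply(m, 2, dt1d, w = w[ax], INF = INF)
    g <- aperm(array(m, dp), order(perm))
  }
  g
}

# 1D squared-distance lower-envelope transform under sampling step w.
# INF is a finite stand-in for +infinity large enough to never win.
dt1d <- function(f, w, INF) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n); zl <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; zl[1L] <- -Inf; zl[2L] <- Inf
  x <- (seq_len(n) - 1) * w
  for (q in 2:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
      if (s <= zl[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    zl[k] <- s
    zl[k + 1L] <- Inf
  }
  out <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (zl[k + 1L] < x[q]) k <- k + 1L
    out[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  out
}
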