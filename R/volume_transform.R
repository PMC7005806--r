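# Block-wise application of a coarse-resolution transform to a
# full-resolution volume. The low-resolution affine is conjugated by
# scale matrices onto high-resolution coordinates; the displacement field
# stays at low resolution and is interpolated trilinearly on the fly, so
# no high-resolution field is ever materialized. Each output block maps
# the points of its six face surfaces into source space to discover its
# region of interest (ROI), loads only the source blocks overlapping that
# ROI, and resamples by pull-back. Blocks are pure functions of (extent,
# source, mapping): any worker count or execution order yields identical
# output.

#' High-resolution mapping (rescaled affine + low-res field + scale)
#'
#' For a high-resolution output coordinate `P`, the source coordinate is
#' `P'' = [P] x M' + s * phi(P / s)` with `phi` interpolated trilinearly
#' on its low-resolution lattice (clamp-to-edge). `s` is the quotient of
#' the low-resolution and high-resolution voxel sizes (>= 1), scalar or
#' per-axis.
#'
#' @param M_prime [affine_transform()] already rescaled to
#'   high-resolution coordinates (see [scale_affine()]).
#' @param field [displacement_field()] on the low-resolution lattice, in
#'   low-resolution voxel units (the pull-back / inverse-direction field
#'   when warping moving images into fixed space).
#' @param s scale factor, scalar or length-3, all >= 1.
#' @param out_shape high-resolution output extent (3 integers).
#' @return Object of class `HighResMapping`.
#' @export
high_res_mapping <- function(M_prime, field, s, out_shape) {
  stopifnot(inherits(M_prime, "AffineTransform"),
            inherits(field, "DisplacementField"))
  s <- rep(as.numeric(s), length.out = 3)
  if (any(s < 1)) stop("scale factor s must be >= 1")
  out_shape <- as.integer(out_shape)
  cover <- (field_shape(field) - 1) * s
  if (any(out_shape - 1 > cover + s))
    warning("field lattice x s does not cover out_shape; ",
            "edge voxels rely on clamp-to-edge extension")
  structure(list(M_prime = M_prime, field = field, s = s,
                 out_shape = out_shape),
            class = "HighResMapping")
}

#' Rescale a low-resolution affine to high-resolution coordinates
#'
#' Conjugation by scale matrices: `M' = diag(1/s, 1) x M x diag(s, 1)`
#' (row-vector convention), so that for any low-resolution point `p` and
#' its high-resolution twin `P = s * p`, `[P] x M' = s * ([p] x M)`
#' exactly: the shrinking matrix takes high-res coordinates down to the
#' low-res lattice where `M` acts, and the amplifying matrix returns the
#' result to high-res coordinates.
#'
#' @param M low-resolution [affine_transform()].
#' @param s scale factor (> 0), scalar or per-axis.
#' @return high-resolution [affine_transform()].
#' @export
scale_affine <- function(M, s) {
  s <- rep(as.numeric(s), length.out = 3)
  if (any(s <= 0)) stop("scale factor must be > 0")
  D1 <- diag(c(1 / s, 1))
  D2 <- diag(c(s, 1))
  affine_transform(D1 %*% M$matrix %*% D2)
}

#' Trilinear interpolation of a displacement field
#'
#' Evaluates the field at continuous low-resolution coordinates by the
#' 8-corner weighted sum with weights `(1-x0)(1-y0)(1-z0) ... x0 y0 z0`,
#' where `(x0, y0, z0)` is the relative position in the voxel box; query
#' points outside the lattice clamp to the boundary cells.
#'
#' @param field [displacement_field()].
#' @param q N x 3 matrix of continuous low-resolution coordinates.
#' @return N x 3 matrix of displacement vectors (low-res voxel units).
#' @export
interp_field <- function(field, q) {
  q <- rbind3(q)
  if (anyNA(q) || !all(is.finite(q))) stop("query coordinates contain NaN")
  d <- field_shape(field)
  q <- clamp_pts(q, d)
  cbind(sample_array(field$components[[1]], q),
        sample_array(field$components[[2]], q),
        sample_array(field$components[[3]], q))
}

#' Map high-resolution points through a HighResMapping
#'
#' `P' = [P] x M'`; `P'' = P' + s * phi(P / s)` componentwise, vectorized
#' over rows.
#'
#' @param m [high_res_mapping()].
#' @param P N x 3 matrix of high-resolution coordinates.
#' @return N x 3 matrix of high-resolution source coordinates.
#' @export
map_point <- function(m, P) {
  P <- rbind3(P)
  P1 <- affine_apply(m$M_prime, P)
  q <- cbind(P[, 1] / m$s[1], P[, 2] / m$s[2], P[, 3] / m$s[3])
  phi <- interp_field(m$field, q)
  cbind(P1[, 1] + m$s[1] * phi[, 1],
        P1[, 2] + m$s[2] * phi[, 2],
        P1[, 3] + m$s[3] * phi[, 3])
}

#' Tile an output space into blocks
#'
#' Half-open tiling; edge blocks are trimmed. Iteration order is
#' row-major in (k, j, i): i (x) varies fastest.
#'
#' @param out_shape 3 integers.
#' @param block_size 3 integers >= 8 (scalar recycled).
#' @return Object of class `BlockGrid` with `out_shape`, `block_size`,
#'   `n_blocks`.
#' @export
plan_blocks <- function(out_shape, block_size) {
  out_shape <- as.integer(out_shape)
  block_size <- as.integer(rep(block_size, length.out = 3))
  if (any(block_size < 8L)) stop("block_size must be >= 8 per axis")
  structure(list(out_shape = out_shape, block_size = block_size,
                 n_blocks = as.integer(ceiling(out_shape / block_size))),
            class = "BlockGrid")
}

#' Block indices of a grid in iteration order
#' @param grid [plan_blocks()] result (or `BlockStore`).
#' @return matrix with one (i, j, k) row per block, i fastest.
#' @export
block_indices <- function(grid) {
  n <- grid$n_blocks
  cbind(rep.int(seq_len(n[1]) - 1L, n[2] * n[3]),
        rep.int(rep(seq_len(n[2]) - 1L, each = n[1]), n[3]),
        rep(seq_len(n[3]) - 1L, each = n[1] * n[2]))
}

#' Source ROI of an output block via six-surface mapping
#'
#' Maps a lattice of points covering all six faces of the block (every
#' face voxel for blocks up to 64 per axis, else a stride-2 lattice that
#' always includes the corners) through [map_point()], takes the
#' axis-aligned bounding box, pads it by `margin` (extrema of a nonlinear
#' map need not lie on the face image, so a conservative margin is always
#' added), and clips to the source extent.
#'
#' @param extent list with `lo`/`hi` half-open 0-based voxel bounds of
#'   the output block.
#' @param m [high_res_mapping()].
#' @param margin padding in high-res voxels (default `2 * max(s)`).
#' @param src_shape source volume shape for clipping (and block overlap).
#' @param src_store optional `BlockStore`; adds the overlapped source
#'   block index set.
#' @return list `lo`, `hi` (half-open source bounds), `empty` flag, and
#'   `src_blocks` (matrix of block index triples) when `src_store` given.
#' @export
roi_for_block <- function(extent, m, margin = NULL, src_shape = NULL,
                          src_store = NULL) {
  if (is.null(margin)) margin <- 2 * max(m$s)
  if (margin < 0) stop("margin must be >= 0")
  if (is.null(src_shape) && !is.null(src_store)) src_shape <- src_store$shape
  pts <- face_lattice(extent)
  S <- map_point(m, pts)
  lo <- floor(apply(S, 2, min)) - margin
  hi <- ceiling(apply(S, 2, max)) + margin + 1  # half-open
  if (!is.null(src_shape)) {
    lo <- pmax(lo, 0)
    hi <- pmin(hi, src_shape)
  }
  roi <- list(lo = as.integer(lo), hi = as.integer(hi),
              empty = any(hi <= lo))
  if (!is.null(src_store)) {
    roi$src_blocks <- if (roi$empty) matrix(integer(), 0, 3)
    else {
      rng <- lapply(1:3, function(ax)
        (lo[ax] %/% src_store$block_size[ax]):((hi[ax] - 1L) %/% src_store$block_size[ax]))
      as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
    }
  }
  roi
}

# All voxel coordinates on the six faces of a half-open extent; stride 2
# plus corners for faces larger than 64 voxels per axis.
face_lattice <- function(extent) {
  lo <- extent$lo; hi <- extent$hi - 1L  # inclusive bounds
  stride <- if (all(hi - lo + 1L <= 64L)) 1L else 2L
  ax_seq <- function(a) unique(c(seq(lo[a], hi[a], by = stride), hi[a]))
  xs <- ax_seq(1); ys <- ax_seq(2); zs <- ax_seq(3)
  rbind(
    as.matrix(expand.grid(x = c(lo[1], hi[1]), y = ys, z = zs)),
    as.matrix(expand.grid(x = xs, y = c(lo[2], hi[2]), z = zs)),
    as.matrix(expand.grid(x = xs, y = ys, z = c(lo[3], hi[3])))
  )
}

#' Transform one output block
#'
#' Discovers the source ROI from the block's six surfaces, assembles the
#' overlapping source blocks, and fills every output voxel `P` with the
#' source value at `map_point(P)` (trilinear for gray, nearest for
#' labels); source coordinates outside the source volume yield the
#' store's fill value. If any sample's interpolation support escapes the
#' surface-derived ROI (possible for strongly nonlinear maps), the ROI is
#' enlarged to the exact bound and the samples are re-taken, counted in a
#' warning rather than silently corrupted. With `brain_mask`, blocks
#' whose ROI misses the mask's bounding box are skipped.
#'
#' @param extent output block extent (list `lo`, `hi`, half-open).
#' @param src `BlockStore` holding the full-resolution source volume.
#' @param m [high_res_mapping()].
#' @param interp `"linear"` or `"nearest"`.
#' @param brain_mask optional low-resolution binary array (sample
#'   silhouette in source space); used only to skip all-background
#'   blocks.
#' @param margin ROI padding, see [roi_for_block()].
#' @return list `data` (block array), `skipped`, `n_src_blocks`,
#'   `violations`.
#' @export
transform_block <- function(extent, src, m, interp = c("linear", "nearest"),
                            brain_mask = NULL, margin = NULL) {
  interp <- match.arg(interp)
  shp <- extent$hi - extent$lo
  roi <- roi_for_block(extent, m, margin = margin, src_store = src)
  fill_block <- array(src$fill_value, shp)
  if (roi$empty)
    return(list(data = fill_block, skipped = FALSE, n_src_blocks = 0L,
                violations = 0L))
  if (!is.null(brain_mask)) {
    bb <- mask_bbox(brain_mask)
    if (is.null(bb))
      return(list(data = fill_block, skipped = TRUE, n_src_blocks = 0L,
                  violations = 0L))
    blo <- bb$lo * m$s; bhi <- (bb$hi + 1) * m$s
    if (any(roi$hi <= blo) || any(roi$lo >= bhi))
      return(list(data = fill_block, skipped = TRUE, n_src_blocks = 0L,
                  violations = 0L))
  }
  g <- grid_coords(shp)
  P <- cbind(g[, 1] + extent$lo[1], g[, 2] + extent$lo[2],
             g[, 3] + extent$lo[3])
  S <- map_point(m, P)
  inside_src <- S[, 1] >= 0 & S[, 1] <= src$shape[1] - 1 &
    S[, 2] >= 0 & S[, 2] <= src$shape[2] - 1 &
    S[, 3] >= 0 & S[, 3] <= src$shape[3] - 1
  # interpolation support must lie inside the loaded ROI
  pad <- if (interp == "linear") 1 else 0.5
  in_roi <- S[, 1] >= roi$lo[1] & S[, 1] <= roi$hi[1] - pad &
    S[, 2] >= roi$lo[2] & S[, 2] <= roi$hi[2] - pad &
    S[, 3] >= roi$lo[3] & S[, 3] <= roi$hi[3] - pad
  violations <- sum(inside_src & !in_roi)
  if (violations > 0) {
    warning(violations, " sample(s) escaped the surface-derived ROI; ",
            "ROI expanded to the exact bound")
    lo <- pmax(floor(apply(S, 2, min)), 0)
    hi <- pmin(ceiling(apply(S, 2, max)) + 1, src$shape)
    roi <- list(lo = as.integer(lo), hi = as.integer(pmax(hi, lo + 1L)),
                empty = FALSE)
    rng <- lapply(1:3, function(ax)
      (roi$lo[ax] %/% src$block_size[ax]):((roi$hi[ax] - 1L) %/% src$block_size[ax]))
    roi$src_blocks <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]],
                                            k = rng[[3]]))
  }
  roi_arr <- assemble_roi(src, roi)
  local <- cbind(S[, 1] - roi$lo[1], S[, 2] - roi$lo[2],
                 S[, 3] - roi$lo[3])
  vals <- sample_array(roi_arr, local, method = interp,
                       fill = src$fill_value)
  vals[!inside_src] <- src$fill_value
  list(data = array(vals, shp), skipped = FALSE,
       n_src_blocks = nrow(roi$src_blocks), violations = violations)
}

mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  list(lo = apply(w, 2, min) - 1L, hi = apply(w, 2, max) - 1L)  # 0-based
}

# Assemble the source subvolume covering a ROI from its blocks.
assemble_roi <- function(src, roi) {
  shp <- roi$hi - roi$lo
  a <- array(src$fill_value, shp)
  for (r in seq_len(nrow(roi$src_blocks))) {
    idx <- as.integer(roi$src_blocks[r, ])
    e <- block_extent(src, idx)
    lo <- pmax(e$lo, roi$lo); hi <- pmin(e$hi, roi$hi)
    if (any(hi <= lo)) next
    blk <- read_block(src, idx)
    a[(lo[1] - roi$lo[1] + 1):(hi[1] - roi$lo[1]),
      (lo[2] - roi$lo[2] + 1):(hi[2] - roi$lo[2]),
      (lo[3] - roi$lo[3] + 1):(hi[3] - roi$lo[3])] <-
      blk[(lo[1] - e$lo[1] + 1):(hi[1] - e$lo[1]),
          (lo[2] - e$lo[2] + 1):(hi[2] - e$lo[2]),
          (lo[3] - e$lo[3] + 1):(hi[3] - e$lo[3])]
  }
  a
}

#' Transform a whole blocked volume
#'
#' Runs [transform_block()] for every block of the output store (order
#' (k, j, i), i fastest; parallel over `workers` forked processes).
#' Skipped blocks (outside the brain mask) are not written; they read
#' back as fill value. Because blocks are pure functions of their extent,
#' the source and the mapping, the output is bit-identical for any worker
#' count.
#'
#' @param src source `BlockStore` (full resolution).
#' @param m [high_res_mapping()] with `out_shape` equal to the output
#'   store's shape.
#' @param out output `BlockStore` (created with [create_block_store()]).
#' @param interp `"linear"` or `"nearest"`.
#' @param workers forked worker count (1 = serial).
#' @param brain_mask optional low-res binary array, see
#'   [transform_block()].
#' @param margin ROI padding, see [roi_for_block()].
#' @return `TransformStats`: `blocks_total`, `blocks_skipped`,
#'   `src_blocks_loaded` (per-block counts), `max_roi_blocks`,
#'   `violations`.
#' @export
transform_volume <- function(src, m, out, interp = c("linear", "nearest"),
                             workers = 1L, brain_mask = NULL,
                             margin = NULL) {
  interp <- match.arg(interp)
  if (!identical(as.integer(m$out_shape), out$shape))
    stop("mapping out_shape does not match the output store")
  idx <- block_indices(out)
  run_one <- function(r) {
    b <- idx[r, ]
    ext <- block_extent(out, b)
    res <- transform_block(ext, src, m, interp = interp,
                           brain_mask = brain_mask, margin = margin)
    if (!res$skipped) {
      data <- res$data
      if (out$dtype != "float32") data <- round(data)
      write_block(out, b, data)
    }
    c(skipped = res$skipped, n_src = res$n_src_blocks,
      violations = res$violations)
  }
  rows <- seq_len(nrow(idx))
  stats <- if (workers > 1L)
    parallel::mclapply(rows, run_one, mc.cores = workers)
  else lapply(rows, run_one)
  stats <- do.call(rbind, stats)
  structure(list(blocks_total = nrow(idx),
                 blocks_skipped = sum(stats[, "skipped"]),
                 src_blocks_loaded = as.integer(stats[, "n_src"]),
                 max_roi_blocks = max(stats[, "n_src"]),
                 violations = sum(stats[, "violations"])),
            class = "TransformStats")
}

#' @export
print.TransformStats <- function(x, ...) {
  cat("TransformStats:", x$blocks_total, "blocks,", x$blocks_skipped,
      "skipped; src blocks per output block: median",
      stats::median(x$src_blocks_loaded), "max", x$max_roi_blocks, "\n")
  invisible(x)
}

#' Whole-volume warp at uniform resolution (reference path)
#'
#' Maps every output voxel through [map_point()] and samples the source
#' volume directly, without blocking. This is the dense reference that
#' the block-wise [transform_volume()] must reproduce exactly.
#'
#' @param v source [volume3d()] or [label_volume()].
#' @param m [high_res_mapping()].
#' @param interp `"linear"` or `"nearest"`.
#' @param fill out-of-source fill value.
#' @return warped object of the same class, shape `m$out_shape`.
#' @export
warp_volume_dense <- function(v, m, interp = c("linear", "nearest"),
                              fill = 0) {
  interp <- match.arg(interp)
  S <- map_point(m, grid_coords(m$out_shape))
  a <- array(sample_array(v$data, S, method = interp, fill = fill),
             m$out_shape)
  if (inherits(v, "LabelVolume"))
    label_volume(a, names = v$names, voxel_size = v$voxel_size)
  else volume3d(a, v$voxel_size)
}

#' Reslice a block store into 2D image sequences
#'
#' Writes one zero-padded 2D TIFF per index along `axis`. Pixel `(a, b)`
#' of slice `k` holds voxel `(a, b, k)` for axis z, `(a, k, b)` for axis
#' y and `(k, a, b)` for axis x (the in-plane axes keep their relative
#' order).
#'
#' @param store `BlockStore` (integer dtype).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param out_dir destination directory (created).
#' @param require_complete error (listing missing indices) if any block
#'   file is absent; set `FALSE` for stores with skipped background
#'   blocks.
#' @return invisible character vector of slice paths.
#' @export
reslice <- function(store, axis = c("z", "y", "x"), out_dir,
                    require_complete = TRUE) {
  axis <- match.arg(axis)
  if (store$dtype == "float32")
    stop("reslice writes integer TIFF sequences; float32 stores are not supported")
  if (require_complete) {
    idx <- block_indices(store)
    missing <- idx[!vapply(seq_len(nrow(idx)), function(r)
      file.exists(block_path(store, idx[r, ])), TRUE), , drop = FALSE]
    if (nrow(missing) > 0)
      stop("incomplete store; missing block(s): ",
           paste(apply(missing, 1, paste, collapse = ","), collapse = " "))
  }
  v <- assemble_volume(store)
  ax <- match(axis, c("x", "y", "z"))
  n <- dim(v$data)[ax]
  scale <- if (store$dtype == "uint8") 255 else 65535
  bits <- if (store$dtype == "uint8") 8L else 16L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(n)
  for (k in seq_len(n)) {
    sl <- switch(ax, v$data[k, , ], v$data[, k, ], v$data[, , k])
    paths[k] <- file.path(out_dir, sprintf("slice_%05d.tif", k - 1L))
    tiff::writeTIFF(as.matrix(sl) / scale, paths[k],
                    bits.per.sample = bits)
  }
  invisible(paths)
}
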