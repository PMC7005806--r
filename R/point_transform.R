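# Warping vectorized datasets (point sets, SWC neuron morphologies) into
# the fixed/atlas space. Points push forward while images pull back, so
# point mapping uses the direct field phi1 together with the inverse of
# the image-resampling affine; the same high-resolution mapping algebra
# (scaled affine + on-the-fly field interpolation) applies.

#' Transform a point set moving -> fixed
#'
#' Each high-resolution source-space point `P` maps to
#' `[P] x M' + s * phi1(P / s)`, where `M'` is the forward affine
#' rescaled by `s` and `phi1` the direct displacement field on the
#' low-resolution moving lattice. Points outside the field's coverage
#' are still mapped (clamp-to-edge) but flagged.
#'
#' @param pts N x 3 matrix of high-resolution voxel coordinates in the
#'   moving space.
#' @param M forward [affine_transform()] (moving -> fixed at low
#'   resolution), i.e. the inverse of the image-warping affine.
#' @param field_forward the direct field phi1 from
#'   [register_diffeomorphic()].
#' @param s high-res-to-low-res scale factor (>= 1), scalar or per-axis.
#' @return N x 3 matrix of fixed-space high-resolution coordinates, with
#'   attribute `outside` (logical: input outside the field lattice).
#' @export
transform_points <- function(pts, M = affine_transform(),
                             field_forward = NULL, s = 1) {
  pts <- rbind3(pts)
  if (!all(is.finite(pts))) stop("point coordinates must be finite")
  s <- rep(as.numeric(s), length.out = 3)
  Ms <- scale_affine(M, s)
  out <- affine_apply(Ms, pts)
  outside <- rep(FALSE, nrow(pts))
  if (!is.null(field_forward)) {
    d <- field_shape(field_forward)
    q <- cbind(pts[, 1] / s[1], pts[, 2] / s[2], pts[, 3] / s[3])
    outside <- q[, 1] < 0 | q[, 1] > d[1] - 1 | q[, 2] < 0 |
      q[, 2] > d[2] - 1 | q[, 3] < 0 | q[, 3] > d[3] - 1
    phi <- interp_field(field_forward, q)
    out <- out + cbind(s[1] * phi[, 1], s[2] * phi[, 2], s[3] * phi[, 3])
  }
  attr(out, "outside") <- outside
  out
}

#' Transform an SWC neuron moving -> fixed
#'
#' Coordinates are converted from physical micrometres to high-resolution
#' voxels, mapped as [transform_points()], and converted back; topology
#' (ids, types, parents) is untouched. Radii are scaled by the cube root
#' of the affine determinant (the field's local Jacobian is ignored for
#' radii); this is noted in the output file header when written.
#'
#' @param n [swc_neuron()].
#' @param M,field_forward,s as in [transform_points()].
#' @param voxel_size_in micrometres per high-res voxel in the moving
#'   space (scalar or triple).
#' @param voxel_size_out micrometres per high-res voxel in the fixed
#'   space; defaults to `voxel_size_in`.
#' @return transformed [swc_neuron()].
#' @export
transform_swc <- function(n, M = affine_transform(), field_forward = NULL,
                          s = 1, voxel_size_in = 1,
                          voxel_size_out = voxel_size_in) {
  stopifnot(inherits(n, "SWCNeuron"))
  vin <- rep(as.numeric(voxel_size_in), length.out = 3)
  vout <- rep(as.numeric(voxel_size_out), length.out = 3)
  pts <- as.matrix(n$nodes[c("x", "y", "z")])
  vox <- sweep(pts, 2, vin, "/")
  mapped <- transform_points(vox, M, field_forward, s)
  phys <- sweep(mapped, 2, vout, "*")
  out <- n
  out$nodes$x <- phys[, 1]; out$nodes$y <- phys[, 2]
  out$nodes$z <- phys[, 3]
  rscale <- abs(det(M$matrix[1:3, 1:3]))^(1 / 3) *
    (prod(vout) / prod(vin))^(1 / 3)
  out$nodes$radius <- n$nodes$radius * rscale
  attr(out, "radius_scale") <- rscale
  out
}

#' Read / write generic point sets as CSV
#'
#' Plain CSV with columns `x`, `y`, `z` (plus any extra payload columns,
#' preserved); the declared coordinate unit travels in a
#' `# unit: <unit>` comment line.
#'
#' @param path CSV file.
#' @return data.frame with attribute `unit`.
#' @export
read_points <- function(path) {
  ln <- readLines(path, n = 5)
  unit <- sub("^#\\s*unit:\\s*", "", grep("^#\\s*unit:", ln, value = TRUE))
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("x", "y", "z") %in% names(df)))
    stop("point CSV must have columns x, y, z")
  attr(df, "unit") <- if (length(unit)) unit[[1]] else "um"
  df
}

#' @param pts data.frame with `x`, `y`, `z` columns.
#' @param unit coordinate unit recorded in the header.
#' @rdname read_points
#' @export
write_points <- function(pts, path, unit = "um") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# unit:", unit), con)
  utils::write.csv(pts, con, row.names = FALSE)
  invisible(path)
}

#' Per-region projection pattern of a neuron
#'
#' Node counts per region by nearest-voxel lookup in the annotation, and
#' cable length per region by subdividing every parent-child segment at
#' steps of the smallest voxel size and assigning each sub-segment to the
#' region under its midpoint. Points on voxel boundaries assign to the
#' lower index; nodes or midpoints outside the annotation count as
#' background (with a warning for nodes).
#'
#' @param n [swc_neuron()] with coordinates in the annotation's physical
#'   space (micrometres).
#' @param annotation [label_volume()].
#' @return `ProjectionPattern`: data.frame with columns `label`,
#'   `region`, `n_nodes`, `length_um`; counts sum to the node total and
#'   lengths to the total cable length (up to subdivision step).
#' @export
projection_pattern <- function(n, annotation) {
  stopifnot(inherits(n, "SWCNeuron"), inherits(annotation, "LabelVolume"))
  vs <- annotation$voxel_size
  lab_at <- function(p_phys) {
    vox <- sweep(p_phys, 2, vs, "/")
    out <- sample_array(annotation$data, vox, "nearest", fill = -1)
    outside <- out < 0
    out[outside] <- 0
    list(label = as.integer(out), outside = outside)
  }
  pts <- as.matrix(n$nodes[c("x", "y", "z")])
  node_lab <- lab_at(pts)
  if (any(node_lab$outside))
    warning(sum(node_lab$outside),
            " node(s) outside the annotation counted as background")
  ids <- c(0L, as.integer(names(annotation$names)))
  counts <- vapply(ids, function(i) sum(node_lab$label == i), 0L)
  step <- min(vs)
  lengths <- stats::setNames(numeric(length(ids)), ids)
  child <- which(n$nodes$parent != -1L)
  if (length(child)) {
    pidx <- match(n$nodes$parent[child], n$nodes$id)
    a <- pts[child, , drop = FALSE]
    b <- pts[pidx, , drop = FALSE]
    seg_len <- sqrt(rowSums((a - b)^2))
    for (si in seq_along(child)) {
      L <- seg_len[si]
      if (L == 0) next
      k <- ceiling(L / step)
      tt <- (seq_len(k) - 0.5) / k
      mids <- cbind(a[si, 1] + tt * (b[si, 1] - a[si, 1]),
                    a[si, 2] + tt * (b[si, 2] - a[si, 2]),
                    a[si, 3] + tt * (b[si, 3] - a[si, 3]))
      ml <- lab_at(mids)$label
      tab <- table(ml)
      lengths[names(tab)] <- lengths[names(tab)] +
        as.numeric(tab) * (L / k)
    }
  }
  structure(data.frame(label = ids,
                       region = c("background",
                                  unname(annotation$names)),
                       n_nodes = counts,
                       length_um = unname(lengths[as.character(ids)]),
                       row.names = NULL),
            class = c("ProjectionPattern", "data.frame"))
}
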