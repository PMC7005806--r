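#' 3D scalar volume with physical voxel size
#'
#' A `Volume3D` wraps a 3D numeric array together with its per-axis physical
#' voxel size in micrometres. Voxel coordinates are 0-based throughout the
#' package and extents are half-open; the physical coordinate of voxel
#' `(i, j, k)` is `(i, j, k) * voxel_size`. The first array index (x) is the
#' fastest-varying index on disk, matching R's column-major layout.
#'
#' @param data 3D numeric array (a 2D matrix is promoted to shape
#'   `c(nrow, ncol, 1)`).
#' @param voxel_size numeric length-3 (or scalar, recycled), micrometres,
#'   all > 0.
#' @return An object of class `Volume3D` with elements `data` and
#'   `voxel_size`.
#' @export
volume3d <- function(data, voxel_size = c(1, 1, 1)) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L)
    stop("Volume3D data must be a 3D array, got dimensionality ",
         length(dim(data)))
  voxel_size <- check_voxel_size(voxel_size)
  structure(list(data = data, voxel_size = voxel_size), class = "Volume3D")
}

check_voxel_size <- function(voxel_size) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || !all(is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be 3 positive finite numbers")
  as.numeric(voxel_size)
}

#' @export
print.Volume3D <- function(x, ...) {
  cat("Volume3D", paste(dim(x$data), collapse = " x "),
      "voxels,", paste(signif(x$voxel_size, 4), collapse = " x "),
      "um/voxel, range [", signif(min(x$data), 5), ",",
      signif(max(x$data), 5), "]\n")
  invisible(x)
}

#' Integer-coded label volume of anatomical regional features
#'
#' Wraps a non-negative integer 3D array where label 0 is background and
#' every nonzero label codes one anatomical regional feature (e.g. outline,
#' corpus callosum, hippocampus). A name table maps label ids to region
#' names.
#'
#' @param data 3D array of non-negative integers (2D promoted as in
#'   [volume3d()]).
#' @param names named character vector: names are label ids (as character),
#'   values are region names. Missing entries are auto-filled as
#'   `"region_<id>"`.
#' @param voxel_size micrometre triple, see [volume3d()].
#' @return Object of class `LabelVolume` with elements `data`, `names`,
#'   `voxel_size`.
#' @export
label_volume <- function(data, names = NULL, voxel_size = c(1, 1, 1)) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L)
    stop("LabelVolume data must be a 3D array")
  if (any(data < 0) || any(data != round(data)))
    stop("labels must be non-negative integers")
  storage.mode(data) <- "integer"
  ids <- sort(setdiff(unique(as.integer(data)), 0L))
  nm <- structure(paste0("region_", ids), names = as.character(ids))
  if (!is.null(names)) {
    names <- unlist(names)
    nm[intersect(base::names(names), base::names(nm))] <-
      names[intersect(base::names(names), base::names(nm))]
  }
  structure(list(data = data, names = nm,
                 voxel_size = check_voxel_size(voxel_size)),
            class = "LabelVolume")
}

#' @export
print.LabelVolume <- function(x, ...) {
  cat("LabelVolume", paste(dim(x$data), collapse = " x "), "voxels,",
      length(x$names), "regions:",
      paste(utils::head(x$names, 8), collapse = ", "),
      if (length(x$names) > 8) "...", "\n")
  invisible(x)
}

#' Homogeneous 4x4 affine transform (row-vector convention)
#'
#' Points map as `[x, y, z, 1] %*% matrix`; the last column must therefore
#' be `(0, 0, 0, 1)`. Translation lives in the fourth row. In registration
#' results the affine maps fixed-space voxel coordinates to moving-space
#' voxel coordinates (pull-back resampling).
#'
#' @param matrix 4x4 numeric, invertible, last column `c(0, 0, 0, 1)`.
#' @return Object of class `AffineTransform`.
#' @export
affine_transform <- function(matrix = diag(4)) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4L, 4L)))
    stop("affine matrix must be 4x4")
  if (max(abs(matrix[, 4] - c(0, 0, 0, 1))) > 1e-12)
    stop("last column must be (0,0,0,1) under the row-vector convention")
  d <- det(matrix)
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("affine matrix is not invertible")
  structure(list(matrix = unname(matrix)), class = "AffineTransform")
}

#' Apply an affine to 0-based point coordinates
#'
#' @param m `AffineTransform`.
#' @param pts N x 3 matrix (or length-3 vector) of coordinates.
#' @return N x 3 matrix of mapped coordinates.
#' @export
affine_apply <- function(m, pts) {
  pts <- rbind3(pts)
  out <- cbind(pts, 1) %*% m$matrix
  out[, 1:3, drop = FALSE]
}

#' Invert an affine transform
#' @param m `AffineTransform`.
#' @return `AffineTransform` with the inverse matrix.
#' @export
affine_invert <- function(m) affine_transform(solve(m$matrix))

rbind3 <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  if (ncol(pts) != 3) stop("points must be N x 3")
  pts
}

#' 3-channel displacement field on the working-resolution lattice
#'
#' Pull-back semantics: for a fixed-space coordinate `q`, the source
#' coordinate sampled is `affine(q) + phi(q)`. Components are stored as
#' three 3D arrays of one common shape, in working-resolution voxel units,
#' component order (phi_x, phi_y, phi_z).
#'
#' @param x,y,z 3D arrays of identical shape (2D matrices promoted), finite.
#' @return Object of class `DisplacementField` with element `components`
#'   (list of the three arrays).
#' @export
displacement_field <- function(x, y, z) {
  comps <- lapply(list(x, y, z), function(a) {
    if (is.matrix(a)) dim(a) <- c(dim(a), 1L)
    a
  })
  dims <- lapply(comps, dim)
  if (length(dims[[1]]) != 3L || !identical(dims[[1]], dims[[2]]) ||
      !identical(dims[[1]], dims[[3]]))
    stop("all three components must share one 3D shape")
  if (!all(vapply(comps, function(a) all(is.finite(a)), TRUE)))
    stop("displacement field must be finite everywhere")
  structure(list(components = comps), class = "DisplacementField")
}

#' Zero displacement field of a given shape
#' @param shape integer length-3.
#' @return `DisplacementField` of zeros.
#' @export
zero_field <- function(shape) {
  z <- array(0, shape)
  displacement_field(z, z, z)
}

#' @export
print.DisplacementField <- function(x, ...) {
  n <- field_norm(x)
  cat("DisplacementField", paste(field_shape(x), collapse = " x "),
      "max |phi| =", signif(max(n), 5), "voxels\n")
  invisible(x)
}

field_shape <- function(f) dim(f$components[[1]])

#' Per-voxel Euclidean norm of a displacement field
#' @param f `DisplacementField`.
#' @return 3D array of vector norms (voxels).
#' @export
field_norm <- function(f) {
  sqrt(f$components[[1]]^2 + f$components[[2]]^2 + f$components[[3]]^2)
}
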