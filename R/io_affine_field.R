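# Plain-text affine matrices and NIfTI displacement fields.

#' Read a 4x4 affine matrix from plain text
#'
#' The file holds 4 lines of 4 whitespace-separated numbers; lines starting
#' with `#` are comments. The matrix uses the row-vector convention
#' (`[x y z 1] %*% M`).
#'
#' @param path text file.
#' @return An [affine_transform()].
#' @export
read_affine <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  if (length(ln) != 4L)
    stop("affine file must have 4 numeric rows, found ", length(ln))
  rows <- lapply(ln, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(lengths(rows) != 4L) || any(vapply(rows, anyNA, TRUE)))
    stop("each affine row must have 4 numbers")
  affine_transform(do.call(rbind, rows))
}

#' Write a 4x4 affine matrix as plain text
#'
#' @param m [affine_transform()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_affine <- function(m, path) {
  stopifnot(inherits(m, "AffineTransform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# 4x4 homogeneous affine, row-vector convention: [x y z 1] %*% M",
    "# rows 1-3: linear part; row 4: translation; last column (0 0 0 1)",
    apply(m$matrix, 1, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = " "))
  ), con)
  invisible(path)
}

#' Read a 3-channel displacement field
#'
#' Accepts a 4D NIfTI file whose last axis has length 3, component order
#' (phi_x, phi_y, phi_z) in working-resolution voxel units.
#'
#' @param path NIfTI file.
#' @return A [displacement_field()].
#' @export
read_field <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) != 4L || dim(a)[4] != 3L)
    stop("displacement field must be 4D with 3 channels, got shape ",
         paste(dim(a), collapse = "x"))
  displacement_field(a[, , , 1], a[, , , 2], a[, , , 3])
}

#' Write a 3-channel displacement field as 4D NIfTI
#'
#' @param f [displacement_field()].
#' @param path destination `.nii`/`.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_field <- function(f, path) {
  stopifnot(inherits(f, "DisplacementField"))
  d <- field_shape(f)
  a <- array(0, c(d, 3))
  for (c3 in 1:3) a[, , , c3] <- f$components[[c3]]
  RNifti::writeNifti(RNifti::asNifti(a), path, datatype = "double")
  invisible(path)
}
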