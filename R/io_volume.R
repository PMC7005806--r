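# Volume I/O: TIFF slice stacks, multi-page 3D TIFF and NIfTI-1.
#
# On-disk conventions (documented here once, used everywhere): a 2D TIFF
# slice holds voxel (i, j, k) at matrix entry [i+1, j+1] of slice k, i.e.
# image rows run along x (the fastest-varying axis) and slices along z.
# Slice stacks are directories of lexicographically ordered 2D TIFFs.
# Integer TIFF samples are written unscaled (8 or 16 bit); floating-point
# volumes go to NIfTI, which preserves dtype exactly.

#' Read a 3D volume
#'
#' @param path a directory (TIFF slice stack, lexicographic z order), a
#'   `.tif`/`.tiff` multi-page file, or a `.nii`/`.nii.gz` NIfTI file.
#' @param format `"tiff-stack"`, `"tiff"` or `"nifti"`; inferred from
#'   `path` when `NULL`.
#' @param voxel_size optional micrometre triple overriding file metadata
#'   (TIFF has none; default `c(1,1,1)`).
#' @return A [volume3d()] object.
#' @export
read_volume <- function(path, format = NULL, voxel_size = NULL) {
  format <- infer_vol_format(path, format)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    vs <- if (is.null(voxel_size)) RNifti::pixdim(img)[1:3] else voxel_size
    a <- as.array(img)
    if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
    if (length(dim(a)) != 3L)
      stop("expected a 3D NIfTI volume, got ", length(dim(a)), "D")
    return(volume3d(a, vs))
  }
  if (format == "tiff") {
    sl <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(sl)) sl <- list(sl)
    return(volume3d(stack_slices(sl, path),
                    if (is.null(voxel_size)) c(1, 1, 1) else voxel_size))
  }
  files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
  if (length(files) == 0L) stop("no TIFF slices found in ", path)
  sl <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
  volume3d(stack_slices(sl, path),
           if (is.null(voxel_size)) c(1, 1, 1) else voxel_size)
}

stack_slices <- function(slices, path) {
  dims <- unique(lapply(slices, dim))
  if (length(dims) != 1L)
    stop("inconsistent slice shapes in ", path, ": ",
         paste(vapply(dims, paste, "", collapse = "x"), collapse = " vs "))
  if (length(dims[[1]]) != 2L)
    stop("slices must be single-channel 2D images: ", path)
  array(unlist(slices, use.names = FALSE),
        c(dims[[1]], length(slices)))
}

infer_vol_format <- function(path, format) {
  if (!is.null(format)) {
    format <- match.arg(format, c("tiff-stack", "tiff", "nifti"))
    return(if (format == "tiff-stack") "stack" else format)
  }
  if (grepl("\\.nii(\\.gz)?$", path)) return("nifti")
  if (grepl("\\.tiff?$", path)) return("tiff")
  "stack"
}

#' Write a 3D volume
#'
#' @param v [volume3d()] or [label_volume()] object.
#' @param path destination (see [read_volume()] for dialects).
#' @param format as in [read_volume()]; inferred when `NULL`.
#' @param dtype `"uint8"`, `"uint16"` or `"float32"`; `"auto"` picks the
#'   narrowest integer type that holds the data, or float32 for
#'   non-integer data (NIfTI only).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, format = NULL, dtype = "auto") {
  stopifnot(inherits(v, c("Volume3D", "LabelVolume")))
  format <- infer_vol_format(path, format)
  a <- v$data
  dtype <- resolve_dtype(a, dtype)
  if (format == "nifti") {
    img <- RNifti::asNifti(a + 0)  # force numeric copy
    RNifti::pixdim(img) <- v$voxel_size
    RNifti::writeNifti(img, path,
                       datatype = switch(dtype, uint8 = "uint8",
                                         uint16 = "uint16", "float"))
    return(invisible(path))
  }
  if (dtype == "float32")
    stop("floating-point TIFF volumes are not supported; use NIfTI")
  scale <- if (dtype == "uint8") 255 else 65535
  bits <- if (dtype == "uint8") 8L else 16L
  d <- dim(a)
  slices <- lapply(seq_len(d[3]), function(k) matrix(a[, , k], d[1], d[2]) / scale)
  if (format == "tiff") {
    tiff::writeTIFF(slices, path, bits.per.sample = bits)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(d[3]))
      tiff::writeTIFF(slices[[k]],
                      file.path(path, sprintf("slice_%05d.tif", k - 1L)),
                      bits.per.sample = bits)
  }
  invisible(path)
}

resolve_dtype <- function(a, dtype) {
  if (dtype != "auto") {
    dtype <- match.arg(dtype, c("uint8", "uint16", "float32"))
    if (dtype != "float32") {
      if (any(a != round(a)) || min(a) < 0 ||
          max(a) > ifelse(dtype == "uint8", 255, 65535))
        stop("data do not fit dtype ", dtype)
    }
    return(dtype)
  }
  if (all(a == round(a)) && min(a) >= 0) {
    if (max(a) <= 255) return("uint8")
    if (max(a) <= 65535) return("uint16")
  }
  "float32"
}
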