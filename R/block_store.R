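# Chunked 3D image storage: a directory of per-block 3D image files plus
# one JSON metadata record. Blocks are addressed by 0-based integer index
# triples (i, j, k); block (i, j, k) covers the half-open voxel extent
# [i*bx, min((i+1)*bx, X)) x ... so interior blocks have exactly
# block_size shape and edge blocks are trimmed. Reading an absent block
# returns a fill_value-filled block, which lets sparse outputs (blocks
# skipped as outside the brain) read back consistently.
#
# Dialect: integer dtypes (uint8/uint16) are stored as multi-page 3D
# TIFFs; float32 blocks as NIfTI (the TIFF writer only defines float
# storage on [0, 1]).

#' Create a chunked block store
#'
#' @param shape overall volume shape (3 positive integers).
#' @param block_size block shape (3 integers, each >= 8).
#' @param dtype `"uint8"`, `"uint16"` or `"float32"`.
#' @param voxel_size micrometre triple.
#' @param root directory to create.
#' @param fill_value value returned for absent blocks (default 0,
#'   the out-of-brain background).
#' @return Object of class `BlockStore`.
#' @export
create_block_store <- function(shape, block_size, dtype = "uint16",
                               voxel_size = c(1, 1, 1), root,
                               fill_value = 0) {
  shape <- as.integer(shape); block_size <- as.integer(rep(block_size, length.out = 3))
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive integers")
  if (any(block_size < 8L)) stop("block_size components must be >= 8")
  dtype <- match.arg(dtype, c("uint8", "uint16", "float32"))
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  store <- structure(list(root = root, shape = shape,
                          block_size = block_size, dtype = dtype,
                          voxel_size = check_voxel_size(voxel_size),
                          fill_value = fill_value,
                          n_blocks = as.integer(ceiling(shape / block_size))),
                     class = "BlockStore")
  meta <- list(shape = shape, block_size = block_size, dtype = dtype,
               voxel_size = store$voxel_size, fill_value = fill_value,
               n_blocks = store$n_blocks)
  jsonlite::write_json(meta, file.path(root, "store.json"),
                       auto_unbox = TRUE, digits = NA)
  store
}

#' Open an existing block store
#' @param root store directory containing `store.json`.
#' @return `BlockStore` object.
#' @export
open_block_store <- function(root) {
  meta <- jsonlite::read_json(file.path(root, "store.json"),
                              simplifyVector = TRUE)
  for (f in c("shape", "block_size", "n_blocks"))
    meta[[f]] <- as.integer(meta[[f]])
  structure(c(list(root = root), meta), class = "BlockStore")
}

#' @export
print.BlockStore <- function(x, ...) {
  cat("BlockStore", paste(x$shape, collapse = "x"), x$dtype, "blocks",
      paste(x$block_size, collapse = "x"), "grid",
      paste(x$n_blocks, collapse = "x"), "at", x$root, "\n")
  invisible(x)
}

check_block_idx <- function(store, idx) {
  idx <- as.integer(idx)
  if (length(idx) != 3L || any(idx < 0L) || any(idx >= store$n_blocks))
    stop("block index (", paste(idx, collapse = ","),
         ") outside grid ", paste(store$n_blocks, collapse = "x"))
  idx
}

#' Half-open voxel extent of a block
#'
#' @param store `BlockStore` (or anything with `shape`, `block_size`).
#' @param idx 0-based index triple.
#' @return list with `lo` (inclusive) and `hi` (exclusive) 0-based voxel
#'   coordinates.
#' @export
block_extent <- function(store, idx) {
  idx <- check_block_idx(store, idx)
  lo <- idx * store$block_size
  hi <- pmin(lo + store$block_size, store$shape)
  list(lo = lo, hi = hi)
}

block_path <- function(store, idx) {
  ext <- if (store$dtype == "float32") "nii" else "tif"
  file.path(store$root, sprintf("block_%04d_%04d_%04d.%s",
                                idx[1], idx[2], idx[3], ext))
}

#' Read one block (absent blocks read as fill_value)
#'
#' @param store `BlockStore`.
#' @param idx 0-based index triple.
#' @return 3D array of the block's (possibly trimmed) shape.
#' @export
read_block <- function(store, idx) {
  idx <- check_block_idx(store, idx)
  ext <- block_extent(store, idx)
  shp <- ext$hi - ext$lo
  p <- block_path(store, idx)
  if (!file.exists(p)) return(array(store$fill_value, shp))
  a <- if (store$dtype == "float32") as.array(RNifti::readNifti(p))
  else {
    sl <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(sl)) sl <- list(sl)
    stack_slices(sl, p)
  }
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  if (!identical(as.integer(dim(a)), as.integer(shp)))
    stop("block file ", p, " has shape ", paste(dim(a), collapse = "x"),
         ", expected ", paste(shp, collapse = "x"))
  a
}

#' Write one block
#'
#' @param store `BlockStore`.
#' @param idx 0-based index triple.
#' @param data 3D array matching the block extent's shape.
#' @return `store`, invisibly.
#' @export
write_block <- function(store, idx, data) {
  idx <- check_block_idx(store, idx)
  ext <- block_extent(store, idx)
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!identical(as.integer(dim(data)), as.integer(ext$hi - ext$lo)))
    stop("data shape ", paste(dim(data), collapse = "x"),
         " does not match block extent ",
         paste(ext$hi - ext$lo, collapse = "x"))
  p <- block_path(store, idx)
  if (store$dtype == "float32") {
    RNifti::writeNifti(RNifti::asNifti(data + 0), p, datatype = "float")
  } else {
    scale <- if (store$dtype == "uint8") 255 else 65535
    if (min(data) < 0 || max(data) > scale || any(data != round(data)))
      stop("data do not fit dtype ", store$dtype)
    d <- dim(data)
    tiff::writeTIFF(lapply(seq_len(d[3]), function(k)
      matrix(data[, , k], d[1], d[2]) / scale), p,
      bits.per.sample = if (store$dtype == "uint8") 8L else 16L)
  }
  invisible(store)
}

#' Ingest a whole volume into a block store
#'
#' @param store `BlockStore`.
#' @param v [volume3d()] or [label_volume()] with `store$shape` data.
#' @return `store`, invisibly.
#' @export
ingest_volume <- function(store, v) {
  if (!identical(as.integer(dim(v$data)), store$shape))
    stop("volume shape does not match store shape")
  for (k in seq_len(store$n_blocks[3]) - 1L)
    for (j in seq_len(store$n_blocks[2]) - 1L)
      for (i in seq_len(store$n_blocks[1]) - 1L) {
        e <- block_extent(store, c(i, j, k))
        write_block(store, c(i, j, k),
                    v$data[(e$lo[1] + 1):e$hi[1], (e$lo[2] + 1):e$hi[2],
                           (e$lo[3] + 1):e$hi[3], drop = FALSE])
      }
  invisible(store)
}

#' Reassemble a block store into one volume
#'
#' @param store `BlockStore`.
#' @return [volume3d()] of shape `store$shape` (absent blocks filled).
#' @export
assemble_volume <- function(store) {
  a <- array(store$fill_value, store$shape)
  for (k in seq_len(store$n_blocks[3]) - 1L)
    for (j in seq_len(store$n_blocks[2]) - 1L)
      for (i in seq_len(store$n_blocks[1]) - 1L) {
        e <- block_extent(store, c(i, j, k))
        a[(e$lo[1] + 1):e$hi[1], (e$lo[2] + 1):e$hi[2],
          (e$lo[3] + 1):e$hi[3]] <- read_block(store, c(i, j, k))
      }
  volume3d(a, store$voxel_size)
}
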