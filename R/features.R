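# Feature encoding: regional-feature labels are turned into scalar
# channels (one per selected region) that drive the registration instead
# of the raw gray values, so the optimizer is blind to staining / noise
# differences between modalities.

#' Encode regional features as registration channels
#'
#' `onehot`: Gaussian-smoothed indicator per region (values 0-1).
#' `distance`: signed Euclidean distance to the region boundary in voxels
#' (positive inside, negative outside), clamped to `±cap`.
#'
#' @param lv [label_volume()].
#' @param regions region names or label ids to encode; default all.
#' @param encoding `"onehot"` or `"distance"`.
#' @param sigma smoothing sigma in voxels for one-hot channels (0 = raw
#'   indicator).
#' @param cap clamp for the distance encoding (voxels).
#' @return Object of class `FeatureImage`: `channels` (list of 3D arrays,
#'   one per region, in the supplied order), `region_ids`, `voxel_size`.
#' @export
encode_features <- function(lv, regions = NULL,
                            encoding = c("onehot", "distance"),
                            sigma = 2, cap = 10) {
  stopifnot(inherits(lv, "LabelVolume"))
  encoding <- match.arg(encoding)
  ids <- resolve_regions(lv, regions)
  d <- dim(lv$data)
  sig <- c(sigma, sigma, if (d[3] == 1L) 0 else sigma)
  channels <- lapply(ids, function(id) {
    ind <- array(as.numeric(lv$data == id), d)
    if (encoding == "onehot") {
      if (sigma > 0) smooth_gauss(ind, sig) else ind
    } else {
      inside <- lv$data == id
      d_out <- sqrt(edt_squared(inside))   # distance to region, 0 inside
      d_in <- sqrt(edt_squared(!inside))   # distance to outside, 0 outside
      pmin(pmax(d_in - d_out, -cap), cap)
    }
  })
  structure(list(channels = channels, region_ids = ids,
                 voxel_size = lv$voxel_size),
            class = "FeatureImage")
}

resolve_regions <- function(lv, regions) {
  if (is.null(regions)) return(as.integer(names(lv$names)))
  if (is.character(regions)) {
    miss <- setdiff(regions, lv$names)
    if (length(miss))
      stop("region(s) absent from label volume: ",
           paste(miss, collapse = ", "))
    return(as.integer(names(lv$names)[match(regions, lv$names)]))
  }
  ids <- as.integer(regions)
  miss <- setdiff(ids, as.integer(names(lv$names)))
  if (length(miss))
    stop("region id(s) absent from label volume: ",
         paste(miss, collapse = ", "))
  ids
}

#' @export
print.FeatureImage <- function(x, ...) {
  cat("FeatureImage", length(x$channels), "channels,",
      paste(dim(x$channels[[1]]), collapse = " x "), "voxels\n")
  invisible(x)
}

# Downsample every channel by an integer factor (block mean).
downsample_features <- function(fi, f) {
  structure(list(channels = lapply(fi$channels, downsample_mean, f = f),
                 region_ids = fi$region_ids,
                 voxel_size = fi$voxel_size * ifelse(dim(fi$channels[[1]]) > 1, f, 1)),
            class = "FeatureImage")
}
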