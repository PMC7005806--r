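# End-to-end orchestration: structured configuration with validation and
# a staged pipeline (preprocess -> encode -> register -> block transform
# -> reslice) writing a manifest with checksums for reproducibility and
# resuming.

pipeline_defaults <- function() {
  list(
    paths = list(src = NULL, moving_labels = NULL, fixed_labels = NULL,
                 out = NULL, brain_mask = NULL),
    working_voxel_um = 10,
    regions = NULL,
    encoding = "onehot",
    encode_sigma = 2,
    registration = list(levels = c(4, 2, 1),
                        iters_per_level = c(80, 50, 25),
                        update_sigma = 2, field_sigma = 1, step = 1,
                        metric = "ssd"),
    block = list(block_size = 64L, margin = NULL, workers = 1L),
    scale = 1,
    interp = "linear",
    reslice_axis = "z",
    seed = 0L
  )
}

#' Validate and complete a pipeline configuration
#'
#' Reads a YAML or JSON file (or takes a list), fills defaults and
#' rejects unknown keys by name. `block_size` must be >= 8.
#'
#' @param config path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @return `PipelineConfig`: the completed configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
    if (is.null(config)) config <- list()
  }
  def <- pipeline_defaults()
  merged <- merge_config(def, config, path = "")
  if (any(merged$block$block_size < 8))
    stop("block_size must be >= 8")
  if (!merged$encoding %in% c("onehot", "distance"))
    stop("encoding must be onehot or distance")
  if (!merged$interp %in% c("linear", "nearest"))
    stop("interp must be linear or nearest")
  structure(merged, class = "PipelineConfig")
}

merge_config <- function(def, cfg, path) {
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      def[[k]] <- merge_config(def[[k]],
                               if (is.null(cfg[[k]])) list() else cfg[[k]],
                               paste0(path, ".", k))
    } else if (!is.null(cfg[[k]])) def[[k]] <- cfg[[k]]
  }
  def
}

#' Run the full registration pipeline
#'
#' Stages: (1) preprocess the moving gray volume (isotropic resampling to
#' the working resolution), (2) encode regional features of both label
#' volumes, (3) register (affine, then symmetric diffeomorphic), writing
#' the matrix, both fields and the energy trace, (4) block-transform the
#' full-resolution source through the scaled mapping, (5) reslice the
#' output store along the configured axis. A manifest (stage, outputs,
#' md5 checksums, wall seconds) is written to the output directory;
#' `resume = TRUE` skips stages whose recorded outputs are unchanged.
#'
#' @param cfg [validate_config()] result (or a list/path accepted by it).
#' @param resume skip completed stages by checksum.
#' @return the manifest, invisibly (list of stage records).
#' @export
run_pipeline <- function(cfg, resume = FALSE) {
  cfg <- validate_config(unclass(cfg))
  p <- cfg$paths
  for (need in c("src", "moving_labels", "fixed_labels", "out"))
    if (is.null(p[[need]]))
      stop("validation error: paths$", need, " is required")
  for (need in c("src", "moving_labels", "fixed_labels"))
    if (!file.exists(p[[need]]))
      stop("validation error: paths$", need, " does not exist: ", p[[need]])
  dir.create(p$out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(p$out, "manifest.json")
  old_manifest <- if (resume && file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else NULL
  manifest <- list()
  stage <- function(name, outputs, fun) {
    if (!is.null(old_manifest)) {
      rec <- Filter(function(s) identical(s$stage, name), old_manifest)
      if (length(rec) == 1L && all(file.exists(outputs)) &&
          identical(as.character(unlist(rec[[1]]$checksums)),
                    unname(tools::md5sum(outputs)))) {
        rec <- rec[[1]]
        rec$outputs <- as.character(unlist(rec$outputs))
        rec$checksums <- as.character(unlist(rec$checksums))
        rec$resumed <- TRUE
        manifest[[length(manifest) + 1L]] <<- rec
        return(invisible(NULL))
      }
    }
    t0 <- proc.time()[["elapsed"]]
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest[[length(manifest) + 1L]] <<- list(
      stage = name, outputs = outputs,
      checksums = unname(tools::md5sum(outputs)),
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      seed = cfg$seed, resumed = FALSE)
    invisible(NULL)
  }
  rc <- registration_config(
    levels = cfg$registration$levels,
    iters_per_level = cfg$registration$iters_per_level,
    update_sigma = cfg$registration$update_sigma,
    field_sigma = cfg$registration$field_sigma,
    step = cfg$registration$step, metric = cfg$registration$metric,
    seed = cfg$seed)

  pre_path <- file.path(p$out, "preprocessed.nii.gz")
  stage("preprocess", pre_path, function() {
    v <- read_volume(p$src)
    v <- resample_isotropic(v, cfg$working_voxel_um)
    write_volume(v, pre_path, dtype = "float32")
  })

  enc_paths <- file.path(p$out, c("features_fixed.json",
                                  "features_moving.json"))
  feats <- new.env()
  stage("encode", enc_paths, function() {
    fx <- read_labels_any(p$fixed_labels)
    mv <- read_labels_any(p$moving_labels)
    feats$fixed <- encode_features(fx, cfg$regions, cfg$encoding,
                                   sigma = cfg$encode_sigma)
    feats$moving <- encode_features(mv, cfg$regions, cfg$encoding,
                                    sigma = cfg$encode_sigma)
    for (i in 1:2)
      jsonlite::write_json(
        list(regions = feats[[c("fixed", "moving")[i]]]$region_ids,
             encoding = cfg$encoding, sigma = cfg$encode_sigma),
        enc_paths[i], auto_unbox = TRUE)
  })
  if (is.null(feats$fixed)) {  # resumed: re-encode (cheap, deterministic)
    feats$fixed <- encode_features(read_labels_any(p$fixed_labels),
                                   cfg$regions, cfg$encoding,
                                   sigma = cfg$encode_sigma)
    feats$moving <- encode_features(read_labels_any(p$moving_labels),
                                    cfg$regions, cfg$encoding,
                                    sigma = cfg$encode_sigma)
  }

  reg_paths <- file.path(p$out, c("M.txt", "phi1.nii.gz", "phi2.nii.gz",
                                  "energy_trace.csv"))
  stage("register", reg_paths, function() {
    M <- register_affine(feats$fixed, feats$moving, rc)
    res <- register_diffeomorphic(feats$fixed, feats$moving, M, rc)
    write_affine(res$M, reg_paths[1])
    write_field(res$phi1, reg_paths[2])
    write_field(res$phi2, reg_paths[3])
    utils::write.csv(res$energy_trace, reg_paths[4], row.names = FALSE)
  })

  out_store_dir <- file.path(p$out, "registered_store")
  stage("transform_volume", file.path(out_store_dir, "store.json"),
        function() {
    M <- read_affine(reg_paths[1])
    phi2 <- read_field(reg_paths[3])
    src_vol <- read_volume(p$src)
    s <- cfg$scale
    src_dir <- file.path(p$out, "source_store")
    src_store <- create_block_store(dim(src_vol$data),
                                    cfg$block$block_size,
                                    dtype = "uint16",
                                    voxel_size = src_vol$voxel_size,
                                    root = src_dir)
    ingest_volume(src_store, src_vol)
    out_shape <- round((field_shape(phi2) - 1) * s) + 1
    mp <- high_res_mapping(scale_affine(M, s), phi2, s, out_shape)
    out_store <- create_block_store(out_shape, cfg$block$block_size,
                                    dtype = "uint16",
                                    voxel_size = src_vol$voxel_size / s,
                                    root = out_store_dir)
    mask <- if (!is.null(p$brain_mask))
      read_labels_any(p$brain_mask)$data > 0
    transform_volume(src_store, mp, out_store, interp = cfg$interp,
                     workers = cfg$block$workers, brain_mask = mask,
                     margin = cfg$block$margin)
  })

  slice_dir <- file.path(p$out, paste0("reslice_", cfg$reslice_axis))
  stage("reslice", file.path(slice_dir, "slice_00000.tif"), function() {
    reslice(open_block_store(out_store_dir), cfg$reslice_axis, slice_dir,
            require_complete = is.null(p$brain_mask))
  })

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

read_labels_any <- function(path) {
  v <- read_volume(path)
  label_volume(v$data, voxel_size = v$voxel_size)
}
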