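# NIfTI-1 volume and label-map I/O with plain-text sidecars, and pipeline
# configuration files.

sidecar_path <- function(path, ext) {
  sub("\\.nii(\\.gz)?$", ext, path)
}

#' Write / read a PET volume as NIfTI-1 with a JSON metadata sidecar
#'
#' The activity volume goes to a NIfTI-1 file (double precision by default
#' so the round trip is bit-exact; `"float"` gives the conventional float32
#' interchange format) and the acquisition metadata (injected dose, body
#' weight, modality) to a JSON sidecar next to it.
#'
#' @param volume A [pet_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype NIfTI on-disk datatype, `"double"` or `"float"`.
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns a [pet_volume()].
#' @export
write_volume <- function(volume, path, datatype = c("double", "float")) {
  datatype <- match.arg(datatype)
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$voxel_size
  RNifti::writeNifti(img, path, datatype = datatype)
  meta <- list(injected_dose_mCi = volume$injected_dose,
               body_weight_g = volume$body_weight,
               modality = volume$modality,
               voxel_size_mm = volume$voxel_size)
  jsonlite::write_json(meta, sidecar_path(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) validation_error(paste("no such file:", path))
  sc <- sidecar_path(path, ".json")
  if (!file.exists(sc)) {
    validation_error(paste("missing metadata sidecar:", sc))
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (f in c("injected_dose_mCi", "body_weight_g", "modality")) {
    if (is.null(meta[[f]])) {
      validation_error(sprintf("sidecar %s lacks required field `%s`",
                               sc, f))
    }
  }
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim(img))
  pet_volume(vox, RNifti::pixdim(img)[1:3],
             meta$injected_dose_mCi, meta$body_weight_g, meta$modality)
}

#' Write / read a label map as uint8 NIfTI-1 with a YAML label dictionary
#'
#' @param labels A [label_map()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `write_label_map()` returns `path` invisibly; `read_label_map()`
#'   returns a [label_map()].
#' @export
write_label_map <- function(labels, path) {
  img <- RNifti::asNifti(labels$voxels)
  RNifti::writeNifti(img, path, datatype = "uint8")
  yaml::write_yaml(as.list(labels$labels), sidecar_path(path, ".labels.yaml"))
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  sc <- sidecar_path(path, ".labels.yaml")
  if (!file.exists(sc)) {
    validation_error(paste("missing label dictionary sidecar:", sc))
  }
  dict <- unlist(yaml::read_yaml(sc))
  img <- RNifti::readNifti(path)
  label_map(array(as.integer(img), dim(img)),
            setNames(as.integer(dict), names(dict)))
}

default_pipeline_config <- function() {
  list(
    mode = "PET_CT",
    n = 38,
    seed = 1,
    use_phantoms = TRUE,
    geometry_preset = "compact",
    dose_mCi = 7,
    weight_g = 65000,
    ims3_band = 0.10,
    score_distribution = NULL,   # NULL = mode default
    hazard = list(
      baseline_hazard = log(2) / 949,
      log_hr_ims45 = log(9.04),
      log_hr_ims5_extra = 0,
      censor_rate = 1 / 1095,
      admin_horizon = 1825,
      post_progression_hazard = log(2) / 180
    ),
    out_dir = NULL
  )
}

#' Build or load a pipeline configuration
#'
#' `pipeline_config()` assembles a validated configuration from defaults
#' plus overrides; `read_pipeline_config()` loads one from a YAML file.
#' Unknown keys are rejected rather than silently ignored.
#'
#' @param ... Named overrides of the default configuration (see
#'   [run_pipeline()] for the fields).
#' @param path YAML file path.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- default_pipeline_config()
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    config_error(paste("unknown configuration keys:", toString(unknown)))
  }
  if (!is.null(over$hazard)) {
    hz_unknown <- setdiff(names(over$hazard), names(defaults$hazard))
    if (length(hz_unknown)) {
      config_error(paste("unknown hazard keys:", toString(hz_unknown)))
    }
    over$hazard <- modifyList(defaults$hazard, over$hazard)
  }
  cfg <- modifyList(defaults, over, keep.null = TRUE)
  if (!cfg$mode %in% c("PET_CT", "PET_MR")) {
    config_error("`mode` must be PET_CT or PET_MR")
  }
  if (!is.numeric(cfg$n) || cfg$n < 1) {
    config_error("`n` must be a positive integer")
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error(paste("no such config file:", path))
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` object.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
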