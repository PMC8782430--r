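#' Read an experiment configuration from YAML
#'
#' The YAML file may set any argument of [experiment_config()]; `schedule`
#' is given as a list of durations in seconds, `tacs` as a mapping from
#' region name to a list of `[time, activity]` control points.
#'
#' @param path path to a YAML file.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$schedule)) {
    raw$schedule <- frame_schedule(unlist(raw$schedule))
  }
  if (!is.null(raw$tacs)) {
    raw$tacs <- tac_set(lapply(raw$tacs, function(cp) {
      do.call(rbind, lapply(cp, as.numeric))
    }))
  }
  do.call(experiment_config, raw)
}

#' Export a dynamic series
#'
#' Writes the frame stack as a NIfTI volume (requires the RNifti package)
#' with the schedule in a JSON sidecar, a plain-text interchange friendly
#' to other imaging tools.
#'
#' @param series a [dynamic_series()].
#' @param path output path without extension; `<path>.nii.gz` and
#'   `<path>.json` are written.
#' @export
write_dynamic_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("write_dynamic_series requires the RNifti package")
  }
  RNifti::writeNifti(simplify2array(series$frames), paste0(path, ".nii.gz"))
  jsonlite::write_json(
    list(kind = series$kind,
         durations = series$schedule$durations,
         start_times = series$schedule$start_times),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a dynamic series written by [write_dynamic_series()]
#'
#' @param path path prefix used at export time.
#' @export
read_dynamic_series <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("read_dynamic_series requires the RNifti package")
  }
  vol <- RNifti::readNifti(paste0(path, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- lapply(seq_len(dim(vol)[3]), function(t) {
    matrix(as.numeric(vol[, , t]), dim(vol)[1], dim(vol)[2])
  })
  dynamic_series(frames, frame_schedule(meta$durations), meta$kind)
}
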