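#' Write a weighted series to NIfTI + JSON sidecar
#'
#' The image stack is stored as a 3-D NIfTI volume `(rows, cols, contrasts)`
#' and the preparation durations as a JSON sidecar
#' `{"prep_ms": [0, 22.98, ..., "inf"]}`; the saturation sentinel is written
#' as the string `"inf"` since JSON has no infinity literal.
#'
#' @param series A [weighted_series()].
#' @param path Output path without extension; `.nii` and `.json` are
#'   appended.
#' @return Invisibly, the two paths written.
#' @export
write_weighted_series <- function(series, path) {
  nii <- paste0(path, ".nii")
  side <- paste0(path, ".json")
  RNifti::writeNifti(RNifti::asNifti(series$images), nii)
  prep <- lapply(series$prep_ms, function(p)
    if (is.infinite(p)) "inf" else p)
  jsonlite::write_json(list(prep_ms = prep), side, auto_unbox = TRUE,
                       digits = I(17))
  invisible(c(nii = nii, json = side))
}

#' Read a weighted series from NIfTI + JSON sidecar
#'
#' Inverse of [write_weighted_series()]: loss-less round trip of image data
#' and metadata. A contrast-count mismatch between the NIfTI volume and the
#' sidecar is refused, naming both counts.
#'
#' @param path Path without extension (expects `path.nii` and `path.json`).
#' @return A [weighted_series()].
#' @export
read_weighted_series <- function(path) {
  nii <- paste0(path, ".nii")
  side <- paste0(path, ".json")
  img <- RNifti::readNifti(nii)
  arr <- array(as.numeric(img), dim(img))
  meta <- jsonlite::read_json(side)
  prep <- vapply(meta$prep_ms, function(p)
    if (identical(p, "inf")) Inf else as.numeric(p), numeric(1))
  if (length(prep) != dim(arr)[3])
    stop(sprintf(
      "contrast-count mismatch: NIfTI has %d images but sidecar lists %d",
      dim(arr)[3], length(prep)), call. = FALSE)
  weighted_series(arr, prep)
}

#' Write fitted maps as NIfTI files
#'
#' Writes the TRAFF2, A, B and SD maps plus an integer flag map
#' (0 converged, 1 at bound, 2 insufficient signal, 3 not fitted) into a
#' directory.
#'
#' @param fit A `traff2_fit` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fit_maps <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maps <- list(traff2 = fit$traff2_map, a = fit$a_map, b = fit$b_map,
               sd = fit$sd_map)
  flags <- matrix(3L, nrow(fit$traff2_map), ncol(fit$traff2_map))
  flags[fit$flags$insufficient_signal] <- 2L
  flags[fit$flags$at_bound] <- 1L
  flags[fit$flags$converged] <- 0L
  maps$flags <- flags
  paths <- character(0)
  for (nm in names(maps)) {
    p <- file.path(dir, paste0(nm, ".nii"))
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read or write a run configuration
#'
#' A run configuration bundles everything needed to reproduce a pipeline
#' run: seed, pulse parameters, protocol, phantom and noise specification.
#' Stored as YAML; deterministic stages reproduce bit-identically from it
#' and stochastic stages reproduce given the stored seed.
#'
#' @param config Named list (for writing).
#' @param path YAML file path.
#' @return `read_run_config` returns the named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Default run configuration
#'
#' The protocol defaults of the mapping experiment: 625 Hz pulses,
#' 8/16/24-pulse trains with 0.7 ms spoilers, 4 s rest periods, ideal
#' saturation, 70 degree readout.
#'
#' @param seed Integer seed recorded in the configuration.
#' @return Named list suitable for [write_run_config()].
#' @export
default_run_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       pulse = list(f1max_hz = 625, phi0_rad = 0, n_samples = 256L,
                    b1_scale = 1),
       protocol = list(n_pulses = c(8L, 16L, 24L), spoiler_ms = 0.7,
                       rest_period_s = 4, saturation_efficiency = 1,
                       readout = "ideal", flip_deg = 70),
       phantom = list(type = "vial", grid_size = 96L, b0_peak_hz = 50,
                      b1_value = 1.05),
       noise = list(sigma = 0.005, model = "rician"))
}
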