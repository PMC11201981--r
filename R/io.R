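#' Read and write phantoms as NIfTI volumes
#'
#' The label grid is stored as an integer NIfTI volume with the voxel size
#' (in mm, the NIfTI convention) in the header `pixdim` and the world origin
#' encoded in the affine, so phantoms interoperate with standard medical
#' imaging viewers. Breast radius and gland fraction travel in a YAML
#' sidecar written next to the volume.
#'
#' @param phantom a `breast_phantom`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `write_phantom_nifti` returns `path` invisibly;
#'   `read_phantom_nifti` returns the reconstructed `breast_phantom`.
#' @export
write_phantom_nifti <- function(phantom, path) {
  stop_if_not_class(phantom, "breast_phantom")
  mm <- phantom$voxel_size * 1000
  img <- RNifti::asNifti(phantom$label)
  aff <- diag(c(mm, mm, mm, 1))
  aff[1:3, 4] <- (phantom$origin * 1000) + mm / 2
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  yaml::write_yaml(list(breast_radius = phantom$breast_radius,
                        gland_fraction = phantom$gland_fraction),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_phantom_nifti
#' @export
read_phantom_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  mm <- abs(aff[1, 1])
  meta <- list(breast_radius = NA_real_, gland_fraction = NA_real_)
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) meta <- modifyList(meta, yaml::read_yaml(sidecar))
  new_breast_phantom(array(as.integer(img), dim = dim(img)),
                     voxel_size = mm / 1000,
                     origin = (aff[1:3, 4] - mm / 2) / 1000,
                     breast_radius = meta$breast_radius,
                     gland_fraction = meta$gland_fraction)
}

#' Write a temperature field as NIfTI
#'
#' @param field a `temperature_field`.
#' @param phantom the phantom it was solved on (supplies the geometry).
#' @param path output path.
#' @export
write_field_nifti <- function(field, phantom, path) {
  stop_if_not_class(field, "temperature_field")
  mm <- phantom$voxel_size * 1000
  img <- RNifti::asNifti(field$T_grid)
  aff <- diag(c(mm, mm, mm, 1))
  aff[1:3, 4] <- (phantom$origin * 1000) + mm / 2
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write surface maps as CSV
#'
#' Plain-text exchange format: one row per skin node with columns
#' `x, y, z, nx, ny, nz, temperature` (meters / degC).
#'
#' @param surface a `surface_map`.
#' @param path output CSV path.
#' @export
write_surface_csv <- function(surface, path) {
  stop_if_not_class(surface, "surface_map")
  write.csv(surface$nodes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surface_csv
#' @param voxel_size,phantom_hash provenance to attach when reading a CSV
#'   produced elsewhere.
#' @export
read_surface_csv <- function(path, voxel_size = NA_real_,
                             phantom_hash = NA_character_) {
  nodes <- read.csv(path)
  need <- c("x", "y", "z", "nx", "ny", "nz", "temperature")
  if (!all(need %in% names(nodes))) {
    stop("surface CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(list(nodes = nodes[need], phantom_hash = phantom_hash,
                 voxel_size = voxel_size, noise = NULL),
            class = "surface_map")
}

#' Serialize a classified inverse result to JSON
#'
#' @param result an `inverse_result`.
#' @param path output JSON path.
#' @param seed,config_hash provenance stamped into the artifact.
#' @export
write_inverse_result <- function(result, path, seed = NA_integer_,
                                 config_hash = NA_character_) {
  stop_if_not_class(result, "inverse_result")
  payload <- list(
    theta_hat = list(center_m = result$theta_hat$center,
                     diameter_m = result$theta_hat$diameter),
    residual_rms = result$residual_rms,
    rms_base = result$rms_base,
    iterations = result$iterations,
    converged = result$converged,
    reason = result$reason,
    detected = result$detected,
    decision_reason = result$decision_reason,
    trajectory = result$trajectory,
    seed = seed,
    config_hash = config_hash
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Export an IR view set as 16-bit grayscale images with a JSON scale sidecar
#'
#' Each view is written as `view_<azimuth>.tif` (16-bit grayscale TIFF,
#' row-major from the top), with the linear degC mapping of the integer
#' range recorded in `views.json` and the raw temperatures in
#' `view_<azimuth>.csv` (full precision).
#'
#' @param views an `ir_view_set`.
#' @param dir output directory (created if needed).
#' @export
write_ir_views <- function(views, dir) {
  stop_if_not_class(views, "ir_view_set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_t <- unlist(lapply(views$views, function(v) v$image[!is.na(v$image)]))
  lo <- if (length(all_t)) min(all_t) else 0
  hi <- if (length(all_t)) max(all_t) else 1
  span <- max(hi - lo, 1e-9)
  for (v in views$views) {
    img <- v$image
    scaled <- (img - lo) / span
    scaled[is.na(scaled)] <- 0
    tiff::writeTIFF(t(scaled)[rev(seq_len(ncol(img))), , drop = FALSE],
                    file.path(dir, sprintf("view_%03d.tif", v$azimuth_deg)),
                    bits.per.sample = 16L)
    write.csv(v$image, file.path(dir, sprintf("view_%03d.csv", v$azimuth_deg)),
              row.names = FALSE)
  }
  jsonlite::write_json(
    list(scale = list(min_degC = lo, max_degC = hi),
         pixel_pitch_m = views$pixel_pitch,
         azimuths_deg = vapply(views$views, `[[`, numeric(1), "azimuth_deg"),
         background = "pixel value 0 outside the breast"),
    file.path(dir, "views.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read and write run configurations as YAML
#'
#' @param config a `run_config`.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  stop_if_not_class(config, "run_config")
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = raw$seed %||% 1L)
  for (nm in setdiff(names(raw), "seed")) {
    cfg[[nm]] <- if (is.list(raw[[nm]]) && is.list(cfg[[nm]]))
      modifyList(cfg[[nm]], raw[[nm]]) else raw[[nm]]
  }
  cfg$props <- validate_tissue_properties(structure(cfg$props,
                                                    class = "tissue_properties"))
  cfg$ambient <- do.call(default_ambient_conditions,
                         list(overrides = unclass(cfg$ambient)))
  cfg
}
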