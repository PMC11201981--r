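#' Extract the skin-surface temperature map from a solved field
#'
#' One node per breast-voxel face adjacent to air: the node position is the
#' face center, its temperature is the adjacent cell's temperature, and its
#' outward normal is the unit radial direction of the pendant dome at the
#' face center (the smooth geometric normal of the convex breast surface,
#' which the multi-view renderer uses for facing tests). Chest-wall base
#' faces are excluded by construction — only faces against air are skin.
#' The node set depends only on the phantom geometry, not on temperatures.
#'
#' @param phantom the `breast_phantom` the field was solved on.
#' @param field the `temperature_field` from [solve_bioheat()].
#' @param geom optional cached [discretize_phantom()] result.
#' @return a `surface_map` with `$nodes` columns
#'   `x, y, z, nx, ny, nz, temperature`.
#' @export
extract_surface <- function(phantom, field, geom = NULL) {
  stop_if_not_class(phantom, "breast_phantom")
  stop_if_not_class(field, "temperature_field")
  if (is.null(geom)) geom <- discretize_phantom(phantom)
  if (!identical(geom$geometry_hash, field$phantom_hash)) {
    stop("temperature field was not solved on this phantom geometry",
         call. = FALSE)
  }
  af <- geom$air_faces
  cell <- af[, 1]
  dirs <- FACE_DIRS[af[, 2], , drop = FALSE]
  pos <- geom$centers[cell, , drop = FALSE] + (geom$h / 2) * dirs
  nrm <- pos
  len <- sqrt(rowSums(nrm^2))
  degen <- len < 1e-12
  nrm[degen, ] <- dirs[degen, ]
  len[degen] <- 1
  nrm <- nrm / len
  nodes <- data.frame(
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
    temperature = field$values[cell]
  )
  structure(list(
    nodes = nodes,
    phantom_hash = geom$geometry_hash,
    voxel_size = geom$h,
    noise = NULL
  ), class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("<surface_map> %d skin nodes, T in [%.2f, %.2f] degC%s\n",
              nrow(x$nodes), min(x$nodes$temperature), max(x$nodes$temperature),
              if (is.null(x$noise)) "" else
                sprintf(", noise sd %.3f degC", x$noise$sigma)))
  invisible(x)
}

#' Camera noise model
#'
#' Additive i.i.d. Gaussian noise with standard deviation equal to the
#' camera's thermal sensitivity (NETD). The default 0.02 degC corresponds to
#' a high-sensitivity research-grade infrared camera.
#'
#' @param sigma noise standard deviation (degC), `>= 0`.
#' @param seed integer RNG seed for reproducible noise draws.
#' @return a `noise_model`.
#' @export
noise_model <- function(sigma = 0.02, seed = 1L) {
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(sigma = sigma, seed = as.integer(seed)), class = "noise_model")
}

#' Apply camera noise to surface temperatures or rendered views
#'
#' Adds i.i.d. Gaussian noise of standard deviation `model$sigma` to every
#' temperature sample, reproducibly from `model$seed`, without disturbing
#' the global RNG stream. With `sigma = 0` the input is returned unchanged.
#'
#' @param x a `surface_map` or `ir_view_set`.
#' @param model a [noise_model()].
#' @return the same type as `x`, with noisy temperatures and the noise
#'   descriptor recorded.
#' @export
add_camera_noise <- function(x, model) UseMethod("add_camera_noise")

#' @export
add_camera_noise.surface_map <- function(x, model) {
  stop_if_not_class(model, "noise_model")
  if (model$sigma > 0) {
    x$nodes$temperature <- x$nodes$temperature +
      with_seed(model$seed, rnorm(nrow(x$nodes), 0, model$sigma))
  }
  x$noise <- list(sigma = model$sigma, seed = model$seed)
  x
}

#' @export
add_camera_noise.ir_view_set <- function(x, model) {
  stop_if_not_class(model, "noise_model")
  if (model$sigma > 0) {
    x$views <- with_seed(model$seed, lapply(x$views, function(v) {
      fg <- !is.na(v$image)
      v$image[fg] <- v$image[fg] + rnorm(sum(fg), 0, model$sigma)
      v
    }))
  }
  x$noise <- list(sigma = model$sigma, seed = model$seed)
  x
}

#' Render the eight-view infrared image set
#'
#' Orthographic projection of the surface nodes onto eight image planes at
#' 45-degree azimuth steps around the pendant breast axis, emulating a ring
#' of horizontal infrared cameras. A node is front-facing in a view when its
#' outward normal has a positive component toward the camera; front-facing
#' nodes are splatted to the nearest pixel with nearest-node z-buffering
#' (the closest node to the camera wins each pixel), so every foreground
#' pixel carries an exact node temperature, with no interpolation.
#'
#' @param surface a `surface_map`.
#' @param pixel_pitch image pixel size (m); defaults to the voxel size.
#' @return an `ir_view_set`: eight views, each with `$azimuth_deg`, the
#'   temperature `$image` (degC, `NA` background), and the `$owner` matrix of
#'   winning node indices.
#' @export
render_views <- function(surface, pixel_pitch = NULL) {
  stop_if_not_class(surface, "surface_map")
  nd <- surface$nodes
  if (nrow(nd) == 0) stop("surface map has no nodes", call. = FALSE)
  pitch <- pixel_pitch %||% surface$voxel_size
  azimuths <- seq(0, 315, by = 45)

  umax <- max(sqrt(nd$x^2 + nd$y^2)) + pitch
  vmin <- min(nd$z) - pitch
  vmax <- max(nd$z) + pitch
  nu <- ceiling(2 * umax / pitch)
  nv <- ceiling((vmax - vmin) / pitch)

  views <- lapply(azimuths, function(az) {
    a <- az * pi / 180
    facing <- nd$nx * cos(a) + nd$ny * sin(a) > 0
    img <- matrix(NA_real_, nu, nv)
    own <- matrix(NA_integer_, nu, nv)
    if (any(facing)) {
      idx <- which(facing)
      u <- -nd$x[idx] * sin(a) + nd$y[idx] * cos(a)
      v <- nd$z[idx]
      depth <- nd$x[idx] * cos(a) + nd$y[idx] * sin(a)
      iu <- pmin(pmax(floor((u + umax) / pitch) + 1, 1), nu)
      iv <- pmin(pmax(floor((v - vmin) / pitch) + 1, 1), nv)
      ord <- order(depth)             # nearest (largest depth) written last
      pix <- cbind(iu[ord], iv[ord])
      img[pix] <- nd$temperature[idx][ord]
      own[pix] <- idx[ord]
    }
    list(azimuth_deg = az, image = img, owner = own)
  })
  structure(list(views = views, pixel_pitch = pitch,
                 phantom_hash = surface$phantom_hash, noise = surface$noise),
            class = "ir_view_set")
}

#' @export
print.ir_view_set <- function(x, ...) {
  d <- dim(x$views[[1]]$image)
  cat(sprintf("<ir_view_set> 8 views at 45 deg steps, %d x %d px @ %.2f mm\n",
              d[1], d[2], 1000 * x$pixel_pitch))
  invisible(x)
}

# Indices of views (1..8) in which each node is front-facing. For a convex
# dome, front-facing implies unoccluded visibility under orthographic
# projection; z-buffer contention is a pixel-sampling effect, not occlusion.
node_visibility <- function(surface) {
  nd <- surface$nodes
  sapply(seq(0, 315, by = 45), function(az) {
    a <- az * pi / 180
    nd$nx * cos(a) + nd$ny * sin(a) > 0
  })
}

#' Residual between simulated and observed surface maps
#'
#' Per-node temperature differences `r_i = T_sim,i - T_obs,i` in the fixed
#' node order shared by construction, plus the root-mean-square residual.
#' The two maps must be defined on the same node set (same phantom geometry,
#' same coordinates).
#'
#' @param sim,obs `surface_map` objects on the same node set.
#' @return list with `residual` (degC per node), `rms` (degC), `n`.
#' @export
surface_residual <- function(sim, obs) {
  stop_if_not_class(sim, "surface_map")
  stop_if_not_class(obs, "surface_map")
  if (nrow(sim$nodes) != nrow(obs$nodes) ||
      !identical(sim$phantom_hash, obs$phantom_hash)) {
    stop("surface maps are defined on different node sets", call. = FALSE)
  }
  r <- sim$nodes$temperature - obs$nodes$temperature
  list(residual = r, rms = sqrt(mean(r^2)), n = length(r))
}
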