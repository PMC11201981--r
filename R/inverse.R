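#' Initial tumor guess for the inverse fit
#'
#' The optimizer starts from a 1.8 cm tumor placed centrally within the
#' breast: the center is the centroid of breast-labeled voxels.
#'
#' @param phantom a `breast_phantom`.
#' @return a [tumor_params()] with diameter 0.018 m.
#' @export
initial_guess <- function(phantom) {
  stop_if_not_class(phantom, "breast_phantom")
  tumor_params(breast_centroid(phantom), 0.018)
}

#' Forward model: surface temperatures for a candidate tumor
#'
#' Embeds the candidate tumor (skipping embedding when the sphere captures
#' no breast voxel, so a source pushed outside the breast or shrunk below
#' the voxel scale is simply absent — the mechanism that lets the inverse
#' fit express "no tumor"), assembles and solves the bioheat system, and
#' extracts the skin-surface map. Deterministic for fixed inputs.
#'
#' @param theta a [tumor_params()] candidate, or `NULL` for a tumor-free solve.
#' @param phantom a tumor-free `breast_phantom`.
#' @param props,ambient tissue and ambient configuration.
#' @param geom optional cached [discretize_phantom()] result.
#' @param tol,x0 solver options passed to [solve_bioheat()].
#' @param source_floor_diameter regularization floor for the tumor source.
#' @return a `surface_map`.
#' @export
forward_model <- function(theta, phantom, props = default_tissue_properties(),
                          ambient = default_ambient_conditions(), geom = NULL,
                          tol = 1e-9, x0 = NULL, source_floor_diameter = 0.01) {
  stop_if_not_class(phantom, "breast_phantom")
  if (is.null(geom)) geom <- discretize_phantom(phantom)
  ph <- phantom
  tum <- NULL
  if (!is.null(theta)) {
    stop_if_not_class(theta, "tumor_params")
    idx <- tumor_voxel_indices(phantom, theta)
    if (length(idx) > 0) {
      ph$label[idx] <- LABEL_TUMOR
      tum <- theta
    }
  }
  sys <- assemble_system(ph, props, ambient, tumor = tum, geom = geom,
                         source_floor_diameter = source_floor_diameter)
  field <- solve_bioheat(sys, tol = tol, x0 = x0)
  extract_surface(ph, field, geom = geom)
}

#' Finite-difference Jacobian of the forward model
#'
#' Central finite differences of the surface temperatures with respect to
#' the tumor parameters, column order `(x_c, y_c, z_c, D)`. Default steps
#' are one voxel for the coordinates and 10% for the diameter — at the scale
#' of the voxelized forward model these secant slopes average over the
#' discrete voxel-membership jumps.
#'
#' @inheritParams forward_model
#' @param theta a [tumor_params()] expansion point.
#' @param steps numeric length-4 step sizes (m); default
#'   `c(h, h, h, 0.1 * D)`.
#' @param scheme `"central"` (default) or `"forward"` differences.
#' @return an n_nodes x 4 matrix (degC per meter); columns named
#'   `xc, yc, zc, D`. All-zero columns are flagged with a warning
#'   (insensitive parameter).
#' @export
jacobian_fd <- function(theta, phantom, props = default_tissue_properties(),
                        ambient = default_ambient_conditions(), geom = NULL,
                        steps = NULL, scheme = c("central", "forward")) {
  scheme <- match.arg(scheme)
  stop_if_not_class(theta, "tumor_params")
  if (is.null(geom)) geom <- discretize_phantom(phantom)
  h <- phantom$voxel_size
  steps <- steps %||% c(h, h, h, 0.1 * theta$diameter)
  fn <- function(v) {
    forward_model(tumor_params(v[1:3], max(v[4], h / 10)), phantom, props,
                  ambient, geom = geom)$nodes$temperature
  }
  J <- fd_jacobian(fn, c(theta$center, theta$diameter), steps, scheme = scheme)
  colnames(J) <- c("xc", "yc", "zc", "D")
  zero_cols <- colSums(abs(J)) == 0
  if (any(zero_cols)) {
    warning("insensitive parameter column(s): ",
            paste(colnames(J)[zero_cols], collapse = ", "), call. = FALSE)
  }
  J
}

#' Levenberg-Marquardt inverse fit of tumor parameters
#'
#' Iterates the damped Gauss-Newton update
#' `delta = -(J'J + lambda diag(J'J))^-1 J' r` over the four tumor
#' parameters, where `r` is the simulated-minus-observed surface temperature
#' residual. Accepted steps (decreasing residual RMS) divide `lambda` by 3,
#' rejected steps multiply it by 3 (`lambda0 = 1e-2`); iteration stops when
#' the relative residual change drops below 1e-4, the scaled step norm drops
#' below 1e-4, or after 50 iterations. The diameter is floored at a tenth of
#' a voxel and the center is unconstrained: wandering outside the breast or
#' to the chest wall is the fit's way of expressing absence. The tumor
#' source magnitude is re-evaluated from the size-dependent heat-generation
#' relation at every iterate.
#'
#' @param observed the observed `surface_map` (defined on the phantom's
#'   node set).
#' @param phantom the tumor-free `breast_phantom`.
#' @param props,ambient tissue and ambient configuration.
#' @param init initial [tumor_params()]; default [initial_guess()].
#' @param control optional list overriding [lm_control()] settings.
#' @param geom optional cached [discretize_phantom()] result.
#' @param multi_start when `TRUE`, additionally runs four quadrant-seeded
#'   starts and keeps the best final residual (insurance against local
#'   minima; the default single start mirrors routine use).
#' @return an `inverse_result`: `$theta_hat`, `$residual_rms`, `$rms_base`
#'   (tumor-free model residual against the same observation),
#'   `$iterations`, `$converged`, `$reason`, `$trajectory`, `$detected` /
#'   `$decision_reason` (filled by [classify_detection()]).
#' @export
lma_fit <- function(observed, phantom, props = default_tissue_properties(),
                    ambient = default_ambient_conditions(), init = NULL,
                    control = NULL, geom = NULL, multi_start = FALSE) {
  stop_if_not_class(observed, "surface_map")
  stop_if_not_class(phantom, "breast_phantom")
  if (is.null(geom)) geom <- discretize_phantom(phantom)
  if (nrow(observed$nodes) != nrow(geom$air_faces)) {
    stop("observed surface map does not match the phantom's node set",
         call. = FALSE)
  }
  ctrl <- do.call(lm_control, control %||% list())
  h <- phantom$voxel_size
  init <- init %||% initial_guess(phantom)
  obs_t <- observed$nodes$temperature

  warm <- new.env(parent = emptyenv())
  warm$x <- NULL
  resid_fn <- function(v) {
    # diameter floored here as well so finite-difference probes below the
    # projection floor stay evaluable
    sm <- forward_model(tumor_params(v[1:3], max(v[4], h / 10)), phantom,
                        props, ambient, geom = geom, x0 = warm$x)
    warm$x <- NULL  # warm start only helps within one solve family; keep simple
    sm$nodes$temperature - obs_t
  }
  project <- function(v) {
    v[4] <- max(v[4], h / 10)
    v
  }
  scale <- c(rep(max(phantom$breast_radius, 10 * h, na.rm = TRUE), 3),
             init$diameter)
  steps <- c(h, h, h, 0.1 * init$diameter)

  starts <- list(c(init$center, init$diameter))
  if (multi_start) {
    r0 <- max(phantom$breast_radius, 10 * h, na.rm = TRUE) / 2
    cz <- init$center[3]
    for (s in list(c(r0, r0), c(-r0, r0), c(-r0, -r0), c(r0, -r0))) {
      starts[[length(starts) + 1L]] <- c(s[1], s[2], cz, init$diameter)
    }
  }

  best <- NULL
  for (th0 in starts) {
    fit <- lm_core(resid_fn, th0, scale = scale, steps = steps,
                   project = project, control = ctrl)
    if (is.null(best) || fit$rms < best$rms) best <- fit
  }

  base_sm <- forward_model(NULL, phantom, props, ambient, geom = geom)
  rms_base <- sqrt(mean((base_sm$nodes$temperature - obs_t)^2))

  traj <- best$trajectory
  names(traj)[2:5] <- c("xc", "yc", "zc", "D")
  structure(list(
    theta_hat = tumor_params(best$theta[1:3], best$theta[4]),
    residual_rms = best$rms,
    rms_base = rms_base,
    n_nodes = length(obs_t),
    iterations = best$iterations,
    converged = best$converged,
    reason = best$reason,
    trajectory = traj,
    n_forward_solves = best$nfev + 1L,
    detected = NA,
    decision_reason = NA_character_
  ), class = "inverse_result")
}

# Decision-rule thresholds; improvement_factor scales the matched-filter
# noise floor 16 * sigma^2 = factor * n_params * sigma^2 on the SSE scale.
detection_control <- function(chest_margin_voxels = 1, subvoxel_factor = 1,
                              improvement_factor = 4, n_params = 4) {
  list(chest_margin_voxels = chest_margin_voxels,
       subvoxel_factor = subvoxel_factor,
       improvement_factor = improvement_factor,
       n_params = n_params)
}

#' Classify an inverse fit as tumor present or absent
#'
#' Encodes the no-tumor branch of the detection flowchart: the fit expresses
#' absence by parking the source where it barely affects the surface.
#' The call is *absent* when any of the following holds, checked in order:
#' the fitted center lies outside breast tissue (`outside-breast`); the
#' center sits within one voxel of the chest-wall plane (`chest-wall`); the
#' fitted diameter is below the voxel scale (`sub-voxel-size`); or the
#' fitted source improves the sum of squared residuals over the tumor-free
#' model by less than the matched-filter camera noise floor
#' `improvement_factor * n_params * sigma_cam^2` (`no-improvement`) — i.e.
#' the recovered thermal signature does not exceed what fitting four
#' parameters to pure camera noise would yield. Otherwise the call is
#' *present* (`in-breast`) with the fitted size and location.
#'
#' @param result an `inverse_result` from [lma_fit()].
#' @param phantom the tumor-free `breast_phantom` the fit ran on.
#' @param noise_sigma camera noise standard deviation (degC) of the
#'   observation; 0 means any strict improvement counts.
#' @param control optional list overriding [detection_control] thresholds.
#' @return the `inverse_result` with `$detected` (logical) and
#'   `$decision_reason` filled in.
#' @export
classify_detection <- function(result, phantom, noise_sigma = 0,
                               control = NULL) {
  stop_if_not_class(result, "inverse_result")
  stop_if_not_class(phantom, "breast_phantom")
  ctrl <- do.call(detection_control, control %||% list())
  h <- phantom$voxel_size
  th <- result$theta_hat

  vox <- world_to_voxel(phantom, th$center)
  inside <- !is.na(vox) && phantom$label[vox] %in% BREAST_LABELS
  sse_gain <- result$n_nodes * (result$rms_base^2 - result$residual_rms^2)
  floor_sse <- ctrl$improvement_factor * ctrl$n_params * noise_sigma^2

  reason <- if (!inside) {
    "outside-breast"
  } else if (th$center[3] < ctrl$chest_margin_voxels * h) {
    "chest-wall"
  } else if (th$diameter < ctrl$subvoxel_factor * h) {
    "sub-voxel-size"
  } else if (sse_gain <= floor_sse) {
    "no-improvement"
  } else {
    "in-breast"
  }
  result$detected <- reason == "in-breast"
  result$decision_reason <- reason
  result$sse_gain <- sse_gain
  result$sse_gain_floor <- floor_sse
  result
}

#' @export
print.inverse_result <- function(x, ...) {
  th <- x$theta_hat
  cat(sprintf("<inverse_result> %s after %d iterations (%s)\n",
              if (isTRUE(x$detected)) "tumor PRESENT"
              else if (isFALSE(x$detected)) "tumor ABSENT" else "unclassified",
              x$iterations, x$reason))
  cat(sprintf("  theta_hat: center (%.1f, %.1f, %.1f) mm, D %.1f mm\n",
              1000 * th$center[1], 1000 * th$center[2], 1000 * th$center[3],
              1000 * th$diameter))
  cat(sprintf("  residual RMS %.4f degC (tumor-free model %.4f degC)\n",
              x$residual_rms, x$rms_base))
  if (!is.na(x$decision_reason)) cat("  decision:", x$decision_reason, "\n")
  invisible(x)
}
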