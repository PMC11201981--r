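# Shared fixtures, built once per test run.  The "coarse" phantom (4 cm
# radius, 5 mm voxels, ~550 breast voxels) keeps forward solves at the
# millisecond scale; the "medium" phantom (5 cm radius, 2.5 mm voxels) is
# used where sub-voxel recovery accuracy matters.

coarse_phantom <- build_hemisphere_phantom(0.04, 0.005, gland_fraction = 0.5)
coarse_geom <- discretize_phantom(coarse_phantom)

medium_phantom <- build_hemisphere_phantom(0.05, 0.0025, gland_fraction = 0.5)
medium_geom <- discretize_phantom(medium_phantom)

test_props <- default_tissue_properties()
test_ambient <- default_ambient_conditions()

# Ambient settings that make the solved field isothermal at T_core: no
# radiation, enormous film coefficient, air temperature equal to core.
isothermal_ambient <- default_ambient_conditions(
  list(epsilon = 0, h = 1e9, T_inf = 37, T_core = 37))

# Properties with no perfusion and no metabolic sources.
inert_props <- default_tissue_properties(list(
  fat = list(omega_b = 0, q_m = 0),
  gland = list(omega_b = 0, q_m = 0),
  tumor = list(omega_b = 0, q_m = 0)))

peak_surface_dt <- function(theta, phantom, geom,
                            props = test_props, ambient = test_ambient) {
  base <- forward_model(NULL, phantom, props, ambient, geom = geom)
  with_t <- forward_model(theta, phantom, props, ambient, geom = geom)
  max(with_t$nodes$temperature - base$nodes$temperature)
}

# --- 1-D two-parameter toy inverse problem -------------------------------
# A slab with a buried heat layer: parameters are the layer's center depth
# x_s (m) and its volumetric magnitude q (W m^-3); the layer has a smooth
# Gaussian cross-section so the residual is differentiable in x_s, and the
# observation is the full cell-center temperature profile.  Used to check
# the LM engine against exhaustive grid search and against an independent
# LM implementation.

toy_slab <- build_slab_phantom(0.1, 0.0025, tissue = "gland")
toy_geom <- discretize_phantom(toy_slab)
toy_ambient <- default_ambient_conditions(list(epsilon = 0))
toy_width <- 0.0025  # heat layer Gaussian sd (m)

toy_forward <- function(x_s, q) {
  src <- q * exp(-0.5 * ((toy_geom$centers[, 3] - x_s) / toy_width)^2)
  sys <- assemble_system(toy_slab, test_props, toy_ambient,
                         extra_source = src, geom = toy_geom)
  solve_bioheat(sys)$values
}

toy_truth <- c(x_s = 0.06, q = 30000)
toy_observed <- toy_forward(toy_truth[1], toy_truth[2])

toy_resid <- function(v) toy_forward(v[1], v[2]) - toy_observed

toy_grid_search <- function(xs_grid, q_grid) {
  best <- c(NA, NA)
  best_rms <- Inf
  for (xs in xs_grid) {
    for (q in q_grid) {
      rms <- sqrt(mean((toy_forward(xs, q) - toy_observed)^2))
      if (rms < best_rms) {
        best_rms <- rms
        best <- c(xs, q)
      }
    }
  }
  list(theta = best, rms = best_rms)
}
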