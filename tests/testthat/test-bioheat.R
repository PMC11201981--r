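test_that("tumor heat generation follows the adopted size-dependent relation", {
  # hand evaluation at D = 1 cm: ln(1) = 0, so q_t = 3.27e6 / 50
  expect_equal(tumor_heat_generation(0.01), 65400)
  # strictly decreasing over the valid domain
  d <- seq(0.0095, 0.05, length.out = 40)
  expect_true(all(diff(tumor_heat_generation(d)) < 0))
  # zero-source limit
  expect_equal(tumor_heat_generation(0.02, c1 = 0), 0)
  # pole of the relation: denominator <= 0 rejected
  expect_error(tumor_heat_generation(0.008), "denominator")
  expect_error(tumor_heat_generation(-0.01), "positive")
})

test_that("regularized source density is finite, continuous and monotone through the floor", {
  d <- seq(0.002, 0.05, length.out = 200)
  q <- tumor_source_density(d)
  expect_true(all(is.finite(q) & q > 0))
  expect_true(all(diff(q) <= 0))
  # clamped exactly at the 1 cm floor below it, untouched above
  expect_equal(tumor_source_density(0.004), tumor_heat_generation(0.01))
  expect_equal(tumor_source_density(0.02), tumor_heat_generation(0.02))
})

test_that("slab oracle satisfies the ODE and its boundary conditions", {
  for (cfg in list(list(q = 0, tissue = "fat"),
                   list(q = 30000, tissue = "gland"))) {
    amb <- default_ambient_conditions(list(epsilon = 0))
    or <- slab_oracle(0.05, test_props, amb, q = cfg$q, tissue = cfg$tissue)
    xs <- seq(0.0005, 0.0495, length.out = 100)
    expect_lt(max(abs(or$residual(xs))), 1e-8)
    expect_lt(max(abs(or$bc_residual())), 1e-8)
  }
  # zero-perfusion branch
  or0 <- slab_oracle(0.05, inert_props, default_ambient_conditions(list(epsilon = 0)),
                     q = 2000, tissue = "fat")
  xs <- seq(0.0005, 0.0495, length.out = 100)
  expect_lt(max(abs(or0$residual(xs))), 1e-8)
  expect_lt(max(abs(or0$bc_residual())), 1e-8)
})

test_that("slab oracle limits collapse to the expected constants", {
  # q = 0, omega = 0, h -> Inf, T_inf = T_core: constant T_core
  or <- slab_oracle(0.05, inert_props, isothermal_ambient, q = 0, tissue = "fat")
  expect_equal(or$profile(seq(0, 0.05, length.out = 20)), rep(37, 20),
               tolerance = 1e-9)
  # omega > 0, q = q_m = 0, both boundaries effectively at T_a: constant T_a
  no_met <- default_tissue_properties(list(gland = list(q_m = 0)))
  or2 <- slab_oracle(0.05, no_met, isothermal_ambient, q = 0, tissue = "gland")
  expect_equal(or2$profile(seq(0, 0.05, length.out = 20)), rep(37, 20),
               tolerance = 1e-9)
})

test_that("finite-volume solve reproduces the slab oracle at second order", {
  amb <- default_ambient_conditions(list(epsilon = 0))
  errs <- sapply(c(0.0025, 0.00125), function(h) {
    ph <- build_slab_phantom(0.05, h, tissue = "fat")
    sys <- assemble_system(ph, test_props, amb)
    fld <- solve_bioheat(sys)
    or <- slab_oracle(0.05, test_props, amb, q = 0, tissue = "fat")
    max(abs(fld$values - or$profile(((2:(round(0.05 / h) + 1)) - 1.5) * h)))
  })
  expect_lt(errs[1], 0.05)
  ratio <- errs[1] / errs[2]
  expect_gte(ratio, 3)
  expect_lte(ratio, 5)
})

test_that("equilibrium configurations solve to a constant field", {
  # isothermal limit on the hemisphere: no sources, no perfusion, pinned skin
  sys <- assemble_system(coarse_phantom, inert_props, isothermal_ambient,
                         geom = coarse_geom)
  fld <- solve_bioheat(sys)
  expect_lt(max(abs(fld$values - 37)), 1e-6)
  expect_true(fld$solver$converged)
})

test_that("the assembled operator is symmetric and strictly diagonally dominant", {
  tum <- tumor_params(c(0.0025, 0.0025, 0.02), 0.012)
  sys <- assemble_system(embed_tumor(coarse_phantom, tum), test_props,
                         test_ambient, tumor = tum, geom = coarse_geom)
  m <- system_matrix(sys)
  expect_lt(max(abs(m$A - Matrix::t(m$A))), 1e-14)
  offdiag_sum <- Matrix::rowSums(abs(m$A)) - 2 * abs(Matrix::diag(m$A))
  expect_true(all(offdiag_sum < 0))
  # the CG kernel agrees with an independent sparse solve
  fld <- solve_bioheat(sys)
  ref <- as.numeric(Matrix::solve(m$A, m$b))
  expect_lt(max(abs(fld$values - ref)), 1e-6)
})

test_that("discrete energy balance holds at the solution", {
  tum <- tumor_params(c(0.0025, 0.0025, 0.02), 0.012)
  pht <- embed_tumor(coarse_phantom, tum)
  sys <- assemble_system(pht, test_props, test_ambient, tumor = tum,
                         geom = coarse_geom)
  fld <- solve_bioheat(sys)
  eb <- energy_balance(sys, fld)
  expect_lt(eb$rel_imbalance, 1e-6)
  expect_gt(eb$source_total, 0)
})

test_that("temperature excess is linear in the metabolic source", {
  amb <- default_ambient_conditions(list(T_inf = 37, T_core = 37))
  props1 <- default_tissue_properties(list(
    fat = list(omega_b = 0, q_m = 300), gland = list(omega_b = 0, q_m = 300)))
  props2 <- default_tissue_properties(list(
    fat = list(omega_b = 0, q_m = 600), gland = list(omega_b = 0, q_m = 600)))
  f1 <- solve_bioheat(assemble_system(coarse_phantom, props1, amb, geom = coarse_geom))
  f2 <- solve_bioheat(assemble_system(coarse_phantom, props2, amb, geom = coarse_geom))
  expect_equal(f2$values - 37, 2 * (f1$values - 37), tolerance = 1e-6)
})

test_that("a pointwise-enlarged source never decreases any temperature", {
  extra <- rep(0, coarse_geom$n)
  extra[coarse_geom$centers[, 3] > 0.02] <- 5000
  f0 <- solve_bioheat(assemble_system(coarse_phantom, test_props, test_ambient,
                                      geom = coarse_geom))
  f1 <- solve_bioheat(assemble_system(coarse_phantom, test_props, test_ambient,
                                      extra_source = extra, geom = coarse_geom))
  expect_true(all(f1$values - f0$values > -1e-8))
  expect_gt(max(f1$values - f0$values), 0.01)
})

test_that("adding a tumor strictly raises the peak skin temperature", {
  tum <- tumor_params(c(0.0025, 0.0025, 0.02), 0.015)
  base <- forward_model(NULL, coarse_phantom, geom = coarse_geom)
  with_t <- forward_model(tum, coarse_phantom, geom = coarse_geom)
  expect_gt(max(with_t$nodes$temperature), max(base$nodes$temperature))
})

test_that("peak skin warming is monotone in tumor depth and diameter", {
  # deeper tumors of fixed size warm the skin less (non-increasing)
  depths <- c(0.012, 0.018, 0.024)
  dts_depth <- sapply(depths, function(dep) {
    peak_surface_dt(tumor_params(c(0.0025, 0.0025, 0.04 - dep), 0.012),
                    coarse_phantom, coarse_geom)
  })
  expect_true(all(diff(dts_depth) <= 1e-9))
  # larger tumors at fixed depth warm the skin more (non-decreasing)
  dts_size <- sapply(c(0.010, 0.014, 0.018), function(d) {
    peak_surface_dt(tumor_params(c(0.0025, 0.0025, 0.018), d),
                    coarse_phantom, coarse_geom)
  })
  expect_true(all(diff(dts_size) >= -1e-9))
})

test_that("assembly rejects inconsistent inputs", {
  empty <- coarse_phantom
  empty$label[empty$label %in% 1:3] <- 0L
  expect_error(assemble_system(empty, test_props, test_ambient), "no breast voxels")
  pht <- embed_tumor(coarse_phantom, tumor_params(c(0.0025, 0.0025, 0.02), 0.012))
  expect_error(assemble_system(pht, test_props, test_ambient), "tumor")
  expect_error(assemble_system(coarse_phantom, test_props, test_ambient,
                               extra_source = c(1, 2, 3), geom = coarse_geom),
               "one entry per breast voxel")
})
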