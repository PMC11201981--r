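solve_field <- function(phantom, geom, props = test_props, ambient = test_ambient) {
  solve_bioheat(assemble_system(phantom, props, ambient, geom = geom))
}

test_that("surface extraction returns one node per air-adjacent face, chest base excluded", {
  fld <- solve_field(coarse_phantom, coarse_geom)
  sm <- extract_surface(coarse_phantom, fld, geom = coarse_geom)

  # independent brute-force face count over the raw label grid
  lab <- coarse_phantom$label
  d <- dim(lab)
  padded <- array(0L, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- lab
  brute <- 0L
  for (shift in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
    core <- padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
    nb <- padded[2:(d[1] + 1) + shift[1], 2:(d[2] + 1) + shift[2],
                 2:(d[3] + 1) + shift[3]]
    brute <- brute + sum(core %in% 1:3 & nb == 0L)
  }
  expect_identical(nrow(sm$nodes), as.integer(brute))

  # all nodes sit above the chest plane and normals are unit length
  expect_true(all(sm$nodes$z > 0))
  expect_equal(sqrt(sm$nodes$nx^2 + sm$nodes$ny^2 + sm$nodes$nz^2),
               rep(1, nrow(sm$nodes)), tolerance = 1e-12)

  # voxelized face count carries the staircase factor over the smooth area
  smooth <- 2 * pi * coarse_phantom$breast_radius^2 / coarse_phantom$voxel_size^2
  expect_gt(nrow(sm$nodes) / smooth, 1.3)
  expect_lt(nrow(sm$nodes) / smooth, 1.7)
})

test_that("an isothermal field yields an isothermal surface map", {
  fld <- solve_bioheat(assemble_system(coarse_phantom, inert_props,
                                       isothermal_ambient, geom = coarse_geom))
  sm <- extract_surface(coarse_phantom, fld, geom = coarse_geom)
  expect_equal(sm$nodes$temperature, rep(37, nrow(sm$nodes)), tolerance = 1e-6)
})

test_that("surface extraction rejects a mismatched phantom/field pair", {
  fld <- solve_field(coarse_phantom, coarse_geom)
  expect_error(extract_surface(medium_phantom, fld, geom = medium_geom),
               "not solved on this phantom")
})

test_that("mirroring phantom and field mirrors the surface map", {
  tum <- tumor_params(c(0.0125, 0.0025, 0.0175), 0.013)
  pht <- embed_tumor(coarse_phantom, tum)
  gt <- discretize_phantom(pht)
  sm <- extract_surface(pht, solve_bioheat(
    assemble_system(pht, test_props, test_ambient, tumor = tum, geom = gt)), gt)

  phm <- mirror_phantom(pht)
  gm <- discretize_phantom(phm)
  smm <- extract_surface(phm, solve_bioheat(
    assemble_system(phm, test_props, test_ambient, tumor = phm$tumor, geom = gm)), gm)

  key <- function(n) sprintf("%.6f|%.6f|%.6f", n$x, n$y, n$z)
  m1 <- sm$nodes
  m1$x <- -m1$x
  ord1 <- order(key(m1))
  ord2 <- order(key(smm$nodes))
  expect_equal(m1$temperature[ord1], smm$nodes$temperature[ord2], tolerance = 1e-7)
})

test_that("eight views are rendered with exact nearest-node temperatures", {
  tum <- tumor_params(c(0.0125, 0.0025, 0.0175), 0.013)
  pht <- embed_tumor(coarse_phantom, tum)
  gt <- discretize_phantom(pht)
  sm <- extract_surface(pht, solve_bioheat(
    assemble_system(pht, test_props, test_ambient, tumor = tum, geom = gt)), gt)
  views <- render_views(sm)

  expect_length(views$views, 8)
  expect_equal(vapply(views$views, `[[`, numeric(1), "azimuth_deg"),
               seq(0, 315, by = 45))
  # no interpolation: every foreground pixel equals its owner node's
  # temperature, so averaging a node's pixels over views reproduces it
  for (v in views$views) {
    fg <- which(!is.na(v$image))
    expect_identical(v$image[fg], sm$nodes$temperature[v$owner[fg]])
  }
})

test_that("an isothermal surface renders isothermal foreground in every view", {
  fld <- solve_bioheat(assemble_system(coarse_phantom, inert_props,
                                       isothermal_ambient, geom = coarse_geom))
  sm <- extract_surface(coarse_phantom, fld, geom = coarse_geom)
  views <- render_views(sm)
  for (v in views$views) {
    expect_equal(v$image[!is.na(v$image)] - 37,
                 rep(0, sum(!is.na(v$image))), tolerance = 1e-6)
  }
})

test_that("every surface node of the convex dome faces at least one of the 8 views", {
  fld <- solve_field(coarse_phantom, coarse_geom)
  sm <- extract_surface(coarse_phantom, fld, geom = coarse_geom)
  vis <- thermoscreen:::node_visibility(sm)
  expect_true(all(rowSums(vis) >= 1))
})

test_that("rotating the tumor azimuth by 45 degrees shifts the warmest view by one", {
  base <- render_views(forward_model(NULL, coarse_phantom, geom = coarse_geom))
  base_mean <- vapply(base$views, function(v) mean(v$image, na.rm = TRUE), 0)
  warmest_view <- function(theta) {
    views <- render_views(forward_model(theta, coarse_phantom, geom = coarse_geom))
    warming <- vapply(views$views, function(v) mean(v$image, na.rm = TRUE), 0) -
      base_mean
    which.max(warming)
  }
  r_xy <- 0.0175
  place <- function(az_deg) {
    a <- az_deg * pi / 180
    tumor_params(c(r_xy * cos(a), r_xy * sin(a), 0.015), 0.014)
  }
  v <- vapply(c(0, 45, 90, 135), function(a) warmest_view(place(a)), 0L)
  expect_equal(diff(v) %% 8, rep(1, 3))
})

test_that("camera noise is reproducible, unbiased in scale, and zero-sigma is identity", {
  fld <- solve_field(medium_phantom, medium_geom)
  sm <- extract_surface(medium_phantom, fld, geom = medium_geom)
  expect_gte(nrow(sm$nodes), 3000)

  expect_identical(add_camera_noise(sm, noise_model(0, seed = 3))$nodes,
                   sm$nodes)
  n1 <- add_camera_noise(sm, noise_model(0.02, seed = 11))
  n2 <- add_camera_noise(sm, noise_model(0.02, seed = 11))
  n3 <- add_camera_noise(sm, noise_model(0.02, seed = 12))
  expect_identical(n1$nodes, n2$nodes)
  expect_false(identical(n1$nodes, n3$nodes))

  # pool independent draws to estimate the sd at >= 1e4 samples
  n4 <- add_camera_noise(sm, noise_model(0.02, seed = 13))
  dev <- c(n1$nodes$temperature, n3$nodes$temperature, n4$nodes$temperature) -
    rep(sm$nodes$temperature, 3)
  expect_gte(length(dev), 1e4)
  expect_gte(stats::sd(dev), 0.018)
  expect_lte(stats::sd(dev), 0.022)
})

test_that("noise on rendered views only touches foreground pixels", {
  fld <- solve_field(coarse_phantom, coarse_geom)
  sm <- extract_surface(coarse_phantom, fld, geom = coarse_geom)
  views <- render_views(sm)
  noisy <- add_camera_noise(views, noise_model(0.02, seed = 5))
  for (i in seq_along(views$views)) {
    expect_identical(is.na(noisy$views[[i]]$image), is.na(views$views[[i]]$image))
    fg <- !is.na(views$views[[i]]$image)
    expect_false(identical(noisy$views[[i]]$image[fg], views$views[[i]]$image[fg]))
  }
})

test_that("surface residuals behave as differences of co-registered maps", {
  fld <- solve_field(coarse_phantom, coarse_geom)
  sm <- extract_surface(coarse_phantom, fld, geom = coarse_geom)

  expect_equal(surface_residual(sm, sm)$rms, 0)

  shifted <- sm
  shifted$nodes$temperature <- sm$nodes$temperature + 0.1
  expect_equal(surface_residual(shifted, sm)$rms, 0.1, tolerance = 1e-12)

  # residual RMS is invariant under a common node permutation
  perm <- sample(nrow(sm$nodes))
  a <- sm
  b <- shifted
  a$nodes <- a$nodes[perm, ]
  b$nodes <- b$nodes[perm, ]
  expect_equal(surface_residual(b, a)$rms, 0.1, tolerance = 1e-12)

  other <- extract_surface(medium_phantom, solve_field(medium_phantom, medium_geom),
                           geom = medium_geom)
  expect_error(surface_residual(sm, other), "different node sets")
})

test_that("noisy observation of a clean surface has RMS residual near sigma", {
  fld <- solve_field(medium_phantom, medium_geom)
  sm <- extract_surface(medium_phantom, fld, geom = medium_geom)
  noisy <- add_camera_noise(sm, noise_model(0.02, seed = 21))
  rms <- surface_residual(sm, noisy)$rms
  expect_gte(rms, 0.018)
  expect_lte(rms, 0.022)
})
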