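# Face classification codes used by the discretization cache.
FACE_NONE <- 0L      # interior coupling to another unknown
FACE_AIR <- 1L       # skin face: convective + linearized radiative flux
FACE_CHEST <- 2L     # coupling to the fixed-temperature chest wall
FACE_OUTSIDE <- 3L   # grid boundary: insulated

FACE_DIRS <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                   c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))

#' Tumor volumetric heat generation
#'
#' The adopted empirical relation between tumor diameter and volumetric
#' metabolic heat release, `q_t(D) = C1 / (C2 * log(100 * D) + C3)` with `D`
#' in meters: smaller (faster-doubling) tumors release more heat per unit
#' volume, and the relation is strictly decreasing in `D` wherever the
#' denominator is positive. Diameters at or below the pole of the relation
#' (about 9 mm under the defaults) are rejected; forward solves extend the
#' source below that scale through the documented regularization in
#' [tumor_source_density()].
#'
#' @param diameter tumor diameter (m); vectorized.
#' @param c1,c2,c3 relation coefficients (defaults `3.27e6`, `468.5`, `50`).
#' @return volumetric heat rate (W m^-3).
#' @examples
#' tumor_heat_generation(0.01)   # 3.27e6 / 50 = 65400
#' @export
tumor_heat_generation <- function(diameter, c1 = 3.27e6, c2 = 468.5, c3 = 50) {
  if (any(!is.finite(diameter)) || any(diameter <= 0)) {
    stop("diameter must be positive and finite", call. = FALSE)
  }
  denom <- c2 * log(100 * diameter) + c3
  if (any(denom <= 0)) {
    stop("diameter below the domain of the heat-generation relation ",
         "(denominator <= 0)", call. = FALSE)
  }
  c1 / denom
}

#' Regularized tumor source density used in forward solves
#'
#' Evaluates [tumor_heat_generation()] at `max(diameter, floor_diameter)`.
#' The raw relation diverges at a pole near 9 mm; clamping the evaluation
#' diameter at the canonical 1 cm reference (where `q_t` = 65,400 W m^-3)
#' keeps the source finite and monotone for arbitrarily small spheres, so
#' the inverse optimizer can traverse small diameters and sub-centimeter
#' tumors behave as centimeter-equivalent sources. Clamping closer to the
#' pole would make a just-sub-floor tumor emit more total power than a
#' larger one — an artifact of the near-pole steepness.
#'
#' @param diameter tumor diameter (m); vectorized.
#' @param floor_diameter evaluation floor (m), default 1 cm.
#' @inheritParams tumor_heat_generation
#' @return volumetric heat rate (W m^-3).
#' @export
tumor_source_density <- function(diameter, floor_diameter = 0.01,
                                 c1 = 3.27e6, c2 = 468.5, c3 = 50) {
  tumor_heat_generation(pmax(diameter, floor_diameter), c1 = c1, c2 = c2, c3 = c3)
}

#' Precompute the finite-volume connectivity of a phantom
#'
#' Builds the 7-point stencil bookkeeping for all breast-tissue voxels:
#' neighbour indices, face classification (interior / skin / chest-wall /
#' insulated grid boundary), per-face air-face geometry for surface
#' extraction, and voxel-center coordinates. The connectivity depends only
#' on the phantom geometry — not on which breast voxels carry a tumor label —
#' so it can be computed once per phantom and reused across every forward
#' solve of an inverse fit.
#'
#' @param phantom a `breast_phantom`.
#' @return a `phantom_discretization` object.
#' @export
discretize_phantom <- function(phantom) {
  stop_if_not_class(phantom, "breast_phantom")
  d <- dim(phantom$label)
  free <- which(phantom$label %in% BREAST_LABELS)
  n <- length(free)
  if (n == 0) stop("phantom contains no breast voxels", call. = FALSE)
  row_of <- array(0L, dim = d)
  row_of[free] <- seq_len(n)
  pos <- arrayInd(free, .dim = d)

  nbr <- matrix(0L, n, 6)
  ftype <- matrix(FACE_NONE, n, 6)
  for (f in 1:6) {
    np <- sweep(pos, 2, FACE_DIRS[f, ], "+")
    inside <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 & np[, 2] <= d[2] &
      np[, 3] >= 1 & np[, 3] <= d[3]
    ftype[!inside, f] <- FACE_OUTSIDE
    lin <- np[inside, 1] + d[1] * (np[inside, 2] - 1) + d[1] * d[2] * (np[inside, 3] - 1)
    lab <- phantom$label[lin]
    r <- row_of[lin]
    nbr[inside, f] <- r
    ft <- integer(length(lab))
    ft[lab == LABEL_AIR] <- FACE_AIR
    ft[lab == LABEL_CHEST] <- FACE_CHEST
    ftype[inside, f] <- ft
  }

  af <- which(ftype == FACE_AIR, arr.ind = TRUE)
  structure(list(
    n = n,
    free = free,
    dim = d,
    h = phantom$voxel_size,
    centers = voxel_centers(phantom, free),
    nbr = nbr,
    ftype = ftype,
    n_air = rowSums(ftype == FACE_AIR),
    n_chest = rowSums(ftype == FACE_CHEST),
    air_faces = af,                        # (cell row, face direction)
    geometry_hash = object_hash(list(d, free, phantom$voxel_size, phantom$origin))
  ), class = "phantom_discretization")
}

# Secant linearization coefficient of the radiative flux about T_ref:
# eps*sigma*(T^4 - Tinf^4) == h_r * (T - Tinf) exactly at T = T_ref.
radiative_coefficient <- function(ambient, t_ref = ambient$T_lin_ref) {
  tr <- t_ref + 273.15
  ti <- ambient$T_inf + 273.15
  ambient$epsilon * ambient$sigma_SB * (tr^2 + ti^2) * (tr + ti)
}

#' Assemble the discrete steady-state bioheat system
#'
#' Cell-centered finite-volume discretization of the steady Pennes equation
#' `div(k grad T) + omega_b rho_b c_b (T_a - T) + q_m + q_t = 0` on the
#' breast voxels of a phantom. Interior faces use harmonic-mean conductivity;
#' skin faces carry the series resistance of half-cell conduction and the
#' combined convective + linearized radiative film
#' `h + h_r` (secant linearization of `eps * sigma * (T^4 - Tinf^4)` about
#' the skin reference temperature); chest-wall voxels act as an isothermal
#' boundary at `T_core` imposed at the shared face; grid-boundary faces are
#' insulated. The tumor source `q_t` from [tumor_source_density()] is applied
#' uniformly over tumor-labeled voxels. The resulting operator is symmetric
#' and strictly diagonally dominant.
#'
#' @param phantom a `breast_phantom` (with the tumor already embedded when
#'   `tumor` is given).
#' @param props a [default_tissue_properties()] object.
#' @param ambient a [default_ambient_conditions()] object.
#' @param tumor optional [tumor_params()]; sets the tumor source magnitude
#'   for tumor-labeled voxels. Required if the phantom contains tumor voxels.
#' @param extra_source optional numeric vector (W m^-3), one entry per breast
#'   voxel in discretization order, added to the volumetric source.
#' @param geom optional precomputed [discretize_phantom()] result.
#' @param source_floor_diameter regularization floor passed to
#'   [tumor_source_density()].
#' @return a `bioheat_system`.
#' @export
assemble_system <- function(phantom, props = default_tissue_properties(),
                            ambient = default_ambient_conditions(),
                            tumor = NULL, extra_source = NULL, geom = NULL,
                            source_floor_diameter = 0.01) {
  stop_if_not_class(phantom, "breast_phantom")
  if (is.null(geom)) geom <- discretize_phantom(phantom)
  n <- geom$n
  h <- geom$h
  lab <- phantom$label[geom$free]

  if (any(lab == LABEL_TUMOR) && is.null(tumor)) {
    stop("phantom contains tumor voxels but no `tumor` parameters were given",
         call. = FALSE)
  }
  q_t <- if (is.null(tumor)) 0 else
    tumor_source_density(tumor$diameter, floor_diameter = source_floor_diameter)

  kmap <- c(props$fat$k, props$gland$k, props$tumor$k)
  wmap <- c(props$fat$omega_b, props$gland$omega_b, props$tumor$omega_b)
  qmap <- c(props$fat$q_m, props$gland$q_m, props$tumor$q_m)
  kcell <- kmap[lab]
  wrc <- wmap[lab] * props$rho_b * props$c_b        # W m^-3 K^-1
  qvol <- qmap[lab]
  qvol[lab == LABEL_TUMOR] <- qvol[lab == LABEL_TUMOR] + q_t
  if (!is.null(extra_source)) {
    if (length(extra_source) != n) {
      stop("extra_source must have one entry per breast voxel", call. = FALSE)
    }
    qvol <- qvol + extra_source
  }

  # Interior face conductances (W K^-1): A * k_harm / h = h * k_harm.
  gcond <- matrix(0, n, 6)
  for (f in 1:6) {
    j <- geom$nbr[, f]
    has <- geom$ftype[, f] == FACE_NONE & j > 0L
    kj <- kcell[j[has]]
    ki <- kcell[has]
    gcond[has, f] <- h * 2 * ki * kj / (ki + kj)
  }

  # Skin faces: U = [h/(2k) + 1/(h_conv + h_rad)]^-1, conductance A*U.
  h_film <- ambient$h + radiative_coefficient(ambient)
  u_skin <- if (h_film > 0) 1 / (h / (2 * kcell) + 1 / h_film) else rep(0, n)
  skin_g <- geom$n_air * h^2 * u_skin

  # Chest-wall faces: isothermal boundary at the shared face (half-cell
  # conduction), equivalent to harmonic coupling with an infinitely
  # conducting pinned chest voxel.
  chest_g <- geom$n_chest * 2 * kcell * h

  perf <- wrc * h^3
  src <- qvol * h^3
  gsum <- rowSums(gcond)

  structure(list(
    n = n,
    h = h,
    nbr = geom$nbr,
    gcond = gcond,
    gsum = gsum,
    skin_g = skin_g,
    chest_g = chest_g,
    perf = perf,
    src = src,
    diag = gsum + skin_g + chest_g + perf,
    b = chest_g * ambient$T_core + skin_g * ambient$T_inf +
      perf * props$T_a + src,
    kcell = kcell,
    geom = geom,
    phantom = phantom,
    props = props,
    ambient = ambient,
    q_t = q_t
  ), class = "bioheat_system")
}

#' Export the assembled operator as a sparse matrix
#'
#' Returns the symmetric sparse matrix `A` and right-hand side `b` of the
#' assembled system, mainly for verification (diagonal dominance, linearity,
#' independent solves).
#'
#' @param system a `bioheat_system`.
#' @return list with `A` (a `dsCMatrix`) and `b`.
#' @export
system_matrix <- function(system) {
  stop_if_not_class(system, "bioheat_system")
  n <- system$n
  has <- which(system$nbr > 0L & system$gcond != 0, arr.ind = TRUE)
  i <- has[, 1]
  j <- system$nbr[has]
  A <- Matrix::sparseMatrix(i = c(i, seq_len(n)), j = c(j, seq_len(n)),
                            x = c(-system$gcond[has], system$diag),
                            dims = c(n, n))
  list(A = Matrix::forceSymmetric(A), b = system$b)
}

#' Solve the assembled bioheat system
#'
#' Jacobi-preconditioned conjugate-gradient solve of the symmetric
#' positive-definite finite-volume system to a relative residual tolerance
#' (default 1e-9). Optionally re-linearizes the radiative film coefficient
#' about the solved mean skin temperature in a fixed-point loop.
#'
#' @param system a `bioheat_system`.
#' @param tol relative residual tolerance.
#' @param maxit conjugate-gradient iteration cap.
#' @param x0 optional warm-start temperature vector (one entry per breast
#'   voxel); defaults to a uniform field at `T_core`.
#' @param relinearize number of radiative re-linearization passes (0 = the
#'   default one-shot linearization about the skin reference temperature).
#' @return a `temperature_field`: the solved grid (`$T_grid`, degC; `NA` in
#'   air, `T_core` in the chest wall), the free-voxel solution `$values`, and
#'   solver diagnostics.
#' @export
solve_bioheat <- function(system, tol = 1e-9, maxit = 20000, x0 = NULL,
                          relinearize = 0) {
  stop_if_not_class(system, "bioheat_system")
  if (is.null(x0)) x0 <- rep(system$ambient$T_core, system$n)
  sol <- pcg_stencil(system$nbr, system$gcond, system$diag, system$b,
                     x0, tol, as.integer(maxit))
  if (relinearize > 0) {
    amb <- system$ambient
    for (pass in seq_len(relinearize)) {
      skin_cells <- system$geom$n_air > 0
      t_ref <- mean(sol$x[skin_cells])
      h_film <- amb$h + radiative_coefficient(amb, t_ref = t_ref)
      u_skin <- if (h_film > 0) 1 / (system$h / (2 * system$kcell) + 1 / h_film) else 0
      system$skin_g <- system$geom$n_air * system$h^2 * u_skin
      system$diag <- system$gsum + system$skin_g + system$chest_g + system$perf
      system$b <- system$chest_g * amb$T_core + system$skin_g * amb$T_inf +
        system$perf * system$props$T_a + system$src
      sol <- pcg_stencil(system$nbr, system$gcond, system$diag, system$b,
                         sol$x, tol, as.integer(maxit))
    }
  }
  if (!sol$converged) {
    warning(sprintf("bioheat solver did not reach tol = %g (achieved %g in %d iterations)",
                    tol, sol$relres, sol$iterations), call. = FALSE)
  }
  lab <- system$phantom$label
  T_grid <- array(NA_real_, dim = dim(lab))
  T_grid[lab == LABEL_CHEST] <- system$ambient$T_core
  T_grid[system$geom$free] <- sol$x
  structure(list(
    T_grid = T_grid,
    values = sol$x,
    free = system$geom$free,
    phantom_hash = system$geom$geometry_hash,
    voxel_size = system$h,
    solver = list(iterations = sol$iterations, relres = sol$relres,
                  converged = sol$converged)
  ), class = "temperature_field")
}

#' Audit the discrete energy balance of a solved system
#'
#' At the solution of a conservative finite-volume scheme, the total heat
#' leaving through the boundaries (skin film + chest-wall faces) equals the
#' total volumetric source (metabolic + tumor + net perfusion exchange) up
#' to the linear-solver residual.
#'
#' @param system the `bioheat_system` that was solved.
#' @param field the corresponding `temperature_field`.
#' @return list with `source_total` (W), `boundary_flux` (W), and
#'   `rel_imbalance`.
#' @export
energy_balance <- function(system, field) {
  stop_if_not_class(system, "bioheat_system")
  stop_if_not_class(field, "temperature_field")
  tt <- field$values
  amb <- system$ambient
  flux_out <- sum(system$skin_g * (tt - amb$T_inf)) +
    sum(system$chest_g * (tt - amb$T_core))
  source_total <- sum(system$src) + sum(system$perf * (system$props$T_a - tt))
  denom <- max(abs(source_total), abs(flux_out), .Machine$double.eps)
  list(source_total = source_total, boundary_flux = flux_out,
       rel_imbalance = abs(source_total - flux_out) / denom)
}

#' Closed-form steady temperature profile of a perfused slab
#'
#' Analytic solution of the 1-D steady bioheat equation on `[0, L]` with the
#' chest side fixed at `T_core` and a purely convective skin face (radiation
#' off): `k T'' + omega_b rho_b c_b (T_a - T) + q_m + q = 0`. For positive
#' perfusion the solution is `T(x) = T_p + A exp(m x) + B exp(-m x)` with
#' `T_p = T_a + (q_m + q) / (omega_b rho_b c_b)` and
#' `m = sqrt(omega_b rho_b c_b / k)`; for zero perfusion it degenerates to
#' the quadratic pure-conduction profile. Serves as the independent oracle
#' for the finite-volume solver on [build_slab_phantom()] geometries.
#'
#' @param thickness slab thickness L (m).
#' @param props a [default_tissue_properties()] object.
#' @param ambient a [default_ambient_conditions()] object; only `h`, `T_inf`,
#'   `T_core` are used.
#' @param q additional uniform volumetric source (W m^-3).
#' @param tissue which tissue class fills the slab.
#' @return a `slab_profile`: `$profile(x)` evaluates T(x) in degC,
#'   `$derivative(x)` its analytic derivative, `$residual(x)` the ODE
#'   residual of the returned profile (W m^-3), and `$bc_residual()` the two
#'   boundary-condition residuals.
#' @export
slab_oracle <- function(thickness, props = default_tissue_properties(),
                        ambient = default_ambient_conditions(), q = 0,
                        tissue = "fat") {
  p <- props[[tissue]]
  if (is.null(p)) stop("unknown tissue class: ", tissue, call. = FALSE)
  k <- p$k
  wrc <- p$omega_b * props$rho_b * props$c_b
  qt <- p$q_m + q
  L <- thickness
  hc <- ambient$h
  t_core <- ambient$T_core
  t_inf <- ambient$T_inf
  t_a <- props$T_a

  if (wrc > 0) {
    m <- sqrt(wrc / k)
    tp <- t_a + qt / wrc
    ep <- exp(m * L)
    en <- exp(-m * L)
    # rows: T(0) = T_core ; -k T'(L) = hc (T(L) - T_inf)
    M <- rbind(c(1, 1),
               c(-k * m * ep - hc * ep, k * m * en - hc * en))
    rhs <- c(t_core - tp, hc * (tp - t_inf))
    ab <- solve(M, rhs)
    profile <- function(x) tp + ab[1] * exp(m * x) + ab[2] * exp(-m * x)
    d1 <- function(x) m * (ab[1] * exp(m * x) - ab[2] * exp(-m * x))
    d2 <- function(x) m^2 * (profile(x) - tp)
  } else {
    # pure conduction: T = -qt x^2 / (2k) + a x + T_core
    a <- (hc * (t_inf - t_core) + hc * qt * L^2 / (2 * k) + qt * L) / (k + hc * L)
    profile <- function(x) -qt * x^2 / (2 * k) + a * x + t_core
    d1 <- function(x) -qt * x / k + a
    d2 <- function(x) rep(-qt / k, length(x))
  }
  residual <- function(x) k * d2(x) + wrc * (t_a - profile(x)) + qt
  # boundary-condition residuals: fixed base and convective skin face
  bc_residual <- function() {
    c(base = profile(0) - t_core,
      skin = -k * d1(L) - hc * (profile(L) - t_inf))
  }
  structure(list(profile = profile, derivative = d1, residual = residual,
                 bc_residual = bc_residual, thickness = L,
                 k = k, wrc = wrc, q_total = qt),
            class = "slab_profile")
}
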