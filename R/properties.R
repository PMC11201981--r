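#' Default tissue thermal properties
#'
#' Returns the package's default per-class thermal property table for the
#' Pennes bioheat model: thermal conductivity `k` (W m^-1 K^-1), blood
#' perfusion rate `omega_b` (s^-1), and metabolic volumetric heat `q_m`
#' (W m^-3) for fat, gland, tumor, and chest-wall tissue, together with the
#' shared blood properties `rho_b` (kg m^-3), `c_b` (J kg^-1 K^-1) and the
#' arterial temperature `T_a` (degC).
#'
#' Defaults are drawn from the breast bioheat modeling literature: fat is a
#' poor conductor with sparse perfusion, fibroglandular tissue conducts and
#' perfuses substantially more, and the tumor class shares gland-level
#' conduction and perfusion — its thermal distinction is the volumetric heat
#' source supplied separately by [tumor_heat_generation()]. Chest-wall voxels
#' are held at the core temperature, so only their conductivity (used in the
#' coupling conductance) matters.
#'
#' @param overrides optional named list merged over the defaults, e.g.
#'   `list(fat = list(k = 0.25))` changes only fat conductivity.
#' @return a `tissue_properties` object (nested list).
#' @examples
#' props <- default_tissue_properties()
#' props$gland$k
#' default_tissue_properties(list(fat = list(k = 0.25)))$fat$k
#' @export
default_tissue_properties <- function(overrides = NULL) {
  props <- list(
    fat   = list(k = 0.21, omega_b = 0.00008, q_m = 400),
    gland = list(k = 0.48, omega_b = 0.00054, q_m = 450),
    tumor = list(k = 0.48, omega_b = 0.00054, q_m = 450),
    chest = list(k = 0.48, omega_b = 0, q_m = 0),
    rho_b = 1060,
    c_b = 3770,
    T_a = 37
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (is.list(overrides[[nm]]) && is.list(props[[nm]])) {
        props[[nm]] <- modifyList(props[[nm]], overrides[[nm]])
      } else {
        props[[nm]] <- overrides[[nm]]
      }
    }
  }
  validate_tissue_properties(structure(props, class = "tissue_properties"))
}

validate_tissue_properties <- function(props) {
  for (cls in c("fat", "gland", "tumor", "chest")) {
    p <- props[[cls]]
    if (is.null(p)) stop("missing tissue class: ", cls, call. = FALSE)
    if (!is.numeric(p$k) || p$k <= 0) stop("k must be > 0 for ", cls, call. = FALSE)
    if (p$omega_b < 0) stop("omega_b must be >= 0 for ", cls, call. = FALSE)
    if (p$q_m < 0) stop("q_m must be >= 0 for ", cls, call. = FALSE)
  }
  if (props$rho_b <= 0 || props$c_b <= 0) {
    stop("blood density and specific heat must be positive", call. = FALSE)
  }
  if (props$T_a <= 30 || props$T_a >= 45) {
    stop("arterial temperature T_a must lie in (30, 45) degC", call. = FALSE)
  }
  props
}

#' Default ambient and boundary conditions
#'
#' Ambient air temperature `T_inf` (degC), convective film coefficient `h`
#' (W m^-2 K^-1), skin emissivity `epsilon`, the Stefan-Boltzmann constant
#' `sigma_SB` (W m^-2 K^-4), the chest-wall/core temperature `T_core` (degC),
#' and the skin reference temperature `T_lin_ref` about which the radiative
#' boundary term is linearized. Defaults describe a draft-free imaging room
#' after acclimation: 21 degC air, natural convection at 5 W m^-2 K^-1,
#' emissivity 0.98, core at 37 degC.
#'
#' @param overrides optional named list merged over the defaults.
#' @return an `ambient_conditions` object.
#' @examples
#' default_ambient_conditions(list(T_inf = 23))$T_inf
#' @export
default_ambient_conditions <- function(overrides = NULL) {
  amb <- list(
    T_inf = 21,
    h = 5,
    epsilon = 0.98,
    sigma_SB = 5.670374419e-8,
    T_core = 37,
    T_lin_ref = 33
  )
  if (!is.null(overrides)) amb <- modifyList(amb, overrides)
  if (amb$epsilon < 0 || amb$epsilon > 1) stop("epsilon must lie in [0, 1]", call. = FALSE)
  if (amb$h < 0) stop("convective coefficient h must be >= 0", call. = FALSE)
  if (amb$T_inf > amb$T_core) stop("T_inf must not exceed T_core", call. = FALSE)
  structure(amb, class = "ambient_conditions")
}

#' Tumor parameter vector
#'
#' The inverse problem's parameter vector: tumor center `(x_c, y_c, z_c)` in
#' world coordinates (meters, origin at the chest-wall center, z from chest
#' wall to nipple) and diameter `D` (meters).
#'
#' @param center numeric length-3 center (m).
#' @param diameter sphere diameter (m), must be positive.
#' @return a `tumor_params` object.
#' @examples
#' tumor_params(c(0, 0.01, 0.03), 0.015)
#' @export
tumor_params <- function(center, diameter) {
  center <- as.numeric(center)
  if (length(center) != 3 || anyNA(center)) {
    stop("center must be a numeric length-3 vector", call. = FALSE)
  }
  if (!is.numeric(diameter) || length(diameter) != 1 || diameter <= 0) {
    stop("diameter must be a single positive number", call. = FALSE)
  }
  structure(list(center = center, diameter = as.numeric(diameter)),
            class = "tumor_params")
}

#' @export
print.tumor_params <- function(x, ...) {
  cat(sprintf("<tumor_params> center = (%.4f, %.4f, %.4f) m, D = %.1f mm\n",
              x$center[1], x$center[2], x$center[3], 1000 * x$diameter))
  invisible(x)
}

#' @export
print.tissue_properties <- function(x, ...) {
  cat("<tissue_properties>\n")
  for (cls in c("fat", "gland", "tumor", "chest")) {
    p <- x[[cls]]
    cat(sprintf("  %-6s k = %.3f W/m/K, omega_b = %.2e 1/s, q_m = %g W/m^3\n",
                cls, p$k, p$omega_b, p$q_m))
  }
  cat(sprintf("  blood rho_b = %g kg/m^3, c_b = %g J/kg/K, T_a = %g degC\n",
              x$rho_b, x$c_b, x$T_a))
  invisible(x)
}
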