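# Tissue class codes shared by all modules.
LABEL_AIR <- 0L
LABEL_FAT <- 1L
LABEL_GLAND <- 2L
LABEL_TUMOR <- 3L
LABEL_CHEST <- 4L
BREAST_LABELS <- c(LABEL_FAT, LABEL_GLAND, LABEL_TUMOR)

new_breast_phantom <- function(label, voxel_size, origin, breast_radius,
                               gland_fraction = NA_real_, tumor = NULL) {
  structure(list(
    label = label,
    voxel_size = voxel_size,
    origin = origin,
    breast_radius = breast_radius,
    gland_fraction = gland_fraction,
    tumor = tumor
  ), class = "breast_phantom")
}

# Voxel-center world coordinates along each grid axis.
voxel_axes <- function(phantom) {
  h <- phantom$voxel_size
  d <- dim(phantom$label)
  list(
    x = phantom$origin[1] + (seq_len(d[1]) - 0.5) * h,
    y = phantom$origin[2] + (seq_len(d[2]) - 0.5) * h,
    z = phantom$origin[3] + (seq_len(d[3]) - 0.5) * h
  )
}

# n x 3 matrix of voxel-center coordinates for the given linear indices.
voxel_centers <- function(phantom, linear_idx) {
  ax <- voxel_axes(phantom)
  ijk <- arrayInd(linear_idx, dim(phantom$label))
  cbind(ax$x[ijk[, 1]], ax$y[ijk[, 2]], ax$z[ijk[, 3]])
}

# World coordinate -> linear voxel index (NA when outside the grid).
world_to_voxel <- function(phantom, p) {
  d <- dim(phantom$label)
  ijk <- floor((p - phantom$origin) / phantom$voxel_size) + 1
  if (any(ijk < 1) || any(ijk > d) || anyNA(ijk)) return(NA_integer_)
  as.integer(ijk[1] + d[1] * (ijk[2] - 1) + d[1] * d[2] * (ijk[3] - 1))
}

#' Build a hemispherical breast phantom on a chest wall
#'
#' Generates a voxelized stand-in for a patient-specific pendant breast:
#' a hemisphere of breast tissue (radius `breast_radius`) resting on a flat
#' chest-wall plane, with an inner concentric hemispherical region of
#' relative radius `gland_fraction` labeled fibroglandular tissue and the
#' remainder labeled fat. World coordinates are in meters with the origin at
#' the chest-wall center and the z axis pointing from the chest wall toward
#' the nipple; voxel centers define tissue membership. The grid is sized so
#' the hemisphere never touches a lateral grid face, and the symmetry axis
#' passes through a voxel corner so the phantom is exactly mirror-symmetric.
#'
#' @param breast_radius hemisphere radius (m); must be at least 5 voxels.
#' @param voxel_size voxel edge length (m). The default 2.5 mm resolves the
#'   clinical size range at desk scale; 1.25 mm is the documented fine preset.
#' @param gland_fraction relative radius in `[0, 1]` of the glandular core
#'   (0 gives an all-fat breast).
#' @param max_voxels guard against accidental huge grids.
#' @return a `breast_phantom` with integer labels 0 = air, 1 = fat,
#'   2 = gland, 3 = tumor, 4 = chest wall.
#' @examples
#' ph <- build_hemisphere_phantom(0.05, 0.005, gland_fraction = 0.5)
#' table(ph$label)
#' @export
build_hemisphere_phantom <- function(breast_radius, voxel_size = 0.0025,
                                     gland_fraction = 0.5,
                                     max_voxels = 4e6) {
  if (!is.numeric(breast_radius) || breast_radius <= 0 ||
      !is.numeric(voxel_size) || voxel_size <= 0) {
    stop("breast_radius and voxel_size must be positive", call. = FALSE)
  }
  if (breast_radius < 5 * voxel_size) {
    stop("breast_radius must be at least 5 voxels", call. = FALSE)
  }
  if (gland_fraction < 0 || gland_fraction > 1) {
    stop("gland_fraction must lie in [0, 1]", call. = FALSE)
  }
  h <- voxel_size
  nr <- ceiling(breast_radius / h)
  nx <- 2L * (nr + 2L)          # 2-voxel air margin, axis through a corner
  nz <- nr + 4L                 # 1 chest layer + dome + >= 2 air layers
  if (as.double(nx) * nx * nz > max_voxels) {
    stop("grid exceeds the configured voxel budget", call. = FALSE)
  }
  origin <- c(-(nx / 2) * h, -(nx / 2) * h, -h)
  xc <- origin[1] + (seq_len(nx) - 0.5) * h
  zc <- origin[3] + (seq_len(nz) - 0.5) * h

  lab <- array(LABEL_AIR, dim = c(nx, nx, nz))
  r2xy <- outer(xc^2, xc^2, "+")
  for (k in seq_len(nz)) {
    if (zc[k] < 0) {
      lab[, , k][r2xy <= breast_radius^2] <- LABEL_CHEST
    } else {
      r2 <- r2xy + zc[k]^2
      sl <- lab[, , k]
      sl[r2 <= breast_radius^2] <- LABEL_FAT
      if (gland_fraction > 0) {
        sl[r2 <= (gland_fraction * breast_radius)^2 & sl == LABEL_FAT] <- LABEL_GLAND
      }
      lab[, , k] <- sl
    }
  }
  new_breast_phantom(lab, h, origin, breast_radius, gland_fraction)
}

#' Build a one-dimensional slab phantom
#'
#' A single-column grid — one chest-wall voxel, `thickness/voxel_size` breast
#' voxels, and air above — whose lateral faces fall outside the grid and are
#' therefore insulated. The finite-volume solve on this geometry reduces
#' exactly to the 1-D bioheat problem with a fixed-temperature base and a
#' convective/radiative skin face, which [slab_oracle()] solves in closed
#' form; the pair is used to verify the solver's discretization order.
#'
#' @param thickness slab thickness (m); must be a multiple of `voxel_size`.
#' @param voxel_size voxel edge length (m).
#' @param tissue label for the slab interior: `"fat"` or `"gland"`.
#' @return a `breast_phantom` of grid dimension 1 x 1 x (n + 3).
#' @examples
#' build_slab_phantom(0.05, 0.005)
#' @export
build_slab_phantom <- function(thickness, voxel_size = 0.0025, tissue = "fat") {
  n <- round(thickness / voxel_size)
  if (n < 2 || abs(n * voxel_size - thickness) > 1e-9) {
    stop("thickness must be a multiple (>= 2) of voxel_size", call. = FALSE)
  }
  code <- switch(tissue, fat = LABEL_FAT, gland = LABEL_GLAND,
                 stop("tissue must be 'fat' or 'gland'", call. = FALSE))
  lab <- array(LABEL_AIR, dim = c(1L, 1L, n + 3L))
  lab[1, 1, 1] <- LABEL_CHEST
  lab[1, 1, 2:(n + 1)] <- code
  new_breast_phantom(lab, voxel_size, c(-voxel_size / 2, -voxel_size / 2, -voxel_size),
                     breast_radius = NA_real_)
}

#' Embed a spherical tumor into a phantom
#'
#' Relabels as tumor every breast-tissue voxel whose center lies within the
#' sphere described by `tumor`. The input phantom is not modified. Embedding
#' the same tumor twice is idempotent. Spheres that capture no breast voxel
#' (fully outside the breast, or smaller than the voxel sampling can resolve)
#' are rejected — the "tumor outside breast" signal consumed by the
#' presence/absence decision rule.
#'
#' @param phantom a `breast_phantom`.
#' @param tumor a [tumor_params()] object.
#' @return a new `breast_phantom` with tumor voxels labeled and the tumor
#'   parameters recorded in `$tumor`.
#' @examples
#' ph <- build_hemisphere_phantom(0.05, 0.005)
#' pht <- embed_tumor(ph, tumor_params(c(0, 0, 0.025), 0.015))
#' sum(pht$label == 3)
#' @export
embed_tumor <- function(phantom, tumor) {
  stop_if_not_class(phantom, "breast_phantom")
  stop_if_not_class(tumor, "tumor_params")
  idx <- tumor_voxel_indices(phantom, tumor)
  if (length(idx) == 0) {
    stop("tumor sphere captures no breast voxel (outside breast or sub-voxel)",
         call. = FALSE)
  }
  out <- phantom
  out$label[idx] <- LABEL_TUMOR
  out$tumor <- tumor
  out
}

# Linear indices of breast voxels whose centers fall inside the tumor sphere.
tumor_voxel_indices <- function(phantom, tumor) {
  cand <- which(phantom$label %in% BREAST_LABELS)
  if (length(cand) == 0) return(integer(0))
  p <- voxel_centers(phantom, cand)
  d2 <- (p[, 1] - tumor$center[1])^2 + (p[, 2] - tumor$center[2])^2 +
    (p[, 3] - tumor$center[3])^2
  cand[d2 <= (tumor$diameter / 2)^2]
}

#' Mirror a phantom across the mid-sagittal plane
#'
#' Reflects the label grid across the x = 0 plane. Because the symmetry axis
#' passes through a voxel corner, voxel centers map exactly onto voxel
#' centers and the mirrored grid is an exact relabeling.
#'
#' @param phantom a `breast_phantom`.
#' @return the mirrored `breast_phantom`.
#' @export
mirror_phantom <- function(phantom) {
  stop_if_not_class(phantom, "breast_phantom")
  out <- phantom
  out$label <- phantom$label[rev(seq_len(dim(phantom$label)[1])), , , drop = FALSE]
  if (!is.null(phantom$tumor)) {
    tc <- phantom$tumor$center
    out$tumor <- tumor_params(c(-tc[1], tc[2], tc[3]), phantom$tumor$diameter)
  }
  out
}

# Centroid of breast-labeled voxel centers.
breast_centroid <- function(phantom) {
  idx <- which(phantom$label %in% BREAST_LABELS)
  if (length(idx) == 0) stop("phantom contains no breast voxels", call. = FALSE)
  colMeans(voxel_centers(phantom, idx))
}

#' @export
print.breast_phantom <- function(x, ...) {
  d <- dim(x$label)
  cat(sprintf("<breast_phantom> %d x %d x %d voxels @ %.2f mm\n",
              d[1], d[2], d[3], 1000 * x$voxel_size))
  cnt <- table(factor(x$label, levels = 0:4,
                      labels = c("air", "fat", "gland", "tumor", "chest")))
  cat("  ", paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  if (!is.null(x$tumor)) {
    cat(sprintf("  tumor: D = %.1f mm at (%.1f, %.1f, %.1f) mm\n",
                1000 * x$tumor$diameter, 1000 * x$tumor$center[1],
                1000 * x$tumor$center[2], 1000 * x$tumor$center[3]))
  }
  invisible(x)
}
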