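#' Voxelized density volume
#'
#' A 3D density map on a regular grid. Coordinates are world mm with the z
#' axis pointing toward the detector bottom (depth positive downward) and the
#' origin at the reference measurement plane's center. `origin_mm` is the
#' center of the first voxel; named ROIs are stored as sparse fractional
#' masks (voxel index, overlap fraction, baseline density) so an override
#' changes only masked voxels and is idempotent.
#'
#' @param origin_mm,spacing_mm Length-3 numeric vectors, mm.
#' @param density 3D array of densities, g/cm^3 (all finite, >= 0).
#' @param roi_masks Named list of ROI masks (see [set_roi_density()]).
#' @param detector_surface_z_mm World z of the detector surface.
#' @return Object of class `density_volume`.
#' @export
density_volume <- function(origin_mm, spacing_mm, density,
                           roi_masks = list(),
                           detector_surface_z_mm = NA_real_) {
  stopifnot(length(origin_mm) == 3, length(spacing_mm) == 3,
            all(spacing_mm > 0), length(dim(density)) == 3)
  if (any(!is.finite(density)) || any(density < 0))
    stop("densities must be finite and >= 0")
  structure(list(origin_mm = as.numeric(origin_mm),
                 spacing_mm = as.numeric(spacing_mm),
                 dim = dim(density), density = density,
                 roi_masks = roi_masks,
                 detector_surface_z_mm = detector_surface_z_mm),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  cat(sprintf(
    "<density_volume> %s voxels, spacing %s mm, origin (%s) mm, ROIs: %s\n",
    paste(x$dim, collapse = " x "),
    paste(signif(x$spacing_mm, 3), collapse = " x "),
    paste(signif(x$origin_mm, 4), collapse = ", "),
    if (length(x$roi_masks)) paste(names(x$roi_masks), collapse = ", ")
    else "none"))
  invisible(x)
}

#' Voxel center coordinates along one axis
#' @param vol A [density_volume] (or a dose grid sharing its fields).
#' @param axis 1 = x, 2 = y, 3 = z.
#' @return Numeric vector of voxel-center positions, mm.
#' @export
vox_centers <- function(vol, axis) {
  vol$origin_mm[axis] + (seq_len(vol$dim[axis]) - 1) * vol$spacing_mm[axis]
}

# z-overlap fraction of each voxel layer (centers zc, spacing dz) with [z0, z1]
.z_overlap_frac <- function(zc, dz, z0, z1) {
  lo <- zc - dz / 2
  hi <- zc + dz / 2
  pmax(0, pmin(hi, z1) - pmax(lo, z0)) / dz
}

#' Build the slab phantom with an embedded detector
#'
#' Water-equivalent build-up and backscatter slabs sandwich the detector
#' stack; the stack is positioned so that the reference measurement plane
#' (the chamber layer's effective point of measurement) coincides with the
#' isocenter plane z = 0, i.e. the source-to-plane distance equals the beam
#' SAD. Voxel densities along z are exact slab overlaps (partial-volume
#' weighting), so the 0.75 mm anode layer keeps its exact areal density on
#' any grid spacing. The anode ROI (lateral extent = the active area) is
#' registered as a fractional mask named `"anode"`.
#'
#' @param buildup_cm,backscatter_cm Water-equivalent slab thicknesses above
#'   and below the detector, cm.
#' @param stack A [detector_stack()].
#' @param spacing_mm Isotropic voxel spacing, mm (must resolve the anode:
#'   refused above 4x the anode thickness).
#' @param lateral_mm Physical lateral extent, a scalar or `c(x, y)`, mm;
#'   snapped to the nearest whole number of voxels.
#' @param layout A [chamber_layout()] (supplies the measurement-plane depth
#'   and active area).
#' @return A [density_volume] with the `"anode"` ROI registered.
#' @export
slab_phantom <- function(buildup_cm = 7, backscatter_cm = 8,
                         stack = detector_stack(), spacing_mm = 1,
                         lateral_mm = 300, layout = chamber_layout()) {
  stopifnot(buildup_cm > 0, backscatter_cm > 0)
  if (spacing_mm > 4 * stack$anode_thickness_mm)
    stop("voxel spacing ", spacing_mm,
         " mm cannot resolve the anode ROI (limit ",
         4 * stack$anode_thickness_mm, " mm)")
  oemp <- layout$oemp_depth_mm
  if (oemp < stack$chamber_layer_mm[1] || oemp > stack$chamber_layer_mm[2])
    stop("measurement-plane depth lies outside the chamber layer")
  surf <- -oemp                       # detector surface world z
  ztop <- surf - buildup_cm * 10
  zstack_bot <- surf + stack$total_thickness_mm
  zbot <- zstack_bot + backscatter_cm * 10

  dz <- spacing_mm
  nz <- as.integer(ceiling((zbot - ztop) / dz - 1e-9))
  if (length(lateral_mm) == 1) lateral_mm <- c(lateral_mm, lateral_mm)
  nx <- max(1L, as.integer(round(lateral_mm[1] / dz)))
  ny <- max(1L, as.integer(round(lateral_mm[2] / dz)))
  origin <- c(-(nx - 1) / 2 * dz, -(ny - 1) / 2 * dz, ztop + dz / 2)
  zc <- origin[3] + (seq_len(nz) - 1) * dz

  # z slab profile: everything water-equivalent at body density except the
  # anode layer (overridden later via its ROI); regions beyond the physical
  # slabs get zero density through the overlap weighting.
  rho_z <- stack$body_density * .z_overlap_frac(zc, dz, ztop, zbot)
  density <- array(rep(rho_z, each = nx * ny), dim = c(nx, ny, nz))

  vol <- density_volume(origin, rep(dz, 3), density,
                        detector_surface_z_mm = surf)
  anode_z0 <- surf + stack$anode_top_mm
  anode_z1 <- anode_z0 + stack$anode_thickness_mm
  frac_z <- .z_overlap_frac(zc, dz, anode_z0, anode_z1)
  half <- layout$active_side_mm / 2
  xin <- abs(vox_centers(vol, 1)) <= half
  yin <- abs(vox_centers(vol, 2)) <= half
  kz <- which(frac_z > 0)
  if (length(kz)) {
    sel <- as.matrix(expand.grid(i = which(xin), j = which(yin), k = kz))
    idx <- sel[, 1] + nx * (sel[, 2] - 1) + nx * ny * (sel[, 3] - 1)
    frac <- frac_z[sel[, 3]]
    vol$roi_masks[["anode"]] <- list(idx = idx, frac = frac,
                                     base = vol$density[idx],
                                     density = stack$anode_density)
  }
  if (stack$anode_density != stack$body_density)
    vol <- set_roi_density(vol, "anode", stack$anode_density)
  attr(vol, "stack") <- stack
  attr(vol, "layout") <- layout
  vol
}

#' Override the density of a named ROI
#'
#' Sets the ROI to the given density using its fractional overlap mask:
#' a voxel covered by fraction f becomes `f * density + (1 - f) * base`.
#' Only masked voxels change; re-applying with the baseline density reverts
#' the override exactly.
#'
#' @param vol A [density_volume].
#' @param name ROI name (e.g. `"anode"`).
#' @param density_g_cm3 New ROI density, g/cm^3.
#' @return The modified volume.
#' @export
set_roi_density <- function(vol, name, density_g_cm3) {
  stopifnot(inherits(vol, "density_volume"))
  m <- vol$roi_masks[[name]]
  if (is.null(m)) stop("no ROI named '", name, "'")
  stopifnot(is.numeric(density_g_cm3), density_g_cm3 >= 0)
  vol$density[m$idx] <- m$frac * density_g_cm3 + (1 - m$frac) * m$base
  vol$roi_masks[[name]]$density <- density_g_cm3
  vol
}

#' Analytic vs voxelized ROI volume
#'
#' Sum of fractional voxel volumes of a named ROI, cm^3.
#' @inheritParams set_roi_density
#' @return Numeric scalar, cm^3.
#' @export
roi_volume_cm3 <- function(vol, name) {
  m <- vol$roi_masks[[name]]
  if (is.null(m)) stop("no ROI named '", name, "'")
  sum(m$frac) * prod(vol$spacing_mm) / 1000
}
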