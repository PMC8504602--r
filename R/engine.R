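#' Dose-engine parameters
#'
#' Parameters of the simplified divergent-beam photon engine: a primary-only
#' model with an analytic buildup/attenuation depth curve driven by the
#' radiological path from the source, separable error-function aperture
#' penumbra, and inverse-square divergence. Defaults approximate a 6 MV beam
#' (depth of maximum dose about 1.5 cm in water).
#'
#' @param mu_eff Effective linear attenuation per areal density, cm^2/g.
#' @param beta_buildup Buildup constant, cm^-1.
#' @param penumbra_sigma_mm Penumbra sigma at the isocenter plane, mm; scales
#'   with divergence (distance from source over SAD).
#' @param output_per_mu Dose output at calibration conditions, Gy/MU.
#' @return Object of class `engine_params`.
#' @export
engine_params <- function(mu_eff = 0.046, beta_buildup = 2.8,
                          penumbra_sigma_mm = 3.0, output_per_mu = 0.01) {
  stopifnot(mu_eff >= 0, beta_buildup > 0, penumbra_sigma_mm > 0,
            output_per_mu > 0)
  structure(list(mu_eff = mu_eff, beta_buildup = beta_buildup,
                 penumbra_sigma_mm = penumbra_sigma_mm,
                 output_per_mu = output_per_mu),
            class = "engine_params")
}

# world-frame beam basis: z = depth (positive toward the detector bottom),
# gantry 0 puts the source at depth -SAD above the isocenter; rotation about y
beam_basis <- function(beam) {
  th <- beam$gantry_deg * pi / 180
  list(source = c(beam$sad_mm * sin(th), 0, -beam$sad_mm * cos(th)),
       b = c(-sin(th), 0, cos(th)),     # beam axis, source -> isocenter
       u = c(cos(th), 0, sin(th)),      # cross-plane (aperture x)
       v = c(0, 1, 0))                  # in-plane (aperture y)
}

#' Radiological path length
#'
#' Areal density (g/cm^2) integrated along the straight segment from `p0` to
#' `p1` through a voxelized density volume, by exact voxel traversal. The
#' integral is additive over subsegments and symmetric in the endpoints;
#' segments missing the volume (or degenerate ones) contribute 0.
#'
#' @param volume A [density_volume].
#' @param p0,p1 Length-3 world points, mm.
#' @return Areal density in g/cm^2.
#' @export
radiological_path <- function(volume, p0, p1) {
  stopifnot(inherits(volume, "density_volume"))
  cpp_radiological_path(volume$density, as.integer(volume$dim),
                        volume$origin_mm, volume$spacing_mm,
                        as.numeric(p0), as.numeric(p1))
}

#' Aperture transmission at a point
#'
#' Separable product of error-function edge profiles of the aperture
#' back-projected to the isocenter plane. Expressing the point in
#' back-projected (isocenter-scaled) coordinates makes the edge width
#' `penumbra_sigma_mm` there, equivalent to a physical penumbra sigma growing
#' with divergence as (distance from source)/SAD.
#'
#' @param beam A [beam()].
#' @param points Length-3 point or n x 3 matrix of world points, mm.
#' @param params [engine_params()].
#' @return Transmission fraction(s) in `[0, 1]`.
#' @export
aperture_transmission <- function(beam, points, params = engine_params()) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  g <- beam_basis(beam)
  w <- sweep(points, 2, g$source)
  t <- drop(w %*% g$b)
  xb <- drop(w %*% g$u) * beam$sad_mm / t
  yb <- drop(w %*% g$v) * beam$sad_mm / t
  s <- params$penumbra_sigma_mm * sqrt(2)
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  a <- beam$aperture_mm
  tr <- 0.5 * (erf((xb - a[1]) / s) - erf((xb - a[2]) / s)) *
    0.5 * (erf((yb - a[3]) / s) - erf((yb - a[4]) / s))
  tr[t <= 0] <- 0
  pmin(pmax(tr, 0), 1)
}

#' Normalized depth-dose factor
#'
#' `f(d) = (1 - exp(-beta d)) exp(-mu_eff d)`, normalized to 1 at its maximum
#' `d* = log((mu_eff + beta)/mu_eff)/beta`. Degenerate limits are served:
#' `mu_eff = 0` gives pure buildup, `beta_buildup = Inf` pure attenuation,
#' and both together a flat factor of 1.
#'
#' @param areal_depth Areal density (radiological depth), g/cm^2; >= 0.
#' @param params [engine_params()].
#' @return Factor(s) in `[0, 1]`.
#' @export
depth_dose_factor <- function(areal_depth, params = engine_params()) {
  d <- pmax(as.numeric(areal_depth), 0)
  mu <- params$mu_eff; beta <- params$beta_buildup
  if (!is.finite(beta)) {
    f <- if (mu > 0) exp(-mu * d) else rep(1, length(d))
    return(f)
  }
  if (mu <= 0) return(1 - exp(-beta * d))
  dstar <- log((mu + beta) / mu) / beta
  fmax <- (1 - exp(-beta * dstar)) * exp(-mu * dstar)
  (1 - exp(-beta * d)) * exp(-mu * d) / fmax
}

#' Compute the 3D dose of one beam
#'
#' Dose at every voxel center p of the (optionally z-restricted) grid:
#' `D(p) = mu * output_per_mu * T(p) * f(path(source -> p)) * (SAD/|S-p|)^2`
#' with T the aperture transmission and f the normalized depth-dose factor of
#' the radiological path from the source. Deterministic given its inputs; a
#' zero-weight beam yields a zero volume.
#'
#' @param beam A [beam()].
#' @param volume A [density_volume] (rays always traverse the full volume
#'   regardless of the output grid).
#' @param params [engine_params()].
#' @param z_range Optional world-z interval `c(z0, z1)` (mm); only dose
#'   planes intersecting it (plus one plane of margin) are computed, which
#'   is how thin extraction slabs are obtained cheaply.
#' @param grid_spacing_mm Optional isotropic spacing of the dose grid, mm.
#'   By default the dose is evaluated on the density grid itself; a value
#'   here evaluates it on an independent grid spanning the same lateral
#'   extent, so the dose-grid resolution can be varied while the density
#'   (CT-like) voxelization stays fixed.
#' @return Object of class `dose3d` (fields like a [density_volume], with a
#'   `dose` array in Gy).
#' @export
compute_beam_dose <- function(beam, volume, params = engine_params(),
                              z_range = NULL, grid_spacing_mm = NULL) {
  stopifnot(inherits(beam, "beam"), inherits(volume, "density_volume"))
  zc <- vox_centers(volume, 3)
  zspan <- c(zc[1], zc[length(zc)])
  if (is.null(z_range)) z_range <- zspan
  if (is.null(grid_spacing_mm)) {
    kk <- which(zc >= z_range[1] - volume$spacing_mm[3] &
                  zc <= z_range[2] + volume$spacing_mm[3])
    if (!length(kk)) stop("z_range does not intersect the volume")
    out_org <- c(volume$origin_mm[1:2], zc[min(kk)])
    out_sp <- volume$spacing_mm
    out_dim <- c(volume$dim[1:2], max(kk) - min(kk) + 1L)
  } else {
    sp <- grid_spacing_mm
    wx <- volume$dim[1] * volume$spacing_mm[1]
    wy <- volume$dim[2] * volume$spacing_mm[2]
    nx <- max(2L, as.integer(round(wx / sp)))
    ny <- max(2L, as.integer(round(wy / sp)))
    # z planes anchored to the volume frame (like a TPS dose grid), not to
    # the query window; the window only selects which planes are computed
    z0 <- zspan[1] + ceiling((max(z_range[1] - sp, zspan[1]) - zspan[1]) /
                               sp - 1e-9) * sp
    z1 <- min(z_range[2] + sp, zspan[2])
    if (z0 > z1) stop("z_range does not intersect the volume")
    nz <- max(2L, as.integer(floor((z1 - z0) / sp + 1e-9)) + 1L)
    out_org <- c(-(nx - 1) / 2 * sp, -(ny - 1) / 2 * sp, z0)
    out_sp <- rep(sp, 3)
    out_dim <- c(nx, ny, nz)
  }
  g <- beam_basis(beam)
  dose <- cpp_beam_dose(volume$density, as.integer(volume$dim),
                        volume$origin_mm, volume$spacing_mm,
                        out_org, out_sp, as.integer(out_dim),
                        g$source, g$b, g$u, g$v,
                        beam$aperture_mm, beam$sad_mm,
                        params$penumbra_sigma_mm, params$mu_eff,
                        params$beta_buildup, params$output_per_mu,
                        beam$mu)
  structure(list(origin_mm = out_org, spacing_mm = out_sp,
                 dim = dim(dose), dose = dose,
                 detector_surface_z_mm = volume$detector_surface_z_mm),
            class = "dose3d")
}

#' @export
print.dose3d <- function(x, ...) {
  cat(sprintf("<dose3d> %s voxels, z in [%.1f, %.1f] mm, max %.4g Gy\n",
              paste(x$dim, collapse = " x "), x$origin_mm[3],
              x$origin_mm[3] + (x$dim[3] - 1) * x$spacing_mm[3],
              max(x$dose)))
  invisible(x)
}

#' Per-beam doses of a plan
#'
#' Computes and retains each beam's 3D dose separately (required for
#' extraction at per-beam measurement-plane depths); their sum is the
#' whole-plan dose.
#'
#' @inheritParams compute_beam_dose
#' @param plan An [rt_plan()].
#' @return List of `dose3d`, one per beam.
#' @export
compute_plan_dose <- function(plan, volume, params = engine_params(),
                              z_range = NULL) {
  stopifnot(inherits(plan, "rt_plan"))
  if (!length(plan$beams)) stop("empty plan")
  lapply(plan$beams, compute_beam_dose, volume = volume, params = params,
         z_range = z_range)
}

#' Sum a list of per-beam doses
#' @param doses List of `dose3d` on identical grids.
#' @return A single `dose3d`.
#' @export
sum_dose3d <- function(doses) {
  out <- doses[[1]]
  if (length(doses) > 1)
    for (d in doses[-1]) {
      stopifnot(all(d$dim == out$dim))
      out$dose <- out$dose + d$dose
    }
  out
}

# ---- dose export: text voxel array + JSON sidecar ---------------------------

#' Write / read a 3D dose as text plus a JSON sidecar
#'
#' The voxel array is written as one whitespace-separated value per line in
#' column-major order; the sidecar (`<path>.json`) records origin, spacing and
#' shape so the file re-reads without the producing configuration.
#'
#' @param dose A `dose3d`.
#' @param path Output path for the voxel text file.
#' @return `write_dose3d` returns `path` invisibly; `read_dose3d` a `dose3d`.
#' @export
write_dose3d <- function(dose, path) {
  writeLines(format(as.vector(dose$dose), digits = 17, trim = TRUE,
                    scientific = TRUE), path)
  jsonlite::write_json(list(origin_mm = dose$origin_mm,
                            spacing_mm = dose$spacing_mm,
                            shape = as.integer(dose$dim),
                            detector_surface_z_mm =
                              dose$detector_surface_z_mm,
                            units = "Gy"),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_dose3d
#' @export
read_dose3d <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.numeric(readLines(path))
  structure(list(origin_mm = meta$origin_mm, spacing_mm = meta$spacing_mm,
                 dim = meta$shape,
                 dose = array(vals, dim = meta$shape),
                 detector_surface_z_mm = meta$detector_surface_z_mm),
            class = "dose3d")
}
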