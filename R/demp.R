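#' Dynamical effective-measurement-plane model
#'
#' The angular-response model of a 2D chamber array: a per-angle depth offset
#' `delta_d_mm` of the effective measurement plane from its gantry-0 position
#' (tabulated on `angles_deg`, default 0 to 180 degrees in 10-degree steps),
#' plus the effective density `rho_g_cm3` of the thin anode layer beneath the
#' chambers. Left-right symmetry is built in: only `[0, 180]` is stored and
#' any angle is first mapped to `min(theta, 360 - theta)`. Interpolation is
#' linear between tabulated angles; angles strictly inside the excluded
#' intervals (default (80,100) and (260,280), where the angular response may
#' fluctuate erratically) are refused or warned about per `policy`, except
#' exact grid hits, which are always served.
#'
#' @param angles_deg Increasing grid of tabulated angles spanning `[0, 180]`.
#' @param delta_d_mm Depth offsets at the grid angles, mm (positive toward
#'   the detector bottom).
#' @param rho_g_cm3 Effective anode density, g/cm^3 (> 0).
#' @param excluded_intervals List of open `(lo, hi)` angle intervals.
#' @param oemp_depth_mm Reference measurement-plane depth below the detector
#'   surface at gantry 0, mm.
#' @param policy `"error"` (default) or `"warn"` for angles strictly inside
#'   an excluded interval.
#' @return Object of class `demp_model`.
#' @export
demp_model <- function(angles_deg = seq(0, 180, by = 10),
                       delta_d_mm = numeric(length(angles_deg)),
                       rho_g_cm3 = 2.0,
                       excluded_intervals = list(c(80, 100), c(260, 280)),
                       oemp_depth_mm = 3.5,
                       policy = c("error", "warn")) {
  policy <- match.arg(policy)
  angles_deg <- round(as.numeric(angles_deg), 1)
  delta_d_mm <- as.numeric(delta_d_mm)
  if (length(angles_deg) != length(delta_d_mm))
    stop("angles_deg and delta_d_mm must have equal length")
  if (length(angles_deg) < 2 || is.unsorted(angles_deg, strictly = TRUE))
    stop("angles_deg must be strictly increasing with at least 2 angles")
  if (angles_deg[1] < 0 || angles_deg[length(angles_deg)] > 180)
    stop("the angle grid must lie within [0, 180] degrees")
  if (any(!is.finite(delta_d_mm))) stop("delta_d_mm must be finite")
  if (!is.finite(rho_g_cm3) || rho_g_cm3 <= 0) stop("rho must be > 0")
  structure(list(angles_deg = angles_deg, delta_d_mm = delta_d_mm,
                 rho_g_cm3 = rho_g_cm3,
                 excluded_intervals = excluded_intervals,
                 oemp_depth_mm = oemp_depth_mm, policy = policy),
            class = "demp_model")
}

#' @export
print.demp_model <- function(x, ...) {
  cat(sprintf(
    "<demp_model> %d grid angles on [0, 180] deg, rho = %.3g g/cm^3\n",
    length(x$angles_deg), x$rho_g_cm3))
  cat(sprintf("  delta-d range [%.2f, %.2f] mm, policy on excluded: %s\n",
              min(x$delta_d_mm), max(x$delta_d_mm), x$policy))
  invisible(x)
}

#' Canonical (left-right symmetric) gantry angle
#'
#' Maps any angle to its representative in `[0, 180]`: theta (mod 360) if at
#' most 180, else 360 - theta. Beams at theta and 360 - theta share the same
#' effective measurement plane.
#'
#' @param theta_deg Numeric vector of angles, degrees.
#' @return Angles in `[0, 180]`.
#' @export
canonical_angle <- function(theta_deg) {
  t <- as.numeric(theta_deg) %% 360
  ifelse(t > 180, 360 - t, t)
}

# angles are matched at 0.1-degree resolution (linac gantry scale)
.grid_hit <- function(theta, angles) {
  i <- which(abs(angles - theta) <= 0.05)
  if (length(i)) i[1] else 0L
}

.check_excluded <- function(model, theta_norm) {
  for (iv in model$excluded_intervals) {
    if (theta_norm > iv[1] + 1e-9 && theta_norm < iv[2] - 1e-9) {
      msg <- sprintf(
        "gantry angle %.1f deg lies strictly inside the excluded interval (%g deg, %g deg) where interpolated delta-d is unreliable",
        theta_norm, iv[1], iv[2])
      if (model$policy == "error") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
      return(invisible(TRUE))
    }
  }
  invisible(FALSE)
}

#' Depth offset of the effective measurement plane
#'
#' Exact table value at grid angles (matched at 0.1-degree resolution);
#' linear interpolation between neighbours otherwise. Angles strictly inside
#' an excluded interval follow the model's policy unless they hit the grid.
#'
#' @param model A [demp_model()].
#' @param theta_deg Gantry angle(s), degrees (any real value; normalized
#'   mod 360 first).
#' @return Offset(s) in mm.
#' @export
delta_d <- function(model, theta_deg) {
  stopifnot(inherits(model, "demp_model"))
  vapply(as.numeric(theta_deg), function(th) {
    tn <- round(th %% 360, 1)
    tc <- canonical_angle(tn)
    i <- .grid_hit(tc, model$angles_deg)
    if (i > 0L) return(model$delta_d_mm[i])
    .check_excluded(model, tn)
    if (tc < model$angles_deg[1] || tc > model$angles_deg[length(model$angles_deg)])
      stop("gantry angle ", th, " deg lies outside the tabulated grid [",
           model$angles_deg[1], ", ",
           model$angles_deg[length(model$angles_deg)], "] deg")
    approx(model$angles_deg, model$delta_d_mm, xout = tc)$y
  }, numeric(1))
}

#' Effective measurement-plane depth
#'
#' Depth below the detector surface of the effective measurement plane at a
#' gantry angle: the gantry-0 reference depth plus the angle's offset
#' (positive toward the detector bottom).
#'
#' @inheritParams delta_d
#' @return Depth(s) in mm below the detector surface.
#' @export
emp_depth <- function(model, theta_deg) {
  model$oemp_depth_mm + delta_d(model, theta_deg)
}

# ---- model file I/O ---------------------------------------------------------

#' Read / write a model file
#'
#' JSON with keys `oemp_depth_mm`, `angles_deg`, `delta_d_mm`, `rho_g_cm3`,
#' `excluded_intervals`, `policy`. Values round-trip at full double
#' precision, so a reloaded model reproduces every tabulated offset exactly.
#'
#' @param path JSON file path.
#' @return `read_demp_model` returns a [demp_model()]; `write_demp_model`
#'   returns `path` invisibly.
#' @export
read_demp_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  demp_model(angles_deg = x$angles_deg, delta_d_mm = x$delta_d_mm,
             rho_g_cm3 = x$rho_g_cm3,
             excluded_intervals = lapply(seq_len(nrow(x$excluded_intervals)),
                                         function(i) x$excluded_intervals[i, ]),
             oemp_depth_mm = x$oemp_depth_mm, policy = x$policy)
}

#' @param model A [demp_model()].
#' @rdname read_demp_model
#' @export
write_demp_model <- function(model, path) {
  stopifnot(inherits(model, "demp_model"))
  jsonlite::write_json(
    list(oemp_depth_mm = model$oemp_depth_mm,
         angles_deg = model$angles_deg,
         delta_d_mm = model$delta_d_mm,
         rho_g_cm3 = model$rho_g_cm3,
         excluded_intervals = do.call(rbind, model$excluded_intervals),
         policy = model$policy),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

# ---- correction-factor curve ------------------------------------------------

#' Angular correction-factor curve of the central chamber
#'
#' For each angle, runs the calibration beam (default 4 cm x 10 cm) on the
#' phantom with the model's anode density, and forms
#' CF = central-axis dose at the effective measurement plane / central-axis
#' dose at the isocenter plane, both trilinearly sampled from the same 3D
#' dose. CF(0) = 1 whenever delta-d(0) = 0, and CF(theta) = CF(360 - theta)
#' by the model's symmetry.
#'
#' @param model A [demp_model()].
#' @param params [engine_params()].
#' @param phantom A [density_volume] from [slab_phantom()]; built with
#'   defaults when `NULL`.
#' @param angles_deg Angles at which to evaluate (must avoid the interiors of
#'   the excluded intervals unless they are grid angles).
#' @param aperture_mm,mu Calibration beam aperture and weight.
#' @param oemp_shift_mm Optional setup-error simulation: world-z shift of
#'   both sampling points, mm.
#' @return Object of class `cf_curve`: a data frame with `angle_deg`,
#'   `delta_d_mm` and `cf`.
#' @export
cf_curve <- function(model, params = engine_params(), phantom = NULL,
                     angles_deg = model$angles_deg,
                     aperture_mm = c(-20, 20, -50, 50), mu = 100,
                     oemp_shift_mm = 0) {
  stopifnot(inherits(model, "demp_model"))
  if (is.null(phantom))
    phantom <- slab_phantom(lateral_mm = 160)
  phantom <- set_roi_density(phantom, "anode", model$rho_g_cm3)
  dd <- delta_d(model, angles_deg)
  cf <- vapply(seq_along(angles_deg), function(i) {
    b <- beam(angles_deg[i], aperture_mm, mu = mu)
    zpts <- oemp_shift_mm + c(0, dd[i])
    dose <- compute_beam_dose(b, phantom, params,
                              z_range = range(zpts) + c(-2.5, 2.5))
    v <- trilinear_sample(dose, cbind(0, 0, zpts))
    if (v[1] <= 0) stop("zero dose at the isocenter-plane sampling point; ",
                        "correction factor undefined")
    v[2] / v[1]
  }, numeric(1))
  structure(data.frame(angle_deg = angles_deg, delta_d_mm = dd, cf = cf),
            class = c("cf_curve", "data.frame"))
}
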