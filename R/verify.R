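#' Gamma-evaluation criteria
#'
#' Dose tolerance (percent of the reference maximum — global, "Van Dyk"
#' normalization), distance to agreement, and the low-dose threshold below
#' which reference pixels are excluded from the passing rate.
#'
#' @param dose_tolerance_pct Dose tolerance, percent of the reference max.
#' @param dta_mm Distance to agreement, mm.
#' @param low_dose_threshold_pct Low-dose cutoff, percent of reference max.
#' @param normalization Only `"global"` is implemented.
#' @return Object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tolerance_pct = 3, dta_mm = 3,
                           low_dose_threshold_pct = 10,
                           normalization = "global") {
  stopifnot(dose_tolerance_pct > 0, dta_mm > 0, low_dose_threshold_pct > 0,
            identical(normalization, "global"))
  structure(list(dose_tolerance_pct = dose_tolerance_pct, dta_mm = dta_mm,
                 low_dose_threshold_pct = low_dose_threshold_pct,
                 normalization = normalization),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %g%%/%g mm, %g%% threshold, %s normalization\n",
              x$dose_tolerance_pct, x$dta_mm, x$low_dose_threshold_pct,
              x$normalization))
  invisible(x)
}

.composite_planar <- function(plan, depths, phantom, params) {
  out <- NULL
  for (i in seq_along(plan$beams)) {
    z <- depths[i] + phantom$detector_surface_z_mm
    dose <- compute_beam_dose(plan$beams[[i]], phantom, params,
                              z_range = c(z - 2.5, z + 2.5))
    pl <- extract_planar(dose, depths[i])
    if (is.null(out)) out <- pl else out$values <- out$values + pl$values
  }
  out$plane_depth_mm <- if (length(unique(depths)) == 1) depths[1]
  else NA_real_
  out
}

#' Angularly corrected composite planar dose
#'
#' For each beam of the plan, the 3D dose (with the model's anode density
#' applied) is extracted at the effective measurement-plane depth for that
#' beam's gantry angle; the per-beam planes are summed into the composite
#' planar dose representing the array's response. A beam at an angle inside
#' an excluded interval is refused (under the model's error policy) with the
#' beam identified.
#'
#' @param plan An [rt_plan()].
#' @param model A [demp_model()].
#' @param phantom [density_volume] from [slab_phantom()].
#' @param params [engine_params()].
#' @return A [planar_dose()] at the phantom's in-plane resolution.
#' @export
corrected_composite <- function(plan, model, phantom,
                                params = engine_params()) {
  stopifnot(inherits(plan, "rt_plan"), inherits(model, "demp_model"))
  phantom <- set_roi_density(phantom, "anode", model$rho_g_cm3)
  angles <- vapply(plan$beams, `[[`, numeric(1), "gantry_deg")
  depths <- vapply(seq_along(angles), function(i) {
    tryCatch(emp_depth(model, angles[i]), error = function(e)
      stop("beam ", i, " (gantry ", angles[i], " deg): ",
           conditionMessage(e), call. = FALSE))
  }, numeric(1))
  .composite_planar(plan, depths, phantom, params)
}

#' Uncorrected composite planar dose
#'
#' As [corrected_composite()], but every beam's plane is extracted at the
#' gantry-0 reference depth (no angular correction); the anode density is
#' still the model's if one is given.
#'
#' @inheritParams corrected_composite
#' @param model Optional [demp_model()]; supplies the anode density and
#'   reference depth (defaults 1.0 g/cm^3 at 3.5 mm without one).
#' @return A [planar_dose()].
#' @export
uncorrected_composite <- function(plan, phantom, params = engine_params(),
                                  model = NULL) {
  stopifnot(inherits(plan, "rt_plan"))
  oemp <- if (is.null(model)) 3.5 else model$oemp_depth_mm
  if (!is.null(model))
    phantom <- set_roi_density(phantom, "anode", model$rho_g_cm3)
  depths <- rep(oemp, length(plan$beams))
  .composite_planar(plan, depths, phantom, params)
}

#' Gamma map and passing rate
#'
#' Per-pixel gamma index of an evaluated planar dose against a reference
#' (both on fine grids, typically 1 mm): the minimum over displacements
#' within a disc of radius `search_factor * dta_mm` of
#' `sqrt((dose diff / (tol% of reference max))^2 + (distance / dta)^2)`,
#' with global normalization to the reference maximum. The search is
#' exhaustive on a sub-pixel displacement lattice of pitch `search_step_mm`
#' with the evaluated dose bilinearly interpolated (a discrete pixel-only
#' search overestimates gamma wherever the evaluated gradient approaches the
#' dose tolerance per pixel). The region of interest is the reference at or
#' above the low-dose threshold; the passing rate is the percentage of ROI
#' pixels with gamma <= 1.
#'
#' @param reference,evaluated [planar_dose()]s with overlapping extents.
#' @param criteria A [gamma_criteria()].
#' @param search_factor Search radius in units of the distance to agreement.
#' @param search_step_mm Displacement lattice pitch, mm; default one tenth
#'   of the distance to agreement.
#' @return Object of class `gamma_result`: `gamma_map` (a [planar_dose]-like
#'   matrix on the reference grid), `roi_mask`, `passing_rate_pct`,
#'   `criteria`.
#' @export
gamma_map <- function(reference, evaluated, criteria = gamma_criteria(),
                      search_factor = 3, search_step_mm = NULL) {
  if (is.null(search_step_mm)) search_step_mm <- criteria$dta_mm / 10
  stopifnot(search_step_mm > 0)
  stopifnot(inherits(reference, "planar_dose"),
            inherits(evaluated, "planar_dose"),
            inherits(criteria, "gamma_criteria"))
  dmax <- suppressWarnings(max(reference$values, na.rm = TRUE))
  if (!is.finite(dmax) || dmax <= 0)
    stop("reference maximum is zero; gamma undefined")
  rx <- range(planar_axis(reference, 1)); ry <- range(planar_axis(reference, 2))
  ex <- range(planar_axis(evaluated, 1)); ey <- range(planar_axis(evaluated, 2))
  if (rx[1] > ex[2] || rx[2] < ex[1] || ry[1] > ey[2] || ry[2] < ey[1])
    stop("reference and evaluated extents do not overlap")
  roi <- !is.na(reference$values) &
    reference$values >= criteria$low_dose_threshold_pct / 100 * dmax
  g <- cpp_gamma_map(reference$values, evaluated$values,
                     reference$origin_mm, reference$spacing_mm,
                     evaluated$origin_mm, evaluated$spacing_mm,
                     roi, criteria$dose_tolerance_pct / 100 * dmax,
                     criteria$dta_mm, criteria$dta_mm * search_factor,
                     search_step_mm)
  ok <- roi & !is.na(g)
  # tolerance on the pass boundary: a dose difference of exactly the
  # criterion must count as passing despite floating-point representation
  structure(list(gamma_map = g, roi_mask = ok,
                 passing_rate_pct = 100 * sum(g[ok] <= 1 + 1e-9) / sum(ok),
                 criteria = criteria,
                 reference_max_gy = dmax),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm: passing rate %.1f%% (%d ROI pixels)\n",
              x$criteria$dose_tolerance_pct, x$criteria$dta_mm,
              x$passing_rate_pct, sum(x$roi_mask)))
  invisible(x)
}

#' One-sided paired t-test on passing rates
#'
#' One-sided paired t-test of the differences `a - b` (alternative: mean
#' difference greater than zero). Identical samples give p = 0.5. If the
#' differences have zero variance but a nonzero mean, the t statistic is
#' infinite and p is 0 (positive mean) or 1 (negative mean) by convention.
#'
#' @param rates_a,rates_b Equal-length numeric vectors (>= 2 pairs), e.g.
#'   gamma passing rates of the same plans under two modalities.
#' @return The p-value.
#' @export
paired_one_sided_t <- function(rates_a, rates_b) {
  stopifnot(length(rates_a) == length(rates_b), length(rates_a) >= 2)
  d <- rates_a - rates_b
  if (sd(d) == 0) {
    m <- mean(d)
    return(if (m > 0) 0 else if (m < 0) 1 else 0.5)
  }
  t.test(rates_a, rates_b, paired = TRUE,
         alternative = "greater")$p.value
}

#' Run a composite dose verification
#'
#' The full comparison workflow for one plan: angularly corrected composite
#' planar dose, detector-response convolution, measurement resampled to the
#' fine grid, gamma evaluation at each requested criteria set, a percent
#' error map on the chamber domain, and central x/y profiles. Deterministic
#' given its inputs.
#'
#' @param plan An [rt_plan()].
#' @param model A [demp_model()].
#' @param measurement A [chamber_grid()] matching the detector layout.
#' @param phantom [density_volume] from [slab_phantom()].
#' @param params [engine_params()].
#' @param criteria List of [gamma_criteria()] to evaluate.
#' @param sigma_response_mm Detector-response convolution sigma, mm.
#' @param corrected Set `FALSE` to evaluate the uncorrected calculation.
#' @return Object of class `verification_report`.
#' @export
run_verification <- function(plan, model, measurement, phantom,
                             params = engine_params(),
                             criteria = list(gamma_criteria(3, 3),
                                             gamma_criteria(3, 2)),
                             sigma_response_mm = 2.0,
                             corrected = TRUE) {
  stopifnot(inherits(measurement, "chamber_grid"))
  calc <- if (corrected)
    corrected_composite(plan, model, phantom, params)
  else uncorrected_composite(plan, phantom, params, model = model)
  calc <- convolve_response(calc, sigma_response_mm)
  ref <- resample_chambers_to_grid(measurement, 1.0)
  gammas <- lapply(criteria, function(cr) gamma_map(ref, calc, cr))
  names(gammas) <- vapply(criteria, function(cr)
    sprintf("%g%%/%gmm", cr$dose_tolerance_pct, cr$dta_mm), character(1))
  calc_at_chambers <- sample_at_chambers(calc, measurement$layout)
  err <- percent_error_map(measurement, calc_at_chambers)
  structure(list(
    plan_label = plan$label,
    corrected = corrected,
    passing_rates_pct = vapply(gammas, `[[`, numeric(1), "passing_rate_pct"),
    gamma = gammas,
    percent_error = err,
    profiles = list(
      calc_x = extract_profile(calc, "x", 0),
      calc_y = extract_profile(calc, "y", 0),
      meas_x = extract_profile(ref, "x", 0),
      meas_y = extract_profile(ref, "y", 0)),
    calculated = calc, reference = ref,
    sigma_response_mm = sigma_response_mm),
    class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification_report> plan '%s' (%s)\n", x$plan_label,
              if (x$corrected) "angular correction applied" else
                "uncorrected"))
  for (nm in names(x$passing_rates_pct))
    cat(sprintf("  gamma %s passing rate: %.1f%%\n", nm,
                x$passing_rates_pct[[nm]]))
  cat(sprintf("  mean |error| on chambers: %.2f%% of max\n",
              x$percent_error$average_pct))
  invisible(x)
}
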