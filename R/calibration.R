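#' Calibration data set
#'
#' Pairs of single-beam calibration plans and their chamber-grid measurements
#' on the calibration phantom, plus the engine parameters used for the fit.
#'
#' @param plans List of single-beam [rt_plan()]s (e.g. from
#'   [make_calibration_plans()]).
#' @param measurements List of [chamber_grid()]s, one per plan, in order.
#' @param phantom The calibration [density_volume] (from [slab_phantom()]).
#' @param params [engine_params()].
#' @param sigma_response_mm Detector-response (volume-averaging) Gaussian
#'   applied to each calculated plane before chamber sampling, mm; must
#'   match the response of the measurements being fitted, else the fit
#'   absorbs the mismatch into biased depth offsets.
#' @return Object of class `calibration_set`.
#' @export
calibration_set <- function(plans, measurements, phantom,
                            params = engine_params(),
                            sigma_response_mm = 2.0) {
  if (length(plans) != length(measurements))
    stop("need exactly one measurement per calibration plan (",
         length(plans), " plans, ", length(measurements), " measurements)")
  if (!all(vapply(plans, function(p)
    inherits(p, "rt_plan") && length(p$beams) == 1, logical(1))))
    stop("calibration plans must be single-beam plans")
  if (!all(vapply(measurements, inherits, logical(1), "chamber_grid")))
    stop("measurements must be chamber_grid objects")
  stopifnot(inherits(phantom, "density_volume"))
  angles <- vapply(plans, function(p) p$beams[[1]]$gantry_deg, numeric(1))
  structure(list(plans = plans, measurements = measurements,
                 phantom = phantom, params = params, angles_deg = angles,
                 sigma_response_mm = sigma_response_mm),
            class = "calibration_set")
}

#' Fit options for the model calibration
#'
#' Bounded Levenberg-Marquardt settings: iteration budget, the relative
#' cost-decrease stopping tolerance, forward finite-difference steps for the
#' per-angle depth offsets and for the anode density, parameter bounds, and
#' initial values (all offsets 0, density 2.0 g/cm^3).
#'
#' @param max_iterations Maximum optimizer iterations.
#' @param relative_cost_tolerance Stop when the relative cost difference
#'   between two iterations falls below this.
#' @param step_delta_d_mm,step_rho Finite-difference steps (mm, g/cm^3).
#' @param bounds_delta_d,bounds_rho Box bounds `c(lo, hi)`.
#' @param init_delta_d,init_rho Initial values.
#' @return Object of class `fit_options`.
#' @export
fit_options <- function(max_iterations = 50, relative_cost_tolerance = 1e-4,
                        step_delta_d_mm = 0.1, step_rho = 0.05,
                        bounds_delta_d = c(-20, 20), bounds_rho = c(1, 9),
                        init_delta_d = 0, init_rho = 2.0) {
  stopifnot(max_iterations >= 1, relative_cost_tolerance > 0,
            step_delta_d_mm > 0, step_rho > 0,
            init_rho >= bounds_rho[1], init_rho <= bounds_rho[2],
            all(init_delta_d >= bounds_delta_d[1]),
            all(init_delta_d <= bounds_delta_d[2]))
  structure(list(max_iterations = max_iterations,
                 relative_cost_tolerance = relative_cost_tolerance,
                 step_delta_d_mm = step_delta_d_mm, step_rho = step_rho,
                 bounds_delta_d = bounds_delta_d, bounds_rho = bounds_rho,
                 init_delta_d = init_delta_d, init_rho = init_rho),
            class = "fit_options")
}

# sum over plans of the mean squared chamber dose difference
cost_from_pairs <- function(measured, calculated) {
  sum(vapply(seq_along(measured), function(i)
    mean((measured[[i]] - calculated[[i]])^2), numeric(1)))
}

# engine cache: per-plan thin-slab 3D doses, recomputed only when rho changes
.cal_cache_new <- function() new.env(parent = emptyenv())

.cal_doses <- function(cal_set, rho, z_range, cache) {
  if (!is.null(cache$rho) && identical(cache$rho, rho)) return(cache$doses)
  phantom <- set_roi_density(cal_set$phantom, "anode", rho)
  doses <- lapply(cal_set$plans, function(p)
    compute_beam_dose(p$beams[[1]], phantom, cal_set$params,
                      z_range = z_range))
  cache$rho <- rho
  cache$doses <- doses
  cache$depths <- rep(NA_real_, length(doses))
  cache$chambers <- vector("list", length(doses))
  doses
}

# per-plan calculated chamber values at given extraction depths (below the
# detector surface); re-extracts only the plans whose depth changed
.cal_calculated <- function(cal_set, depths, rho, z_range, cache) {
  doses <- .cal_doses(cal_set, rho, z_range, cache)
  for (i in seq_along(doses)) {
    if (!isTRUE(cache$depths[i] == depths[i])) {
      pl <- extract_planar(doses[[i]], depths[i])
      if (cal_set$sigma_response_mm > 0)
        pl <- convolve_response(pl, cal_set$sigma_response_mm)
      cache$chambers[[i]] <-
        sample_at_chambers(pl, cal_set$measurements[[i]]$layout)$values
      cache$depths[i] <- depths[i]
    }
  }
  cache$chambers
}

#' Calibration cost of a model
#'
#' For each calibration plan: extract the calculated planar dose at the
#' model's effective measurement-plane depth for that plan's gantry angle,
#' sample it at the chamber positions, and take the mean squared difference
#' to the measurement; the cost is the sum of these per-plan means. The
#' engine is re-run only when the anode density changes; a changed depth
#' offset only re-extracts the affected plane.
#'
#' @param model A [demp_model()].
#' @param cal_set A [calibration_set()].
#' @param z_range World-z slab on which per-plan doses are computed, mm;
#'   defaults to the span of the model's extraction depths plus margin.
#' @param cache Optional cache environment (reused across calls).
#' @return Scalar cost, Gy^2.
#' @export
calibration_cost <- function(model, cal_set, z_range = NULL, cache = NULL) {
  stopifnot(inherits(model, "demp_model"),
            inherits(cal_set, "calibration_set"))
  if (is.null(cache)) cache <- .cal_cache_new()
  depths <- emp_depth(model, cal_set$angles_deg)
  if (is.null(z_range))
    z_range <- range(depths + cal_set$phantom$detector_surface_z_mm) +
      c(-2.5, 2.5)
  calc <- .cal_calculated(cal_set, depths, model$rho_g_cm3, z_range, cache)
  cost_from_pairs(lapply(cal_set$measurements, `[[`, "values"), calc)
}

# residual vector: per-plan differences scaled by 1/sqrt(n_chambers), so the
# sum of squares equals the calibration cost
.cal_residuals <- function(dd, rho, cal_set, grid_angles, z_range, cache,
                           oemp, only_plans = NULL) {
  depths <- oemp + vapply(cal_set$angles_deg, function(th)
    approx(grid_angles, dd, xout = canonical_angle(th))$y, numeric(1))
  calc <- .cal_calculated(cal_set, depths, rho, z_range, cache)
  res <- lapply(seq_along(calc), function(i) {
    (calc[[i]] - cal_set$measurements[[i]]$values) /
      sqrt(length(calc[[i]]))
  })
  if (!is.null(only_plans)) res <- res[only_plans]
  unlist(res)
}

#' Calibrate the model by bounded Levenberg-Marquardt least squares
#'
#' Determines the per-angle depth offsets and the effective anode density
#' that minimize [calibration_cost()] over the calibration set. The model
#' grid is the sorted set of canonical plan angles (19 offsets plus the
#' density for the default suite, 20 free parameters). The Jacobian is built
#' by forward finite differences with the per-parameter steps from
#' [fit_options()]; offset columns reuse the cached 3D doses (re-extraction
#' only), the density column costs one extra engine pass.
#'
#' @param cal_set A [calibration_set()].
#' @param options A [fit_options()].
#' @param z_range Optional world-z slab for the engine (defaults to the
#'   offset bounds plus margin).
#' @return Object of class `demp_fit`: a list with the fitted `model` and
#'   `diagnostics` (cost per iteration, per-plan final residuals, parameter
#'   sensitivities = Jacobian column norms at the solution, convergence
#'   reason).
#' @export
fit_demp <- function(cal_set, options = fit_options(), z_range = NULL) {
  stopifnot(inherits(cal_set, "calibration_set"),
            inherits(options, "fit_options"))
  grid_angles <- sort(unique(round(canonical_angle(cal_set$angles_deg), 1)))
  if (length(grid_angles) < 2)
    stop("calibration plans must cover at least two distinct canonical angles")
  na <- length(grid_angles)
  oemp <- cal_set$measurements[[1]]$layout$oemp_depth_mm
  if (is.null(z_range))
    z_range <- options$bounds_delta_d +
      cal_set$phantom$detector_surface_z_mm + oemp + c(-2.5, 2.5)
  cache <- .cal_cache_new()
  init_dd <- rep_len(options$init_delta_d, na)

  fn <- function(par) {
    .cal_residuals(par[seq_len(na)], par[na + 1], cal_set, grid_angles,
                   z_range, cache, oemp)
  }
  jac <- function(par) {
    dd <- par[seq_len(na)]; rho <- par[na + 1]
    r0 <- fn(par)
    J <- matrix(0, length(r0), na + 1)
    lens <- vapply(cal_set$measurements, function(m) length(m$values),
                   integer(1))
    ends <- cumsum(lens); starts <- c(1, ends[-length(ends)] + 1)
    canon <- canonical_angle(cal_set$angles_deg)
    for (k in seq_len(na)) {
      h <- options$step_delta_d_mm
      if (dd[k] + h > options$bounds_delta_d[2]) h <- -h
      ddk <- dd; ddk[k] <- ddk[k] + h
      # only plans whose interpolated offset involves grid angle k respond
      aff <- which(abs(approx(grid_angles, ddk, xout = canon)$y -
                         approx(grid_angles, dd, xout = canon)$y) > 0)
      if (!length(aff)) next
      rk <- .cal_residuals(ddk, rho, cal_set, grid_angles, z_range, cache,
                           oemp, only_plans = aff)
      # restore cache planes perturbed by the trial offsets
      base <- .cal_residuals(dd, rho, cal_set, grid_angles, z_range, cache,
                             oemp, only_plans = aff)
      idx <- unlist(lapply(aff, function(i) starts[i]:ends[i]))
      J[idx, k] <- (rk - base) / h
    }
    h <- options$step_rho
    if (rho + h > options$bounds_rho[2]) h <- -h
    rho_cache <- .cal_cache_new()
    rr <- .cal_residuals(dd, rho + h, cal_set, grid_angles, z_range,
                         rho_cache, oemp)
    J[, na + 1] <- (rr - r0) / h
    J
  }

  # the optimizer's stop reason is reported in the diagnostics; its own
  # warning about hitting the iteration cap would be redundant noise
  muffle_lm <- function(expr) withCallingHandlers(
    expr, warning = function(w) {
      if (grepl("lmdif|lmder", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  res <- muffle_lm(minpack.lm::nls.lm(
    par = c(init_dd, options$init_rho),
    lower = c(rep(options$bounds_delta_d[1], na), options$bounds_rho[1]),
    upper = c(rep(options$bounds_delta_d[2], na), options$bounds_rho[2]),
    fn = fn, jac = jac,
    control = minpack.lm::nls.lm.control(
      maxiter = options$max_iterations,
      ftol = options$relative_cost_tolerance,
      nprint = 0)))

  par <- res$par
  model <- demp_model(grid_angles, par[seq_len(na)],
                      rho_g_cm3 = par[na + 1], oemp_depth_mm = oemp)
  rfin <- fn(par)
  lens <- vapply(cal_set$measurements, function(m) length(m$values),
                 integer(1))
  grp <- rep(seq_along(lens), lens)
  per_plan <- tapply(rfin^2, grp, sum) # per-plan mean squared difference
  Jfin <- jac(par)
  sens <- sqrt(colSums(Jfin^2))
  names(sens) <- c(sprintf("delta_d_%g", grid_angles), "rho")
  reason <- if (grepl("maxiter", res$message)) "max-iterations"
  else trimws(res$message)
  # rsstrace carries one uninitialized trailing slot when the iteration cap
  # stops the run; keep only the recorded deviances
  nk <- min(length(res$rsstrace), res$niter + 1)
  trace <- res$rsstrace[seq_len(nk)]
  if (nk > 1 && (!is.finite(trace[nk]) || trace[nk] < 1e-300))
    trace <- trace[-nk]
  structure(list(
    model = model,
    diagnostics = list(
      cost_trace = trace, n_iterations = res$niter,
      convergence = reason, info = res$info,
      final_cost = sum(rfin^2),
      residual_per_plan = setNames(as.numeric(per_plan),
                                   sprintf("gantry_%g", cal_set$angles_deg)),
      sensitivity = sens)),
    class = "demp_fit")
}

#' @export
print.demp_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<demp_fit> %d iterations, cost %.3g Gy^2 (%s)\n",
              d$n_iterations, d$final_cost, d$convergence))
  print(x$model)
  invisible(x)
}
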