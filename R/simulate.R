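#' Measurement-noise specification
#'
#' Additive Gaussian noise applied per chamber, with standard deviation
#' expressed as a percentage of the maximum chamber dose, and a seed that
#' makes the draw reproducible.
#'
#' @param sigma_pct_of_max Noise sigma, percent of the maximum dose (>= 0).
#' @param seed Integer seed, or NULL to draw from the session RNG stream.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_pct_of_max = 0.5, seed = NULL) {
  stopifnot(sigma_pct_of_max >= 0)
  structure(list(sigma_pct_of_max = sigma_pct_of_max, seed = seed),
            class = "noise_spec")
}

#' Injected ground-truth model for the virtual detector
#'
#' A plausible truth table for simulation studies: offsets near zero for
#' beams from above, flipping sign past horizontal and deepening to about
#' -1 cm for beams from below. The negative posterior branch moves the
#' effective plane away from a posterior source, which reproduces the deep
#' correction-factor valley around 180 degrees (the array under-responds to
#' posterior beams), and keeps the plane above the anode layer so that
#' near-horizontal posterior rays cross the anode and the density mechanism
#' peaks near 90 degrees. The effective anode density defaults to
#' 3.5 g/cm^3, the mixture average of glass fiber, epoxy and copper. These
#' values are a simulation fixture of this package, not measured detector
#' properties.
#'
#' @param delta_d_mm Offsets at 0, 10, ..., 180 degrees, mm.
#' @param rho_g_cm3 Effective anode density, g/cm^3.
#' @param ... Passed to [demp_model()].
#' @return A [demp_model()].
#' @export
demp_truth_model <- function(delta_d_mm = c(0, 0.1, 0.2, 0.4, 0.6, 0.9,
                                            1.2, 1.6, 2.0, -1.0, -3.0,
                                            -5.5, -7.0, -8.0, -8.8, -9.3,
                                            -9.7, -9.9, -10),
                             rho_g_cm3 = 3.5, ...) {
  demp_model(angles_deg = seq(0, 180, by = 10), delta_d_mm = delta_d_mm,
             rho_g_cm3 = rho_g_cm3, ...)
}

with_noise_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Simulate a chamber-array measurement
#'
#' Forward model of the detector response under a ground-truth angular
#' model: per beam, the 3D dose is computed with the truth anode density,
#' the planar dose is extracted at the truth effective measurement-plane
#' depth for the beam's angle, smoothed by the Gaussian volume-averaging
#' response, and sampled at the chamber centers; beams are summed and seeded
#' Gaussian noise (sigma as a percentage of the maximum chamber dose) is
#' added. Negative post-noise values are clipped to zero with a message.
#'
#' @param plan An [rt_plan()].
#' @param truth The ground-truth [demp_model()].
#' @param phantom A [density_volume] from [slab_phantom()].
#' @param params [engine_params()].
#' @param layout [chamber_layout()] to sample (its chambers must lie inside
#'   the phantom's lateral extent).
#' @param noise A [noise_spec()].
#' @param sigma_avg_mm Volume-averaging Gaussian sigma, mm.
#' @return A [chamber_grid()].
#' @export
simulate_measurement <- function(plan, truth, phantom,
                                 params = engine_params(),
                                 layout = chamber_layout(),
                                 noise = noise_spec(),
                                 sigma_avg_mm = 2.0) {
  stopifnot(inherits(plan, "rt_plan"), inherits(truth, "demp_model"),
            inherits(phantom, "density_volume"))
  phantom <- set_roi_density(phantom, "anode", truth$rho_g_cm3)
  angles <- vapply(plan$beams, `[[`, numeric(1), "gantry_deg")
  depths <- emp_depth(truth, angles)
  vals <- 0
  for (i in seq_along(plan$beams)) {
    z <- depths[i] + phantom$detector_surface_z_mm
    dose <- compute_beam_dose(plan$beams[[i]], phantom, params,
                              z_range = c(z - 2.5, z + 2.5))
    pl <- extract_planar(dose, depths[i])
    pl <- convolve_response(pl, sigma_avg_mm)
    vals <- vals + sample_at_chambers(pl, layout)$values
  }
  if (noise$sigma_pct_of_max > 0) {
    sdv <- noise$sigma_pct_of_max / 100 * max(vals)
    vals <- vals + with_noise_seed(noise$seed,
                                   rnorm(length(vals), sd = sdv))
    nneg <- sum(vals < 0)
    if (nneg > 0) {
      message(nneg, " negative post-noise chamber value(s) clipped to 0")
      vals[vals < 0] <- 0
    }
  }
  chamber_grid(layout, vals)
}

#' Standard virtual test-plan suite
#'
#' Thirteen plans mirroring a commissioning-style inventory: eight open-field
#' single-beam plans (4 cm x 4 cm and 5 cm x 3 cm apertures, gantry 0, 50,
#' 130 and 180 degrees each), one seven-beam conformal-like plan with
#' equispaced angles steering clear of the excluded intervals, and four
#' multi-segment pseudo-IMRT plans of 5 to 9 beams with 2 to 5 weighted
#' rectangular segments per beam. Every generated beam angle lies outside
#' (80, 100) and (260, 280).
#'
#' @param phantom Optional [density_volume] attached to the plans.
#' @return List of 13 [rt_plan()]s.
#' @export
make_test_suite <- function(phantom = NULL) {
  single <- list()
  for (ap in list(`4x4` = c(-20, 20, -20, 20), `5x3` = c(-25, 25, -15, 15)))
    for (th in c(0, 50, 130, 180))
      single[[length(single) + 1]] <-
        rt_plan(beam(th, ap), label = sprintf("open-%gx%g-g%03d",
                                              (ap[2] - ap[1]) / 10,
                                              (ap[4] - ap[3]) / 10, th),
                phantom = phantom)
  conf_angles <- c(0, 40, 75, 130, 180, 230, 320)
  conformal <- rt_plan(lapply(conf_angles, function(th)
    beam(th, c(-30, 30, -30, 30), mu = 40)),
    label = "conformal-7f", phantom = phantom)
  seg <- function(th, x1, x2, y1, y2, mu) beam(th, c(x1, x2, y1, y2), mu)
  imrt <- list(
    rt_plan(c(lapply(c(0, 50, 130, 180, 310), function(th) list(
      seg(th, -30, 30, -30, 30, 30), seg(th, -12, 12, -30, -5, 15))) |>
        unlist(recursive = FALSE)),
      label = "imrt-multitarget", phantom = phantom),
    rt_plan(c(lapply(c(0, 55, 105, 180, 255, 305, 355), function(th) list(
      seg(th, -25, 25, -20, 20, 25), seg(th, -10, 18, -15, 15, 12),
      seg(th, -20, 0, -8, 20, 8))) |> unlist(recursive = FALSE)),
      label = "imrt-prostate", phantom = phantom),
    rt_plan(c(lapply(seq(0, 320, by = 40), function(th) list(
      seg(th, -35, 35, -35, 35, 20), seg(th, -18, 18, -35, -10, 10),
      seg(th, -18, 18, 10, 35, 10), seg(th, -8, 8, -12, 12, 6),
      seg(th, -30, -5, -20, 20, 5))) |> unlist(recursive = FALSE)),
      label = "imrt-headneck", phantom = phantom),
    rt_plan(c(lapply(c(20, 70, 130, 180, 230, 290, 340), function(th) list(
      seg(th, -28, 28, -28, 28, 22), seg(th, -28, -6, -28, 28, 10),
      seg(th, 6, 28, -28, 28, 10), seg(th, -28, 28, 8, 28, 8))) |>
        unlist(recursive = FALSE)),
      label = "imrt-cshape", phantom = phantom))
  c(single, list(conformal), imrt)
}
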