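# Shared fixtures, built once per test run and memoized across files.
.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(key, expr) {
  if (is.null(.fixtures[[key]])) assign(key, force(expr), envir = .fixtures)
  .fixtures[[key]]
}

# calibration-style phantom, full-depth, reduced lateral extent (1 mm grid)
fix_cal_phantom <- function() {
  memo_fixture("cal_phantom",
               slab_phantom(7, 8, spacing_mm = 1, lateral_mm = c(200, 144)))
}

# verification phantom (10 cm water above and below the measurement plane)
fix_ver_phantom <- function() {
  memo_fixture("ver_phantom",
               slab_phantom(10, 10, spacing_mm = 1, lateral_mm = c(160, 104)))
}

# chambers the reduced phantoms can sample
fix_cal_chambers <- function() {
  memo_fixture("cal_chambers",
               subset_chambers(chamber_layout(), c(-38, 38), c(-68, 68)))
}

fix_ver_chambers <- function() {
  memo_fixture("ver_chambers",
               subset_chambers(chamber_layout(), c(-46, 46), c(-38, 38)))
}

# single 4x4 cm oblique-beam verification scenario with injected truth
# (offset 5 mm at gantry 130) and noisy virtual measurement; reused by the
# verification tests and the end-to-end acceptance checks
fix_oblique_case <- function() {
  memo_fixture("oblique_case", {
    truth <- demp_truth_model()
    truth$delta_d_mm[truth$angles_deg == 130] <- 5
    plan <- rt_plan(beam(130, c(-20, 20, -20, 20), mu = 100),
                    label = "open-4x4-g130")
    phantom <- fix_ver_phantom()
    meas <- suppressMessages(simulate_measurement(
      plan, truth, phantom, engine_params(), layout = fix_ver_chambers(),
      noise = noise_spec(0.5, seed = 71), sigma_avg_mm = 2))
    list(truth = truth, plan = plan, phantom = phantom, measurement = meas)
  })
}

# small synthetic planar doses for gamma tests: a smooth Gaussian blob
blob_planar <- function(n = 31, origin = c(-15, -15), spacing = 1,
                        sigma = 6, amp = 2) {
  xs <- origin[1] + (seq_len(n) - 1) * spacing
  ys <- origin[2] + (seq_len(n) - 1) * spacing
  v <- amp * exp(-outer(xs^2, ys^2, "+") / (2 * sigma^2))
  planar_dose(origin, c(spacing, spacing), v)
}

# independent brute-force gamma oracle: exhaustive displacement search on a
# fine lattice with bilinear interpolation of the evaluated dose, plain R
oracle_gamma <- function(ref, ev, dose_pct, dta, thr_pct = 10,
                         radius = 3 * dta, step = dta / 10) {
  dmax <- max(ref$values, na.rm = TRUE)
  dd <- dose_pct / 100 * dmax
  out <- matrix(NA_real_, ref$dim[1], ref$dim[2])
  exs <- ev$origin_mm[1] + (seq_len(ev$dim[1]) - 1) * ev$spacing_mm[1]
  eys <- ev$origin_mm[2] + (seq_len(ev$dim[2]) - 1) * ev$spacing_mm[2]
  offs <- expand.grid(dx = seq(-radius, radius, by = step),
                      dy = seq(-radius, radius, by = step))
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, ]
  for (j in seq_len(ref$dim[2])) {
    yr <- ref$origin_mm[2] + (j - 1) * ref$spacing_mm[2]
    for (i in seq_len(ref$dim[1])) {
      Dr <- ref$values[i, j]
      if (is.na(Dr) || Dr < thr_pct / 100 * dmax) next
      xr <- ref$origin_mm[1] + (i - 1) * ref$spacing_mm[1]
      xq <- xr + offs$dx
      yq <- yr + offs$dy
      inside <- xq >= exs[1] & xq <= exs[length(exs)] &
        yq >= eys[1] & yq <= eys[length(eys)]
      De <- bilinear_sample(ev, xq[inside], yq[inside])
      g2 <- ((De - Dr) / dd)^2 +
        (offs$dx[inside]^2 + offs$dy[inside]^2) / dta^2
      out[i, j] <- sqrt(min(g2))
    }
  }
  out
}
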