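# small hand-built volumes for ray-tracing checks
water_block <- function(n = c(20, 20, 120), sp = 1, rho = 1) {
  density_volume(origin_mm = -(n - 1) / 2 * sp, spacing_mm = rep(sp, 3),
                 density = array(rho, dim = n),
                 detector_surface_z_mm = -3.5)
}

test_that("radiological path reproduces slab arithmetic", {
  vol <- water_block()
  # 100 mm vertical segment in unit-density water -> 10 g/cm2
  expect_equal(radiological_path(vol, c(0, 0, -50), c(0, 0, 50)), 10,
               tolerance = 1e-12)
  # degenerate segment
  expect_equal(radiological_path(vol, c(1, 2, 3), c(1, 2, 3)), 0)
  # segment missing the volume
  expect_equal(radiological_path(vol, c(500, 0, 0), c(500, 0, 50)), 0)

  # a 0.75 mm slab at 3.5 g/cm3 built from three 0.25 mm voxel layers
  n <- c(8, 8, 40)
  dens <- array(0, dim = n)
  dens[, , 21:23] <- 3.5 # z in [0, 0.75] with origin below
  anode <- density_volume(origin_mm = c(-3.5 * 0.25, -3.5 * 0.25, -4.875),
                          spacing_mm = rep(0.25, 3), density = dens)
  zs <- dempqa::vox_centers(anode, 3)
  z0 <- zs[21] - 0.125; z1 <- zs[23] + 0.125
  expect_equal(z1 - z0, 0.75)
  # perpendicular crossing: 0.075 cm x 3.5 = 0.2625 g/cm2
  expect_equal(radiological_path(anode, c(0, 0, z0 - 2), c(0, 0, z1 + 2)),
               0.2625, tolerance = 1e-12)
  # crossing at 60 degrees from the slab normal: path 1.5 mm -> 0.525 g/cm2
  run <- (0.75 + 4) * tan(60 * pi / 180)
  p0 <- c(-run / 2, 0, z0 - 2); p1 <- c(run / 2, 0, z1 + 2)
  expect_equal(radiological_path(anode, p0, p1), 2 * 0.2625,
               tolerance = 1e-9)
})

test_that("radiological path is symmetric and additive over split points", {
  ph <- slab_phantom(7, 8, spacing_mm = 1, lateral_mm = 60)
  ph <- set_roi_density(ph, "anode", 3.5)
  set.seed(4)
  for (i in 1:20) {
    p0 <- c(runif(2, -25, 25), runif(1, -70, -60))
    p1 <- c(runif(2, -25, 25), runif(1, 90, 110))
    a <- radiological_path(ph, p0, p1)
    expect_equal(radiological_path(ph, p1, p0), a, tolerance = 1e-9)
    lam <- runif(1)
    pm <- p0 + lam * (p1 - p0)
    expect_equal(radiological_path(ph, p0, pm) +
                   radiological_path(ph, pm, p1), a, tolerance = 1e-9)
  }
})

test_that("aperture transmission has erf edge behaviour", {
  b <- beam(0, c(-20, 20, -50, 50))
  expect_gte(aperture_transmission(b, c(0, 0, 0)), 0.999)
  # exactly on one edge: that edge factor is 0.5 (other edge ~1)
  expect_equal(aperture_transmission(b, c(20, 0, 0)), 0.5, tolerance = 1e-4)
  # 5 sigma outside both aperture edges
  p <- engine_params()
  s <- p$penumbra_sigma_mm
  expect_lt(aperture_transmission(b, c(20 + 5 * s, 50 + 5 * s, 0)), 1e-5)
})

test_that("depth-dose factor peaks at the closed-form maximum and decreases past it", {
  p <- engine_params()
  dstar <- log((p$mu_eff + p$beta_buildup) / p$mu_eff) / p$beta_buildup
  expect_equal(dstar, 1.473, tolerance = 1e-3)
  expect_equal(depth_dose_factor(0, p), 0)
  expect_equal(depth_dose_factor(dstar, p), 1, tolerance = 1e-12)
  d <- seq(dstar, 30, length.out = 200)
  expect_true(all(diff(depth_dose_factor(d, p)) < 0))
  # degenerate limits
  flat <- engine_params(mu_eff = 1e-12, beta_buildup = Inf)
  flat$mu_eff <- 0; flat$beta_buildup <- Inf
  expect_equal(depth_dose_factor(c(0, 5, 20), flat), c(1, 1, 1))
})

test_that("beam dose is linear in MU, symmetric for gantry 0, and inverse-square without attenuation", {
  ph <- slab_phantom(7, 8, spacing_mm = 1, lateral_mm = 60)
  p <- engine_params()
  b1 <- beam(0, c(-15, 15, -15, 15), mu = 100)
  b2 <- beam(0, c(-15, 15, -15, 15), mu = 200)
  d1 <- compute_beam_dose(b1, ph, p, z_range = c(-2, 2))
  d2 <- compute_beam_dose(b2, ph, p, z_range = c(-2, 2))
  expect_equal(d2$dose, 2 * d1$dose, tolerance = 1e-12)
  # x -> -x symmetry on the symmetric phantom
  expect_equal(d1$dose, d1$dose[rev(seq_len(d1$dim[1])), , ],
               tolerance = 1e-9)
  # inverse-square scaling with attenuation and buildup disabled
  flat <- engine_params()
  flat$mu_eff <- 0; flat$beta_buildup <- Inf
  d3 <- compute_beam_dose(b1, ph, flat, z_range = c(-60, 60))
  zc <- vox_centers(d3, 3)
  v <- trilinear_sample(d3, cbind(0, 0, zc))
  r <- 1000 + zc
  # tolerance covers the sub-ppm transmission deficit of the finite field
  expect_equal(v, b1$mu * flat$output_per_mu * (1000 / r)^2,
               tolerance = 1e-5)
})

test_that("plan dose retains per-beam doses whose sum is the plan dose", {
  ph <- slab_phantom(7, 8, spacing_mm = 1, lateral_mm = 60)
  p <- engine_params()
  b <- beam(0, c(-15, 15, -15, 15), mu = 50)
  single <- compute_plan_dose(rt_plan(b), ph, p, z_range = c(-2, 2))
  expect_length(single, 1L)
  expect_equal(single[[1]]$dose,
               compute_beam_dose(b, ph, p, z_range = c(-2, 2))$dose)
  pair <- compute_plan_dose(rt_plan(list(b, b)), ph, p, z_range = c(-2, 2))
  expect_equal(pair[[1]]$dose, pair[[2]]$dose)
  expect_equal(sum_dose3d(pair)$dose, 2 * single[[1]]$dose)
  expect_error(compute_plan_dose(structure(list(beams = list()),
                                           class = "rt_plan"), ph, p),
               "empty plan")
})

test_that("parallel-opposed beams give a depth-symmetric summed dose about the isocenter", {
  # water columns above and below z = 0 both 73.5 mm: 70 + 3.5 above the
  # plane, (43.75 - 3.5) of stack + 33.25 of backscatter below
  ph <- slab_phantom(7, 3.325, spacing_mm = 1, lateral_mm = 60)
  p <- engine_params()
  ap <- c(-15, 15, -15, 15)
  dsum <- sum_dose3d(compute_plan_dose(
    rt_plan(list(beam(0, ap), beam(180, ap))), ph, p))
  zq <- seq(5, 60, by = 5)
  up <- trilinear_sample(dsum, cbind(0, 0, -zq))
  dn <- trilinear_sample(dsum, cbind(0, 0, zq))
  expect_equal(up, dn, tolerance = 1e-6)
})

test_that("gantry mirror symmetry: theta -> 360 - theta mirrors the dose in x", {
  ph <- slab_phantom(7, 8, spacing_mm = 1, lateral_mm = 60)
  ph <- set_roi_density(ph, "anode", 3.5)
  p <- engine_params()
  ap <- c(-15, 15, -15, 15)
  da <- compute_beam_dose(beam(130, ap), ph, p, z_range = c(-2, 2))
  db <- compute_beam_dose(beam(230, ap), ph, p, z_range = c(-2, 2))
  expect_equal(da$dose, db$dose[rev(seq_len(db$dim[1])), , ],
               tolerance = 1e-9)
})

test_that("dose text export round-trips with its sidecar", {
  ph <- slab_phantom(7, 8, spacing_mm = 1, lateral_mm = 20)
  d <- compute_beam_dose(beam(0, c(-5, 5, -5, 5)), ph, engine_params(),
                         z_range = c(-2, 2))
  f <- tempfile()
  write_dose3d(d, f)
  d2 <- read_dose3d(f)
  expect_equal(d2$dose, d$dose)
  expect_equal(d2$origin_mm, d$origin_mm)
  unlink(c(f, paste0(f, ".json")))
})
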