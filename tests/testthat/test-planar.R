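random_dose3d <- function(n = c(5, 5, 5), seed = 11) {
  set.seed(seed)
  structure(list(origin_mm = c(0, 0, 0), spacing_mm = c(1, 1, 1),
                 dim = n, dose = array(runif(prod(n)), dim = n),
                 detector_surface_z_mm = 0),
            class = "dose3d")
}

# brute-force trilinear oracle, scalar, straight from the definition
oracle_trilinear <- function(d, p) {
  f <- (p - d$origin_mm) / d$spacing_mm
  i <- floor(f); w <- f - i
  v <- 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    wt <- (if (a) w[1] else 1 - w[1]) * (if (b) w[2] else 1 - w[2]) *
      (if (cc) w[3] else 1 - w[3])
    v <- v + wt * d$dose[i[1] + a + 1, i[2] + b + 1, i[3] + cc + 1]
  }
  v
}

test_that("planar extraction is exact on grid planes and linear between them", {
  d <- random_dose3d()
  pl <- extract_planar(d, 2) # depth 2 with surface z 0 -> slice z = 2
  expect_equal(pl$values, d$dose[, , 3])
  # linear-in-z dose: midway plane is the mean of adjacent slices
  d2 <- d
  for (k in 1:5) d2$dose[, , k] <- k * d$dose[, , 1]
  pl2 <- extract_planar(d2, 1.5)
  expect_equal(pl2$values, 0.5 * (d2$dose[, , 2] + d2$dose[, , 3]),
               tolerance = 1e-12)
  expect_error(extract_planar(d, 9), "outside")
})

test_that("trilinear sampling agrees with the brute-force oracle on random grids", {
  d <- random_dose3d(seed = 7)
  set.seed(8)
  pts <- cbind(runif(50, 0, 4), runif(50, 0, 4), runif(50, 0, 4))
  v <- trilinear_sample(d, pts)
  vo <- vapply(seq_len(nrow(pts)), function(i) oracle_trilinear(d, pts[i, ]),
               numeric(1))
  expect_lt(max(abs(v - vo)), 1e-12)
})

test_that("chamber sampling is exact for constant and linear fields and matches a brute-force oracle", {
  lay <- subset_chambers(chamber_layout(), c(-30, 30), c(-30, 30))
  xs <- seq(-35, 35, by = 1)
  const <- planar_dose(c(-35, -35), c(1, 1),
                       matrix(2.5, length(xs), length(xs)))
  expect_equal(sample_at_chambers(const, lay)$values,
               rep(2.5, nrow(lay$positions)), tolerance = 1e-12)
  lin <- planar_dose(c(-35, -35), c(1, 1),
                     matrix(3 + 0.02 * xs, length(xs), length(xs)))
  cg <- sample_at_chambers(lin, lay)
  expect_equal(cg$values, 3 + 0.02 * lay$positions$x_mm, tolerance = 1e-12)
  # random field against an independent bilinear implementation
  set.seed(3)
  rnd <- planar_dose(c(-35, -35), c(1, 1),
                     matrix(runif(length(xs)^2), length(xs)))
  v <- sample_at_chambers(rnd, lay)$values
  vo <- vapply(seq_len(nrow(lay$positions)), function(i) {
    x <- lay$positions$x_mm[i]; y <- lay$positions$y_mm[i]
    fi <- x + 35; fj <- y + 35
    i0 <- floor(fi); j0 <- floor(fj); wi <- fi - i0; wj <- fj - j0
    (1 - wi) * (1 - wj) * rnd$values[i0 + 1, j0 + 1] +
      wi * (1 - wj) * rnd$values[i0 + 2, j0 + 1] +
      (1 - wi) * wj * rnd$values[i0 + 1, j0 + 2] +
      wi * wj * rnd$values[i0 + 2, j0 + 2]
  }, numeric(1))
  expect_lt(max(abs(v - vo)), 1e-12)
  # chambers outside the extent are reported
  small <- planar_dose(c(-5, -5), c(1, 1), matrix(1, 11, 11))
  expect_error(sample_at_chambers(small, lay), "outside the planar extent")
})

test_that("chamber-to-grid resampling is exact for linear fields and round-trips at chamber centers", {
  lay <- subset_chambers(chamber_layout(), c(-30, 30), c(-30, 30))
  vals <- 2 + 0.05 * lay$positions$x_mm
  pl <- resample_chambers_to_grid(chamber_grid(lay, vals), 1)
  xs <- planar_axis(pl, 1)
  expect_equal(pl$values[, 5], 2 + 0.05 * xs, tolerance = 1e-12)
  # constant field stays constant
  plc <- resample_chambers_to_grid(chamber_grid(lay, rep(4, length(vals))), 1)
  expect_true(all(abs(plc$values - 4) < 1e-12))
  # resample then re-sample at chamber centers returns the original values
  set.seed(9)
  vr <- runif(length(vals))
  # exact only when the fine spacing divides the pitch (cell edges align)
  plr <- resample_chambers_to_grid(chamber_grid(lay, vr), 7.62 / 4)
  back <- sample_at_chambers(plr, lay)$values
  expect_lt(max(abs(back - vr)), 1e-12)
  expect_error(resample_chambers_to_grid(chamber_grid(lay, vr), 0),
               "spacing")
})

test_that("unpopulated lattice corners become NA pixels and nothing is extrapolated", {
  lay <- chamber_layout() # corners unpopulated
  cg <- chamber_grid(lay, rep(1, 1020))
  pl <- resample_chambers_to_grid(cg, 7.62 / 2)
  expect_true(is.na(pl$values[1, 1]))
  expect_true(is.na(pl$values[pl$dim[1], pl$dim[2]]))
  expect_equal(pl$values[ceiling(pl$dim[1] / 2), ceiling(pl$dim[2] / 2)], 1)
  xs <- planar_axis(pl, 1)
  expect_lte(max(xs), max(lay$positions$x_mm))
})

test_that("detector-response convolution is identity at sigma 0, reproduces its sigma on an impulse, and shifts with the field", {
  n <- 61
  imp <- matrix(0, n, n); imp[31, 31] <- 1
  pl <- planar_dose(c(-30, -30), c(1, 1), imp)
  expect_identical(convolve_response(pl, 0)$values, imp)
  sm <- convolve_response(pl, 2)$values
  # fitted sigma from second moments, within 2%
  xs <- seq(-30, 30)
  sig <- sqrt(sum(sm * outer(xs^2, rep(1, n))) / sum(sm))
  expect_equal(sig, 2, tolerance = 0.02)
  # mass conserved away from borders
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # constant field interior unchanged
  cst <- convolve_response(planar_dose(c(0, 0), c(1, 1),
                                       matrix(3, 30, 30)), 2)
  expect_lt(max(abs(cst$values - 3)), 1e-6)
  # shift invariance on interior pixels
  imp2 <- matrix(0, n, n); imp2[36, 31] <- 1
  sm2 <- convolve_response(planar_dose(c(-30, -30), c(1, 1), imp2), 2)$values
  expect_lt(max(abs(sm2[11:51 + 5, ] - sm[11:51, ])), 1e-9)
})

test_that("percent-error maps follow the global-normalization arithmetic", {
  lay <- subset_chambers(chamber_layout(), c(-10, 10), c(-10, 10))
  n <- nrow(lay$positions)
  a <- chamber_grid(lay, rep(1, n))
  expect_equal(percent_error_map(a, a)$average_pct, 0)
  b <- chamber_grid(lay, rep(1.01, n))
  expect_equal(percent_error_map(a, b)$average_pct, 1, tolerance = 1e-9)
  # two-value toy: ref (1, 2), test (1, 1.9) -> errors (0%, 5%), average 2.5%
  p1 <- planar_dose(c(0, 0), c(1, 1), matrix(c(1, 2), 1, 2))
  p2 <- planar_dose(c(0, 0), c(1, 1), matrix(c(1, 1.9), 1, 2))
  pe <- percent_error_map(p1, p2)
  expect_equal(as.numeric(pe$map), c(0, 5))
  expect_equal(pe$average_pct, 2.5)
  z <- chamber_grid(lay, rep(0, n))
  expect_error(percent_error_map(z, a), "all-zero reference")
})

test_that("profiles are symmetric for symmetric fields and reproduce the engine penumbra width", {
  ph <- fix_cal_phantom()
  p <- engine_params()
  d <- compute_beam_dose(beam(0, c(-20, 20, -50, 50)), ph, p,
                         z_range = c(-1, 1))
  pl <- extract_planar(d, 3.5)
  pr <- extract_profile(pl, "x", 0)
  v <- pr$dose / max(pr$dose)
  expect_lt(max(abs(v - rev(v))), 1e-9)
  # constant field profile
  flat <- extract_profile(planar_dose(c(-5, -5), c(1, 1),
                                      matrix(2, 11, 11)), "y", 0)
  expect_true(all(flat$dose == 2))
  # 80-20% penumbra width vs the closed form for an erf edge:
  # width = sigma * (qnorm(0.8) - qnorm(0.2)), at the isocenter plane
  sel <- pr$pos_mm >= 10 & pr$pos_mm <= 32 # strictly monotone penumbra part
  xr <- pr$pos_mm[sel]
  vr <- v[sel]
  w80_20 <- approx(vr, xr, xout = 0.2)$y - approx(vr, xr, xout = 0.8)$y
  expect_equal(w80_20, p$penumbra_sigma_mm * (qnorm(0.8) - qnorm(0.2)),
               tolerance = 0.1)
  expect_error(extract_profile(pl, "x", 1000), "outside")
})

test_that("chamber-grid and planar files round-trip through the text dialect", {
  lay <- subset_chambers(chamber_layout(), c(-20, 20), c(-20, 20))
  set.seed(5)
  vals <- signif(runif(nrow(lay$positions)), 6)
  f <- tempfile(fileext = ".tsv")
  write_chamber_grid(chamber_grid(lay, vals), f)
  cg2 <- read_chamber_grid(f)
  expect_equal(cg2$values, vals, tolerance = 1e-12)
  expect_equal(cg2$layout$positions$x_mm, lay$positions$x_mm,
               tolerance = 1e-6)
  expect_equal(cg2$layout$oemp_depth_mm, 3.5)
  unlink(f)
  pl <- planar_dose(c(-3, -2), c(1, 1),
                    matrix(signif(runif(12), 6), 4, 3), plane_depth_mm = 5.5)
  f2 <- tempfile(fileext = ".tsv")
  write_planar_dose(pl, f2)
  pl2 <- read_planar_dose(f2)
  expect_equal(pl2$values, pl$values, tolerance = 1e-12)
  expect_equal(pl2$plane_depth_mm, 5.5)
  expect_equal(pl2$origin_mm, pl$origin_mm)
  unlink(f2)
})

test_that("full-lattice chamber files keep unpopulated corners as NA", {
  lay <- chamber_layout()
  vals <- rep(1.5, 1020)
  f <- tempfile(fileext = ".tsv")
  write_chamber_grid(chamber_grid(lay, vals), f)
  lines <- readLines(f)
  body <- lines[!grepl("^#", lines)]
  first_row <- strsplit(body[2], "\t")[[1]]
  expect_equal(first_row[2], "NA") # corner cell
  cg <- read_chamber_grid(f)
  expect_equal(nrow(cg$layout$positions), 1020L)
  unlink(f)
})
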