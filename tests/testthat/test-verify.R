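test_that("composite planes follow linearity, commutativity, and the zero-offset identity", {
  ph <- fix_ver_phantom()
  model <- demp_truth_model()
  p <- engine_params()
  # single gantry-0 beam with delta_d(0) = 0: corrected == uncorrected
  plan0 <- rt_plan(beam(0, c(-20, 20, -20, 20)))
  c0 <- corrected_composite(plan0, model, ph, p)
  u0 <- uncorrected_composite(plan0, ph, p, model = model)
  expect_equal(c0$values, u0$values, tolerance = 1e-12)
  # two identical beams double the single-beam plane
  plan2 <- rt_plan(list(beam(130, c(-20, 20, -20, 20)),
                        beam(130, c(-20, 20, -20, 20))))
  c2 <- corrected_composite(plan2, model, ph, p)
  c1 <- corrected_composite(rt_plan(beam(130, c(-20, 20, -20, 20))),
                            model, ph, p)
  expect_equal(c2$values, 2 * c1$values, tolerance = 1e-12)
  # beam order is irrelevant
  pa <- rt_plan(list(beam(50, c(-15, 15, -15, 15)),
                     beam(130, c(-20, 20, -20, 20))))
  pb <- rt_plan(rev(pa$beams))
  expect_equal(corrected_composite(pa, model, ph, p)$values,
               corrected_composite(pb, model, ph, p)$values,
               tolerance = 1e-12)
  # an oblique beam with nonzero offset separates the two composites
  cu <- uncorrected_composite(rt_plan(beam(130, c(-20, 20, -20, 20))),
                              ph, p, model = model)
  expect_gt(max(abs(c1$values - cu$values)), 0)
  # a beam inside an excluded interval is refused with the beam named
  bad <- rt_plan(list(beam(0, c(-10, 10, -10, 10)),
                      beam(265, c(-10, 10, -10, 10))))
  expect_error(corrected_composite(bad, model, ph, p), "beam 2")
})

test_that("uncorrected equals corrected when every offset is zero, and an opposed-pair difference is confined to the offset beam", {
  ph <- fix_ver_phantom()
  p <- engine_params()
  flat <- demp_model(rho_g_cm3 = 1.0) # all offsets zero, water anode
  plan <- rt_plan(list(beam(0, c(-20, 20, -20, 20)),
                       beam(180, c(-20, 20, -20, 20))))
  expect_equal(corrected_composite(plan, flat, ph, p)$values,
               uncorrected_composite(plan, ph, p, model = flat)$values,
               tolerance = 1e-12)
  # offset only at 180: composite difference equals that beam's plane shift
  shift <- demp_model(delta_d_mm = c(rep(0, 18), 4), rho_g_cm3 = 1.0)
  cc <- corrected_composite(plan, shift, ph, p)
  cu <- uncorrected_composite(plan, ph, p, model = shift)
  d180c <- extract_planar(compute_beam_dose(plan$beams[[2]], ph, p,
                                            z_range = c(-2, 7)),
                          emp_depth(shift, 180))
  d180u <- extract_planar(compute_beam_dose(plan$beams[[2]], ph, p,
                                            z_range = c(-2, 7)), 3.5)
  expect_equal(cc$values - cu$values, d180c$values - d180u$values,
               tolerance = 1e-9)
})

test_that("gamma is zero on self-comparison and exactly one for a uniform 3%-of-max offset", {
  u <- planar_dose(c(-10, -10), c(1, 1), matrix(1, 21, 21))
  g0 <- gamma_map(u, u, gamma_criteria(3, 3))
  expect_true(all(g0$gamma_map[g0$roi_mask] == 0))
  expect_equal(g0$passing_rate_pct, 100)
  up <- planar_dose(c(-10, -10), c(1, 1), matrix(1 + 0.03 * 1, 21, 21))
  g1 <- gamma_map(u, up, gamma_criteria(3, 3))
  expect_equal(max(g1$gamma_map[g1$roi_mask]), 1, tolerance = 1e-12)
  expect_equal(g1$passing_rate_pct, 100)
  expect_error(gamma_map(planar_dose(c(0, 0), c(1, 1), matrix(0, 3, 3)),
                         u, gamma_criteria()), "reference maximum")
})

test_that("gamma of a laterally shifted field matches the brute-force oracle", {
  ref <- blob_planar()
  ev <- blob_planar(origin = c(-13, -15)) # 2 mm lateral shift
  for (cr in list(c(3, 3), c(3, 2), c(2, 1))) {
    g <- gamma_map(ref, ev, gamma_criteria(cr[1], cr[2]))
    o <- oracle_gamma(ref, ev, cr[1], cr[2])
    expect_lt(max(abs(g$gamma_map - o), na.rm = TRUE), 1e-6)
    expect_equal(is.na(g$gamma_map), is.na(o))
  }
})

test_that("gamma passing rates are monotone in the distance criterion and the search radius", {
  case <- fix_oblique_case()
  rep <- run_verification(case$plan, case$truth, case$measurement,
                          case$phantom)
  expect_gte(rep$passing_rates_pct[["3%/3mm"]],
             rep$passing_rates_pct[["3%/2mm"]])
  # enlarging the search disc never increases gamma
  ref <- blob_planar()
  ev <- blob_planar(origin = c(-12, -16), amp = 2.1)
  g_small <- gamma_map(ref, ev, gamma_criteria(3, 3), search_factor = 1)
  g_big <- gamma_map(ref, ev, gamma_criteria(3, 3), search_factor = 3)
  expect_true(all(g_big$gamma_map <= g_small$gamma_map + 1e-12,
                  na.rm = TRUE))
  expect_true(all(g_big$gamma_map >= 0, na.rm = TRUE))
})

test_that("correcting the calculation never hurts an oblique beam with a true offset", {
  case <- fix_oblique_case()
  rc <- run_verification(case$plan, case$truth, case$measurement,
                         case$phantom)
  ru <- run_verification(case$plan, case$truth, case$measurement,
                         case$phantom, corrected = FALSE)
  expect_gte(rc$passing_rates_pct[["3%/3mm"]],
             ru$passing_rates_pct[["3%/3mm"]])
  expect_gt(rc$passing_rates_pct[["3%/3mm"]], 99)
  expect_lt(ru$passing_rates_pct[["3%/3mm"]], 90)
  # the report is reproducible bit for bit
  rc2 <- run_verification(case$plan, case$truth, case$measurement,
                          case$phantom)
  expect_identical(rc, rc2)
})

test_that("the paired one-sided t-test matches its textbook formula and edge conventions", {
  expect_equal(paired_one_sided_t(c(97, 98, 99), c(97, 98, 99)), 0.5)
  # constant positive differences: infinite t, p -> 0
  expect_equal(paired_one_sided_t(c(98, 99, 97), c(97, 98, 96)), 0)
  expect_equal(paired_one_sided_t(c(97, 98, 96), c(98, 99, 97)), 1)
  set.seed(21)
  a <- 95 + runif(6, 0, 5)
  b <- 94 + runif(6, 0, 5)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(6))
  p_formula <- pt(tstat, df = 5, lower.tail = FALSE)
  expect_lt(abs(paired_one_sided_t(a, b) - p_formula), 1e-10)
  expect_error(paired_one_sided_t(1:3, 1:2))
})
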