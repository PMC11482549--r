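geom <- channel_geometry()        # 1 mm x 50 um x 15 mm
flow <- flow_conditions()         # 40 uL/min, medium at 37 C

test_that("mean inlet velocity matches Q/(w h) and the device operating point", {
  expect_equal(mean_inlet_velocity(geom, flow), 0.013, tolerance = 0.03)
  expect_equal(mean_inlet_velocity(geom, flow),
               flow$q_m3_s / (geom$width_m * geom$height_m), tolerance = 1e-12)
  expect_equal(mean_inlet_velocity(geom, flow_conditions(q_ul_min = 0)), 0)
  # continuity: doubling the height halves the velocity
  tall <- channel_geometry(height_m = 100e-6)
  expect_equal(mean_inlet_velocity(tall, flow),
               mean_inlet_velocity(geom, flow) / 2, tolerance = 1e-12)
})

test_that("plates wall shear follows 6 mu Q / (w h^2) and is linear in Q and mu", {
  tau <- plates_wall_shear(geom, flow)
  expect_equal(tau, 10 * 6 * 0.964e-3 * (40e-9 / 60) / (1e-3 * (50e-6)^2),
               tolerance = 1e-12)
  expect_equal(tau, 15.42, tolerance = 1e-3)

  expect_equal(plates_wall_shear(geom, flow_conditions(q_ul_min = 80)),
               2 * tau, tolerance = 1e-12)
  thick <- flow_conditions(mu_pa_s = 2 * 0.964e-3)
  expect_equal(plates_wall_shear(geom, thick), 2 * tau, tolerance = 1e-12)
  expect_warning(plates_wall_shear(channel_geometry(1e-4, 50e-6), flow),
                 "w >> h")
})

test_that("design flow rate inverts the shear formula", {
  q <- design_flow_rate(geom, flow, 12)
  expect_equal(q, 31.12, tolerance = 1e-3)
  # round trip through the forward formula
  expect_equal(plates_wall_shear(geom, flow_conditions(q_ul_min = q)), 12,
               tolerance = 1e-9)
  expect_equal(design_flow_rate(geom, flow, 24), 2 * q, tolerance = 1e-12)
  expect_error(design_flow_rate(geom, flow, -1), "> 0")
})

test_that("Reynolds number is computed for both characteristic lengths", {
  dh <- 2 * geom$width_m * geom$height_m / (geom$width_m + geom$height_m)
  u <- mean_inlet_velocity(geom, flow)
  expect_equal(reynolds_number(geom, flow, "hydraulic_diameter"),
               1012 * u * dh / 0.964e-3, tolerance = 1e-12)
  expect_equal(reynolds_number(geom, flow, "hydraulic_diameter"), 1.33,
               tolerance = 0.01)
  expect_equal(reynolds_number(geom, flow, "height"), 0.70, tolerance = 0.01)
  expect_equal(reynolds_number(geom, flow_conditions(q_ul_min = 0)), 0)
  expect_error(reynolds_number(geom, flow, "width"))
})

test_that("duct velocity field satisfies no-slip and conserves mass", {
  field <- duct_velocity_field(geom, flow, n_y = 65, n_z = 65)
  walls <- field$y_m %in% range(field$y_m) | field$z_m %in% range(field$z_m)
  expect_true(all(field$u_m_s[walls] == 0))
  expect_true(all(field$u_m_s >= 0))

  # trapezoid integral over the cross-section recovers Q within 0.1%
  u <- matrix(field$u_m_s, nrow = 65, byrow = TRUE)
  wts <- function(m) c(0.5, rep(1, m - 2), 0.5)
  dy <- geom$width_m / 64; dz <- geom$height_m / 64
  q_num <- as.numeric(wts(65) %*% u %*% wts(65)) * dy * dz
  expect_equal(q_num, flow$q_m3_s, tolerance = 1e-3)
})

test_that("max/mean velocity ratio hits the plates limit and the square-duct value", {
  # wide duct: parallel-plates parabola gives u_max/u_mean -> 3/2
  wide <- channel_geometry(width_m = 200e-3, height_m = 1e-3)
  fw <- duct_velocity_field(wide, flow, n_y = 201, n_z = 41)
  ratio_wide <- max(fw$u_m_s) / (flow$q_m3_s / (200e-3 * 1e-3))
  expect_equal(ratio_wide, 1.5, tolerance = 0.004)

  # square duct against the independent finite-difference Poisson oracle
  sq <- channel_geometry(width_m = 1e-3, height_m = 1e-3)
  fs <- duct_velocity_field(sq, flow, n_y = 101, n_z = 101, n_terms = 301)
  ratio_sq <- max(fs$u_m_s) / (flow$q_m3_s / 1e-6)
  expect_equal(ratio_sq, 2.096, tolerance = 0.005)
  expect_equal(ratio_sq, fd_duct_ratio(1e-3, 1e-3, n = 121), tolerance = 0.01)
})

test_that("series and finite-difference solutions agree across aspect ratios", {
  for (ar in c(1, 4, 20)) {
    g <- channel_geometry(width_m = ar * 1e-3, height_m = 1e-3)
    f <- duct_velocity_field(g, flow, n_y = 81, n_z = 81, n_terms = 201)
    ratio <- max(f$u_m_s) / (flow$q_m3_s / (g$width_m * g$height_m))
    expect_equal(ratio, fd_duct_ratio(g$width_m, g$height_m, n = 101),
                 tolerance = 0.01)
  }
})

test_that("wall shear profile is symmetric, corner-stagnant and plates-limited", {
  prof <- duct_wall_shear_profile(geom, flow)
  bottom <- prof[prof$wall == "bottom", ]
  # corners carry no shear
  expect_lt(abs(bottom$shear_dyn_cm2[1]), 1e-6 * max(bottom$shear_dyn_cm2))
  expect_lt(abs(bottom$shear_dyn_cm2[nrow(bottom)]),
            1e-6 * max(bottom$shear_dyn_cm2))
  # mirror symmetry about the channel midline
  expect_equal(bottom$shear_dyn_cm2, rev(bottom$shear_dyn_cm2),
               tolerance = 1e-9)
  # wall-centre shear approaches the plates value for a wide channel
  centre <- bottom$shear_dyn_cm2[(nrow(bottom) + 1) / 2]
  expect_equal(centre, plates_wall_shear(geom, flow), tolerance = 0.1)
  # and to within 2% at w/h = 100
  g100 <- channel_geometry(width_m = 100e-3, height_m = 1e-3)
  p100 <- duct_wall_shear_profile(g100, flow)
  b100 <- p100[p100$wall == "bottom", ]
  expect_equal(b100$shear_dyn_cm2[(nrow(b100) + 1) / 2],
               plates_wall_shear(g100, flow), tolerance = 0.02)
})

test_that("duct shear scales linearly in flow rate and viscosity", {
  prof1 <- duct_wall_shear_profile(geom, flow, n_samples = 17)
  prof2 <- duct_wall_shear_profile(geom, flow_conditions(q_ul_min = 80),
                                   n_samples = 17)
  expect_equal(prof2$shear_dyn_cm2, 2 * prof1$shear_dyn_cm2,
               tolerance = 1e-12)
  prof3 <- duct_wall_shear_profile(
    geom, flow_conditions(mu_pa_s = 3 * 0.964e-3), n_samples = 17)
  expect_equal(prof3$shear_dyn_cm2, 3 * prof1$shear_dyn_cm2,
               tolerance = 1e-12)
})
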