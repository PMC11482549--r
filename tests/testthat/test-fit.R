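test_that("amplitude deviation is the mean relative magnitude residual", {
  gt <- bbb_ground_truth()
  sp <- circuit_impedance(stage_preset("i", gt$stages$i)$model,
                          frequency_grid())
  expect_equal(amplitude_deviation(sp, sp), 0)

  # uniform 2% offset sits exactly at the acceptance boundary
  off <- sp
  off$z_mod_ohm <- 1.02 * sp$z_mod_ohm
  expect_equal(amplitude_deviation(sp, off), 2, tolerance = 1e-12)

  # scale invariance: multiplying both magnitudes by c > 0 changes nothing
  a <- sp; b <- off
  a$z_mod_ohm <- 37.5 * a$z_mod_ohm
  b$z_mod_ohm <- 37.5 * b$z_mod_ohm
  expect_equal(amplitude_deviation(a, b), amplitude_deviation(sp, off),
               tolerance = 1e-12)

  mism <- circuit_impedance(stage_preset("i", gt$stages$i)$model,
                            frequency_grid(1, 1e4))
  expect_error(amplitude_deviation(sp, mism), "grid")
})

test_that("powell minimizer solves smooth benchmark problems", {
  # convex quadratic with strong coupling
  quad <- function(x) sum((x - c(1, -2, 3))^2) + 0.9 * x[1] * x[2]
  res <- powell_minimize(quad, c(10, 10, 10))
  expect_true(res$converged)
  grad_norm <- sqrt(sum((2 * (res$par - c(1, -2, 3)) +
                           c(0.9 * res$par[2], 0.9 * res$par[1], 0))^2))
  expect_lt(grad_norm, 1e-4)

  # Rosenbrock valley in 2-d
  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  res2 <- powell_minimize(rosen, c(-1.2, 1), max_iterations = 500)
  expect_equal(res2$par, c(1, 1), tolerance = 1e-3)
})

test_that("a pure resistor is fitted exactly from its plateau", {
  sp <- circuit_impedance(resistor("R_medium", 740), frequency_grid())
  preset <- structure(list(stage = "i", model = resistor("R_medium", 1)),
                      class = "stage_preset")
  fit <- fit_circuit(sp, preset,
                     fit_config(initial_values = c(R_medium = 300)))
  expect_equal(fit$parameters[["R_medium"]], 740, tolerance = 1e-6)
  expect_lt(fit$deviation_percent, 1e-6)
  expect_true(fit$accepted)
})

test_that("noiseless stage-i spectra are recovered from a 2x-off start", {
  truth <- c(CPE_electrode_Q = 1e-5, CPE_electrode_n = 0.85, R_medium = 500,
             R_matrix = 5000, CPE_matrix_Q = 1e-6, CPE_matrix_n = 0.9)
  sp <- circuit_impedance(stage_preset("i", truth)$model, frequency_grid())
  fit <- fit_circuit(sp, teerfit:::stage_preset_from_init("i"),
                     fit_config(initial_values = truth * 2))
  expect_lt(fit$deviation_percent, 0.1)
  expect_true(all(abs(fit$parameters / truth[names(fit$parameters)] - 1)
                  < 0.05))
})

test_that("the fit never reports a worse deviation than its start", {
  gt <- bbb_ground_truth()
  sp <- generate_spectrum(stage_preset("ii", gt$stages$ii),
                          noise = noise_model(0.02, 1, seed = 3))
  set.seed(9)
  for (k in 1:3) {
    start <- gt$stages$ii * exp(stats::runif(length(gt$stages$ii), -1, 1))
    start[grepl("_n$", names(start))] <-
      pmin(start[grepl("_n$", names(start))], 1)
    cfg <- fit_config(initial_values = start, max_iterations = 30,
                      restarts = 1)
    fit <- fit_circuit(sp, teerfit:::stage_preset_from_init("ii"), cfg)
    expect_lte(fit$deviation_percent, fit$initial_deviation_percent)
  }
})

test_that("acceptance flag is strict at the 2% boundary", {
  gt <- bbb_ground_truth()
  sp <- circuit_impedance(stage_preset("i", gt$stages$i)$model,
                          frequency_grid())
  off <- sp
  off$z_mod_ohm <- 1.02 * sp$z_mod_ohm
  # a uniform 2% magnitude offset sits at the boundary ...
  expect_equal(amplitude_deviation(sp, off), 2, tolerance = 1e-12)
  # ... and the rule is strict: exactly 2 is not accepted
  accepted <- function(dev, threshold = 2) dev < threshold
  expect_false(accepted(2))
  expect_true(accepted(2 - 1e-9))
})

test_that("staged calibration recovers the shared truth and propagates bounds", {
  fx <- staged_fixture()
  fits <- staged_fits_fixture()
  expect_named(fits, c("i", "ii", "iii", "iv"))
  truth_iv <- fx$truth$stages$iv

  rel <- fits$iv$parameters / truth_iv[names(fits$iv$parameters)]
  r_terms <- grep("^R_", names(rel), value = TRUE)
  expect_true(all(abs(rel[r_terms] - 1) < 0.05))
  n_terms <- grep("_n$", names(rel), value = TRUE)
  expect_true(all(abs(fits$iv$parameters[n_terms] - truth_iv[n_terms])
                  < 0.05))
  expect_equal(fits$iv$parameters[["R_TEER"]], truth_iv[["R_TEER"]],
               tolerance = 0.1)
})

test_that("stage-i-only input yields a single fit without propagation", {
  fx <- staged_fixture()
  expect_warning(
    fits <- staged_calibration(fx$noiseless$spectra["i"]),
    "missing stage")
  expect_named(fits, "i")
  expect_lt(fits$i$deviation_percent, 0.1)
})

test_that("TEER extraction multiplies barrier resistance by the sensing area", {
  t1 <- extract_teer(c(R_TEER = 7587.2), area_cm2 = 2.35e-3)
  expect_equal(t1$teer_ohm_cm2, 17.83, tolerance = 1e-3)
  expect_identical(t1$teer_ohm_cm2, 7587.2 * 2.35e-3)

  expect_equal(extract_teer(c(R_TEER = 1000), area_cm2 = 1e-3)$teer_ohm_cm2,
               1, tolerance = 1e-12)
  expect_error(extract_teer(c(R_matrix = 1000)), "R_TEER")
  expect_error(extract_teer(c(R_TEER = 10), area_cm2 = 0), "> 0")
})

test_that("barrier assessment classifies via the mean magnitude ratio", {
  gt <- bbb_ground_truth()
  grid <- frequency_grid()
  control <- circuit_impedance(stage_preset("i", gt$stages$i)$model, grid)
  mature <- circuit_impedance(stage_preset("iv", gt$stages$iv)$model, grid)

  same <- assess_barrier(control, control)
  expect_equal(same$mean_magnitude_ratio, 1, tolerance = 1e-12)
  expect_equal(same$classification, "immature")

  res <- assess_barrier(control, mature, crossover_hz = 50)
  expect_gt(res$mean_magnitude_ratio, 1)
  expect_equal(res$classification, "mature")

  expect_error(assess_barrier(control, mature, crossover_hz = 1e6),
               "crossover")
})

test_that("tidy and glance summarise fits as tibbles", {
  fits <- staged_fits_fixture()
  td <- tidy(fits$iv)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, stage_parameter_names("iv"))
  gl <- glance(fits$iv)
  expect_equal(gl$stage, "iv")
  expect_true(gl$accepted)
})
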