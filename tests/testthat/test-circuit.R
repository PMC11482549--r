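test_that("resistor impedance is frequency-independent and CPE follows its power law", {
  r <- resistor("R", 1000)
  z <- element_impedance(r, c(1, 1e3, 1e6))
  expect_equal(z, rep(complex(real = 1000, imaginary = 0), 3))

  # n = 1 reduces to an ideal capacitor 1/(j w C)
  zc <- element_impedance(cpe("C", 1e-6, 1), 1e3)
  expect_equal(Mod(zc), 1000, tolerance = 1e-12)
  expect_equal(Arg(zc) * 180 / pi, -90, tolerance = 1e-12)

  # hand-derived: Q = 1e-5, n = 0.8, f = 100 Hz
  z8 <- element_impedance(cpe("C", 1e-5, 0.8), 2 * pi * 100)
  expect_equal(Mod(z8), 1 / (1e-5 * (2 * pi * 100)^0.8), tolerance = 1e-12)
  expect_equal(Mod(z8), 577.3725, tolerance = 1e-6)
  expect_equal(Arg(z8) * 180 / pi, -72, tolerance = 1e-12)
})

test_that("element constructors reject invalid parameters", {
  expect_error(resistor("R", -5), "> 0")
  expect_error(cpe("C", 0, 0.9), "> 0")
  expect_error(cpe("C", 1e-6, 1.2), "0, 1")
  expect_error(element_impedance(resistor("R", 10), -1), "> 0")
})

test_that("series adds impedances and parallel adds admittances", {
  s <- circuit_impedance(circuit_series(resistor("a", 100), resistor("b", 200)),
                         c(1, 50, 1e5))
  expect_equal(s$z_mod_ohm, rep(300, 3))
  expect_equal(s$z_phase_deg, rep(0, 3))

  # parallel RC at wRC = 1: |Z| = R/sqrt(2), phase -45 deg
  f_c <- 1000 / (2 * pi)
  p <- circuit_impedance(circuit_parallel(resistor("R", 1000),
                                          cpe("C", 1e-6, 1)), f_c)
  expect_equal(p$z_mod_ohm, 1000 / sqrt(2), tolerance = 1e-9)
  expect_equal(p$z_phase_deg, -45, tolerance = 1e-9)
})

test_that("series composition is associative pointwise", {
  a <- resistor("a", 123)
  b <- cpe("b", 2e-6, 0.8)
  c3 <- cpe("c", 5e-7, 0.95)
  f <- frequency_grid()
  z1 <- circuit_impedance(circuit_series(a, circuit_series(b, c3)), f)
  z2 <- circuit_impedance(circuit_series(a, b, c3), f)
  expect_equal(z1$z_mod_ohm, z2$z_mod_ohm, tolerance = 1e-12)
  expect_equal(z1$z_phase_deg, z2$z_phase_deg, tolerance = 1e-12)
})

test_that("n = 1 CPE magnitude falls with log-log slope -1", {
  f <- frequency_grid()
  sp <- circuit_impedance(cpe("C", 1e-6, 1), f)
  slope <- stats::coef(stats::lm(log10(sp$z_mod_ohm) ~ log10(f)))[[2]]
  expect_equal(slope, -1, tolerance = 1e-6)
})

test_that("evaluator matches the brute-force real/imaginary oracle on random trees", {
  set.seed(7)
  f <- c(1, 17.3, 420, 9999, 1e5)
  for (k in 1:100) {
    model <- random_circuit()
    got <- circuit_impedance(model, f)
    want <- oracle_spectrum(model, f)
    expect_equal(got$z_mod_ohm, want$z_mod_ohm, tolerance = 1e-12)
    expect_equal(got$z_phase_deg, want$z_phase_deg, tolerance = 1e-12)
  }
})

test_that("random R/CPE trees are passive: Re(Z) >= 0 and phase in [-90, 0]", {
  set.seed(11)
  omega <- 2 * pi * frequency_grid()
  for (k in 1:50) {
    model <- random_circuit()
    z <- teerfit:::eval_impedance(model, omega)
    expect_true(all(Re(z) >= -1e-12 * Mod(z)))
    ph <- Arg(z) * 180 / pi
    expect_true(all(ph <= 1e-9 & ph >= -90 - 1e-9))
  }
})

test_that("duplicate leaf names are rejected", {
  expect_error(circuit_series(resistor("x", 1), resistor("x", 2)),
               "unique")
})

test_that("stage presets expose the canonical element sets", {
  expect_setequal(circuit_leaf_names(teerfit:::stage_topology("iv")),
                  c("CPE_cells_E", "R_medium", "R_TEER", "CPE_BBB",
                    "R_matrix_cells", "CPE_matrix_cells"))
  expect_setequal(stage_parameter_names("i"),
                  c("CPE_electrode_Q", "CPE_electrode_n", "R_medium",
                    "R_matrix", "CPE_matrix_Q", "CPE_matrix_n"))

  params <- c(CPE_electrode_Q = 1e-5, CPE_electrode_n = 0.85, R_medium = 500,
              R_matrix = 5000, CPE_matrix_Q = 1e-6, CPE_matrix_n = 0.9)
  p <- stage_preset("i", params)
  expect_s3_class(p, "stage_preset")

  expect_error(stage_preset("i", params[-4]), "R_matrix")
  expect_error(stage_preset("i", c(params, bogus = 1)), "bogus")
})

test_that("stage presets rise capacitively at low frequency and plateau at R_medium", {
  gt <- bbb_ground_truth()
  for (st in c("i", "ii", "iii", "iv")) {
    p <- stage_preset(st, gt$stages[[st]])
    sp <- circuit_impedance(p$model, c(1, 1e5))
    expect_gt(sp$z_mod_ohm[1], sp$z_mod_ohm[2])
    # far above every corner frequency only the series resistance survives
    hf <- circuit_impedance(p$model, 1e8)
    expect_equal(hf$z_mod_ohm, gt$stages[[st]][["R_medium"]],
                 tolerance = 1e-3)
  }
})

test_that("bode_table preserves length and spectra round-trip through CSV", {
  gt <- bbb_ground_truth()
  sp <- circuit_impedance(stage_preset("i", gt$stages$i)$model,
                          frequency_grid(1, 100, 1),
                          metadata = list(stage = "i", amplitude_mV = 10))
  expect_equal(nrow(bode_table(sp)), 3)

  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  back <- read_spectrum_csv(path)
  expect_equal(back$freq_hz, sp$freq_hz, tolerance = 1e-9)
  expect_equal(back$z_mod_ohm, sp$z_mod_ohm, tolerance = 1e-9)
  expect_equal(back$z_phase_deg, sp$z_phase_deg, tolerance = 1e-9)
  expect_equal(attr(back, "metadata")$stage, "i")

  expect_error(impedance_spectrum(numeric(0), numeric(0), numeric(0)),
               "empty")
  # a spectrum filtered down to zero rows violates the nonempty invariant
  expect_error(bode_table(sp[sp$freq_hz > 1e6, ]), "empty")
})
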