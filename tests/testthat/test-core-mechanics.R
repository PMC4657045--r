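# Closed-form beam-on-elastic-foundation relations and calibration
# arithmetic.

test_that("wave number and radius of curvature follow the sinusoid geometry", {
  expect_equal(wave_number(2 * pi), 1)
  expect_equal(wave_number(21.14), 2 * pi / 21.14)
  expect_equal(wave_number(3.11), 2 * pi / 3.11)

  expect_equal(radius_of_curvature(2 * pi, 1), 1)
  # frozen from the independent oracle 1 / (A q^2)
  expect_equal(radius_of_curvature(21.14, 2.16), 5.2407866, tolerance = 1e-6)
  expect_equal(radius_of_curvature(3.11, 0.72), 0.34027383, tolerance = 1e-6)
  # symbolic cross-check: curvature kappa(x) of y = A sin(q x) maximizes at
  # the crest where |y''| = A q^2
  A <- 2.16; q <- wave_number(21.14)
  xg <- seq(0, 21.14, by = 1e-4)
  kap <- abs(-A * q^2 * sin(q * xg)) / (1 + (A * q * cos(q * xg))^2)^1.5
  expect_equal(radius_of_curvature(21.14, A), 1 / max(kap), tolerance = 1e-6)

  expect_error(wave_number(0), "wavelength")
  expect_error(radius_of_curvature(10, 0), "straight")
})

test_that("bending energy per length reproduces the reported pN values", {
  mech <- std_mech()
  # 0.47 pN is printed to 2 decimals; the exact value is 0.4672
  expect_identical(round(as_pN(bending_energy_per_length(mech, um(4.18))), 2),
                   0.47)
  expect_equal(as_pN(bending_energy_per_length(mech, um(0.54))), 27.99,
               tolerance = 0.005)
  # total energy scales linearly in contour length; straight rod limit
  expect_equal(bending_energy(mech, um(4.18), um(27.5)),
               27.5e-6 * bending_energy_per_length(mech, um(4.18)))
  expect_equal(bending_energy_per_length(mech, 1e12), 0, tolerance = 1e-30)
  # R^-2 scaling: halving R quadruples the value
  expect_equal(bending_energy_per_length(mech, um(2)),
               4 * bending_energy_per_length(mech, um(4)))
})

test_that("foundation modulus, wavelength and critical force are consistent", {
  mech <- std_mech()
  expect_equal(foundation_modulus(1, 1), 1)
  expect_equal(foundation_modulus(1e-3, nm(95)), 1.0526316e4,
               tolerance = 1e-6)
  expect_equal(foundation_modulus(1, 2), foundation_modulus(1, 1) / 2)

  expect_equal(buckling_wavelength(1, 1), 2 * pi)
  # round trip pins E_c at the 21.14 um wavelength
  ec <- foundation_modulus_from_wavelength(mech, um(21.14))
  expect_equal(ec, 0.1274, tolerance = 1e-3)
  expect_equal(as_um(buckling_wavelength(mech, ec)), 21.14)

  expect_equal(critical_force(1, 1), 2)
  expect_equal(as_pN(critical_force(mech, ec)), 2.885, tolerance = 1e-3)
  # brute-force oracle: minimum of F(q) = EI q^2 + E_c / q^2
  qs <- exp(seq(log(1e4), log(1e7), length.out = 400001))
  fmin <- min(mech$flexural_rigidity * qs^2 + ec / qs^2)
  expect_equal(critical_force(mech, ec), fmin, tolerance = 1e-6)

  # reported force pair is consistent with the lambda^-2 scaling:
  # F(21.14) / F(3.11) matches 73.8 / 1.6 to ~0.2%
  ratio <- (21.14 / 3.11)^2
  expect_equal(ratio, 73.8 / 1.6, tolerance = 0.005)
})

test_that("combined relations equal the composed continuum forms", {
  mech <- std_mech()
  withr::with_seed(42, {
    for (i in 1:100) {
      k <- 10^runif(1, -6, -2)
      ld <- 10^runif(1, -8.5, -6.5)
      expect_equal(combined_wavelength(mech, k, ld),
                   buckling_wavelength(mech, foundation_modulus(k, ld)))
      expect_equal(combined_critical_force(mech, k, ld),
                   critical_force(mech, foundation_modulus(k, ld)))
    }
  })
  # log-log derivatives with respect to spacing: +1/4 and -1/2
  ld <- nm(c(18, 23, 36, 51, 95))
  lam <- vapply(ld, function(s) combined_wavelength(mech, 1e-3, s),
                numeric(1))
  fc <- vapply(ld, function(s) combined_critical_force(mech, 1e-3, s),
               numeric(1))
  expect_equal(diff(log(lam)) / diff(log(ld)), rep(0.25, 4))
  expect_equal(diff(log(fc)) / diff(log(ld)), rep(-0.5, 4))
})

test_that("round trip wavelength <-> foundation modulus over random draws", {
  withr::with_seed(7, {
    for (i in 1:50) {
      ei <- 10^runif(1, -24, -21)
      ec <- 10^runif(1, -3, 2)
      expect_equal(foundation_modulus_from_wavelength(
        ei, buckling_wavelength(ei, ec)), ec, tolerance = 1e-10)
    }
  })
})

test_that("operations are unit-consistent: rescaling preserves ratios", {
  # evaluate the wavelength relation in SI and in um/pN units; the
  # dimensionless ratio lambda / L_d must agree
  ei_si <- std_mech()$flexural_rigidity
  k_si <- 1e-3; ld_si <- nm(95)
  r_si <- combined_wavelength(ei_si, k_si, ld_si) / ld_si
  r_sim <- combined_wavelength(ei_si * 1e24, k_si * 1e6, ld_si * 1e6) /
    (ld_si * 1e6)
  expect_equal(r_si, r_sim)
})

test_that("spacing from density matches the reported table", {
  expect_equal(spacing_from_density(1), 1)
  expect_equal(kinesin_spacing_nm(1), 1000)
  got <- kinesin_spacing_nm(c(112, 381, 749, 1800, 2982))
  expect_true(all(abs(got - c(95, 51, 36, 23, 18)) <= 1))
  expect_identical(kinesin_spacing_nm(381), 51)
  expect_identical(kinesin_spacing_nm(2982), 18)
  expect_error(spacing_from_density(-1), "density")
})

test_that("fluorescence and Sauerbrey calibrations are linear", {
  expect_equal(density_from_fluorescence(0), 0)
  expect_equal(density_from_fluorescence(1), 27.4)
  expect_equal(density_from_fluorescence(100), 2740)
  expect_error(density_from_fluorescence(-1), "intensity")
  # Sauerbrey: C = 17.7 ng cm^-2 Hz^-1 = 1.77e-7 kg m^-2 Hz^-1, a 10 Hz
  # shift of a 120 kDa protein
  got <- sauerbrey_mass_density(-10, 1.77e-7, 120)
  manual <- 10 * 1.77e-7 / 120 * 6.02214076e23
  expect_equal(got, manual)
  expect_equal(sauerbrey_mass_density(20, 1.77e-7, 120), 2 * manual)
})

test_that("constructors validate and derive fields", {
  mech <- std_mech()
  expect_equal(mech$flexural_rigidity,
               mech$youngs_modulus * mech$second_moment)
  expect_error(filament_mechanics(-1, 1), "youngs_modulus")
  fs <- foundation_spec(spring_stiffness = 1e-3, spacing = nm(95))
  expect_equal(fs$foundation_modulus, 1e-3 / nm(95))
  expect_error(foundation_spec(1e-3, nm(95), foundation_modulus = 99),
               "inconsistent")
})
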