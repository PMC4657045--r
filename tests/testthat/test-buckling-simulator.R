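# Quasi-static rod-on-springs simulator: discretization checks, wavelength
# selection, Euler limit, and finite-length effects.

test_that("discrete energies match closed forms", {
  EI <- std_EI_sim()
  model <- rod_model(length = 20, node_spacing = 0.1, EI = EI,
                     k_spring = 1e-9, anchor_spacing = 1)
  # straight rest shape stores nothing
  expect_equal(as.numeric(total_energy(model, rest_shape(model))), 0)
  # circular arc of radius R: energy EI L / (2 R^2) within 1% at 200 nodes
  R <- 30
  th <- seq(0, 20 / R, length.out = model$n_nodes)
  arc <- cbind(R * sin(th), R * (1 - cos(th)))
  expect_equal(as.numeric(total_energy(model, arc)), EI * 20 / (2 * R^2),
               tolerance = 0.01)
  # a pure transverse offset of one anchor node costs k delta^2 / 2
  stiff <- rod_model(length = 20, node_spacing = 0.1, EI = 1e-9,
                     k_spring = 5, anchor_spacing = 2,
                     axial_stiffness = 1e-9)
  shape <- rest_shape(stiff)
  a <- stiff$anchor_idx[3]
  shape[a, 2] <- 0.3
  e <- total_energy(stiff, shape)
  expect_equal(attr(e, "components")[["foundation"]], 5 * 0.3^2 / 2)
  expect_error(total_energy(model, rest_shape(model)[-1, ]), "matrix")
})

test_that("relaxation at zero strain stays straight with ~zero energy", {
  m <- sim_scenario(4, length = 16, node_spacing = 0.4)
  r <- relax(m, 0, seed = 1)
  expect_true(r$converged)
  expect_lt(max(abs(r$shape[, 2])), 1e-3)
  expect_lt(r$energy, 1e-6 * m$EI / m$node_spacing)
})

test_that("buckled equilibria lie below the straight branch", {
  m <- sim_scenario(4, length = 16, node_spacing = 0.4)
  strain <- 0.008   # twice the onset strain of the scenario
  r <- relax(m, strain, seed = 1)
  expect_gt(max(abs(r$shape[, 2])), 0.05)
  straight <- rest_shape(m)
  straight[, 1] <- straight[, 1] * (1 - strain)
  expect_lt(r$energy, as.numeric(total_energy(m, straight)))
})

test_that("selected wavelength matches the continuum theory within 10%", {
  for (lam_t in c(3, 5, 8)) {
    m <- sim_scenario(lam_t)
    res <- simulate_ramp(m, 0.012, 8, seed = 11)
    lam <- res$dominant_wavelength[8]
    expect_lt(abs(lam - lam_t) / lam_t, 0.1)
    # crest spacing cross-check of the periodogram estimate
    sh <- res$shapes[[8]]
    cr <- detect_crests(filament_trace(sh[, 1], sh[, 2], strain = 0.012),
                        noise_sigma = 0, window = lam_t / 6,
                        amplitude_floor = 0.02)
    lam_crest <- 2 * mean(diff(cr$position))
    expect_lt(abs(lam_crest - lam) / lam, 0.1)
  }
})

test_that("wavelength is insensitive to seed and to strain-step count", {
  lam_t <- 2.5
  m <- sim_scenario(lam_t, length = 30, node_spacing = 0.125)
  l8 <- simulate_ramp(m, 0.012, 8, seed = 4)$dominant_wavelength[8]
  l32 <- simulate_ramp(m, 0.012, 32, seed = 4)$dominant_wavelength[32]
  expect_lt(abs(l8 - l32) / l32, 0.05)
  s1 <- simulate_ramp(m, 0.012, 8, seed = 1)$dominant_wavelength[8]
  s42 <- simulate_ramp(m, 0.012, 8, seed = 42)$dominant_wavelength[8]
  expect_lt(abs(s1 - s42) / s42, 0.05)
})

test_that("vanishing foundation gives single-crest Euler buckling", {
  EI <- std_EI_sim()
  fc_euler <- 4 * pi^2 * EI / 20^2
  m <- rod_model(length = 20, node_spacing = 0.2, EI = EI, k_spring = 1e-8,
                 anchor_spacing = 1, axial_stiffness = fc_euler / 0.004)
  res <- simulate_ramp(m, 0.02, 10, seed = 3)
  sh <- res$shapes[[10]]
  cr <- detect_crests(filament_trace(sh[, 1], sh[, 2], strain = 0.02),
                      noise_sigma = 0, window = 4, detrend = "none")
  expect_equal(nrow(cr), 1)
  expect_gt(max(abs(sh[, 2])), 1)
})

test_that("crest count rises as anchor spacing shrinks (mode transition)", {
  EI <- std_EI_sim()
  k <- 80
  counts <- vapply(c(1.9, 1.02, 0.72, 0.46, 0.36), function(ld) {
    fc <- 2 * sqrt(k / ld * EI)
    m <- rod_model(length = 20, node_spacing = 0.12, EI = EI, k_spring = k,
                   anchor_spacing = ld, axial_stiffness = fc / 0.004)
    res <- simulate_ramp(m, 0.01, 6, seed = 5)
    sh <- res$shapes[[6]]
    lam_t <- 2 * pi * (EI * ld / k)^0.25
    nrow(detect_crests(filament_trace(sh[, 1], sh[, 2], strain = 0.01),
                       noise_sigma = 0, window = lam_t / 6,
                       amplitude_floor = 0.02, detrend = "none"))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[5], counts[1])
})

test_that("onset strain is non-decreasing in foundation stiffness", {
  EI <- std_EI_sim()
  ka <- 2 * sqrt(16.29 / 0.4 * EI) / 0.004
  onsets <- vapply(c(0.25, 1, 4), function(f) {
    m <- rod_model(length = 25, node_spacing = 0.2, EI = EI,
                   k_spring = 16.29 * f, anchor_spacing = 0.4,
                   axial_stiffness = ka)
    simulate_ramp(m, 0.016, 16, seed = 9)$onset_strain
  }, numeric(1))
  expect_false(anyNA(onsets))
  expect_true(all(diff(onsets) >= 0))
  expect_gt(onsets[3], onsets[1])
})

test_that("axial force at onset approaches the finite-length critical force", {
  lam_t <- 5
  m <- sim_scenario(lam_t, eps_c = 0.004)
  res <- simulate_ramp(m, 0.008, 16, seed = 7, amplitude_threshold = 0.02)
  i_on <- which(res$max_amplitude > 0.02)[1]
  ec <- m$k_spring / m$anchor_spacing
  f_th <- finite_length_critical_force(m$EI, ec, m$length, "clamped")$force
  expect_lt(abs(res$axial_force[i_on] - f_th) / f_th, 0.15)
})

test_that("doubling the node count changes the converged energy by < 1%", {
  lam_t <- 5
  m1 <- sim_scenario(lam_t, node_spacing = 0.25)
  m2 <- sim_scenario(lam_t, node_spacing = 0.125)
  e1 <- simulate_ramp(m1, 0.01, 5, seed = 4)$energy[5]
  e2 <- simulate_ramp(m2, 0.01, 5, seed = 4)$energy[5]
  expect_lt(abs(e1 - e2) / abs(e2), 0.01)
})

test_that("dominant wavelength reads pure, noisy and mixed sinusoids", {
  x <- seq(0, 40, by = 0.1)
  expect_equal(dominant_wavelength(x, sin(2 * pi * x / 10)), 10,
               tolerance = 0.02)
  withr::with_seed(8, {
    noisy <- sin(2 * pi * x / 10) + rnorm(length(x), 0, 0.05)
  })
  expect_equal(dominant_wavelength(x, noisy), 10, tolerance = 0.05)
  mixed <- 0.8 * sin(2 * pi * x / 10) + 0.2 * sin(2 * pi * x / 4.2)
  expect_equal(dominant_wavelength(x, mixed), 10, tolerance = 0.05)
  # flat profile is below threshold
  expect_true(is.na(dominant_wavelength(x, rep(0.01 * sin(x), 1))))
})

test_that("finite-length critical force has the right limits", {
  mech <- std_mech()
  EI <- mech$flexural_rigidity
  # no foundation: classical Euler load of the boundary type
  L <- um(20)
  expect_equal(finite_length_critical_force(mech, 0, L, "pinned")$force,
               pi^2 * EI / L^2)
  expect_equal(finite_length_critical_force(mech, 0, L, "clamped")$force,
               4 * pi^2 * EI / L^2)
  expect_equal(finite_length_critical_force(mech, 0, L)$mode, 1L)
  # long-rod limit approaches the continuum critical force within 2%
  ec <- foundation_modulus_from_wavelength(mech, um(5))
  f_cont <- critical_force(mech, ec)
  f_long <- finite_length_critical_force(mech, ec, 50 * um(5))$force
  expect_lt(abs(f_long - f_cont) / f_cont, 0.02)
  # finite rods always pay a penalty, growing for short rods
  ls <- um(c(2, 3.5, 5, 10, 25, 100))
  fs <- vapply(ls, function(l)
    finite_length_critical_force(mech, ec, l)$force, numeric(1))
  expect_true(all(fs >= f_cont * (1 - 1e-12)))
  expect_true(all(diff(fs[1:3]) < 0))   # penalty grows as L drops below ~lam
  expect_error(finite_length_critical_force(mech, ec, -1), "length")
})
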