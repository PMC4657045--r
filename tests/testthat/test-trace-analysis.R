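# Crest detection and buckle measurement on filament centerline traces.

test_that("applied strain uses the elongated substrate as reference", {
  expect_equal(applied_strain(8.0, 8.0), 0)
  expect_equal(applied_strain(8.0, 7.0), 0.125)
  expect_equal(applied_strain(8.0, 4.0), 0.5)
  expect_error(applied_strain(8.0, 8.5), "extension")
})

test_that("crest detection finds the analytic extrema of a sinusoid", {
  tr <- sine_trace(10, 2, length = 40, step = 0.1)
  cr <- detect_crests(tr, noise_sigma = 0)
  expect_equal(nrow(cr), 8)
  expect_equal(cr$position, seq(2.5, 37.5, by = 5), tolerance = 0.02)
  expect_equal(cr$sign, rep(c(1, -1), 4))
  # robust to optical-scale noise
  trn <- sine_trace(10, 2, length = 40, step = 0.1, noise = 0.05, seed = 5)
  crn <- detect_crests(trn, noise_sigma = 0.05)
  expect_equal(nrow(crn), 8)
  expect_true(all(abs(crn$position - cr$position) < 0.3))
})

test_that("straight filaments yield no crests", {
  expect_equal(nrow(detect_crests(straight_trace(seed = 2))), 0)
  expect_equal(nrow(detect_crests(straight_trace(seed = 9))), 0)
  cs <- measure_buckle(straight_trace(seed = 4))
  expect_equal(cs$n_crests, 0)
  expect_true(is.na(cs$wavelength))
})

test_that("measure_buckle recovers generator wavelength and amplitude", {
  m <- measure_buckle(sine_trace(10, 2, length = 40), noise_sigma = 0)
  expect_equal(m$wavelength, 10, tolerance = 0.01)
  expect_equal(m$amplitude, 2, tolerance = 0.01)
  expect_equal(m$wavenumber, 2 * pi / m$wavelength)
  # radius consistent with the closed-form sinusoid curvature
  m2 <- measure_buckle(sine_trace(21.14, 2.16, length = 64, step = 0.05),
                       noise_sigma = 0)
  expect_equal(m2$radius, 5.24, tolerance = 0.02)
  # single-crest trace: the crest contour spans the whole filament
  half <- sine_trace(55, 2.5, length = 27.5, step = 0.05)
  mh <- measure_buckle(half, noise_sigma = 0)
  expect_equal(mh$n_crests, 1)
  expect_true(is.na(mh$wavelength))
  expect_equal(mh$crest_contour_length, 27.5, tolerance = 0.05 * 27.5)
})

test_that("estimates are invariant to translation and point reversal", {
  tr <- sine_trace(10, 2, length = 40, noise = 0.03, seed = 11)
  m0 <- measure_buckle(tr)
  p <- tr$points
  m_tr <- measure_buckle(filament_trace(p$x + 13.7, p$y - 5.2, strain = 0.1))
  m_rev <- measure_buckle(filament_trace(rev(p$x), rev(p$y), strain = 0.1))
  expect_equal(m_tr$wavelength, m0$wavelength)
  expect_equal(m_tr$amplitude, m0$amplitude)
  expect_equal(m_rev$wavelength, m0$wavelength)
  expect_equal(m_rev$amplitude, m0$amplitude)
})

test_that("amplitude estimate is nearly unbiased at SNR >= 10", {
  a_true <- 0.5
  withr::with_seed(21, {
    amps <- replicate(300, {
      tr <- sine_trace(runif(1, 8, 15), a_true,
                       length = runif(1, 20, 40), noise = 0.05,
                       phase = runif(1, 0, 2 * pi))
      measure_buckle(tr)$amplitude
    })
  })
  expect_lt(abs(mean(amps, na.rm = TRUE) / a_true - 1), 0.02)
})

test_that("detected crest count is monotone in programmed amplitude", {
  counts <- vapply(c(0.05, 0.12, 0.2, 0.5, 1, 2), function(a) {
    tr <- sine_trace(8, a, length = 40, noise = 0.03, seed = 31)
    measure_buckle(tr, noise_sigma = 0.03)$n_crests
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)   # below the amplitude floor
  expect_equal(counts[6], 10)
})

test_that("critical strain is the first strain with a crest", {
  cnd <- data.frame(kinesin_nM = 50, spacing_nm = 36, wavelength_um = 8,
                    wavelength_sd_um = 1.5, amplitude_um = 1,
                    amplitude_sd_um = 0.2, critical_strain = 0.012,
                    n_filaments = 1)
  strains <- c(0.004, 0.008, 0.012, 0.02, 0.05)
  traces <- lapply(seq_along(strains), function(i) {
    generate_trace(cnd, strains[i], seed = 100 + i, length_range = c(30, 40),
                   filament_id = "f1")
  })
  expect_equal(critical_strain(strain_series(traces)), 0.012)
  # programmed onset at 0.02
  cnd$critical_strain <- 0.02
  traces <- lapply(seq_along(strains), function(i) {
    generate_trace(cnd, strains[i], seed = 200 + i, length_range = c(30, 40),
                   filament_id = "f1")
  })
  expect_equal(critical_strain(strain_series(traces)), 0.02)
  # an all-straight series never buckles
  flat <- lapply(seq_along(strains), function(i) {
    tr <- straight_trace(seed = 300 + i, strain = strains[i])
    tr$filament_id <- "f1"
    tr
  })
  expect_true(is.na(critical_strain(strain_series(flat))))
  expect_error(strain_series(list()), "empty")
})

test_that("aggregation filters misaligned filaments and tracks orderings", {
  cnd <- default_conditions()[1, ]
  withr::with_seed(61, {
    traces <- lapply(1:30, function(i) {
      generate_trace(cnd, 0.025, seed = NULL, filament_id = sprintf("f%d", i))
    })
  })
  # one strongly tilted filament must be excluded by the orientation filter
  tilt <- sine_trace(10, 1, length = 30, kinesin_nM = 10, strain = 0.025)
  p <- tilt$points
  ang <- 35 * pi / 180
  tilted <- filament_trace(p$x * cos(ang) - p$y * sin(ang),
                           p$x * sin(ang) + p$y * cos(ang),
                           strain = 0.025, kinesin_nM = 10,
                           filament_id = "tilted")
  ds <- experiment_dataset(c(traces, list(tilted)))
  agg <- aggregate_condition(ds, kinesin_nM = 10, strain = 0.025)
  expect_equal(agg$n_traces, 30)
  expect_true(agg$wavelength_sd > 0)
  # single matching trace: SD reported as 0
  ds1 <- experiment_dataset(traces[1])
  agg1 <- aggregate_condition(ds1, kinesin_nM = 10, strain = 0.025)
  expect_equal(agg1$n_traces, 1)
  expect_equal(agg1$wavelength_sd, 0)
  expect_error(aggregate_condition(ds, kinesin_nM = 999, strain = 0.025),
               "no traces")
})

test_that("programmed strain trends survive aggregation", {
  cnd <- default_conditions()[1, ]
  mk <- function(strain, seed0) {
    withr::with_seed(seed0, {
      lapply(1:30, function(i) {
        generate_trace(cnd, strain, seed = NULL,
                       filament_id = sprintf("f%d", i))
      })
    })
  }
  ds <- experiment_dataset(c(mk(0.025, 71), mk(0.125, 72)))
  lo <- aggregate_condition(ds, 10, 0.025)
  hi <- aggregate_condition(ds, 10, 0.125)
  # wavelength falls and amplitude rises with strain
  expect_gt(lo$wavelength_mean, hi$wavelength_mean)
  expect_lt(lo$amplitude_mean, hi$amplitude_mean)
})
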