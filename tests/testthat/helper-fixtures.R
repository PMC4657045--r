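# Shared fixtures: the standard microtubule mechanics used throughout
# (E = 49.75 MPa at sparse kinesin, I = 32.82e-32 m^4), and sinusoidal
# trace builders.

std_mech <- function() filament_mechanics(MPa(49.75), 32.82e-32)

# EI of the standard microtubule in simulator units (pN um^2)
std_EI_sim <- function() std_mech()$flexural_rigidity * 1e24

sine_trace <- function(wavelength, amplitude, length = 40, step = 0.1,
                       phase = 0, noise = 0, strain = 0.1, seed = NULL,
                       kinesin_nM = NA_real_, filament_id = "MT1") {
  gen <- function() {
    x <- seq(0, length, by = step)
    y <- amplitude * sin(2 * pi * x / wavelength + phase)
    if (noise > 0) {
      x <- x + stats::rnorm(length(x), 0, noise)
      y <- y + stats::rnorm(length(y), 0, noise)
    }
    filament_trace(x, y, strain = strain, kinesin_nM = kinesin_nM,
                   filament_id = filament_id)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

straight_trace <- function(length = 30, step = 0.1, noise = 0.05,
                           strain = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- seq(0, length, by = step)
    filament_trace(x + stats::rnorm(length(x), 0, noise),
                   stats::rnorm(length(x), 0, noise), strain = strain)
  })
}

# small foundation-supported rod scenario with onset at ~0.4% strain;
# lam_t is the continuum buckling wavelength in um
sim_scenario <- function(lam_t, anchor_spacing = lam_t / 10,
                         length = 6 * lam_t, eps_c = 0.004,
                         node_spacing = min(anchor_spacing, lam_t / 20),
                         EI = std_EI_sim(), k_scale = 1, ...) {
  k <- (2 * pi)^4 * EI * anchor_spacing / lam_t^4 * k_scale
  fc <- 2 * sqrt(k / anchor_spacing * EI)
  rod_model(length = length, node_spacing = node_spacing, EI = EI,
            k_spring = k, anchor_spacing = anchor_spacing,
            axial_stiffness = fc / eps_c, ...)
}
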