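#' Filament mechanical constants
#'
#' Bundles the Young's modulus `E`, the cross-section second moment of area
#' `I` and their product, the flexural rigidity `EI`, of a microtubule (or any
#' slender elastic filament).
#'
#' @param youngs_modulus Young's modulus in Pa (use [MPa()] for MPa inputs).
#' @param second_moment Second moment of area in m^4.
#' @return An object of class `filament_mechanics` with fields
#'   `youngs_modulus`, `second_moment` and `flexural_rigidity` (N m^2).
#' @examples
#' mech <- filament_mechanics(MPa(49.75), 32.82e-32)
#' mech$flexural_rigidity   # ~1.63e-23 N m^2
#' @export
filament_mechanics <- function(youngs_modulus, second_moment) {
  check_positive(youngs_modulus, "youngs_modulus")
  check_positive(second_moment, "second_moment")
  structure(
    list(
      youngs_modulus = youngs_modulus,
      second_moment = second_moment,
      flexural_rigidity = youngs_modulus * second_moment
    ),
    class = "filament_mechanics"
  )
}

#' @export
print.filament_mechanics <- function(x, ...) {
  cat("<filament_mechanics>\n")
  cat(sprintf("  E  = %.4g MPa\n", as_MPa(x$youngs_modulus)))
  cat(sprintf("  I  = %.4g m^4\n", x$second_moment))
  cat(sprintf("  EI = %.4g N m^2\n", x$flexural_rigidity))
  invisible(x)
}

# Accept either a filament_mechanics object or a bare EI value.
.ei <- function(mech) {
  if (inherits(mech, "filament_mechanics")) mech$flexural_rigidity
  else check_positive(mech, "EI")
}

#' Elastic foundation specification
#'
#' A Winkler-type foundation made of discrete linear springs (kinesin
#' molecules) of stiffness `k_spring` spaced `L_d` apart. The continuum
#' foundation modulus is `E_c = k_spring / L_d`.
#'
#' @param spring_stiffness Spring constant of one kinesin, N/m.
#' @param spacing Kinesin spacing `L_d`, m.
#' @param foundation_modulus Foundation modulus `E_c`, N/m^2. Computed from
#'   the other two when omitted; when all three are given they must be
#'   mutually consistent.
#' @return An object of class `foundation_spec`.
#' @export
foundation_spec <- function(spring_stiffness = NULL, spacing = NULL,
                            foundation_modulus = NULL) {
  if (is.null(foundation_modulus)) {
    check_positive(spring_stiffness, "spring_stiffness")
    check_positive(spacing, "spacing")
    foundation_modulus <- spring_stiffness / spacing
  } else if (!is.null(spring_stiffness) && !is.null(spacing)) {
    check_positive(foundation_modulus, "foundation_modulus")
    if (abs(foundation_modulus - spring_stiffness / spacing) >
        1e-9 * foundation_modulus) {
      stop("foundation_modulus inconsistent with spring_stiffness / spacing",
           call. = FALSE)
    }
  } else {
    check_positive(foundation_modulus, "foundation_modulus")
  }
  structure(
    list(spring_stiffness = spring_stiffness, spacing = spacing,
         foundation_modulus = foundation_modulus),
    class = "foundation_spec"
  )
}

.ec <- function(ec) {
  if (inherits(ec, "foundation_spec")) ec$foundation_modulus
  else check_positive(ec, "foundation_modulus")
}

#' Wave number of a buckle
#'
#' @param wavelength Buckling wavelength (any length unit).
#' @return Wave number `q = 2 pi / wavelength` in the reciprocal unit.
#' @examples
#' wave_number(21.14)  # per-um wave number of a 21.14 um buckle
#' @export
wave_number <- function(wavelength) {
  check_positive(wavelength, "wavelength")
  2 * pi / wavelength
}

#' Minimum radius of curvature of a sinusoidal buckle
#'
#' For a buckle `y = A sin(q x)` the curvature is maximal at the crests where
#' it equals `A q^2`, so the minimum radius of curvature is `1 / (A q^2)`.
#'
#' @param wavelength Buckling wavelength (any length unit).
#' @param amplitude Buckling amplitude, same unit.
#' @return Radius of curvature in the same unit.
#' @examples
#' radius_of_curvature(21.14, 2.16)  # ~5.24 um
#' @export
radius_of_curvature <- function(wavelength, amplitude) {
  check_positive(wavelength, "wavelength")
  if (any(!is.finite(amplitude)) || any(amplitude < 0)) {
    stop("`amplitude` must be finite and >= 0", call. = FALSE)
  }
  if (any(amplitude == 0)) {
    stop("straight filament, curvature undefined (amplitude = 0)",
         call. = FALSE)
  }
  q <- wave_number(wavelength)
  1 / (amplitude * q^2)
}

#' Bending energy stored in a buckled filament
#'
#' A filament bent at radius of curvature `R` over contour length `L` stores
#' `E_bend = EI L / (2 R^2)`. The per-unit-length value `EI / (2 R^2)` has
#' force units and is how bending energies are usually reported (e.g. in pN
#' times the crest contour length).
#'
#' @param mech A [filament_mechanics()] object (or a bare `EI` in N m^2).
#' @param radius Radius of curvature, m.
#' @param contour_length Contour length over which the curvature acts, m.
#' @return `bending_energy()`: energy in J; `bending_energy_per_length()`:
#'   force in N.
#' @examples
#' mech <- filament_mechanics(MPa(49.75), 32.82e-32)
#' as_pN(bending_energy_per_length(mech, um(4.18)))  # ~0.47 pN
#' @export
bending_energy_per_length <- function(mech, radius) {
  check_positive(radius, "radius")
  .ei(mech) / (2 * radius^2)
}

#' @rdname bending_energy_per_length
#' @export
bending_energy <- function(mech, radius, contour_length) {
  check_positive(contour_length, "contour_length", allow_zero = TRUE)
  bending_energy_per_length(mech, radius) * contour_length
}

#' Foundation modulus from spring constant and spacing
#'
#' @param spring_stiffness Spring constant, N/m.
#' @param spacing Spring spacing `L_d`, m.
#' @return Foundation modulus `E_c = k / L_d`, N/m^2.
#' @export
foundation_modulus <- function(spring_stiffness, spacing) {
  check_positive(spring_stiffness, "spring_stiffness")
  check_positive(spacing, "spacing")
  spring_stiffness / spacing
}

#' Buckling wavelength on a continuum elastic foundation
#'
#' A long filament of flexural rigidity `EI` on a foundation of modulus `E_c`
#' buckles with wavelength `lambda = 2 pi (EI / E_c)^(1/4)`.
#' `foundation_modulus_from_wavelength()` is the exact inverse,
#' `E_c = EI (2 pi / lambda)^4`.
#'
#' @param mech A [filament_mechanics()] object or bare `EI` (N m^2).
#' @param ec Foundation modulus (N/m^2) or a [foundation_spec()].
#' @param wavelength Buckling wavelength, m.
#' @return Wavelength in m, or foundation modulus in N/m^2.
#' @examples
#' mech <- filament_mechanics(MPa(49.75), 32.82e-32)
#' ec <- foundation_modulus_from_wavelength(mech, um(21.14))
#' as_um(buckling_wavelength(mech, ec))  # 21.14
#' @export
buckling_wavelength <- function(mech, ec) {
  2 * pi * (.ei(mech) / .ec(ec))^0.25
}

#' @rdname buckling_wavelength
#' @export
foundation_modulus_from_wavelength <- function(mech, wavelength) {
  check_positive(wavelength, "wavelength")
  .ei(mech) * (2 * pi / wavelength)^4
}

#' Critical buckling force on a continuum elastic foundation
#'
#' The minimum over wave number of `F(q) = EI q^2 + E_c / q^2`, attained at
#' the selected buckling wavelength: `F_c = 2 sqrt(E_c EI)`, equivalently
#' `2 EI (2 pi / lambda)^2`. The prefactor is configurable because reported
#' absolute values in the literature differ in the constant convention; the
#' scaling with `E_c` and `EI` does not.
#'
#' @inheritParams buckling_wavelength
#' @param constant Prefactor multiplying `sqrt(E_c EI)` (default 2, the
#'   continuum minimum).
#' @return Force in N.
#' @export
critical_force <- function(mech, ec, constant = 2) {
  check_positive(constant, "constant")
  constant * sqrt(.ec(ec) * .ei(mech))
}

#' Combined foundation relations in terms of spring constant and spacing
#'
#' Substituting `E_c = k / L_d` into the continuum results gives
#' `lambda = 2 pi (EI L_d / k)^(1/4)` and `F_c = 2 sqrt(k EI / L_d)`: the
#' quarter-power dependence of wavelength, and inverse-square-root dependence
#' of critical force, on kinesin spacing.
#'
#' @inheritParams buckling_wavelength
#' @param k_spring Spring constant, N/m.
#' @param spacing Spring spacing `L_d`, m.
#' @param constant Prefactor as in [critical_force()].
#' @return Wavelength in m, or force in N.
#' @export
combined_wavelength <- function(mech, k_spring, spacing) {
  buckling_wavelength(mech, foundation_modulus(k_spring, spacing))
}

#' @rdname combined_wavelength
#' @export
combined_critical_force <- function(mech, k_spring, spacing, constant = 2) {
  critical_force(mech, foundation_modulus(k_spring, spacing), constant)
}

#' Mean spacing from an areal density
#'
#' Molecules scattered at areal density `rho` have mean nearest-lattice
#' spacing `rho^(-1/2)`. `kinesin_spacing_nm()` is the presentation-layer
#' convenience for densities quoted per square micrometre, returning integer
#' nanometres.
#'
#' @param density Areal density, m^-2 (SI) for `spacing_from_density()`;
#'   um^-2 for `kinesin_spacing_nm()`.
#' @return Spacing in m, or rounded nm.
#' @examples
#' kinesin_spacing_nm(c(112, 381, 749, 1800, 2982))
#' @export
spacing_from_density <- function(density) {
  check_positive(density, "density")
  density^-0.5
}

#' @rdname spacing_from_density
#' @export
kinesin_spacing_nm <- function(density) {
  round(1e3 * spacing_from_density(density))
}

#' Kinesin density from fluorescence intensity
#'
#' Linear calibration between fluorescence intensity (arbitrary units) on the
#' substrate and kinesin areal density, default factor 27.4 molecules um^-2
#' per au.
#'
#' @param intensity Fluorescence intensity, au (>= 0).
#' @param factor Calibration factor, molecules um^-2 au^-1.
#' @return Density in molecules per um^2.
#' @export
density_from_fluorescence <- function(intensity, factor = 27.4) {
  if (!is.numeric(intensity) || any(!is.finite(intensity)) ||
      any(intensity < 0)) {
    stop("`intensity` must be finite and >= 0", call. = FALSE)
  }
  check_positive(factor, "factor")
  intensity * factor
}

#' Areal molecule density from a quartz-crystal-microbalance frequency shift
#'
#' The Sauerbrey relation converts a resonance frequency shift into deposited
#' areal mass, `delta_m = C |delta_f|`; dividing by the molar mass and
#' multiplying by Avogadro's number gives molecules per area. Units are free
#' as long as they are consistent: with `mass_sensitivity` in kg m^-2 Hz^-1
#' and `molar_mass` in kg/mol the result is m^-2.
#'
#' @param freq_shift Frequency shift, Hz (sign ignored; deposition lowers the
#'   resonance frequency).
#' @param mass_sensitivity Sauerbrey mass sensitivity `C`, mass per area per Hz.
#' @param molar_mass Molar mass of the deposited species, mass per mole.
#' @return Molecules per area (reciprocal of the area unit in
#'   `mass_sensitivity`).
#' @export
sauerbrey_mass_density <- function(freq_shift, mass_sensitivity, molar_mass) {
  if (!is.numeric(freq_shift) || any(!is.finite(freq_shift))) {
    stop("`freq_shift` must be finite numeric", call. = FALSE)
  }
  check_positive(mass_sensitivity, "mass_sensitivity")
  check_positive(molar_mass, "molar_mass")
  abs(freq_shift) * mass_sensitivity / molar_mass * .N_AVOGADRO
}
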