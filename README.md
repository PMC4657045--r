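# mtbuckle

Analysis of compression-induced buckling of microtubules (MTs) supported on
a two-dimensional elastic substrate by kinesin cross-linkers.

An unsupported slender rod under axial compression buckles in the classical
single-arch Euler mode. A rod tethered to an elastic foundation instead
selects a finite buckling wavelength from the competition between bending
rigidity and foundation stiffness:

    lambda = 2 pi (EI / E_c)^(1/4),    F_c = 2 sqrt(E_c EI),
    E_c    = k / L_d

with `EI` the filament's flexural rigidity, `k` the stiffness of one
kinesin spring and `L_d` the spacing between anchored kinesins. These imply
a log-log slope of exactly +1/4 for wavelength, and -1/2 for critical
force, against spacing. Because bound kinesin also softens the MT lattice,
the package additionally provides a spacing-dependent Young's modulus
`E(L_d) = E0 L_d^n / (L_d^n + L*^n)` and the modified wavelength relation
`lambda = 2 pi (E(L_d) I L_d / k)^(1/4)`, from which the kinesin spring
constant can be extracted from wavelength-vs-spacing measurements.

The package covers the full analysis chain:

* **core mechanics** — the closed-form relations above, buckle geometry
  (wave number, sinusoid radius of curvature, bending energy `EI/(2R^2)`
  per unit length), and substrate calibration arithmetic (Sauerbrey
  frequency-shift-to-density conversion, fluorescence calibration,
  density-to-spacing).
* **kinesin softening** — calibration of the softening model from anchor
  measurements, the modified foundation model, and geometric-mean spring
  constant extraction.
* **trace analysis** — crest detection and per-crest wavelength /
  amplitude / curvature measurement from filament centerline traces,
  critical-strain detection, per-condition aggregation.
* **model fitting** — two-segment breakpoint ("transitional strain")
  regression, log-log slope and power-law exponent estimation, end-to-end
  fitting of the modified model.
* **buckling simulator** — a quasi-static discrete rod on transverse
  springs (energy minimization with analytic gradients) reproducing
  wavelength selection, the Euler-to-multiwave mode transition,
  strain-rate insensitivity and finite-length effects.
* **synthetic data** — a seeded generator producing noisy filament traces
  and full concentration-by-strain experiments with ground truth.

## Worked example

```r
library(mtbuckle)

# standard MT mechanics: E = 49.75 MPa (sparse kinesin), I = 32.82e-32 m^4
mech <- filament_mechanics(MPa(49.75), 32.82e-32)
mech
#> <filament_mechanics>
#>   E  = 49.75 MPa
#>   I  = 3.282e-31 m^4
#>   EI = 1.633e-23 N m^2

# bending energy per unit contour length at radius of curvature 4.18 um
round(as_pN(bending_energy_per_length(mech, um(4.18))), 2)
#> [1] 0.47   # pN

# kinesin densities (per um^2) -> spacings (nm)
kinesin_spacing_nm(c(112, 381, 749, 1800, 2982))
#> [1] 94 51 37 24 18

# calibrate the softening model on two anchor moduli
soft <- calibrate_softening(nm(c(95, 18)), MPa(c(49.75, 7.15)))
soft
#> <softening_model>
#>   family = hill (n = 2)
#>   E_MT^0 = 63.93 MPa
#>   L_d*   = 50.73 nm

# generate synthetic buckled filaments and measure them back
set.seed(1)
cnd <- default_conditions()[1, ]            # 10 nM / 95 nm condition
wls <- replicate(50, {
  tr <- generate_trace(cnd, strain = cnd$critical_strain)
  measure_buckle(tr)$wavelength
})
sprintf("recovered: %.2f +/- %.2f um (programmed 21.14 +/- 5.6)",
        mean(wls, na.rm = TRUE), sd(wls, na.rm = TRUE))
#> "recovered: 22.48 +/- 4.98 um (programmed 21.14 +/- 5.6)"

# extract the spring constant from noisy wavelength-vs-spacing summaries
ld  <- nm(c(95, 51, 36, 23, 18))
lam <- modified_wavelength(soft, 32.82e-32, 2.5e-4, ld)
fit <- fit_modified_model(ld, lam * exp(rnorm(5, 0, 0.05)), soft, 32.82e-32)
sprintf("spring constant: %.3g N/m (true 2.5e-4)", fit$k_spring)
#> "spring constant: 0.000245 N/m"
```

The numbers mean: a filament curved at 4.18 um radius stores 0.47 pN of
bending energy per micrometre of contour; densities of 112-2982 kinesins
per um^2 correspond to 94-18 nm anchor spacings; the two-anchor calibration
places the bare-MT modulus near 64 MPa with drastic softening below ~51 nm
spacing; the measurement pipeline recovers a programmed wavelength
distribution within sampling error; and the spring constant is recovered
within a few percent from 5%-noisy summaries.

A quasi-static compression simulation of a 30 um filament with anchors
every 0.4 um:

```r
m <- rod_model(length = 30, node_spacing = 0.1, EI = 16.33,  # pN um^2
               k_spring = 16.3, anchor_spacing = 0.4,
               axial_stiffness = 1.3e4)
res <- simulate_ramp(m, max_strain = 0.012, n_steps = 12, seed = 2)
res$onset_strain            # buckling onset (strain fraction)
tail(res$dominant_wavelength, 1)   # selected wavelength, um (theory: 5.0)
```

A thin command-line wrapper (`inst/cli/mtbuckle`) chains the stages via
files: `generate`, `measure`, `fit`, `simulate`, `report`.

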