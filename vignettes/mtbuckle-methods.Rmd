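---
title: "Methods: microtubule buckling on an elastic kinesin foundation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microtubule buckling on an elastic kinesin foundation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtbuckle)
```

## The physical problem

A microtubule (MT) lying on a soft elastomer substrate, tethered to it by
kinesin motor proteins (no ATP, so the motors act as passive cross-linkers),
is compressed axially when the substrate is compressed. An unsupported
slender rod under axial compression buckles in the classical Euler mode: one
long-wavelength arch. A rod laterally supported by an elastic foundation
instead selects a finite wavelength set by the competition between bending
stiffness and foundation stiffness, and buckles in a periodic multiwave
mode. The density of kinesin tethers controls which regime the filament is
in, and — because bound kinesin also softens the MT lattice — the observed
wavelength shrinks with kinesin density faster than the bare foundation
theory predicts.

`mtbuckle` implements this analysis end to end: the closed-form
foundation-model relations, the kinesin-softening modification, measurement
of buckling metrics from filament centerline traces, the statistical fits
connecting them, a quasi-static rod-on-springs simulator, and a
synthetic-data generator with known ground truth.

## Models

### Continuum elastic foundation

For a filament of Young's modulus $E$ and second moment of area $I$
(flexural rigidity $EI$) on a foundation of modulus $E_c$ (N/m$^2$):

$$\lambda = 2\pi\left(\frac{EI}{E_c}\right)^{1/4},\qquad
  F_c = 2\sqrt{E_c\,EI},\qquad E_c = \frac{k}{L_d},$$

where $k$ is the stiffness of one kinesin spring and $L_d$ the spacing
between anchored kinesins ($L_d = \rho^{-1/2}$ for areal density $\rho$).
Substituting $E_c$ gives $\lambda = 2\pi(EI\,L_d/k)^{1/4}$ and
$F_c = 2\sqrt{k\,EI/L_d}$: a log–log slope of exactly $+1/4$ for wavelength
and $-1/2$ for critical force against spacing. Buckle geometry is treated as
sinusoidal, $y = A\sin(qx)$ with $q = 2\pi/\lambda$, whose minimum radius of
curvature is $R = 1/(Aq^2)$; the bending energy per unit contour length is
$EI/(2R^2)$, which has force units and is reported in pN.

The prefactor of $F_c$ is configurable (`critical_force(..., constant =)`).
Reported absolute critical forces in the experimental literature are not
always consistent with a single constant convention, while the
$\lambda^{-2}$ scaling is; the package therefore asserts scaling, not the
prefactor, and defaults to the continuum minimum ($2\sqrt{E_c EI}$).

### Kinesin softening

Dense kinesin decoration lowers the effective Young's modulus of the MT. The
package models $E(L_d)$ with a saturating family — default a hill curve with
exponent $n = 2$,

$$E(L_d) = E^0_{\mathrm{MT}}\,\frac{L_d^{\,n}}{L_d^{\,n} + L_d^{*\,n}},$$

where $E^0_{\mathrm{MT}}$ is the bare-filament modulus and $L_d^*$ the
critical spacing below which the filament is drastically softened
($E(L_d^*) = E^0_{\mathrm{MT}}/2$ for the hill family). The default family
is the simplest form able to pass through both measured anchor moduli
(49.75 MPa at 95 nm spacing and 7.15 MPa at 18 nm): an exponential
saturation $E^0(1 - e^{-L_d/L_d^*})$ provably cannot, since its attainable
modulus ratio between two spacings is bounded by the spacing ratio
(95/18 ≈ 5.28 < 49.75/7.15 ≈ 6.96), and `calibrate_softening()` reports
exactly this bound when asked for an infeasible family. Calibrated on the
two anchors, the hill-2 family gives $E^0_{\mathrm{MT}} \approx 63.9$ MPa
and $L_d^* \approx 50.7$ nm.

The modified foundation model replaces $E$ by $E(L_d)$:
$\lambda(L_d) = 2\pi\,(E(L_d)\,I\,L_d/k)^{1/4}$. Its local log–log slope
exceeds $1/4$ wherever $E(L_d)$ is rising, which is exactly the deviation
from the bare theory seen at short spacings. Inverting it pointwise yields
per-observation spring constants
$k_i = (2\pi)^4 E(L_{d,i})\,I\,L_{d,i}/\lambda_i^4$, combined by geometric
mean because $k$ enters at the fourth power multiplicatively — wavelength
noise of a few percent maps to spring-constant noise four times larger, and
log-symmetric averaging keeps the estimator median-unbiased (verified by
Monte Carlo in the test suite: median within 30% of truth at 10% wavelength
noise).

## Trace measurement

Input traces are ordered centerline polylines (µm) tagged with strain and
kinesin concentration. Measurement proceeds in the chord frame of the trace:

1. project points onto the end-to-end chord, resample the transverse
   deviation on a uniform grid (tolerant of small backtracking from
   localization noise);
2. estimate the filament axis by least squares, then re-estimate it jointly
   with a sinusoid at the crest-implied wave number (a linear fit in
   intercept, slope, sine and cosine, iterated to a fixed point) so the
   baseline cannot absorb part of the buckle on traces only one or two
   wavelengths long;
3. smooth with a Savitzky–Golay filter (window 1 µm, order 3 by default),
   take sign-alternating local extrema above
   $\max(\text{amplitude floor},\ \text{prominence factor}\times\sigma)$,
   with positions refined by parabolic interpolation and projected onto the
   fitted axis (raw chord-frame gaps carry an alternating
   $\sim 2A\sin(\text{tilt})$ error that the projection removes);
4. per adjacent opposite-sign extremum pair: wavelength = twice the axial
   gap, amplitude = half the peak-to-valley distance, radius of curvature
   $1/(Aq^2)$; crest contour length is the polyline arc length between the
   zero crossings flanking each crest.

Amplitudes are read from the raw (unsmoothed) detrended profile averaged
over ±2 samples around each extremum, so filter attenuation does not bias
them (measured bias < 1% at signal-to-noise 10). For traces showing only
2–3 extrema the trace-level wavelength is refined by a sinusoid-plus-line
fit with free wave number (grid search then 1-D optimization), because
crest-gap estimates degrade when less than ~1.5 periods are visible; with
fewer than 2 extrema the wavelength is reported as absent, not zero. A
filament whose end-to-end vector deviates more than 15° from the
compression axis is excluded from condition aggregates.

Key defaults, all configurable: coordinate noise scale 0.05 µm (a
diffraction-limited localization surrogate), amplitude floor 0.15 µm,
prominence factor 3 — chosen so optical-scale jitter never produces false
crests (a spurious crest would need an 8σ smoothed-noise excursion);
smoothing window 1 µm, which passes even the shortest reported buckles
(λ ≈ 3 µm) with negligible position error.

The `transitional_strain_fit()` procedure objectivizes the two-line
construction used to pick a per-condition wavelength: candidate breakpoints
are midpoints between consecutive observed strains with at least two points
per side, each side gets an ordinary least squares line, and the breakpoint
minimizing total SSE wins (ties towards the smallest breakpoint, flagged
when the two-line fit is no better than one line). Either the transitional
or the critical wavelength can feed the spacing fits
(`wavelength_selection` in the run config); critical is the default.

## Simulator

`rod_model()` discretizes the filament as $n$ nodes with rest spacing $ds$,
in micrometre/piconewton units (for MT-scale parameters $EI \approx 16$
pN µm², which keeps all optimizer quantities of order one — this replaces an
explicit nondimensionalization layer):

* bending $\frac{EI}{2\,ds}\theta_i^2$ per interior node (turning angle
  $\theta_i$),
* axial stretching $\frac{k_a}{2\,ds}(l_j - ds)^2$ per segment, with $k_a$
  the axial stiffness (force per unit strain; default $10^3 EI/ds^2$,
  effectively inextensible),
* foundation $\frac{k}{2}y_a^2$ at each anchor node (one anchor per $L_d$),
  measuring transverse offset from the anchor's affinely compressed
  substrate position — the springs act perpendicular to the filament only.

Equilibria are found by quasi-static energy minimization (L-BFGS-B with an
analytic gradient) over the transverse deflections; the axial node
positions follow the substrate affinely. The transverse-only
parametrization is what makes the minimization robust: the full 2-D problem
couples near-rigid axial stretching modes (stiffness $k_a/ds$) with soft
bending modes, a conditioning gap of ~10⁶ that stalls quasi-Newton methods,
while the transverse problem converges in ~10³ evaluations. Quasi-statics
(no dynamics) is justified by the experimental strain-rate insensitivity;
"strain-rate" checks are exposed as step-count sensitivity, and the
post-onset wavelength agrees to well under 5% between 8- and 32-step ramps.

Each relaxation is seeded with a transverse perturbation of amplitude
$ds/100$ to break the symmetry of the straight (unstable) branch;
convergence requires the projected gradient below $10^{-7}EI/ds^2$ (a force
about $10^{-6}$ pN at default scales), with up to three warm restarts.
Boundary conditions are clamped by default (positions and tangents of both
end node pairs follow the substrate), pinned optional.

One numerical point matters for interpretation: wavelength selection is
physical only when the strain ramp resolves the buckling onset
$\varepsilon_c \approx F_c/k_a$. Far beyond onset a wide band of
wavelengths is linearly unstable, and a cold-started minimizer can settle
into any of them — a real feature of the energy landscape, not an artifact.
With the near-inextensible default $k_a$ the onset is at $\sim 10^{-5}$
strain, so quantitative scenarios pass an explicit softer $k_a$ placing
onset at ~0.4% strain and ramp through it in steps no larger than that.
Under those conditions the selected wavelength matches
$2\pi(EI L_d/k)^{1/4}$ within 10% across the tested range (2–8 µm), the
axial force at onset matches the finite-length critical force within 15%,
the Euler-to-multiwave crest-count transition is monotone in $L_d$, and
onset strain is monotone in foundation stiffness. Finite-size effects make
the selected wavelength quantized in units of the rod length; test
scenarios use rods at least 6 wavelengths long (mode quantum below 10%, and
below 5% where the step-count comparison demands it).

`finite_length_critical_force()` gives the finite-rod counterpart by
minimizing $F(m) = EI(m\pi/L_e)^2 + E_c(L_e/(m\pi))^2$ over integer mode
count $m$ ($L_e = L$ pinned, $L/2$ clamped); it reduces to the Euler load
at $E_c = 0$, approaches $2\sqrt{EI\,E_c}$ from above as $L \to \infty$
(within 2% at $L = 50\lambda_c$), and explains why short filaments resist
buckling to much larger strains.

## Synthetic data

The generator emulates the measured phenomenology, not the microscopy:
below a per-condition critical strain a filament is a straight line plus
Gaussian coordinate noise; above it, a sinusoid whose per-filament
wavelength and amplitude are drawn from truncated normal distributions
(truncation at a tenth of the mean — the reported histograms give mean ± SD
but no distributional form), with uniform random phase, filament length
uniform in 20–50 µm, and sampling step 0.1 µm. The five default conditions
carry the reported values where reported — 21.14 ± 5.6 µm and 2.16 ± 0.89 µm
at 95 nm spacing, 3.11 ± 1.21 µm and 0.72 ± 0.16 µm at 18 nm, critical
strains 0.6%, 1.2% and 2.0% at 95, 36 and 18 nm — and power-law
interpolations in spacing (exponents set by the two end conditions, relative
SDs interpolated linearly in log spacing) for the intermediate conditions,
whose distributions are not reported. Beyond the critical strain the
programmed wavelength falls with strain in the two-slope piecewise-linear
shape implied by the transitional-strain phenomenology (knee at 15% strain,
rates 3.0 and 0.3 per unit strain, floored at 20% of the critical-strain
value) and the amplitude rises (rate 3.0 per unit strain); these response
rates are generator conventions chosen once to reproduce the qualitative
trends, as no quantitative response curve is reported.

What passing the recovery tests shows — and does not show: the pipeline
recovers programmed sinusoid parameters through realistic noise, chord
geometry and detection thresholds (mean wavelength within ~1% at the dense
condition, ~1.5% at the sparse condition where traces hold only 1–2
periods). It does not exercise image segmentation, non-sinusoidal buckle
shapes, photobleaching, or filament crossings; real-trace performance
depends on the upstream tracing step, which is out of scope (an optional
`render_raster()` produces synthetic fluorescence images for any future
pixel-level work).

## Interfaces

Traces travel as CSV (one row per point: `filament_id`, `strain` with a
`strain_pct` alias, `strain_rate_pct_per_s`, `kinesin_nM`, `point_index`,
`x_um`, `y_um`); write-then-read round trips are loss-free to below
10⁻⁹ µm. Fit reports and simulation summaries are JSON; run configuration
is YAML, validated at load (partial mechanics sections are rejected, not
defaulted), and a resolved copy is archived next to outputs for provenance.
The `mtbuckle_cli()` function (wrapped by `inst/cli/mtbuckle`) exposes
`generate`, `measure`, `fit`, `simulate` and `report` as thin shells over
the package functions; the functions themselves are the primary interface.

## Problem sizes and limitations

The shipped tests and the acceptance script use 200 synthetic traces per
recovery condition, 300 Monte-Carlo replicates for parameter-recovery
checks, and simulator rods of 120–240 nodes ramped in 6–32 strain steps —
sizes at which every stated tolerance is met with margin while the whole
suite runs in about two minutes.

Known limitations: deformation is planar and small-to-moderate amplitude
(the affine axial registration distorts geometry at very large strains);
kinesin binding/unbinding kinetics, thermal fluctuations, substrate
viscoelasticity and filament fracture are not modelled; the softening
family's true functional form is unidentifiable from two anchors, so all
downstream spring-constant numbers inherit that model choice; and absolute
critical forces depend on the prefactor convention discussed above.
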