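---
title: "Quantifying interfacial solute enrichment from SPR scans and density profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interfacial solute enrichment from SPR scans and density profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprgamma)
```

## The problem

An aqueous glycine solution in contact with a solid surface can develop a
nanometer-scale region next to the surface in which the solute is
substantially more concentrated than in the bulk, even while the bulk is
undersaturated. Two observables quantify this: in Kretschmann-configuration
surface plasmon resonance (SPR), a shift of the plasmon coupling angle
$\theta_{SPR}$ at fixed total-internal-reflection angle $\theta_{TIR}$; in
molecular simulation, species-resolved density profiles $\rho(z)$ against
the wall. `sprgamma` implements both analysis chains and the unit
conversions that connect them.

## The optical model and its assumptions

Reflectivity of the planar multilayer (prism, metal film, optional polymer
coat, optional interfacial layer, bulk liquid) is computed by the 2×2
characteristic-matrix method for p-polarization. Each layer is a
homogeneous slab with a scalar relative permittivity at the working
wavelength; there is no dispersion model and no s-polarization. Absorbing
media carry a positive imaginary permittivity, and the layer phase uses the
principal branch of the complex square root with the sign fixed so
evanescent fields decay away from the prism. The implementation is verified
against the independent two-interface Airy closed form to $10^{-12}$ and
obeys $0 \le R \le 1$ and $R + T = 1$ (lossless case) as property tests.

All angles are internal incidence angles at the prism base. Because the
instrument-to-internal angle mapping of a real spectrometer is unknown, the
effective prism permittivity is treated as a calibration constant:
$\varepsilon_{prism} = \varepsilon_{ref}/\sin^2\theta_{TIR}$ from a scan of
a reference liquid of known permittivity. The packaged default constants
(`chip_constants()`) are *effective, instrument-level* values chosen the
same way: the prism permittivity is anchored so that a liquid of
permittivity 1.8489 has its TIR edge at 49.53°, and the metal film's real
permittivity and thickness (at fixed loss 1.26) are calibrated so that the
layer-free stack resonates at 62.55° and a 1 nm layer of permittivity
2.1070 shifts the resonance by exactly 0.13°. They are not tabulated gold
constants at 632.8 nm and should not be reused as such; for a real
instrument, replace them with a stack configuration file and calibrate the
prism from your own reference scans.

## Feature extraction

The TIR edge is defined operationally as the angle of maximum positive
first derivative of reflectivity. On sampled data the derivative peak at a
TIR kink is essentially one grid bin wide, so the sub-grid refinement fits
a parabola only to the peak sample and its two neighbours; wider fits are
visibly biased by the peak's asymmetry. With the default 0.01° grid the
extracted edge of a simulated layer-free chip reproduces the analytic
critical angle to better than 0.01°, and averaging 200 replicates with
reflectivity noise $\sigma_R = 0.002$ moves the mean by less than 0.005°.

The SPR minimum needs the opposite treatment. Near its bottom the
resonance dip is extremely flat — the modelled reflectivity changes by only
$\sim 10^{-4}$ over 0.1° — so a three-point parabola is hopeless under
realistic noise (the raw argmin wanders by ±0.2°). `find_spr_minimum`
therefore fits the quadratic to the whole dip bottom: all samples within
30% of the dip depth above the minimum. Membership in that set is decided
on a lightly smoothed copy of the curve (7-point running mean) so that
whether a borderline sample is included does not correlate with its own
noise, which would otherwise bias the vertex. The result resolves the
minimum with a standard deviation below 0.01° at $\sigma_R = 0.002$. The
wide fit does acquire a small deterministic offset from the dip's
asymmetry (a few hundredths of a degree); this cancels exactly where it
matters, because the stage-2 fit extracts the model's minimum on the
scan's own grid with the same estimator, and because index-matched
comparisons difference two identically treated scans. If several samples
tie for the minimum the smallest angle is reported with an uncertainty
inflated to the tie's span.

Default search windows are 48–52° (TIR) and 60–66° (SPR), bracketing the
default chip's features with margin; both are arguments everywhere.

## Two-stage inversion

Stage 1 converts the edge: $\varepsilon_{bulk} = \varepsilon_{prism}
\sin^2\theta_{TIR}$. When an index-matched partner scan is available the
pipeline calibrates the prism and fixes the bulk from the partner, which
makes the bulk estimate exact by construction and mirrors the measurement
protocol; the partner is assumed to form no interfacial layer of its own —
an assumption the user should be conscious of, since any enrichment in the
reference liquid would be subtracted from the reported excess.

Stage 2 inserts a single interfacial layer of assumed thickness $t$
(default 1 nm) and adjusts only its permittivity. In the default
`"feature"` mode the fitted permittivity is the root of
$\hat\theta_{SPR}(\varepsilon) = \hat\theta_{SPR}^{obs}$, solved by
bracketed bisection (tolerance $10^{-6}$ in $\varepsilon$, budget 200
iterations, bracket [1, 3.8]); in `"curve"` mode the squared reflectivity
mismatch over the SPR window is minimized by Brent search. Both modes are
deterministic; non-bracketing or boundary solutions are flagged as
non-converged rather than returned silently. A full-curve expert mode
(`fit_full_curve`) frees up to three named stack parameters under bounded
Levenberg–Marquardt and attaches a covariance estimate; jointly freeing a
thin layer's permittivity and thickness is reported as unidentifiable,
which is the optical $\varepsilon$–$t$ trade-off: a thicker assumed layer
with proportionally smaller permittivity contrast produces the same
resonance shift.

That trade-off is also why the final observable is robust: fits of the
same scan at assumed $t = 0.5, 1, 2$ nm give different
$\varepsilon_{interf}$ but excess mass densities within a few percent of
each other (the tests require < 5% spread).

## From permittivity to excess mass

The Clausius–Mossotti (Lorentz–Lorenz) mixture rule

$$\frac{\varepsilon - 1}{\varepsilon + 2} = \rho(x)\left[x\,r_{gly} +
(1 - x)\,r_{water}\right]$$

is inverted for the glycine mass fraction $x$ by bracketed root finding on
[0, 1] (tolerance $10^{-10}$; verified against a $10^{-6}$-step grid
search). The specific refractions are calibrated once: $r_{water}$ exactly
from the packaged water point ($\varepsilon = 1.7770$, $\rho = 0.9977$
g/cm³ at 22 °C), $r_{gly}$ by least squares over packaged solution points
built from the literature molar refraction of glycine (16.43 cm³/mol,
equivalent to a dilute-limit refractive-index increment of ~0.18 mL/g at
the sodium D line). Dispersion between the calibration wavelength and the
SPR wavelength is neglected, consistent with treating all permittivities
as per-wavelength scalars.

The solution density $\rho(x)$ interpolates a packaged table (monotone
Hyman spline) derived from the literature apparent-molar-volume
correlation $\phi_V(m) = 43.2 + 0.85\,m$ cm³/mol at ~22 °C, from pure
water (0.9977 g/cm³) up to just above saturation. Interfacial compositions
can exceed bulk solubility, so beyond the last tabulated point the
*apparent specific volume* of the solute is extended linearly to the value
implied by the crystal density (1.607 g/cm³) at $x = 1$; this keeps
$\rho(x)$ monotone, continuous, and exact at both endpoints. Temperature
is fixed at 22 °C throughout; there is no temperature model, no activity
or supersaturation thermodynamics.

The excess interfacial mass density of the assumed layer is then

$$\Gamma = t\left[\rho(x_i)\,x_i - \rho(x_b)\,x_b\right],$$

in ng/cm² (1 g/cm³ over 1 nm = 100 ng/cm²), with the per-nm² equivalent
($\times 10^{-14}$) and the excess number density
($\Gamma/t \cdot N_A/M$, $M = 75.07$ g/mol) attached. Negative excess
(depletion) is allowed and reported with its sign. Worth knowing: the
concentration convention is grams of glycine per kilogram of *water*, so
250 g/kg corresponds to $x = 0.2$.

```{r}
gamma_excess(eps_interf = 2.0717, eps_bulk = 1.8489, t_nm = 1)
```

## Density-profile analysis

Particle frames (one row per molecule: wall distance, species, molecular
mass) are binned into 0.05 nm mass-density histograms normalized by the
bin volume and frame count; binning conserves the inserted mass exactly.
The container also accepts pre-binned profile text and LAMMPS-style
chunk-averaged output with explicit column mapping; the particle reader
assumes molecular center positions. The film width is the distance at
which the solvent density first drops below 0.1 g/cm³, scanning outward
from the last bin above half the solvent maximum (the guard keeps
near-wall depletion dips from terminating the scan early) with linear
interpolation between bins. Window averages weight partial bins by
overlap, and the profile-based surface excess integrates
$\rho(z) - \rho_{bulk}$ from the wall to the start of a user-chosen bulk
plateau region — the simulation-side counterpart of $\Gamma$.

## What the synthetic data emulate — and what they do not

The generator provides every input with known truth under full seeding:

* **Chips** (`make_chip`): metal thickness drawn uniformly within ±2 nm of
  the calibrated default and a small permittivity jitter, emulating
  chip-to-chip resonance spread; polystyrene-coated chips add a 4–6 nm
  coat of permittivity 2.53. The coat default is deliberately thin so the
  resonance stays inside the default 60–66° window; real spin-coated films
  may be thicker and then need a wider window.
* **Scan pairs** (`synth_scan_pair`): the sample and its index-matched
  reference share the bulk permittivity exactly, differ only through the
  interfacial layer, and receive additive Gaussian reflectivity noise
  (default $\sigma_R = 0.002$), clipped to [0, 1] with the clip rate
  recorded.
* **Profiles** (`synth_profile`): solute = bulk plateau plus Gaussian
  near-wall peaks (defaults: two sub-nm peaks and a weaker one at 1.25
  nm), solvent complementarily depleted where the solute is enriched, both
  decaying smoothly (tanh edge, width 0.08 nm) to zero at the film edge.
  The edge is positioned so the 0.1 g/cm³ criterion is met exactly at the
  requested width, and the default plateau densities (0.216 / 0.866
  g/cm³) are those of a 250 g/kg solution. `interfacial_target` rescales
  the peaks so the analytic 0–1 nm average hits a requested value, which
  is how the thick-film 1.0 g/cm³ benchmark fixture is built. Profiles can
  be realized as seeded particles by inverse-CDF sampling.

Passing tests on these fixtures demonstrates that the *analysis* is
correct and unbiased under the stated noise model. It does not demonstrate
anything about real instruments or simulations: there is no instrument
drift, bubble or surface-defect artifact, no angle-calibration error-in-
variables, and the synthetic profiles have idealized Gaussian structure
rather than molecular layering fine structure. The experimental
interfacial permittivities and the 1.0 g/cm³ simulation average are inputs
taken at face value, reproduced here through the conversion chains, not
re-measured.

## Numerical choices and problem sizes

Root finding and minimization use base R's Brent implementations with
explicit brackets; quadratic refinements center their predictor before
fitting (the raw normal equations are ill-conditioned on narrow angle
windows). Degenerate inputs fail loudly with classed conditions
(`sprgamma_domain_error`, `sprgamma_feature_error`, ...), except where a
flagged value is more useful (film width with no edge; permittivities
below the water point map to $x = 0$ with `below_water = TRUE`). The test
suite's Monte-Carlo sizes — 200 noisy feature replicates, 100 noisy scan
pairs for end-to-end recovery, 100-point oracle comparisons — were chosen
to estimate means to well inside the tolerances they check while keeping
the default run in the minutes range on one CPU.

## Known limitations

* Effective optical defaults, not material constants (see above).
* One interfacial layer of uniform permittivity; no graded profiles on the
  optical side.
* The index-matched reference is assumed layer-free.
* Single-wavelength, p-polarization only; no dispersion.
* The density extrapolation above saturation is a smooth idealization of a
  metastable regime with no independent data.
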