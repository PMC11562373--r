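---
title: "Ring-polymer spectra as a convolution: weight functions and deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring-polymer spectra as a convolution: weight functions and deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringdeconv)
```

## The model

Path-integral molecular dynamics (PIMD) represents each quantum nucleus by
`P` classical replicas ("beads") joined into a ring by harmonic springs with
chain frequency `omega_P = P/(beta*hbar)`. In the representation used here
the simulation temperature is `P*T`, the masses are physical, and every bead
feels the full physical potential; the reported potential energy is the bead
average. For a harmonic mode of frequency `omega`, the ring polymer
oscillates at the `P` normal-mode frequencies

```
omega_k^2 = omega^2 + 4 omega_P^2 sin^2(k*pi/P),  k = 0 ... P-1,
```

which in reduced units (`omega' = omega/omega_T`, `omega_T = 2/(beta*hbar)`)
become `omega'_k^2 = omega'^2 + c_k` with constant offsets
`c_k = P^2 sin^2(k*pi/P)`. Two consequences drive everything in this
package:

1. **Weight functions.** The bead-averaged potential energy of a harmonic
   mode falls short of the exact quantum value at finite `P`. A
   frequency-dependent weight `w(omega')` restores it, satisfying the
   functional equation
   `sum_k (omega'^2/omega'_k^2) w(omega'_k) = omega' coth(omega')`.
   For `P = 1` the solution is the familiar quantum harmonic correction
   `w(omega') = omega' coth(omega')`. Such weights are the target spectra
   of generalized-Langevin and quantum-thermal-bath thermostats.

2. **Spectral convolution.** In the squared reduced frequency `z =
   omega'^2` the constant offsets turn the ring-polymer replication of
   spectral lines into a *discrete convolution*: the bead-level
   (path-integral) density of states is `g_PI = (1/P) sum_k g_cl(z - c_k)`,
   a banded lower-triangular Toeplitz matrix acting on the classical
   density. The amplitude `1/P` per shifted copy follows from
   equipartition of the normal-mode velocities at the simulation
   temperature `P*T`. Inverting this operator (deconvolution) recovers
   physical spectra from ring-polymer MD (RPMD), including cases where an
   internal ring-polymer mode resonates with a physical vibration and
   contaminates the centroid spectrum.

## The weight-function equation is ill-posed — and what we do about it

Written on the half-line `z >= 0` with `a(z) = w(sqrt z)/z` and
`b(z) = coth(sqrt z)/sqrt z`, the functional equation is
`sum_k a(z + c_k) = b(z)`. Its symbol `sum_k exp(i c_k xi)` has zeros: real
zeros for commensurate offset sets (e.g. `P = 4, 6`), and complex zeros with
`Im(xi) = ln(2)/c_min` for every `P >= 3` (the smallest offset is always
doubly degenerate, `c_1 = c_{P-1}`). The equation therefore admits bounded
oscillatory homogeneous solutions and decaying oscillatory transients: the
weight function is only defined up to such components. Numerically this
shows up in two ways, both reproduced and documented by the package's own
diagnostics:

* an exact triangular solve of the truncated Toeplitz system is unstable —
  boundary errors amplify like `2^(z/c_min)` toward `z = 0`, producing a
  discontinuous, sign-alternating "solution";
* two differently-regularized solvers can both satisfy the equation to
  `1e-4` and still differ by several per cent around `omega' = 2 ... 4`.

The package therefore *defines* the weight function variationally: it is
the minimizer of

```
|| T a - b ||^2 + sum_i || S_i (a - a_ref) ||^2
```

where `T` is the discrete (pole-subtracted) Toeplitz operator, `a_ref =
b/P` is the smooth asymptotic first approximation, and the `S_i` are two
second-difference penalties taken at strides near half the null wavelength
`c_min` (an incommensurate pair, weight `reg_lambda = 3e-3`), which pin the
oscillatory near-null components to the smooth reference while leaving the
data-determined components untouched. Penalizing the *deviation from the
reference* rather than the curvature itself removes almost all penalty bias;
the plug-back residual of the converged tables stays below `1e-4`
(`residual_functional_equation()` verifies this for every table).

Two independent routes compute this one minimizer:

* `solve_weights_toeplitz()` — conjugate-gradient iteration on the
  penalized normal equations, in C++, with a quadruple-precision backend
  (`precision = "quad"`) retained for verification;
* `solve_weights_fixed_point()` — a Nesterov-accelerated gradient
  fixed-point iteration written entirely in R.

Both share the analytic ingredients (pole subtraction so that `w(0) = 1`
holds exactly; a damped-Jacobi refined asymptotic tail closure; a grid
extended internally by `10 c_min` so the boundary layer stays outside the
reported range) but differ in algorithm and code path; their agreement —
about 0.2 % at worst across `P = 2 ... 32`, measured by
`scripts/acceptance.R` — is the package's cross-validation of the solver.
Bead counts above 32 are refused: the near-null structure thickens with
`P` and the approach degrades irrecoverably towards `P = 64`.

Grid choices: the offsets must land on grid multiples. For
`P in {2, 3, 4, 6}` the default spacing `0.05` is exactly commensurate.
For other `P` the offsets are irrational multiples of each other;
`choose_z_spacing()` searches divisor families of the extreme offsets for a
spacing whose worst snap error is below `spacing/20`. For `P = 32` seven
independent irrationals make that tolerance unattainable at any usable
spacing (simultaneous Diophantine approximation would require ~1e9 grid
points); the solver then accepts the best achievable snapping and records
the snap error in the kernel.

## The simulator

`integrate_pimd()` / `integrate_rpmd()` implement velocity Verlet with
exact normal-mode propagation of the free ring polymer and a PILE
thermostat in the normal-mode representation (centroid friction `1/tau`
with `tau = 1000 fs` by default, internal-mode friction `2*omega_k`,
scalable). Initial conditions are beads collapsed onto the potential
minimum with Maxwell-Boltzmann velocities at `P*T`; ensembles discard 2 ps
of thermostatted equilibration before the microcanonical production run,
and each replica's rigid translation and rotation is removed both at the
RPMD launch and from the recorded velocities (3D runs). Conserved-energy
drift is measured as the difference of block means over the first and last
quarter of the run — the velocity-Verlet energy oscillates boundedly at
`O(dt^2)`, so endpoint differences overstate drift — and stays below
`1e-5` for the bundled models at `dt = 0.25 fs`.

Estimators recorded per frame: bead-averaged potential, total classical
kinetic energy (equipartition check: `P/(2*beta)` per bead per degree of
freedom), spring energy per bead, and the primitive kinetic-energy
estimator `dof*P/(2*beta) - spring_per_bead`. For harmonic models these
are validated against closed forms (`harmonic_reference()`): normal-mode
frequencies against a numerically diagonalized Hessian, and the
bead-averaged potential `<V>_P = (omega^2/(2*beta)) sum_k 1/omega_k^2`,
which rises monotonically to the quantum limit
`(hbar*omega/4) coth(beta*hbar*omega/2)`.

Bundled potentials (`inst/extdata/`): a 1D harmonic oscillator; the OH
radical as a Morse oscillator (`D = 0.18748 Eh`, `a = 1.1605 1/a0`,
`r0 = 1.8324 a0`, following the published OH Morse model; harmonic
frequency 3751 cm^-1); and a single gas-phase-like water molecule with
harmonic (or Morse) bonds plus a harmonic bend. The water force constants
are a *synthetic re-parametrization* calibrated to harmonic frequencies
1595/3680/3734 cm^-1 — the original model's constants are not reproduced —
so quantitative water results are model-faithful rather than
literature-faithful. At 380.8 K and `P = 16` the second internal image of
the bend, `sqrt(omega_bend^2 + c_2 omega_T^2) ~ 3610 cm^-1`, crosses the
stretches: exactly the resonance that produces spurious satellites in the
centroid RPMD spectrum.

## Spectra and deconvolution

`vacf()` computes the mass-weighted velocity autocorrelation
(`c_vv(0) = 1` exactly; FFT with unbiased lag counts), `vdos()` its cosine
transform after a Hann taper (selectable) of the even extension, with
4-fold zero padding for smooth peak interpolation. Ensembles average the
mass-weighted periodograms — equivalently the autocorrelations — across
trajectories *before* any transform (`rpmd_ensemble()` keeps memory flat in
the ensemble size). Velocities are recorded every 0.5 fs, which resolves
frequencies far above the 10000 cm^-1 analysis window.

`to_z()`/`from_z()` map spectra between the frequency axis and the z axis
area-preservingly (rebinning through the cumulative integral, exact for the
total area). `deconvolve()` solves

```
min || A g - g_PI ||^2 + lambda^2 || D g ||^2,   lower <= g <= upper,
```

on z bins whose frequency image lies between `objective_min` and
`artifact_max = 10000 cm^-1` (finite-trajectory broadening pushes intensity
above the physical range), with `g = 0` enforced above the
`physical_max = 5000 cm^-1` image. By default `objective_min =
physical_max`: the fit sees only the internal-mode images above the
physical range, so resonance-distorted line shapes *inside* the physical
range — precisely where internal and physical vibrations interfere —
cannot push misfit into the deconvolved density. (Setting `objective_min =
0` fits the full range; for small bead counts, whose offsets may map no
image into the window, that is the only usable choice.) The
default solver is a monotone accelerated projected-gradient (FISTA-type)
iteration that converges to the constrained minimizer for both
non-negative (`nnls`) and box (`bvls`) bounds; the classic active-set
Lawson-Hanson NNLS (via pracma) is available as `solver = "lawson-hanson"`
and is used as an independent cross-check in the test suite — its cubic
per-iteration cost makes it impractical for the production grids. The
smoothing weight defaults to `lambda_scale = 0` (pure NNLS); the
deconvolved density is then spiky, which is why peak positions are read
either by quadratic interpolation through the three bins around a maximum
(smooth spectra) or by the intensity-weighted centroid over a window
(deconvolved spectra).

The z-grid spacing for deconvolution defaults to ~0.1 (about 9 cm^-1
resolution at the OH stretch), snapped to the `P = 16` offsets with a
relaxed tolerance (`snap_tol_div = 2`): at these resolutions the snap
error is far below the spectral line width, so commensurability is a
far weaker constraint than for the weight-function solve.

`quantum_correct()` multiplies a deconvolved spectrum by the `P = 1`
weight `omega' coth(omega')` — the classical-to-quantum harmonic map —
completing the six-stage pipeline of `pipeline_rpmd_to_quantum()`:
bead-level VDOS, z transform, deconvolution, back transform, quantum
correction, with the centroid (RPMD) spectrum carried alongside for
comparison.

## What the synthetic generator does and does not emulate

`generate_fixture_spectrum()` builds a classical density of states as an
analytic peak sum and its *exact* forward convolution (plus seeded
Gaussian noise), so the deconvolution stack is testable without any
dynamics. It emulates line positions, areas, widths and additive noise; it
does not emulate anharmonic mode coupling, resonance intensity borrowing,
or finite-trajectory window broadening — those only appear in the
simulated ensembles. A passing round trip on fixtures therefore validates
the operator algebra and solver, not the physics of real spectra; the
simulated OH and water experiments in the test suite cover the latter.

## Problem sizes and study conditions

All defaults were fixed before the validation runs and are the package's
study conditions: `dt = 0.25 fs`, PILE `tau = 1000 fs`, 2 ps
equilibration, 10 ps production, `P = 16`, `T = 436.5 K` (OH) and
`380.8 K` (water). Ensemble sizes are scaled down from the
ten-thousand-trajectory scale of a production study to desk scale: 200
trajectories for the OH stretch-shift experiment (the shift carries a few
cm^-1 of sampling error at this size) and 150 for the water
satellite-removal experiment; the harmonic-oracle checks use 12 short
trajectories per bead count with a 100 fs thermostat for fast
equilibration. The weight-function comparison uses the full default grids
(`z <= 400`, i.e. `omega' <= 20`).

## Known limitations

* The weight function is variationally selected; other regularizations
  (including other published implementations) legitimately differ at the
  per-mille-to-per-cent level along the near-null directions. The
  cross-method agreement reported by the acceptance script quantifies the
  reproducibility of *this* definition, not a uniqueness the equation does
  not possess.
* `P > 32` is refused for the weight solvers.
* The deconvolution assumes independent harmonic oscillators behind the
  convolution model; anharmonicity shifts the internal-mode images off the
  harmonic offsets, which is visible as the ~15 cm^-1 blue shift of the
  deconvolved OH stretch relative to the centroid peak.
* The water model is a synthetic re-parametrization; satellite positions
  and intensities are faithful to the model, not to any published water
  spectrum.
* Thermostat-broadening deconvolution (TRPMD/GLE-style) and IR/Raman
  intensities are out of scope; only the velocity-based density of states
  is treated.
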