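# ringdeconv

Path-integral molecular dynamics (PIMD) replaces each quantum nucleus by
`P` classical beads joined into a ring by harmonic springs. The springs add
unphysical "internal" vibrations on top of every physical mode: a harmonic
mode at reduced frequency `omega' = omega/omega_T` (with
`omega_T = 2/(beta*hbar)`) appears in bead-level spectra at all

    omega'_k^2 = omega'^2 + c_k,      c_k = P^2 sin^2(k*pi/P),  k = 0 ... P-1.

Because the shifts `c_k` are constants, switching to the squared reduced
frequency `z = omega'^2` turns this replication into a **discrete
convolution** — a banded triangular Toeplitz matrix acting on the classical
density of states. `ringdeconv` builds on that observation in both
directions:

* **Weight functions.** It solves the functional equation
  `sum_k (omega'^2/omega'_k^2) w(omega'_k) = omega' coth(omega')` for the
  frequency-dependent weight that makes a P-bead harmonic average exactly
  quantum — the target spectrum of generalized-Langevin / quantum-thermal-bath
  thermostats — as a penalized Toeplitz least-squares problem, by two
  independent numerical routes (a C++ conjugate-gradient solver with a
  quadruple-precision backend, and a pure-R gradient fixed-point iteration).
* **Spectral deconvolution.** It recovers physical vibrational densities of
  states from ring-polymer MD (RPMD) by bounded non-negative (NNLS/BVLS)
  deconvolution of the bead-level spectrum, including cases where an
  internal ring-polymer mode resonates with a physical vibration and
  contaminates the centroid spectrum with spurious peaks.

It ships a compact PIMD/RPMD engine (velocity Verlet with exact
normal-mode propagation and a PILE thermostat) for few-atom models — a 1D
harmonic oscillator, the OH radical as a Morse oscillator, and a single
harmonic/anharmonic water molecule — so every claim is testable end to end
from simulation to deconvolved spectrum. The intended audience is method
developers in path-integral and vibrational-spectroscopy simulation.

## Worked example

```r
library(ringdeconv)

# weight function for a 4-bead ring polymer
tb <- solve_weights_toeplitz(4, n_iter = 2000, z_max = 150)
tb
#> <weight_table> P = 4, method = toeplitz_iterative, 3001 points on omega' in [0, 12.2474], 1643 iterations
round(weight_at(tb, c(1, 5, 10)), 4)
#> [1] 0.9894 1.4604 2.6025
residual_functional_equation(tb)
#> <residual_profile> 2681 probes, max 8.14e-05, median 2.6e-05

# synthetic two-line classical spectrum, exact P = 16 forward convolution,
# then NNLS deconvolution
fx  <- generate_fixture_spectrum(fixture_spec(peaks = c(1600, 3700),
                                              areas = c(1, 2), P = 16, seed = 1))
dec <- deconvolve(fx$g_pi, fx$operator, deconv_config())
sp  <- from_z(dec)
c(peak_position(sp, c(1200, 2000)), peak_position(sp, c(3300, 4100)))
#> [1] 1600 3700
attr(dec, "residual_norm")
#> [1] 3.93e-12
```

The weight values say that a 4-bead simulation already carries most of the
zero-point amplification at `omega' = 1` (`w ~ 0.99`, essentially classical)
but must be boosted by a factor 2.6 at `omega' = 10`; the plug-back
residual shows the table satisfies the functional equation to better than
`1e-4` everywhere. The deconvolution recovers both synthetic line positions
to the bin width with a residual at machine noise.

The full simulation pipeline is one call per stage:

```r
pot <- read_potential_config(system.file("extdata", "morse_oh.cfg", package = "ringdeconv"))
ens <- rpmd_ensemble(pot$model, pot$masses, P = 16, temperature = 436.5,
                     n_traj = 200, seed = 1, constrain_1d = TRUE, fix_com = TRUE)
res <- pipeline_rpmd_to_quantum(ens)   # PI, RPMD, deconvolved and quantum spectra
```

A command-line interface wrapping the same functions is installed under
`inst/cli/ringdeconv` (subcommands `weights`, `simulate`, `spectrum`,
`deconvolve`, `pipeline`, `fixture`; every run writes a JSON manifest).

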