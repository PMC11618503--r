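---
title: "Landscape thermodynamics of quantum water: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape thermodynamics of quantum water: models, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelwater)
```

## The problem

Liquid and glassy water can be described through the topography of their
potential energy landscape (PEL): the potential energy as a hypersurface over
all configurational degrees of freedom, partitioned into basins around local
minima (inherent structures, IS). Classical PEL thermodynamics writes the
partition function as a sum over IS energies $e_{IS}$, with a configurational
entropy $S_{IS}$ counting basins and a vibrational free energy $F_{vib}$ for
the exploration within a basin.

When nuclear quantum effects matter — as they do for water's light hydrogens —
the system is mapped, via imaginary-time path integrals, onto a classical
system of ring polymers: each atom becomes $n_b$ beads joined in a closed
loop by temperature-dependent harmonic springs with constant
$k^{sp}_i = m_i n_b / (\hbar\beta)^2$. The ring-polymer potential

$$\mathcal{U}_{RP}(\mathbf R) \;=\; \sum_{i=1}^{n}\sum_{k=1}^{n_b}
\tfrac12 k^{sp}_i \left(\mathbf r_i^{k+1}-\mathbf r_i^{k}\right)^2
\;+\; \frac{1}{n_b}\sum_{k=1}^{n_b} U(\mathbf r_1^k,\ldots,\mathbf r_n^k)$$

defines a landscape of its own (the RP-PEL) — and, unlike the classical PEL,
a temperature-dependent one, because the springs stiffen as $T$ grows. This
package implements the full chain from the force field to the landscape
statistics for the flexible q-TIP4P/F water model, at sizes a single CPU
handles in minutes.

Two structural facts make the quantum landscape tractable, and both are
verified by this package's test suite rather than assumed:

1. **Ring polymers collapse at inherent structures.** Minimizing
   $\mathcal{U}_{RP}$ drives every ring polymer's radius of gyration to
   (numerically) zero, so an RP inherent structure is a classical inherent
   structure replicated $n_b$ times, and $e_{IS}^{RP} = U(\text{classical})$
   exactly.
2. **The RP spectrum at a collapsed IS is analytic.** The $d\,n_b$
   eigenfrequencies of the mass-weighted RP Hessian follow from the $d$
   classical ones:
   $$\omega_{i,j}^2 = \frac{\omega_{i,0}^2}{n_b^2}
   - \frac{2}{(\hbar\beta)^2}\left[\cos\!\left(\frac{2\pi j}{n_b}\right)-1\right],
   \qquad j = 1,\ldots,n_b,$$
   with the $j = n_b$ branch being the classical spectrum rescaled by
   $1/n_b$. `rp_modes_numeric()` is the brute-force oracle that checks this
   against full Hessian diagonalization on small clusters; the agreement
   criterion is a relative deviation below $10^{-6}$.

## The force field

q-TIP4P/F is a four-site flexible water model: a Lennard-Jones site on the
oxygen, charges $q_H$ on the hydrogens and $-2q_H$ on a massless M site at
$\mathbf r_M = \gamma_M\mathbf r_O + \tfrac{1-\gamma_M}{2}(\mathbf r_{H1}+\mathbf r_{H2})$,
a quartic expansion of a Morse potential for each OH bond,
$V(\Delta r) = D_r\alpha_r^2\Delta r^2\,[1-\alpha_r\Delta r+\tfrac{7}{12}\alpha_r^2\Delta r^2]$,
and a harmonic HOH angle. The constants ship in
`inst/extdata/qtip4pf.yaml` and as the defaults of `water_params()`; all are
the published model values converted to the internal unit system
(nm, amu, ps, kJ/mol — chosen so that 1 amu nm$^2$/ps$^2$ = 1 kJ/mol exactly,
mass-weighted Hessian eigenvalues are in ps$^{-2}$, and conversion to
cm$^{-1}$ happens only at the reporting boundary, dividing by $2\pi c$ with
$c = 0.0299792458$ cm/ps).

M-site forces are redistributed onto the real atoms by the chain rule
($\gamma_M$ to O, $(1-\gamma_M)/2$ to each H); the analytic gradient is
validated against central finite differences to $10^{-4}$ kJ/mol/nm on random
liquid configurations.

### Cutoffs and boundary handling

Periodic boxes use the minimum-image convention with electrostatics treated
by the reaction-field method (continuum dielectric 78.3 beyond the cutoff,
nominal $r_c = 1.0$ nm); open clusters use plain Coulomb with no cutoff.
Three choices here were genuinely open and deserve explanation:

* **Effective cutoff in small boxes.** Desk-scale boxes (8–16 molecules,
  $L \approx 0.6$–$0.8$ nm) are smaller than $2r_c$, where minimum-image
  bookkeeping breaks down. The effective cutoff is therefore capped at half
  the shortest box edge. For any box with $L \ge 2$ nm the nominal 1.0 nm
  cutoff applies unchanged.
* **Site-resolved cutoff.** Each site–site pair term is truncated at its own
  distance (rather than gating all nine charge pairs on the O–O distance).
  The alternative molecule-based cutoff keeps interacting charge groups
  neutral but leaves a discontinuity when a whole molecule pair crosses the
  boundary; with the shifts below, the site-resolved form is globally
  continuous.
* **Shift-force cutoffs.** Both the Lennard-Jones and the reaction-field pair
  terms are energy- *and* force-shifted so the pair energy and the pair force
  vanish continuously at $r_c$ ($C^1$ continuity). A plain truncation leaves
  force discontinuities of order 10 kJ/mol/nm at the cutoff in these dense
  small boxes, which stalls quasi-Newton minimization around gradient norms
  of a few kJ/mol/nm — orders of magnitude above the inherent-structure
  tolerance. The energy-only and sharp variants remain available
  (`force_shift = FALSE`, `lj_shift = FALSE`) for comparison.

## Minimization to inherent structures

Inherent structures are located with L-BFGS-B, the standard choice for this
task. Two numerical floors matter:

* The classical minimizer runs L-BFGS-B to its floating-point stall and then
  applies a Newton polish: the finite-difference Hessian is diagonalized,
  near-zero modes (translations, and rotations for clusters) are projected
  out, and Newton steps are accepted while the gradient norm falls. This
  reliably reaches the default tolerance of $10^{-6}$ kJ/mol/nm (max-norm).
* The ring-polymer minimization works on all $3nn_b$ bead coordinates. Its
  stall floor grows with dimension, and polishing a $3nn_b$-dimensional
  Hessian is disproportionate, so the default tolerance is $10^{-3}$
  kJ/mol/nm. On the softest ring-polymer mode this still pins bead
  displacements to $\sim 10^{-5}$ Å — four orders below the $10^{-4}$ Å
  collapse threshold the package tests — and the residual spring energy at
  converged minima is below $10^{-8}$ kJ/mol.

A two-stage fast path (`sample_is(..., path = "centroid")`) collapses the
beads to their centroid and minimizes classically; the test suite checks it
lands in the same basin with the same energy as the direct path.

Basin identity between two minimizations is declared when
$|\Delta e_{IS}| < 10^{-6}$ kJ/mol; the Hessian step is $h = 10^{-5}$ nm by
default (central differences of analytic forces, symmetrized), exposed as
`hessian_h`.

## The PIMD engine

`pimd_run()` integrates the ring-polymer equations of motion with the PILE
scheme: velocity Verlet on the physical forces, exact normal-mode evolution
of the free ring polymer, and an Ornstein–Uhlenbeck thermostat per normal
mode (OBABO splitting). The centroid is thermostatted at the collision rate
$\gamma$; internal modes are critically damped at $\gamma_k = 2\omega_k$.
Classical Langevin MD is literally the $n_b = 1$ case of the same code path,
which the suite verifies bit-for-bit against an independent R implementation
consuming the same noise stream.

Numerical and sampling choices:

* **Time step** 0.25 fs, resolving the stiffest OH-stretch and spring modes.
* **Bead masses.** Thermodynamic averages do not depend on the dynamical
  bead masses, so they are a pure sampling choice. The engine uses the
  physical atomic mass for every normal mode: with the textbook fictitious
  masses $m' = n_b m$ the centroid explores configuration space
  $\sqrt{n_b}$-fold slower than classical MD, which would make an
  equal-budget MD/PIMD comparison of inherent-structure energies
  systematically unfair at desk scale.
* **Thermostat rate.** $\gamma = 0.1$ ps$^{-1}$ — the value appropriate for
  nanosecond production runs — is the engine default. Desk-scale protocols
  (`run_statepoint()`) default to $\gamma = 1$ ps$^{-1}$ for production and
  $5$ ps$^{-1}$ for equilibration, because a thermostat time constant of
  10 ps cannot control temperature inside a picosecond-long window.
* **Initialization.** Toy state points start from a *minimized* packing
  (jittered lattice relaxed to an IS) with Maxwell–Boltzmann momenta; beads
  start collapsed with a Gaussian jitter of one tenth of the free-particle
  radius of gyration.
* **Equilibration check.** The bulk criterion — molecular MSD reaching
  1.0 nm$^2$, roughly one intermolecular spacing of diffusion — is kept with
  a configurable threshold defaulting to 0.01 nm$^2$ (one tenth of a spacing)
  at desk scale, where full diffusive decorrelation is unreachable in
  picoseconds. Runs that fail the check carry an explicit
  `equilibrated = FALSE` flag; at deeply supercooled toy conditions this flag
  is routinely FALSE and should be read as "landscape aging is still in
  progress", exactly as in the bulk systems these toys emulate.

Two energy estimators are reported: the primitive (thermodynamic) estimator
$E = \tfrac{d\,n_b}{2\beta} - \langle U_{spring}\rangle + \langle \bar U\rangle$,
which is the $\beta$-derivative of the ring-polymer partition function, and
the lower-variance centroid-virial estimator as a cross-check. Both are
validated against the closed-form quantum harmonic oscillator (including the
exact finite-$n_b$ Trotter value) and the free ring polymer.

### Barostat

Constant pressure is needed only for the vitrification protocol;
this package implements a Monte Carlo barostat: isotropic log-volume moves
every 25 steps, molecule centroids scaled with intramolecular and intra-ring
geometry rigidly translated, acceptance
$\min\{1, \exp[-\beta(\Delta U_{RP} + P\Delta V) + (N+1)\Delta\ln V]\}$, and
the step amplitude auto-tuned towards 40–50% acceptance. The Metropolis core
is exposed (`metropolis_volume()`) so the rule can be validated on the
analytically solvable ideal gas, whose NPT volume distribution is
Gamma$(N{+}1)$.

## Landscape statistics

The statistics layer works on tidy tables and fitted-model objects with
`tidy()`/`glance()`/`autoplot()` methods:

* **Shape function** $\mathcal S = \sum_i \ln(\hbar\omega_i/A_0)$ over the
  $d\,n_b - 3$ positive modes ($d-6$ for free clusters), $A_0 = 1$ kJ/mol.
* **Linear shape law** $\mathcal S = a + b\,e_{IS}$ by ordinary least
  squares (`fit_shape_linear()`); on the quantum landscape $a$ and $b$ are
  temperature-dependent.
* **Gaussian landscape** $E_{IS}(T) = E_0 - \sigma^2[b(T) + \beta]$:
  `fit_gaussian_pel()` regresses $E_{IS}$ on $b(T) + 1/(k_BT)$, giving
  $-\sigma^2$ as slope and $E_0$ as intercept, inside a fit window
  $T \le 280$ K by default. A positive slope is flagged as non-Gaussian, not
  clipped. $(E_0, \sigma^2)$ are fitted per volume under the assumption that
  they are temperature-independent.
* **Configurational entropy**
  $S_{IS} = k_B[\alpha N - (e_{IS}-E_0)^2/2\sigma^2]$. The parameter
  $\alpha$ (total number of basins) is not identifiable from IS sampling
  alone; without it the entropy is reported relative to $k_B\alpha N$ with an
  explicit flag.
* **Vibrational free energy**
  $F_{vib} = n_{modes}\,k_BT\ln(\beta A_0) + k_BT\,\mathcal S$. The
  prefactor counts the modes actually summed in $\mathcal S$
  ($n_{modes} = d\,n_b - 3$ by default), which makes the Helmholtz free
  energy $F = E_{IS} - TS_{IS} + F_{vib}$ exactly independent of the
  arbitrary scale $A_0$ — an invariance the suite asserts numerically. The
  thermodynamic-limit bookkeeping with prefactor $d\,n_b$ (which breaks the
  invariance by exactly $3k_BT\ln(A_0'/A_0)$, negligible at large $N$) is
  available via `n_modes = d * n_b`.
* **Harmonic vibrational energy**
  $E_{vib}^{harm} = d\,n_b k_BT + (\partial\mathcal S/\partial\beta)_{N,V,E_{IS}}$,
  with the derivative taken by central differences along the fitted linear
  shape law at a common $E_{IS}$ (grids coarser than 40 K trigger a
  warning). With $n_b = 1$ and a $T$-independent $\mathcal S$ this reduces
  exactly to the classical $d\,k_BT$. The full bracket with
  $\partial\alpha/\partial\beta$, $\partial E_0/\partial\beta$,
  $\partial\sigma^2/\partial\beta$ is deliberately not implemented: those
  parameters are treated as $T$-independent throughout, so the simplified
  form is the consistent one.

### The synthetic landscape generator

`simulate_pel_landscape()` draws $e_{IS}$ samples from the canonical tilt of
a Gaussian density of states — $e_{IS} \sim N(E_0 - \sigma^2(b+\beta),\,
\sigma^2)$ at each temperature — and shape values $S = a + b\,e_{IS}$ with
optional Gaussian noise. It emulates exactly what the theory layer assumes:
a Gaussian basin-energy distribution with a linear shape law and
$T$-dependent $(a, b)$. It does **not** emulate anharmonicity, non-Gaussian
tails, finite-size correlations between basins, or the temperature drift of
$(E_0, \sigma^2)$ — so recovery tests on it validate the estimator
machinery, not the physical accuracy of the Gaussian approximation for any
real liquid. Those aspects are probed separately (and only qualitatively, at
toy scale) by the MD/PIMD state-point protocols.

## Desk-scale protocols and problem sizes

All simulations in the test suite and acceptance script run on one CPU:

* clusters of 1–16 molecules for spectrum validation (the RP-Hessian oracle
  is quadratic in $3nn_b$ and guarded at 5000 coordinates);
* periodic boxes of 8–16 molecules ($d$ = 72–144) for liquid state points,
  with $n_b$ = 4–16 beads, equilibration/production of a few thousand
  0.25 fs steps, and 10–25 inherent structures per state point (25 is the
  standard protocol default);
* isobaric cooling of 8 molecules with $n_b$ = 4–8 over a handful of
  temperature stages.

These sizes reproduce the *structural* claims quantitatively (collapse,
spectrum equivalence, zero-mode count, band edge) and the *thermodynamic*
claims qualitatively (IS-energy trends, MD/PIMD agreement); bulk quantities
such as onset temperatures or amorphous-ice densities require hundreds of
molecules and nanoseconds, and are out of scope.

## Known limitations

* Reaction-field (not Ewald) electrostatics, with the shift-force dialect
  described above; no virial/pressure tail corrections.
* Sub-$2$ nm boxes use a density-dependent effective cutoff, so absolute
  energies are not comparable across box sizes.
* The equilibration flag measures translational decorrelation only.
* The Hessian is finite-difference (step $10^{-5}$ nm); eigenvalues carry
  $O(h^2)$ truncation noise of order $10^{-3}$ ps$^{-2}$, far below the
  5 cm$^{-1}$ zero-mode threshold but visible if thresholds are tightened
  aggressively.
* For toy boxes the lowest real lattice mode divided by $n_b$ can approach
  the 5 cm$^{-1}$ zero-mode threshold on the $j = n_b$ branch of the RP
  spectrum; the threshold is configurable and reported next to every count.

## A small worked chain

```{r chain, eval = FALSE}
sp <- run_statepoint(N = 16, rho_g_cm3 = 1.0, temperature = 260, n_b = 8,
                     n_steps_eq = 3000, n_steps_prod = 4000,
                     n_is_samples = 10, seed = 1)
tidy(sp)                       # one-row state-point summary
tidy(sp$is_sample)             # per-frame inherent structures
shape_function(sp$spectrum_rp) # basin curvature of the RP landscape
autoplot(sp$spectrum_rp)       # ring-polymer IS-VDOS
```
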