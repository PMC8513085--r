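---
title: "Electrostatic-potential-fitted QM/MM: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrostatic-potential-fitted QM/MM: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`espfqmm` couples a quantum-mechanical (QM) solute to a classical (MM) solvent
through electrostatic-potential-fitted (ESPF) charge operators. The QM/MM
interaction is written as a sum of atom-centered terms,

$$\Delta E = \sum_A^{N_{QM}} q_A \phi_A,
\qquad \phi_A = \sum_i^{N_{MM}} \frac{q_i^{FF}}{|R_A - R_i|},$$

where the ESPF partial charge on QM atom $A$ is
$q_A = Z_A - \mathrm{Tr}(P\,Q_A)$ and the charge population operators
$Q_{A,\mu\nu}$ are obtained by least-squares fitting of the electrostatic
integrals $V_{k,\mu\nu} = \langle\mu| |r - r_k|^{-1} |\nu\rangle$ on a
molecular-shaped grid:

$$Q_{A,\mu\nu} = \sum_k T^+_{A,k}\, V_{k,\mu\nu},
\qquad T_{k,A} = |r_k - R_A|^{-1}.$$

Because the grid is finite, the operator-form charge-conservation condition
$\sum_A Q_A = S$ holds only approximately; the defect matrix
$D = \sum_A Q_A - S$ quantifies the incompleteness of the fit. The embedding
one-electron operator used in every Fock build imposes charge conservation
explicitly,

$$h'_{\mu\nu} = \sum_A Q_{A,\mu\nu}\,(\Phi_{av} - \phi_A) - \Phi_{av} S_{\mu\nu},
\qquad \Phi_{av} = \frac{1}{N_{QM}}\sum_A \phi_A,$$

so that a uniform external potential acts as a pure gauge: it shifts the
electronic energy by exactly $-c\,N_{el}$ and leaves the density and every
excitation energy unchanged. The total energy is

$$E = \mathrm{Tr}[P(F_0 + h')] \text{-consistent QM energy}
 + E_{MM} + \sum_A Z_A\,\phi_A \;(+\,\omega_I),$$

with the nuclear-MM electrostatics summed as exact point-point Coulomb terms
(never through the fitted charges) and the MM energy containing the
intermolecular Coulomb and Lennard-Jones sums, the intramolecular bonded
terms, and the QM-MM Lennard-Jones wall. QM-MM electrostatics lives
exclusively in the ESPF terms.

## The electronic-structure backend

The package ships its own Gaussian-basis electronic-structure backend:
restricted Hartree-Fock with DIIS, and excited states from
configuration-interaction singles, i.e. the Tamm-Dancoff approximation with a
pure Hartree plus exact-exchange kernel,

$$A_{ai,bj} = \delta_{ij}\delta_{ab}\,(\epsilon_a - \epsilon_b)
 + 2(ia|jb) - (ij|ab),$$

where the orbital energies come from the *embedded* Fock matrix $F_0 + h'$.
Integrals are computed by the McMurchie-Davidson scheme (Cartesian shells of
arbitrary angular momentum; Boys function by series plus downward recursion).
Analytic nuclear derivatives of every integral follow from the
angular-momentum raising/lowering identity applied to the Hermite expansion
coefficients, with operator-center derivatives from translational invariance.

Excited-state gradients use the Lagrangian (Z-vector) formulation. The relaxed
difference density $P_I$ combines the unrelaxed difference density of the CIS
amplitudes with the orbital-relaxation part from the coupled-perturbed
equations; these equations contain only orbital-energy differences and
two-electron integrals, so the embedding operator enters them exclusively
through the orbital energies. The energy-weighted matrix that contracts with
$S^x$ is assembled from the same Lagrangian; only its symmetric part couples
to the (symmetric) overlap derivative. Every gradient path in the package is
validated against central finite differences with the fitting grid rebuilt at
each displaced geometry (`fd_validate()`), which is the package's primary
correctness oracle: agreement to $10^{-6}$ hartree/bohr or better on
water/6-31G* embedded in point charges.

The backend supports the restricted closed-shell reference only, and only the
Hartree-Fock model (`functional = "hf"`); density-functional kernels are out
of scope for the built-in engine. This matters when comparing with published
numbers computed at hybrid-DFT levels: topology and identities are
transferable, absolute excitation energies are not (CIS overestimates
excitation energies by 1-2 eV and shifts critical-point energetics
accordingly).

## Basis sets

Plain-text basis data are bundled: STO-3G for H, C, N, O and 6-31G/6-31G*
(Cartesian d) for H and O. The property tests (gauge invariance, fit
optimality, finite-difference consistency, charge conservation) hold for any
valid basis and do not depend on the tabulated values digit-for-digit.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `angular_order` | 50 | points per spherical shell; 6, 26, 50 are exact octahedrally-symmetric sets, other values use a Fibonacci sphere |
| `n_shells` | 9 | radial shells per atom |
| `shell_span` | 1.2-2.8 | shell radii as multiples of the Bondi van der Waals radius |
| `exclusion_scale` | 1.0 | points inside this multiple of any atom's Bondi radius are discarded |
| `gap_tol` | 1e-3 hartree | intersection-optimizer gap threshold |
| `grad_tol` | 3e-4 hartree/bohr | projected average-gradient RMS threshold |
| `mm_tol` | 1e-4 hartree/bohr | microiteration MM gradient RMS threshold |
| `sigma` | 1 hartree^-1 | gap-penalty weight in the composite objective |
| `trust` | 0.3 bohr | quasi-Newton trust radius |

The shell placement (linear from 1.2 to 2.8 Bondi radii) is a package choice:
only the shell *count* is prescribed by common usage; the placement spans the
region just outside the van der Waals surface where the ESP is well defined
but still molecule-dominated. Grid exclusion uses 1.0 Bondi radii against
*all* atoms (the inner shells at 1.2 radii survive against their own parent
by construction). The least squares is unweighted, solved through an SVD
pseudo-inverse (relative cutoff 1e-10) rather than the normal equations,
which is numerically safer for dense grids and identical in well-conditioned
cases; a rank-deficient fit matrix is an error, not a silent regularization.

Internal units are atomic throughout; angstrom appears only in file I/O.

# Gradient structure

The nuclear gradient splits into a QM block ($x$) and an MM block
($\tilde x$):

* QM block: $\mathrm{Tr}\,P(F_0^x + h'^x) - \mathrm{Tr}\,W S^x + E_{MM}^x +
  \sum_A Z_A \phi_A^x$. The ESPF operator derivative $h'^x$ has three
  sources: motion of the atom position inside $T$, rigid motion of the grid
  points attached to their parent atom (in both $T$ and the integrals), and
  the basis-center dependence of $V_{k,\mu\nu}$. Dropping the grid-motion
  terms breaks the finite-difference match at the $10^{-4}$ level — the
  ablation is part of the test suite.
* MM block: $\sum_A Q_A (\Phi_{av} - \phi_A)^{\tilde x} -
  \Phi_{av}^{\tilde x} N_{el} + \sum_A Z_A \phi_A^{\tilde x} +
  E_{MM}^{\tilde x}$ with $Q_A = \mathrm{Tr}(P Q_A)$ (for excited states, the
  state populations $Q_{A,I} = \mathrm{Tr}(P_I Q_A)$).

State-difference gradients are implemented as the literal difference of the
state-gradient expressions, which realizes the cancellation of the MM and
nuclear terms at fixed geometry automatically and keeps
`difference_gradient(I, J) = excited_gradient(J) - excited_gradient(I)` an
exact identity.

One caveat is inherent to a geometry-dependent exclusion rule: when a grid
point crosses another atom's van der Waals sphere the retained point set
changes discretely, so the energy is smooth only piecewise. The
finite-difference validator therefore uses geometries whose minimal
point-to-sphere margin exceeds the step (the symmetric water monomer has a
margin of ~9e-4 bohr against the default 1e-4 step).

# Conical-intersection search

Minimum-energy crossing points are located by minimizing the composite
objective

$$E = \tfrac12 (E_I + E_J) + \sigma\,(E_J - E_I)^2$$

with the gradient $B\,\nabla E_{av} + 2\sigma (E_J - E_I)(\nabla E_J -
\nabla E_I)$, where $B = 1 - \tilde d \tilde d^T - \tilde o \tilde o^T$
projects the branching plane out of the average gradient. The printed form of
the composite objective is dimensionally inhomogeneous, so the penalty
carries an explicit weight $\sigma$ (default 1 hartree$^{-1}$); its sign is
fixed by requiring that the penalty force closes the gap. $\tilde d$ is the
normalized difference gradient; $\tilde o$ is *estimated*, not computed: it
is updated from the previous plane by

$$\tilde o_k \propto (\tilde d_k \cdot \tilde d_{k-1})\,\tilde o_{k-1}
 - (\tilde d_k \cdot \tilde o_{k-1})\,\tilde d_{k-1},$$

renormalized and re-orthogonalized against $\tilde d_k$. Steps are
trust-radius BFGS on the composite gradient (radius 0.3 bohr by default);
convergence requires both the gap and the projected average-gradient RMS
below their thresholds.

**Step acceptance.** Because the projector makes the composite gradient a
non-conservative field, two acceptance rules are provided. The default
(`accept = "value"`) requires the composite energy to decrease, which is a
true descent criterion on peaked intersections and on the model surfaces. On
*sloped* intersections the average energy legitimately rises along the
difference direction while the gap closes, so a value line search stalls;
`accept = "gradient"` (accept steps that do not increase the composite
gradient norm) is the appropriate rule there and is what the nucleobase seam
searches use. A practical protocol for seams far from the starting point is
to first scan along the normalized difference-gradient direction until the
gap changes sign, then refine from the near-degenerate point.

**Initialization of the orthogonal vector.** The update recursion confines
$\tilde o_k$ to the span of its initial value and the difference-direction
history. Consequently, any gradient direction captured by the *initial*
$\tilde o$ that stays orthogonal to all later difference directions is
projected out of the optimization permanently. Initializing $\tilde o$ from
the average gradient (the default, matching common practice) therefore
freezes exactly the environment-relaxation direction in separable problems —
this is demonstrable on the bundled two-state model with harmonic spectator
coordinates, where the spectators never move. The `o_init = "random"` option
(seeded, reproducible) initializes $\tilde o$ with a random unit vector
orthogonal to $\tilde d$ instead, which leaves at most a random one-dimensional
blind spot and lets separable environments relax; the QM/MM intersection
searches in this package use it. In the worst case the method degrades into a
plain gap-penalty minimization, which still converges to the intersection
(with a softer gap), so the choice affects efficiency, not correctness.

Electronic states are tracked across geometries by the overlap of their AO
transition densities; if the maximal overlap is ambiguous (below 0.5) the
states are taken in energy order.

**Microiterations.** Between electronic-structure steps the MM environment
can be relaxed at fixed QM geometry and frozen QM density: the
MM-coordinate-dependent part of the total energy (the ESPF coupling at frozen
populations, the nuclear-MM Coulomb term and $E_{MM}$) is minimized with
L-BFGS, after which the SCF is re-converged. Re-polarization of the QM
density happens at the next macro-step, which is standard microiteration
practice.

# The synthetic systems

The droplet packer emulates the construction used in solvent-droplet studies:
rigid copies of a bundled solvent template (TIP3P-compatible flexible water;
an all-atom Amber94-style methanol with charges adjusted to exact
neutrality) are placed by rejection sampling with random rigid-body poses, a
2.0 angstrom minimum intersite distance and full containment in the droplet
sphere, reproducibly for a fixed seed. The packer reproduces liquid-like
densities (100 methanol molecules in a 12 angstrom sphere pack in seconds).
What it does *not* emulate: thermal disorder distributions (no Monte Carlo
or dynamics — packed configurations are athermal), polarizable charges, bulk
boundary conditions, and hydrogen-bond network statistics. Tests passing on
packed droplets therefore validate the mechanics (energies, gradients,
relaxation) rather than solvation thermodynamics.

The two-state linear-coupling model
$H(x, y) = \begin{pmatrix} \kappa x & \lambda y \\ \lambda y & -\kappa x
\end{pmatrix}$ has its conical intersection at the origin with an exactly
known branching plane, optionally embedded in higher dimension by harmonic
spectator coordinates; it is the analytic ground truth for the optimizer
tests.

# Numerical choices and degenerate inputs

* SCF: DIIS (subspace 8) on the orthonormalized error matrix, core-Hamiltonian
  guess, convergence at 1e-10 max DIIS error by default; non-convergence is an
  error carrying the last density.
* Boys function: series evaluation with downward recursion below T = 35,
  asymptotic form with upward recursion above.
* Two-electron derivative contractions require the density-factor tensor
  symmetrized over the eight permutations; primitive pairs are screened by
  their Gaussian prefactor against the largest density factor of the quartet
  (threshold 1e-14).
* `composite_gradient` rejects equal state gradients (degenerate plane);
  `update_orthogonal` falls back to Gram-Schmidt of the previous orthogonal
  vector when the new difference direction is orthogonal to the whole
  previous plane.
* Droplet packing validates the requested density up front and reports the
  achieved count on failure.
* ESPF fitting fails loudly when rank(T) < N_QM (e.g. overlapping atoms).

# Known limitations

* Hartree-Fock/CIS only: no DFT exchange-correlation in the built-in backend,
  hence quantitative excited-state energetics differ from hybrid-DFT results
  by the usual CIS errors. Reported critical-point energetics computed with
  this backend on a minimal basis are qualitative surrogates.
* Atom-centered monopole fits bound the far-field fidelity: for water the
  fitted-charge dipole deviates from the exact quantum dipole by ~1.6%
  regardless of grid density, so the relative far-field ESP error plateaus
  near 2e-2. This is a property of the charge model, not of the fit.
* The fitting grid is lab-frame; ESPF charges are rotationally invariant only
  up to the grid anisotropy (~1e-2 e) unless the grid orientation is rotated
  with the system (`build_grid(orientation = )`).
* No Ewald/periodicity, no polarizable force fields, no analytic Hessians,
  no exact nonadiabatic couplings (the branching-plane update replaces them
  by construction).

# Problem sizes used in the shipped checks

The test suite and the acceptance script run water (3 QM atoms, STO-3G and
6-31G*) with small point-charge environments for all gradient oracles, the
analytic two-state model for the optimizer, droplets of up to 100 solvent
molecules for the packer audits and the microiteration-relaxed droplet
estimates, and thymine (15 atoms, CIS/STO-3G) single points on
package-optimized critical-point structures for the
nucleobase-photochemistry surrogate. The droplet estimates average over three
independent packings; because packed configurations are athermal single
snapshots, the seed-to-seed spread of environment-sensitive energy gaps is of
order 1 eV and is reported alongside the mean. These sizes keep every check
deterministic and fast while exercising all code paths (s/p/d shells, both
gradient blocks, state tracking, microiterations).
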