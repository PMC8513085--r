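# espfqmm

Electrostatic embedding QM/MM with electrostatic-potential-fitted (ESPF)
charge operators, analytic excited-state gradients, and a branching-plane
conical-intersection optimizer — for mapping the photochemical critical
points of a chromophore inside a classical solvent droplet.

The package is aimed at method developers and computational photochemists who
want a small, fully self-contained, testable implementation of the ESPF
coupling chain: fit grid → charge operators → embedding Hamiltonian →
embedded SCF/TDA → analytic gradients → critical-point search.

## The model

The QM–MM electrostatic interaction is written through atom-centered fitted
charges,

```
ΔE = Σ_A q_A φ_A,      q_A = Z_A − Tr(P Q_A),      φ_A = Σ_i q_i^FF / |R_A − R_i|,
```

where the charge operators `Q_A,μν = Σ_k T⁺_{A,k} V_k,μν` are least-squares
fits of the electrostatic integrals on an atom-centered, van-der-Waals-excluded
grid (50 angular points × 9 radial shells per atom by default). Charge
conservation is imposed at the operator level through the embedding
Hamiltonian added to every Fock build,

```
h′ = Σ_A Q_A (Φ_av − φ_A) − Φ_av S,      Φ_av = (1/N_QM) Σ_A φ_A,
```

so a uniform external potential is an exact gauge: it shifts the electronic
energy by `−c·N_el` and leaves the density and all excitation energies
untouched. Total energies add the exact nuclear–MM Coulomb sum, the classical
MM energy, and (for excited states) the TDA excitation energy from the
embedded Fock matrix. Analytic nuclear gradients are available for the ground
state, excited states (Lagrangian/Z-vector relaxed densities) and state
differences, split into QM-atom and MM-site blocks, and are validated against
central finite differences with the fit grid rebuilt at every displaced
geometry.

Minimum-energy conical intersections are located by the branching-plane
update method: minimize `(E_I+E_J)/2 + σ(E_J−E_I)²` with the branching plane
(normalized difference-gradient vector plus an iteratively updated orthogonal
vector) projected out of the average gradient — no nonadiabatic couplings
required.

The electronic structure is supplied by a built-in Gaussian-basis backend
(McMurchie–Davidson integrals, restricted Hartree–Fock with DIIS, CIS/TDA
excited states, Z-vector relaxed densities, analytic derivative integrals).
Bundled plain-text data: STO-3G (H, C, N, O), 6-31G and 6-31G* (H, O) basis
sets; TIP3P-compatible water and Amber94-style methanol parameters; a
rejection-sampling droplet packer reproduces liquid-like solvent shells
deterministically per seed.

## Worked example

Water (QM, STO-3G) in a shell of 8 TIP3P waters (MM):

```r
library(espfqmm)
qm <- qm_region(c("O","H","H"),
        rbind(c(0,0,0.222), c(0,1.431,-0.887), c(0,-1.431,-0.887)))  # bohr
mm <- pack_droplet(qm, solvent_template("water"), 8, 11.3, seed = 1)
sys <- qmmm_system(qm, mm, basis = "sto-3g")
pt  <- prepare_point(sys, n_states = 1)

espf_charges(pt$scf$P, pt$ops, qm)
#> -0.6207  0.3059  0.3169    (total 0.0021; bounded by the fit-closure defect)

total_energy(pt)      # E(S0) = -74.960771 hartree (gas phase: -74.963023)
total_energy(pt, 1)   # E(S1) = -74.476189 hartree  -> omega = 13.19 eV (CIS/STO-3G)

excited_gradient(pt, 1)
#> gradient (state 1): |QM| rms 1.841e-01, |MM| rms 2.002e-03 hartree/bohr
# summed QM+MM force per Cartesian direction: ~1e-14 (translational invariance)
```

The lowest CIS/STO-3G excitation of water is high (13.2 eV) because the
minimal basis has essentially no diffuse virtual space; the embedding shift
relative to gas phase and all gradient identities are the meaningful outputs
here.

Locating a conical intersection on the analytic two-state model
(`H = [[x, y], [y, −x]]`, intersection at the origin):

```r
r <- optimize_ci(model_two_state(1, 1), 1, 2, c(1, 1),
                 gap_tol = 1e-8, grad_tol = 1e-4)
#> converged after 5 steps; gap 2.4e-14, position |x| ~ 1e-14
```

A command-line surface is installed at `inst/cli/espfqmm` with subcommands
`charges`, `energy`, `grad`, `fdcheck`, `opt-min`, `opt-ci`, `scan`,
`pack-droplet` and `path`.

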