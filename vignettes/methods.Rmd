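---
title: "Methods: emulating a hybrid quantum-classical drug-design pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulating a hybrid quantum-classical drug-design pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqemol)
```

## Scope and model

`vqemol` emulates, end to end, the workflow by which a small quantum
processor can be inserted into two standard drug-design computations: Gibbs
free-energy profiles of a prodrug-activation reaction (C-C bond cleavage in
solution) and QM/MM molecular dynamics of a covalent inhibitor. The quantum
processor's job in both is the same: store the correlated wave function of a
small active space and return measured energies and reduced density matrices
(RDMs). Everything else - mean field, solvation, forces, dynamics,
thermochemistry - is classical and couples to the quantum side only through
those RDMs.

The electronic Hamiltonian is the standard second-quantized form

$$\hat H = \sum_{pq} h_{pq}\, a^\dagger_p a_q
 + \tfrac12 \sum_{pqrs} [ps|qr]\, a^\dagger_p a^\dagger_q a_r a_s ,$$

with one- and two-electron integrals in the canonical restricted
Hartree-Fock (RHF) molecular-orbital basis. The package computes these
integrals itself: a compact McMurchie-Davidson Gaussian-integral engine
(`src/integrals.cpp`) with STO-3G and 6-31G basis data, plus an RHF solver
with DIIS. This is a deliberately minimal ab initio engine for small
closed-shell molecules; it is validated against textbook total energies
(H2/STO-3G -1.11676, H2O/STO-3G -74.96302, H2O/6-31G -75.98397 Hartree) and
against its own finite differences. Integral tensors are stored in Mulliken
(chemists') order, `eri[p,q,r,s] = (pq|rs)`, so the Hamiltonian coefficient
above is `eri[p,s,q,r]`.

### Active space and frozen core

Chemically interesting correlation is confined to a HOMO-LUMO-centered
active space - `(2e, 2o)` throughout the worked examples. The remaining
doubly occupied orbitals are frozen at mean field: they contribute an
effective one-electron potential
$V^{\mathrm{eff}}_{pq} = \sum_{m}(2[mm|pq]-[mp|qm])$
and a scalar core energy
$E_{\mathrm{core}} = 2\sum_m h_{mm} + \sum_{mn}(2[mm|nn]-[mn|nm])$
(spatial-orbital, closed-shell form). `casci()` diagonalizes the folded
Hamiltonian exactly in the $S_z=0$ determinant basis; it is both the
classical reference engine and the oracle for the quantum emulation.
Canonical RHF orbitals are assumed for every species; ties in the orbital
energy window are broken by ascending orbital index.

### Qubit mapping

`parity_transform()` maps the active space to qubits with the parity
encoding (qubit $j$ stores the cumulative occupation parity of spin-orbitals
$1..j$), using blocked spin ordering (all alpha, then all beta). Blocking
localizes two exact symmetries - alpha parity and total parity - on qubits
$N/2$ and $N$, whose Pauli-$Z$ operators can be replaced by their sector
eigenvalues: a `(2e,2o)` problem runs on 2 qubits. Coefficients below
1e-10 Hartree are truncated (far below chemical relevance, far above
double-precision noise). The Jordan-Wigner mapping is included as a
cross-check; spectra of both mappings are tested against dense fermionic
matrices built by an independent Kronecker-product construction.

A generic (symmetry-free) `(2e,2o)` Hamiltonian maps to 8 measurable Pauli
strings, {ZI, IZ, ZZ, XX, XI, IX, XZ, ZX}; point-group symmetry (as in H2)
removes half of them. `group_commuting()` partitions strings into
qubit-wise-commuting groups by greedy first-fit in order of decreasing
coefficient magnitude, each group measurable in one product basis. For the
generic 8-string set this yields 4 groups, which is in fact the minimum:
the four single-X strings always pair up with a compatible partner, and the
count is invariant under per-qubit basis relabeling. Hardware workflows
have been reported that measure the same Hamiltonian in 5 settings; that is
a valid but non-minimal partition, and this package intentionally keeps the
algorithmically defined (minimal greedy) result rather than reproducing a
particular tool's output.

### VQE emulation

The ansatz is the single-layer hardware-efficient circuit
$|\psi(\theta)\rangle = L^{(k)}_{R_y}\cdots L^{(1)}_{\mathrm{CNOT}}
L^{(0)}_{R_y}|\phi\rangle$ with $k=1$ by default: one Ry rotation per qubit,
a CNOT ladder, one more Ry layer. Ry and CNOT preserve real amplitudes,
which suits real molecular ground states. The initial bitstring $|\phi\rangle$
is the Hartree-Fock determinant in the parity encoding (the choice is a
convention; the optimizer is tested to reach the exact ground state from it
with random restarts). `vqe()` optimizes the angles with L-BFGS-B and
parameter-shift gradients against the exact statevector expectation -
classical pre-optimization, as one does before committing shots on
hardware. Across random `(2e,2o)` fixtures the single-layer ansatz recovers
the exact (CASCI) energy to better than 1e-6 Hartree; the variational bound
is asserted everywhere.

Shot-based measurement (`measurement_plan()`) rotates the optimized state
into each group's product basis, samples 8192 bitstrings per group by
default, and sums coefficient-weighted outcomes. Readout error is modeled
as independent per-qubit 2x2 confusion matrices; mitigation inverts the
tensor-product confusion matrix and clips negative quasi-probabilities.
Repeated sampled pipelines (`simulate()`, default 4 repeats) are aggregated
as mean +/- sample standard deviation, the way repeated hardware
experiments are reported. The reported standard error follows the variance
model $\epsilon^2 \approx \frac1K \sum_j |\alpha_j|^2$ and is tested to
scale as $K^{-1/2}$.

RDMs are measured under the same mapping: each spatial 1- and 2-RDM element
is a small Pauli sum (all RDM operators conserve both tapered symmetries,
so the two-qubit reduction applies unchanged), and one grouped sampling run
is shared across all elements.

### Continuum solvation

The conductor-like screening model places the solute in a cavity of
atom-centered spheres (UFF radii x 1.2 by default, overridable), discretized
with 194 quasi-uniform Fibonacci points per sphere; buried points are
removed. Surface charges solve the conductor condition $V_r(s) = -\Phi(s)$
as a boundary-element system whose diagonal $1.0694\sqrt{4\pi/S_i}$ makes
the Born sphere exact in the grid limit (verified to <1% at 194 points).
Energies and the reaction-field operator are scaled by
$f(\varepsilon) = (\varepsilon-1)/\varepsilon$, water
$\varepsilon = 78.3553$. No domain-decomposition solver is used: at these
cavity sizes (tens to a few hundred points) a dense solve is exact and
cheap, and the contract - boundary condition, scaling, density interface -
is what the rest of the pipeline depends on. Nonelectrostatic terms
(cavitation, dispersion) are out of scope.

The coupling is the single-pass scheme used on hardware: converge the
solvated mean field classically; fold the mean-field reaction field into
the active-space Hamiltonian; solve the active space once (CASCI or VQE);
re-polarize the continuum with the measured 1-RDM; report
$E = \langle \hat H_{\mathrm{gas}}\rangle + E_s[\rho]$. A fully
self-consistent loop (`iterate = TRUE`, fixed mean-field orbitals, 1-RDM
convergence 1e-6) exists behind a flag; on the water fixture the difference
from the single pass is ~3e-12 Hartree, orders of magnitude below the
8192-shot sampling noise (~3e-3 Hartree), which is why the single pass is
the default.

### Analytic forces

Because the RHF orbitals are fixed before the correlated solve, the energy
is not stationary with respect to the orbital coefficients and the nuclear
gradient needs more than Hellmann-Feynman terms. `assemble_forces()`
decomposes the force into: nuclear and electronic Hellmann-Feynman terms;
an "integral force" from the basis-function derivatives of the one- and
two-electron integrals, contracted with the inactive density, the
active density back-transformed from the measured 1-RDM, and the full
two-body density (inactive products, inactive-active Coulomb/exchange
cross terms, correlated active block from the measured 2-RDM); and a
"density force" from the orbital rotations. For the density force the
package solves the coupled-perturbed Hartree-Fock (CPHF) equations of the
canonical orbitals and contracts the rotation with the generalized-Fock
energy-weighted density (which reduces to $C\epsilon C^\dagger$ with
occupation weights in the mean-field limit). The perturbation-independent
CPHF response matrix is factored once per geometry, so the per-coordinate
cost is one small linear solve. With the response included the gradient is
exact: 5-point finite differences agree to ~1e-10 Hartree/Bohr on both
full-active-space and frozen-core fixtures, and net force and torque vanish
for isolated molecules. Without it, frozen-core gradients err at the
1e-3 Hartree/Bohr level, which is why the response is not optional.
Solvation-energy gradients are not implemented (the dynamics embeds point
charges, not a continuum).

### QM/MM dynamics

The MM region enters the QM Hamiltonian as point charges (electrostatic
embedding); MM sites feel the exact electronic force through the
Hellmann-Feynman operator derivative plus the CPHF response. MM-MM Coulomb
and all Lennard-Jones interactions are classical and live in the MD driver,
not in the QM energy. The integrator is BAOAB Langevin splitting (a
robust, widely used discretization; defaults dt = 0.5 fs, gamma = 1/ps,
T = 300 K), which reduces to velocity Verlet at zero friction; symplectic
energy conservation and thermostat equipartition are both tested. QM
engines are hot-swappable per step with identical state hand-off: the
central claim - that an exact-expectation quantum engine is
trajectory-identical to the classical engine, and that shot-noise segments
stay inside the statistical envelope - is asserted at 1e-8 on toy systems
(H2 in a neutral random charge bath). There are no covalent QM/MM cuts in
the toy systems, so no link atoms; periodic boundaries and force-field
preparation are out of scope.

## Synthetic fixtures

`random_active_integrals()` draws Hamiltonians with exactly the structure
the physics guarantees: symmetric $h$, two-electron tensors built as sums
of symmetric rank-one factors (hence full 8-fold permutational symmetry and
a positive-semidefinite Coulomb metric), and a dominant diagonal
$(pp|pp)$. Asymmetric mode bounds one-electron off-diagonals away from
zero so the generic 8-string qubit Hamiltonian is realized; symmetric mode
imposes two mock irreducible representations whose selection rules mimic a
point-group-symmetric molecule. `toy_solvated_system()` builds an H2 or
water QM region inside a neutral random point-charge bath with
Lennard-Jones sites - a stand-in for a solvated protein environment with
none of its slow time scales, heterogeneity, or covalent boundary. Passing
the test suite therefore demonstrates the correctness of the machinery, not
the biophysical fidelity of any particular force field.

## Problem sizes and numerical choices

The test suite runs spectra checks on ~20 random fixtures of 2-4 orbitals
(dense oracles up to 256x256), 20 VQE optimizations, finite-difference
force checks on 5 displaced small-molecule fixtures, MD segments of 10-20
steps for engine-equivalence and envelope checks, and 1e4-1e5-step
classical integrator checks; the whole suite completes in about a minute on
one core. Key tolerances: SCF residual 1e-10; CASCI degeneracy flag 1e-10;
Pauli coefficient truncation 1e-10 Hartree; VQE gradient-norm target 1e-6;
CPHF degenerate-pair guard 1e-8 (degenerate orbital pairs take the
orthonormality rotation only). Every stochastic path takes an explicit
seed, and all internal seeding is RNG-hygienic (the caller's RNG state is
restored), which is what makes hybrid trajectories with and without quantum
segments bitwise comparable.

## Worked reaction profile

The packaged species table carries published per-species Gibbs energies for
the prodrug-activation reaction `4 -> TS -> 5 + 6 + H2O` (reactant,
transition state, cleavage products). The stoichiometry is the config
default but overridable. Profile assembly converts with 627.5095
kcal/mol per Hartree and propagates independent per-species standard
deviations in quadrature:

```{r profile}
prof <- assemble_profile(prodrug_species("CASCI", "with"),
                         reactants = "4", transition_state = "TS",
                         products = c("5", "6", "H2O"))
prof
classify_spontaneity(prof)
```

One known rounding limit: the gas-phase CASCI barrier computed from the
printed per-species values is 1.3 kcal/mol where the published table prints
1.4 - the per-species precision (1e-4 Hartree ~ 0.06 kcal/mol per species)
does not determine the last digit. The test asserts agreement within
0.1 kcal/mol there and exact agreement (after rounding to one decimal)
everywhere else. Each printed energy is treated as a complete Gibbs energy;
thermal corrections, when supplied separately, are accepted as inputs
(`gibbs_correction`) rather than re-derived.

## Known limitations

* The integral engine covers s/p Gaussians (STO-3G, 6-31G; H, He, C, N, O,
  S) and closed-shell RHF references only; open-shell frozen cores are
  rejected. Larger basis sets (e.g. triple-zeta with polarization) would
  need d-function basis data and are the main reason absolute energies here
  are not comparable to published triple-zeta numbers.
* `casci()` uses dense diagonalization, limited to ~8 active orbitals.
* The readout model is a tensor product of per-qubit confusion matrices;
  gate noise and relaxation during the circuit are not modeled (relaxation
  enters only the resource estimator's reset-time model).
* The continuum solver is a single-level boundary-element COSMO; it is
  exact for the Born sphere and adequate for small cavities, but has no
  domain-decomposition scaling for large solutes.
* Resource estimates are arithmetic models (pairing-restricted excitation
  counts, empirical 0.7 N^2 Pauli-term scaling, reset-time-dominated shot
  timing), not circuit compilations.
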