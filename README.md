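# vqemol

Hybrid quantum–classical electronic structure for drug design, fully
emulated in R.

Two computations dominate early structure-based drug design: Gibbs
free-energy profiles of activation reactions (is the barrier low enough to
proceed in a cell?) and QM/MM molecular dynamics of drug–target complexes
(is the covalent bond stable?). A small quantum processor can take over the
correlated part of both: it stores the wave function of a HOMO/LUMO-centered
active space and returns measured energies and reduced density matrices
(RDMs), which classical code folds into solvation models, nuclear forces and
thermochemistry. `vqemol` implements that whole pipeline with an emulated
quantum backend, for computational chemists who want to study the workflow —
accuracy, shot-noise behavior, classical/quantum hand-off — without hardware.

The core model, in the field's standard notation:

* **Electronic Hamiltonian** `H = Σ h_pq a†_p a_q + ½ Σ [ps|qr] a†_p a†_q a_r a_s`
  in canonical RHF orbitals, from a built-in Gaussian-integral (McMurchie–
  Davidson) + RHF engine (STO-3G, 6-31G).
* **Frozen-core active space**: `V_eff_pq = Σ_m (2[mm|pq] − [mp|qm])`,
  `E_core = 2Σ h_mm + Σ (2[mm|nn] − [mn|nm])`; exact CASCI reference by
  dense diagonalization.
* **Parity fermion–qubit mapping** with two-qubit reduction (a `(2e,2o)`
  space runs on 2 qubits), Pauli terms grouped by qubit-wise commutation.
* **VQE**: single-layer hardware-efficient Ry ansatz, L-BFGS-B with
  parameter-shift gradients, shot-based measurement with per-qubit readout
  confusion and linear-inversion mitigation, variance model
  `ε² ≈ (1/K) Σ_j |α_j|²`.
* **COSMO solvation** (conductor boundary condition `V_r = −Φ` on an
  atom-sphere cavity, scaled by `f(ε) = (ε−1)/ε`), coupled to the quantum
  solver single-pass through the measured 1-RDM.
* **Analytic forces** for the non-variational frozen-core energy
  (Hellmann–Feynman + density force + integral force, with full CPHF
  orbital response), feeding **BAOAB Langevin QM/MM dynamics** with
  hot-swappable classical/quantum engines.
* **pUCCD resource arithmetic**: paired-excitation counts
  `(N_elec/2)(N − N_elec/2)`, `0.7 N²` Pauli terms, reset-time-limited shot
  budgets.

## Worked example

Water, (2e,2o) active space, 2-qubit VQE, solvation, and the packaged
prodrug reaction profile:

```r
library(vqemol)
h2o <- geometry(c("O","H","H"),
                rbind(c(0,0,0.1173), c(0,0.7572,-0.4692), c(0,-0.7572,-0.4692)))
ints <- mol_integrals(h2o)
#> Molecular integrals: 7 orbitals, 10 electrons, basis sto-3g
#>   E(HF) = -74.9630231629 Hartree (nuclear repulsion 9.1895337626)

qh <- parity_transform(fold_active_space(ints, active_space(ints, 2, 2)))
#> Qubit Hamiltonian (parity): 2 qubits, 4 Pauli terms, offset -74.44212446
#> (water is symmetric; an asymmetric species has the generic 8 strings)

fit <- vqe(qh)
summary(fit)
#> VQE summary (2 qubits, 1 layers, 4 Pauli terms)
#>   E(VQE)   = -74.9642716974 Hartree
#>   E(exact) = -74.9642716974 Hartree (diagonalization)
```

The VQE energy equals the exact active-space (CASCI) energy to machine
precision: the single-layer Ry ansatz is expressive enough for a 2-qubit
sector. Four repeated shot-based "hardware runs" (8192 shots/group, 2%
readout error, mitigated) scatter around it with millihartree noise:

```r
simulate(fit, nsim = 4, seed = 1, shots = 8192,
         readout = readout_confusion(2, 0.02), mitigate = TRUE)$energy
#> -74.9645 -74.9619 -74.9630 -74.9623
```

Single-pass solvation couples the measured 1-RDM to the continuum
(`E_solv < 0` stabilizes the polar molecule), and the packaged per-species
Gibbs table assembles the prodrug-activation profile:

```r
solvated_energy_single_pass(h2o, engine = "vqe")$e_total
#> E(gas) = -74.964174, E_solv = -0.003516, E(total) = -74.967690 Hartree

assemble_profile(prodrug_species("VQE", "with"),
                 reactants = "4", transition_state = "TS",
                 products = c("5", "6", "H2O"))
#> Reaction profile: 4 -> TS -> 5 + 6 + H2O
#>   dG_barrier  = 6.7 +/- 5.4 kcal/mol
#>   dG_reaction = -51.3 +/- 12.4 kcal/mol
```

A barrier below 20 kcal/mol means the activation step is accessible under
physiological conditions (`classify_spontaneity()`); the large negative
reaction energy means the cleavage is strongly favorable.

See `vignettes/methods.Rmd` for the full account of the models, defaults,
and numerical choices.

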