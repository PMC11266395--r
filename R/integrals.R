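# Molecular integrals in the molecular-orbital basis: the entry point of the
# electronic-structure pipeline. Runs restricted HF and transforms the AO
# integrals; all stored energies in Hartree.

# four-index transform (pq|rs) -> MO basis, O(n^5) via repeated contraction
ao2mo_full <- function(eri, C) {
  n <- nrow(C)
  M <- eri
  for (i in 1:4) M <- array(t(matrix(M, n, n^3)) %*% C, c(n, n, n, n))
  M
}

nuclear_repulsion <- function(Z, xyz_bohr) {
  n <- length(Z)
  e <- 0
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      e <- e + Z[i] * Z[j] / sqrt(sum((xyz_bohr[i, ] - xyz_bohr[j, ])^2))
  e
}

#' Compute molecular integrals and the mean-field reference
#'
#' Runs restricted Hartree-Fock for a closed-shell molecule in a Gaussian
#' basis and returns one- and two-electron integrals transformed to the
#' canonical molecular-orbital basis, together with the orbital coefficients,
#' orbital energies and nuclear repulsion. Optionally embeds external point
#' charges (an MM environment) in the one-electron Hamiltonian, and accepts an
#' additional AO-basis one-electron operator (used for solvent reaction
#' fields).
#'
#' The two-electron tensor is stored in Mulliken (chemists') order,
#' `eri[p,q,r,s] = (pq|rs)`; the Hamiltonian coefficient of
#' `a+_p a+_q a_r a_s` is `[ps|qr] = eri[p,s,q,r]`.
#'
#' @param geom a [geometry()] object.
#' @param basis basis-set name, `"sto-3g"` (default) or `"6-31g"`.
#' @param charge total molecular charge.
#' @param point_charges optional MM environment: data frame with columns
#'   `x`, `y`, `z` (Angstrom) and `q` (elementary charges).
#' @param h_extra_ao optional AO-basis one-electron operator added to the core
#'   Hamiltonian before SCF (Hartree).
#' @param scf_conv SCF convergence threshold on the orbital-gradient residual.
#' @return An object of class `mol_integrals` with fields `n_orb`, `n_elec`,
#'   `h_core` (MO one-electron integrals), `eri` (MO two-electron tensor),
#'   `e_nuc` (nuclear repulsion plus nucleus/point-charge interaction),
#'   `mo_coeff`, `mo_energy`, `ao_overlap`, `e_hf`, and the AO-basis
#'   ingredients needed for density back-transformation and gradients.
#' @examples
#' h2 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
#' ints <- mol_integrals(h2)
#' ints$n_orb   # 2 spatial orbitals in a minimal basis
#' ints$e_hf    # restricted HF total energy (Hartree)
#' @export
mol_integrals <- function(geom, basis = "sto-3g", charge = 0,
                          point_charges = NULL, h_extra_ao = NULL,
                          scf_conv = 1e-10) {
  stopifnot(inherits(geom, "mol_geometry"))
  Z <- element_Z(geom$symbols)
  n_elec <- sum(Z) - charge
  xyz <- coords_bohr(geom)
  sh <- build_shells(geom$symbols, basis)
  one <- cpp_int1e(sh$l, sh$atom, sh$exps, sh$coefs, xyz)
  Vnuc <- cpp_attraction(sh$l, sh$atom, sh$exps, sh$coefs, xyz, xyz, as.numeric(Z))
  Hcore <- one$T + Vnuc
  e_nuc <- nuclear_repulsion(Z, xyz)
  mm <- NULL
  if (!is.null(point_charges) && nrow(point_charges) > 0) {
    mm_xyz <- as.matrix(point_charges[, c("x", "y", "z")]) / BOHR_ANGSTROM
    mm_q <- point_charges$q
    Vmm <- cpp_attraction(sh$l, sh$atom, sh$exps, sh$coefs, xyz, mm_xyz, mm_q)
    Hcore <- Hcore + Vmm
    for (i in seq_along(Z))
      e_nuc <- e_nuc + sum(Z[i] * mm_q / sqrt(colSums((t(mm_xyz) - xyz[i, ])^2)))
    mm <- list(xyz_bohr = mm_xyz, q = mm_q)
  }
  eri_ao <- array(cpp_eri(sh$l, sh$atom, sh$exps, sh$coefs, xyz),
                  c(sh$nbf, sh$nbf, sh$nbf, sh$nbf))
  scf <- scf_rhf(one$S, Hcore, eri_ao, n_elec, h_extra = h_extra_ao,
                 conv = scf_conv)
  C <- scf$C
  h_ao_tot <- Hcore + if (is.null(h_extra_ao)) 0 else h_extra_ao
  h_mo <- t(C) %*% h_ao_tot %*% C
  eri_mo <- ao2mo_full(eri_ao, C)
  structure(list(
    n_orb = sh$nbf, n_elec = n_elec,
    h_core = h_mo, eri = eri_mo, e_nuc = e_nuc,
    mo_coeff = C, mo_energy = scf$mo_energy, ao_overlap = one$S,
    geometry = geom, basis = basis, charge = charge,
    e_hf = scf$e_elec + e_nuc,
    ao = list(S = one$S, T = one$T, Vnuc = Vnuc, Hcore = h_ao_tot,
              Hcore_bare = Hcore, h_extra = h_extra_ao,
              eri = eri_ao, D_hf = scf$D, fock = scf$fock, shells = sh,
              Z = Z, xyz_bohr = xyz, mm = mm),
    scf_iterations = scf$n_iter
  ), class = "mol_integrals")
}

#' @export
print.mol_integrals <- function(x, ...) {
  cat(sprintf("Molecular integrals: %d orbitals, %d electrons, basis %s\n",
              x$n_orb, x$n_elec, x$basis))
  cat(sprintf("  E(HF) = %.10f Hartree (nuclear repulsion %.10f)\n",
              x$e_hf, x$e_nuc))
  invisible(x)
}
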