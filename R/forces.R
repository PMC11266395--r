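# Analytic nuclear gradients of the frozen-core active-space (CASCI) energy
# from measured reduced density matrices. The mean-field orbitals are fixed
# (not variationally relaxed), so beyond the Hellmann-Feynman terms the
# gradient carries a "density force" built from the generalized-Fock
# energy-weighted density (which reduces to C eps C^T for canonical HF
# occupations) and an "integral force" from the basis-set derivatives,
# contracted with the inactive/active one-body densities and the active
# two-body density. All forces in Hartree/Bohr.

# Mulliken mean-field-like 2-RDM form: G[pqrs] = D_pq D_rs - 1/2 D_ps D_qr
.dd_gamma <- function(D) {
  J <- outer(D, D)                         # [p,q,r,s] = D_pq D_rs
  Kt <- aperm(outer(D, D), c(1, 4, 2, 3))  # [p,q,r,s] = D_ps D_qr
  J - 0.5 * Kt
}

# basis change of a rank-4 Mulliken tensor: out = sum T[ijkl] M[i,a]M[j,b]...
.tensor_change <- function(T4, M) {
  din <- nrow(M); dout <- ncol(M)
  cur <- T4
  d <- rep(din, 4)
  for (step in 1:4) {
    cur <- array(t(matrix(cur, d[1], prod(d[-1]))) %*% M, c(d[-1], dout))
    d <- c(d[-1], dout)
  }
  cur
}

#' Assemble force inputs from integrals and active-space RDMs
#'
#' Builds the AO-basis inactive and active one-body densities, the full
#' two-body density (inactive mean-field product terms, inactive-active
#' Coulomb/exchange cross terms, and the correlated active block), the
#' generalized-Fock energy-weighted density, and the derivative integrals.
#'
#' @param ints a [mol_integrals()] object (gas phase or with embedded point
#'   charges; continuum-solvent gradients are not supported).
#' @param spec the [active_space()] used (`NULL` = all orbitals active).
#' @param rdm1,rdm2 active-space RDMs (from [casci()] or [measure_rdms()]).
#' @return A `force_inputs` list consumed by [assemble_forces()].
#' @export
force_inputs <- function(ints, spec, rdm1, rdm2) {
  n <- ints$n_orb
  C <- ints$mo_coeff
  if (is.null(spec))
    spec <- structure(list(n_active_orb = n, n_active_elec = ints$n_elec,
                           frozen_set = integer(0), active_set = seq_len(n)),
                      class = "active_space_spec")
  act <- spec$active_set; frz <- spec$frozen_set
  Ca <- C[, act, drop = FALSE]
  D_I <- if (length(frz)) {
    Cf <- C[, frz, drop = FALSE]
    2 * Cf %*% t(Cf)
  } else matrix(0, n, n)
  D_A <- Ca %*% rdm1 %*% t(Ca)
  D <- D_I + D_A
  # Mulliken active 2-RDM: GammaM[P,Q,R,S] = rdm2[P,R,S,Q]
  gammaM_act <- aperm(rdm2, c(1, 4, 2, 3))
  # full-space MO one-body density
  gmo <- matrix(0, n, n)
  if (length(frz)) gmo[cbind(frz, frz)] <- 2
  gmo[act, act] <- rdm1
  gmo_A <- matrix(0, n, n)
  gmo_A[act, act] <- rdm1
  # full MO Mulliken 2-RDM: mean-field form of the total density, with the
  # active-active product block replaced by the correlated block
  gamma_full_mo <- .dd_gamma(gmo) - .dd_gamma(gmo_A)
  gamma_full_mo[act, act, act, act] <- gamma_full_mo[act, act, act, act] + gammaM_act
  # generalized Fock -> energy-weighted density W = 1/2 C X C^T
  h_mo <- t(C) %*% ints$ao$Hcore_bare %*% C
  X1 <- 2 * h_mo %*% gmo
  G1 <- matrix(ints$eri, n, n^3)
  G2 <- matrix(gamma_full_mo, n, n^3)
  X2 <- 2 * G1 %*% t(G2)
  X <- X1 + X2
  W <- C %*% ((X + t(X)) / 2) %*% t(C) / 2
  # AO two-body density for the integral-force contraction
  gamma_full_ao <- .dd_gamma(D) - .dd_gamma(D_A) +
    .tensor_change(gammaM_act, t(Ca))
  sh <- ints$ao$shells
  xyz <- ints$ao$xyz_bohr
  Z <- ints$ao$Z
  mm <- ints$ao$mm
  cpos <- xyz; cq <- as.numeric(Z)
  if (!is.null(mm)) { cpos <- rbind(cpos, mm$xyz_bohr); cq <- c(cq, mm$q) }
  d1 <- cpp_int1e_deriv(sh$l, sh$atom, sh$exps, sh$coefs, xyz, cpos, cq)
  dg <- cpp_eri_deriv(sh$l, sh$atom, sh$exps, sh$coefs, xyz)
  # coupled-perturbed HF machinery: the orbital-rotation response of the
  # canonical orbitals. The occupied-virtual response matrix
  # A[(ai),(bj)] = (eps_a - eps_i) delta - [4(ai|bj) - (ab|ij) - (aj|ib)]
  # is perturbation-independent; factor it once.
  eps <- ints$mo_energy
  nocc <- ints$n_elec / 2
  occ <- seq_len(nocc); virt <- setdiff(seq_len(n), occ)
  g <- ints$eri
  nov <- length(virt) * nocc
  Acphf <- NULL
  if (nov > 0) {
    Acphf <- matrix(0, nov, nov)
    k1 <- 0
    for (i in occ) for (a in virt) {
      k1 <- k1 + 1; k2 <- 0
      for (j in occ) for (b in virt) {
        k2 <- k2 + 1
        Acphf[k1, k2] <- 4 * g[a, i, b, j] - g[a, b, i, j] - g[a, j, i, b]
        if (k1 == k2) Acphf[k1, k2] <- Acphf[k1, k2] + (eps[a] - eps[i])
      }
    }
  }
  list(ints = ints, spec = spec, D_I = D_I, D_A = D_A, D = D, W = W, X = X,
       gamma_full_ao = gamma_full_ao, deriv1 = d1, deriv_eri = dg,
       charges_pos = cpos, charges_q = cq,
       n_mm = if (is.null(mm)) 0 else length(mm$q),
       cphf = list(A = Acphf, occ = occ, virt = virt, eps = eps, h_mo = h_mo))
}

# first-order orbital rotation U for one perturbation, from the canonical
# perturbed-Fock equations: U_pq = (F1_pq - S1_pq eps_q) / (eps_q - eps_p)
# with the occupied-virtual block solved self-consistently (CPHF)
.cphf_rotation <- function(fi, S1, h1, g1_mo) {
  cp <- fi$cphf
  ints <- fi$ints
  n <- ints$n_orb
  occ <- cp$occ; virt <- cp$virt; eps <- cp$eps
  g <- ints$eri
  # frame part of the Fock derivative in MO
  G1 <- matrix(0, n, n)
  if (!is.null(g1_mo)) {
    for (i in occ) G1 <- G1 + 2 * g1_mo[, , i, i] - g1_mo[, i, , i]
  }
  # known density response from orthonormality (occupied-occupied rotations)
  Dk <- matrix(0, n, n)
  Dk[occ, occ] <- -2 * S1[occ, occ]
  GDk <- matrix(0, n, n)
  for (p in seq_len(n)) for (q in seq_len(n))
    GDk[p, q] <- sum(Dk * (g[p, q, , ] - 0.5 * g[p, , q, ]))
  F1k <- h1 + G1 + GDk
  U <- matrix(0, n, n)
  diag(U) <- -0.5 * diag(S1)
  if (length(virt) > 0) {
    rhs <- numeric(length(virt) * length(occ))
    k <- 0
    for (i in occ) for (a in virt) {
      k <- k + 1
      rhs[k] <- -(F1k[a, i] - S1[a, i] * eps[i])
    }
    u <- solve(cp$A, rhs)
    k <- 0
    Du <- matrix(0, n, n)
    for (i in occ) for (a in virt) {
      k <- k + 1
      U[a, i] <- u[k]
      U[i, a] <- -S1[i, a] - u[k]
      Du[a, i] <- Du[i, a] <- 2 * u[k]
    }
    GDu <- matrix(0, n, n)
    for (p in seq_len(n)) for (q in seq_len(n))
      GDu[p, q] <- sum(Du * (g[p, q, , ] - 0.5 * g[p, , q, ]))
    F1 <- F1k + GDu
  } else F1 <- F1k
  # remaining blocks (occ-occ, virt-virt) from the canonical condition
  for (blk in list(occ, virt)) {
    if (length(blk) < 2) next
    for (p in blk) for (q in blk) {
      if (p == q) next
      de <- eps[q] - eps[p]
      U[p, q] <- if (abs(de) > 1e-8) (F1[p, q] - S1[p, q] * eps[q]) / de
                 else -0.5 * S1[p, q]  # degenerate pair: orthonormality part only
    }
  }
  U
}

# gradient of the classical Coulomb energy among the listed charges wrt one
# charge position (Hartree/Bohr); `partners` restricts which pair terms are
# part of the differentiated energy (MM-MM Coulomb lives in the classical
# force field, not in the QM Hamiltonian)
.coulomb_grad <- function(pos, q, i, partners = seq_along(q)) {
  g <- numeric(3)
  for (j in partners) {
    if (j == i) next
    d <- pos[i, ] - pos[j, ]
    g <- g - q[i] * q[j] * d / sum(d^2)^1.5
  }
  g
}

#' Assemble the force decomposition
#'
#' Contracts the derivative integrals with the densities from
#' [force_inputs()]: nuclear and electronic Hellmann-Feynman forces, the
#' density force (energy-weighted density against the overlap derivative),
#' and the integral force (one- and two-electron basis-derivative terms).
#' The total force is minus the energy gradient.
#'
#' @param fi a [force_inputs()] object.
#' @return A `force_decomposition`: per-atom 3-vectors `f_nuc`, `f_elec`,
#'   `f_density`, `f_integral`, `total` (Hartree/Bohr), and `mm_forces` for
#'   embedded point charges (electrostatic part only).
#' @export
assemble_forces <- function(fi) {
  ints <- fi$ints
  natom <- nrow(ints$geometry$coords)
  nbf <- ints$n_orb
  C <- ints$mo_coeff
  f_nuc <- f_elec <- f_density <- f_integral <- matrix(0, natom, 3)
  for (a in seq_len(natom)) for (dim in 1:3) {
    x <- 3 * (a - 1) + dim
    dS <- matrix(fi$deriv1$dS[, , x], nbf, nbf)
    dHb <- matrix(fi$deriv1$dT[, , x] + fi$deriv1$dVbasis[, , x], nbf, nbf)
    dVop <- matrix(fi$deriv1$dVop[, , x], nbf, nbf)
    de_nuc <- .coulomb_grad(fi$charges_pos, fi$charges_q, a)[dim]
    f_nuc[a, dim] <- -de_nuc
    f_elec[a, dim] <- -sum(dVop * fi$D)
    # orbital response: CPHF rotation against the generalized-Fock gradient
    S1 <- t(C) %*% dS %*% C
    h1 <- t(C) %*% (dHb + dVop) %*% C
    g1_mo <- ao2mo_full(array(fi$deriv_eri[, x], rep(nbf, 4)), C)
    U <- .cphf_rotation(fi, S1, h1, g1_mo)
    f_density[a, dim] <- -sum(fi$X * U)
    e_int <- sum(dHb * fi$D) +
      0.5 * sum(fi$deriv_eri[, x] * as.vector(fi$gamma_full_ao))
    f_integral[a, dim] <- -e_int
  }
  mm_forces <- NULL
  if (fi$n_mm > 0) {
    nmm <- fi$n_mm
    mm_forces <- matrix(0, nmm, 3)
    S0 <- matrix(0, nbf, nbf)
    for (c in seq_len(nmm)) for (dim in 1:3) {
      x <- 3 * (natom + c - 1) + dim
      dVop <- matrix(fi$deriv1$dVop[, , x], nbf, nbf)
      h1 <- t(C) %*% dVop %*% C
      U <- .cphf_rotation(fi, S0, h1, NULL)
      de <- sum(dVop * fi$D) + sum(fi$X * U) +
        .coulomb_grad(fi$charges_pos, fi$charges_q, natom + c,
                      partners = seq_len(natom))[dim]
      mm_forces[c, dim] <- -de
    }
  }
  structure(list(f_nuc = f_nuc, f_elec = f_elec, f_density = f_density,
                 f_integral = f_integral,
                 total = f_nuc + f_elec + f_density + f_integral,
                 mm_forces = mm_forces),
            class = "force_decomposition")
}

#' @export
print.force_decomposition <- function(x, ...) {
  cat("Force decomposition (Hartree/Bohr):\n")
  cat("  total:\n")
  print(round(x$total, 8))
  cat(sprintf("  net force: [%s]\n",
              paste(sprintf("%.2e", colSums(x$total)), collapse = ", ")))
  invisible(x)
}

#' Forces from a classical CASCI solve
#'
#' @param ints a [mol_integrals()] object.
#' @param spec the [active_space()] (`NULL` = full space).
#' @return A `force_decomposition`.
#' @export
casci_forces <- function(ints, spec = NULL) {
  cs <- casci(fold_active_space(ints, spec))
  assemble_forces(force_inputs(ints, spec, cs$rdm1, cs$rdm2))
}

#' Forces from the VQE pipeline
#'
#' Optimizes the Ry-ansatz VQE for the active space, measures the one- and
#' two-body reduced density matrices (exactly or with the shot-based plan),
#' back-transforms them, and assembles the analytic forces. In exact mode the
#' result matches [casci_forces()].
#'
#' @param ints a [mol_integrals()] object.
#' @param spec the [active_space()] (`NULL` = full space).
#' @param plan optional [measurement_plan()] for sampled RDMs.
#' @param ... passed to [vqe()].
#' @return A `force_decomposition`.
#' @export
forces_from_vqe <- function(ints, spec = NULL, plan = NULL, ...) {
  ah <- fold_active_space(ints, spec)
  fit <- vqe(parity_transform(ah), ...)
  rd <- measure_rdms(fit, plan)
  assemble_forces(force_inputs(ints, spec, rd$rdm1, rd$rdm2))
}

#' Convert forces from Hartree/Bohr to kcal/mol/Angstrom
#'
#' @param f numeric forces in Hartree/Bohr.
#' @return forces in kcal/mol/Angstrom.
#' @export
force_to_kcal_angstrom <- function(f) f * HARTREE_KCAL / BOHR_ANGSTROM
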