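# Conductor-like continuum solvation (COSMO). The molecular cavity is a
# union of atom-centered spheres discretized with quasi-uniform surface
# points; the conductor boundary condition V_r(s) = -Phi(s) is solved as a
# boundary-element linear system, and the resulting reaction field, scaled by
# f(eps) = (eps - 1)/eps, is folded back into the one-electron Hamiltonian.
# Internally everything is in atomic units (Bohr, Hartree).

#' Continuum-solvent configuration
#'
#' @param epsilon relative permittivity of the solvent (water 78.3553).
#' @param radii optional named per-element cavity radii (Angstrom); defaults
#'   to UFF van der Waals radii.
#' @param radii_scale scaling factor applied to the radii.
#' @param points_per_sphere surface points per atomic sphere.
#' @return A `solvent_config`.
#' @export
solvent_config <- function(epsilon = 78.3553, radii = NULL, radii_scale = 1.2,
                           points_per_sphere = 194) {
  stopifnot(epsilon > 1)
  structure(list(epsilon = epsilon, radii = radii, radii_scale = radii_scale,
                 points_per_sphere = as.integer(points_per_sphere)),
            class = "solvent_config")
}

# dielectric screening factor; -> 1 in the conductor limit
f_eps <- function(epsilon) (epsilon - 1) / epsilon

# quasi-uniform points on the unit sphere (golden-angle spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# discretized cavity surface: exposed points of the union of atomic spheres
cosmo_cavity <- function(geom, config) {
  radii <- config$radii
  if (is.null(radii)) radii <- .uff_radii
  r_at <- radii[geom$symbols] * config$radii_scale
  if (anyNA(r_at)) stop("no cavity radius for element(s): ",
                        paste(unique(geom$symbols[is.na(r_at)]), collapse = ", "))
  r_at <- r_at / BOHR_ANGSTROM
  centers <- coords_bohr(geom)
  npt <- config$points_per_sphere
  unit <- fibonacci_sphere(npt)
  pts <- NULL; areas <- NULL; atom <- NULL
  for (a in seq_along(r_at)) {
    p <- unit * r_at[a] + matrix(centers[a, ], npt, 3, byrow = TRUE)
    exposed <- rep(TRUE, npt)
    for (b in seq_along(r_at)) {
      if (b == a) next
      d2 <- rowSums((p - matrix(centers[b, ], npt, 3, byrow = TRUE))^2)
      exposed <- exposed & d2 > r_at[b]^2
    }
    if (!any(exposed)) next
    pts <- rbind(pts, p[exposed, , drop = FALSE])
    areas <- c(areas, rep(4 * pi * r_at[a]^2 / npt, sum(exposed)))
    atom <- c(atom, rep(a, sum(exposed)))
  }
  list(points = pts, areas = areas, atom = atom)
}

# conductor solve: A q = -phi with the classic self-interaction diagonal
.cosmo_conductor <- function(cavity, phi) {
  pts <- cavity$points
  np <- nrow(pts)
  A <- 1 / as.matrix(stats::dist(pts))
  diag(A) <- 1.0694 * sqrt(4 * pi / cavity$areas)
  q <- solve(A, -phi)
  list(q = q, e_cond = 0.5 * sum(phi * q))
}

#' Solve the continuum reaction field for a solute density
#'
#' Computes the solute electrostatic potential on the cavity surface (nuclei
#' plus electron density, or explicit point charges), solves the conductor
#' boundary condition for the surface charges, and returns the
#' dielectric-scaled solvation energy together with the one-electron
#' reaction-field operator.
#'
#' @param geom solute [geometry()].
#' @param config a [solvent_config()].
#' @param ints optional [mol_integrals()] (for the electronic potential and
#'   the returned AO operator `h_solv`).
#' @param D_ao AO density matrix matching `ints` (defaults to the HF
#'   density).
#' @param solute_charges optional data frame `x`, `y`, `z` (Angstrom), `q`:
#'   classical solute charges used instead of nuclei + density.
#' @return A `solvation_result`: `surface_charges` (scaled by `f(eps)`),
#'   `e_solv` (Hartree, `<= 0` for neutral solutes), `h_solv` (AO matrix or
#'   `NULL`), `potential_phi`, `cavity`, `f`.
#' @export
solve_reaction_field <- function(geom, config, ints = NULL, D_ao = NULL,
                                 solute_charges = NULL) {
  cavity <- cosmo_cavity(geom, config)
  pts <- cavity$points
  if (!is.null(solute_charges)) {
    src_xyz <- as.matrix(solute_charges[, c("x", "y", "z")]) / BOHR_ANGSTROM
    src_q <- solute_charges$q
    phi <- vapply(seq_len(nrow(pts)), function(i)
      sum(src_q / sqrt(colSums((t(src_xyz) - pts[i, ])^2))), 0)
  } else {
    if (is.null(ints)) stop("provide either ints (+density) or solute_charges")
    if (is.null(D_ao)) D_ao <- ints$ao$D_hf
    Z <- ints$ao$Z
    xyz <- ints$ao$xyz_bohr
    phi_nuc <- vapply(seq_len(nrow(pts)), function(i)
      sum(Z / sqrt(colSums((t(xyz) - pts[i, ])^2))), 0)
    sh <- ints$ao$shells
    phi_el <- cpp_esp_density(sh$l, sh$atom, sh$exps, sh$coefs, xyz, pts, D_ao)
    phi <- phi_nuc + phi_el
  }
  sol <- .cosmo_conductor(cavity, phi)
  f <- f_eps(config$epsilon)
  h_solv <- NULL
  if (!is.null(ints)) {
    sh <- ints$ao$shells
    h_solv <- cpp_attraction(sh$l, sh$atom, sh$exps, sh$coefs,
                             ints$ao$xyz_bohr, pts, f * sol$q)
  }
  structure(list(surface_charges = f * sol$q, e_solv = f * sol$e_cond,
                 h_solv = h_solv, potential_phi = phi, cavity = cavity,
                 f = f, epsilon = config$epsilon),
            class = "solvation_result")
}

#' @export
print.solvation_result <- function(x, ...) {
  cat(sprintf("COSMO reaction field: %d surface points, f(eps) = %.6f\n",
              nrow(x$cavity$points), x$f))
  cat(sprintf("  E_solv = %.8f Hartree (%.3f kcal/mol)\n",
              x$e_solv, hartree_to_kcal(x$e_solv)))
  invisible(x)
}

#' Solvated mean-field reference
#'
#' Iterates restricted HF and the reaction field to mutual self-consistency:
#' the converged SCF density polarizes the continuum, whose potential enters
#' the next SCF, until the total energy is stable.
#'
#' @param geom solute [geometry()].
#' @param basis basis-set name.
#' @param charge molecular charge.
#' @param config a [solvent_config()].
#' @param point_charges optional MM environment passed to [mol_integrals()].
#' @param tol convergence threshold on the total energy (Hartree).
#' @param max_cycles outer-iteration cap.
#' @return list with `ints` (integrals in the solvated mean-field orbitals,
#'   reaction field folded into the one-electron Hamiltonian), `e_total`
#'   (gas-phase functional + solvation energy), `solvation`, `cycles`.
#' @export
solvated_scf <- function(geom, basis = "sto-3g", charge = 0,
                         config = solvent_config(), point_charges = NULL,
                         tol = 1e-8, max_cycles = 50) {
  h_solv <- NULL
  e_prev <- Inf
  for (cyc in seq_len(max_cycles)) {
    ints <- mol_integrals(geom, basis, charge, point_charges = point_charges,
                          h_extra_ao = h_solv)
    sr <- solve_reaction_field(geom, config, ints = ints)
    # gas-phase energy functional of the polarized density, plus E_s
    D <- ints$ao$D_hf
    Hb <- ints$ao$Hcore_bare
    G <- fock_2e(ints$ao$eri, D)
    e_total <- 0.5 * sum(D * (2 * Hb + G)) + ints$e_nuc + sr$e_solv
    if (abs(e_total - e_prev) < tol)
      return(list(ints = ints, e_total = e_total, solvation = sr, cycles = cyc))
    e_prev <- e_total
    h_solv <- sr$h_solv
  }
  stop("solvated SCF did not converge in ", max_cycles, " cycles")
}

#' Total AO density from an active-space one-body RDM
#'
#' Back-transforms the (measured) active-space density through the orbital
#' coefficients and adds the closed-shell frozen-core density;
#' `Tr(D S) = n_elec`.
#'
#' @param rdm1_active active-space spatial 1-RDM.
#' @param ints a [mol_integrals()] object.
#' @param spec the [active_space()] used.
#' @return AO-basis density matrix.
#' @export
density_from_rdm <- function(rdm1_active, ints, spec) {
  tr <- sum(diag(rdm1_active))
  if (abs(tr - spec$n_active_elec) > 1e-6)
    stop(sprintf("active 1-RDM trace %.8f != %d active electrons",
                 tr, spec$n_active_elec))
  C <- ints$mo_coeff
  D <- matrix(0, ints$n_orb, ints$n_orb)
  if (length(spec$frozen_set)) {
    Cf <- C[, spec$frozen_set, drop = FALSE]
    D <- D + 2 * Cf %*% t(Cf)
  }
  Ca <- C[, spec$active_set, drop = FALSE]
  D + Ca %*% rdm1_active %*% t(Ca)
}

# fold with the gas-phase (bare) one-electron Hamiltonian in the same MOs
.fold_gas_view <- function(ints, spec) {
  gas <- ints
  gas$h_core <- t(ints$mo_coeff) %*% ints$ao$Hcore_bare %*% ints$mo_coeff
  fold_active_space(gas, spec)
}

#' Single-pass solvated active-space energy
#'
#' The coupling scheme used on hardware: converge the solvated mean field
#' classically, fold the reaction field of the mean-field density into the
#' active-space Hamiltonian, solve the active space once (CASCI or VQE),
#' re-polarize the continuum with the measured one-body density, and report
#' `E_total = <H_gas> + E_s[rho]` without further iteration. Setting
#' `iterate = TRUE` instead repeats the active-space solve with the updated
#' reaction field until the density is stable (1-RDM change below `rdm_tol`),
#' keeping the mean-field orbitals fixed.
#'
#' @param geom solute [geometry()].
#' @param basis basis-set name.
#' @param charge molecular charge.
#' @param n_active_elec,n_active_orb active-space size.
#' @param config a [solvent_config()], or `NULL` for gas phase.
#' @param engine `"casci"` or `"vqe"` (exact-expectation VQE).
#' @param plan optional [measurement_plan()] for sampled VQE RDMs.
#' @param iterate self-consistent loop instead of single pass.
#' @param rdm_tol 1-RDM convergence threshold for the iterated variant.
#' @param ... passed to [vqe()].
#' @return list with `e_total`, `e_gas` (gas Hamiltonian expectation),
#'   `solvation`, `rdm1`, `engine`, `iterations`, `mean_field`.
#' @export
solvated_energy_single_pass <- function(geom, basis = "sto-3g", charge = 0,
                                        n_active_elec = 2, n_active_orb = 2,
                                        config = solvent_config(),
                                        engine = c("casci", "vqe"),
                                        plan = NULL, iterate = FALSE,
                                        rdm_tol = 1e-6, ...) {
  engine <- match.arg(engine)
  mf <- solvated_scf(geom, basis, charge, config)
  ints <- mf$ints
  spec <- active_space(ints, n_active_elec, n_active_orb)
  ah_gas <- .fold_gas_view(ints, spec)
  solve_active <- function(h_solv_ao) {
    ah <- ah_gas
    Ca <- ints$mo_coeff[, spec$active_set, drop = FALSE]
    ah$h_eff <- ah$h_eff + t(Ca) %*% h_solv_ao %*% Ca
    # frozen-core interaction with the reaction field (constant this solve)
    e_frz <- if (length(spec$frozen_set)) {
      Cf <- ints$mo_coeff[, spec$frozen_set, drop = FALSE]
      2 * sum(diag(t(Cf) %*% h_solv_ao %*% Cf))
    } else 0
    ah$e_core <- ah$e_core + e_frz
    if (engine == "casci") {
      cs <- casci(ah)
      list(rdm1 = cs$rdm1, rdm2 = cs$rdm2)
    } else {
      fit <- vqe(parity_transform(ah), ...)
      measure_rdms(fit, plan)
    }
  }
  h_solv <- mf$solvation$h_solv
  rdm_prev <- NULL
  max_pass <- if (iterate) 50 else 1
  for (pass in seq_len(max_pass)) {
    res <- solve_active(h_solv)
    D_tot <- density_from_rdm(res$rdm1, ints, spec)
    sr <- solve_reaction_field(geom, config, ints = ints, D_ao = D_tot)
    if (iterate && !is.null(rdm_prev) &&
        max(abs(res$rdm1 - rdm_prev)) < rdm_tol) break
    rdm_prev <- res$rdm1
    h_solv <- sr$h_solv
  }
  e_gas <- rdm_energy(ah_gas, res$rdm1, res$rdm2)
  list(e_total = e_gas + sr$e_solv, e_gas = e_gas, solvation = sr,
       rdm1 = res$rdm1, engine = engine, iterations = pass,
       mean_field = mf, spec = spec)
}

#' Gas-phase active-space energy (reference for the solvent coupling)
#'
#' @inheritParams solvated_energy_single_pass
#' @return list with `e_total`, `rdm1`, `engine`.
#' @export
gas_phase_energy <- function(geom, basis = "sto-3g", charge = 0,
                             n_active_elec = 2, n_active_orb = 2,
                             engine = c("casci", "vqe"), ...) {
  engine <- match.arg(engine)
  ints <- mol_integrals(geom, basis, charge)
  spec <- active_space(ints, n_active_elec, n_active_orb)
  ah <- fold_active_space(ints, spec)
  if (engine == "casci") {
    cs <- casci(ah)
    list(e_total = cs$energy, rdm1 = cs$rdm1, engine = engine)
  } else {
    fit <- vqe(parity_transform(ah), ...)
    rd <- measure_rdms(fit)
    list(e_total = fit$energy, rdm1 = rd$rdm1, engine = engine)
  }
}
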