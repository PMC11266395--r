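# Synthetic test systems: random active-space integral sets with the full
# permutational symmetry and positive-semidefinite Coulomb metric, and toy
# QM-in-point-charge-bath systems. Everything is reproducible from a seed; no
# external data is needed anywhere in the package.

#' Random active-space integral fixture
#'
#' Draws a symmetric one-electron matrix and a two-electron tensor built as a
#' sum of symmetric rank-one Coulomb factors, `g[pqrs] = sum_k L_k[pq]
#' L_k[rs]`, which guarantees the 8-fold permutational symmetry of real
#' orbitals and a positive-semidefinite Coulomb metric. In asymmetric mode
#' (the default) all one-electron off-diagonals are bounded away from zero,
#' so a `(2e,2o)` fixture realizes the generic 8-term qubit Hamiltonian; in
#' symmetric mode orbitals alternate between two mock irreducible
#' representations and all integrals coupling an odd number of
#' second-irrep indices vanish, mimicking a point-group-symmetric molecule.
#'
#' @param n_orb number of active orbitals (at most 6).
#' @param n_elec number of active electrons.
#' @param symmetric logical; impose the two-irrep selection rules.
#' @param seed RNG seed.
#' @param h_scale,g_scale magnitude of one-/two-electron elements (Hartree).
#' @return An `active_hamiltonian`.
#' @export
random_active_integrals <- function(n_orb = 2, n_elec = 2, symmetric = FALSE,
                                    seed = 1, h_scale = 1, g_scale = 0.3) {
  stopifnot(n_orb <= 6)
  set.seed(seed)
  n <- n_orb
  irrep <- seq_len(n) %% 2   # alternate mock irreps (used in symmetric mode)
  h <- matrix(rnorm(n * n), n, n)
  h <- (h + t(h)) / 2 * h_scale
  diag(h) <- diag(h) - seq_len(n)  # loosely ordered "orbital energies"
  if (symmetric) {
    h[outer(irrep, irrep, "!=")] <- 0
  } else {
    # keep every off-diagonal away from zero
    off <- abs(h) < 0.05 & row(h) != col(h)
    h[off] <- sign(h[off] + (h[off] == 0)) * 0.05
  }
  nfac <- 2 * n
  eri <- array(0, c(n, n, n, n))
  for (k in seq_len(nfac)) {
    L <- matrix(rnorm(n * n), n, n)
    L <- (L + t(L)) / 2
    if (symmetric) {
      # factors live in a single irrep-coupling class: diagonal blocks or
      # pure off-diagonal blocks, so all products have even irrep character
      if (k %% 2 == 0) L[outer(irrep, irrep, "!=")] <- 0
      else L[outer(irrep, irrep, "==")] <- 0
    }
    eri <- eri + outer(L, L) * g_scale / nfac
  }
  # lift the diagonal so that (pp|pp) dominates (physical Coulomb ordering)
  for (p in seq_len(n)) eri[p, p, p, p] <- eri[p, p, p, p] + 0.5 * g_scale
  active_hamiltonian(h, eri, e_core = round(rnorm(1), 3), n_active_elec = n_elec)
}

#' Toy QM region in a neutral point-charge bath
#'
#' Builds an H2 (or water) QM region centered in a randomized bath of point
#' charges with Lennard-Jones sites, standing in for a protein/solvent MM
#' environment. Bath charges are drawn uniformly in a cubic box, excluded
#' from a cavity around the QM region, and shifted to exact overall
#' neutrality.
#'
#' @param qm `"H2"` or `"H2O"`.
#' @param bath_size number of point charges.
#' @param bath_box box edge length (Angstrom).
#' @param charge_scale charge magnitude scale (elementary charges).
#' @param cavity minimum distance between bath sites and QM atoms (Angstrom).
#' @param seed RNG seed.
#' @return list with `geom` (a [geometry()]) and `mm` (an [mm_environment()]).
#' @export
toy_solvated_system <- function(qm = "H2", bath_size = 20, bath_box = 12,
                                charge_scale = 0.2, cavity = 2.5, seed = 1) {
  set.seed(seed)
  geom <- switch(qm,
    H2 = geometry(c("H", "H"), rbind(c(0, 0, -0.37), c(0, 0, 0.37))),
    H2O = geometry(c("O", "H", "H"),
                   rbind(c(0, 0, 0.1173), c(0, 0.7572, -0.4692),
                         c(0, -0.7572, -0.4692))),
    stop("unknown QM region: ", qm))
  if (bath_size == 0)
    return(list(geom = geom, mm = mm_environment(NULL)))
  pos <- matrix(NA_real_, bath_size, 3)
  filled <- 0
  while (filled < bath_size) {
    cand <- runif(3, -bath_box / 2, bath_box / 2)
    d <- sqrt(rowSums((geom$coords - matrix(cand, nrow(geom$coords), 3,
                                            byrow = TRUE))^2))
    far_qm <- all(d >= cavity)
    far_mm <- filled == 0 ||
      all(sqrt(rowSums((pos[seq_len(filled), , drop = FALSE] -
                        matrix(cand, filled, 3, byrow = TRUE))^2)) >= 1.5)
    if (far_qm && far_mm) {
      filled <- filled + 1
      pos[filled, ] <- cand
    }
  }
  q <- rnorm(bath_size, 0, charge_scale)
  q <- q - mean(q)  # exact neutrality
  mm <- mm_environment(data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3], q = q),
                       lj_sigma = rep(3.2, bath_size),
                       lj_eps = rep(0.1 / HARTREE_KCAL, bath_size),
                       masses = rep(18, bath_size))
  list(geom = geom, mm = mm)
}
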