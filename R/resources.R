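# Quantum-resource estimation for paired unitary coupled cluster (pUCCD):
# one qubit per spatial orbital, excitations restricted to electron pairs
# implemented as a Givens-SWAP network, measurement cost from the
# shot-noise variance model eps^2 ~ (1/K) sum_j |alpha_j|^2.

# contracted basis functions per element, frozen from the standard basis-set
# tables (6-31G: H = 2s; C/N/O = 3s2p = 9; S = 4s3p = 13)
.basis_counts <- list(
  "6-31g"  = c(H = 2, C = 9, N = 9, O = 9, S = 13),
  "sto-3g" = c(H = 1, C = 5, N = 5, O = 5, S = 9)
)

#' Count contracted basis functions for a molecule
#'
#' @param elements character vector of element symbols (repeats allowed).
#' @param basis basis-set name.
#' @return integer total.
#' @examples
#' count_basis_functions(c("S", "C", "C", "C", "O"), "6-31g")  # 49
#' @export
count_basis_functions <- function(elements, basis = "6-31g") {
  tbl <- .basis_counts[[tolower(basis)]]
  if (is.null(tbl)) stop("no basis-function table for basis: ", basis)
  cnt <- tbl[elements]
  if (anyNA(cnt))
    stop("no entry for element(s): ",
         paste(unique(elements[is.na(cnt)]), collapse = ", "))
  as.integer(sum(cnt))
}

#' Number of paired double excitations
#'
#' Under the electron-pairing restriction, the doubles count is
#' `(n_elec/2) * (N - n_elec/2)`: each of the occupied pairs can be promoted
#' into each empty orbital. This also equals the Givens-SWAP gate count of
#' the pUCCD circuit.
#'
#' @param n_elec electron count (even).
#' @param n_orb number of spatial orbitals `N`.
#' @return integer count.
#' @examples
#' paired_double_excitations(196, 630)  # 52136
#' paired_double_excitations(42, 49)    # 588
#' @export
paired_double_excitations <- function(n_elec, n_orb) {
  if (n_elec %% 2 != 0) stop("paired ansatz requires an even electron count")
  pairs <- n_elec / 2
  if (n_orb < pairs) stop("fewer orbitals than electron pairs")
  as.integer(round(pairs * (n_orb - pairs)))
}

#' Pauli-term count of the pUCCD Hamiltonian
#'
#' Empirical scaling `0.7 N^2` terms for `N` orbitals.
#'
#' @param n_orb number of spatial orbitals.
#' @return integer term count.
#' @export
pucc_pauli_terms <- function(n_orb) {
  stopifnot(n_orb >= 1)
  as.integer(round(0.7 * n_orb^2))
}

#' Shot budget for a target precision
#'
#' From the variance model `eps^2 = (1/K) sum_j |alpha_j|^2` with `M` terms
#' of typical magnitude `|alpha|` split into `n_groups` equal measurement
#' groups: `K = (M / n_groups) * alpha^2 / eps^2` shots per group.
#'
#' @param M Pauli-term count.
#' @param n_groups number of measurement groups.
#' @param alpha assumed coefficient magnitude (Hartree).
#' @param eps target precision (Hartree).
#' @param shot_reset_time seconds per shot (reset-limited, default 1e-3).
#' @return list with `K` (shots per group), `total_shots`,
#'   `wall_time_seconds`.
#' @export
shot_budget <- function(M, n_groups = 3, alpha = 0.1, eps = 0.01,
                        shot_reset_time = 1e-3) {
  if (eps <= 0) stop("target precision eps must be positive")
  K <- (M / n_groups) * alpha^2 / eps^2
  total <- n_groups * K
  list(K = K, total_shots = total, wall_time_seconds = total * shot_reset_time)
}

#' Full pUCCD resource estimate
#'
#' @param elements element symbols of the fragment, or `NULL` if `n_orb`
#'   given directly.
#' @param n_elec electron count.
#' @param basis basis-set name (for the orbital count).
#' @param n_orb orbital count override.
#' @param n_groups measurement groups.
#' @param alpha,eps,shot_reset_time see [shot_budget()].
#' @return A `resource_estimate`: qubits, Givens-SWAP gates, Pauli terms,
#'   shots and wall time.
#' @export
resource_estimate <- function(elements = NULL, n_elec, basis = "6-31g",
                              n_orb = NULL, n_groups = 3, alpha = 0.1,
                              eps = 0.01, shot_reset_time = 1e-3) {
  if (is.null(n_orb)) n_orb <- count_basis_functions(elements, basis)
  sb <- shot_budget(pucc_pauli_terms(n_orb), n_groups, alpha, eps,
                    shot_reset_time)
  structure(list(
    qubits = as.integer(n_orb),
    givens_swap_gates = paired_double_excitations(n_elec, n_orb),
    pauli_terms = pucc_pauli_terms(n_orb),
    shots_per_group = sb$K, total_shots = sb$total_shots,
    wall_time_seconds = sb$wall_time_seconds,
    n_orb = n_orb, n_elec = n_elec, basis = basis
  ), class = "resource_estimate")
}

#' @export
print.resource_estimate <- function(x, ...) {
  cat(sprintf("pUCCD resource estimate (%d electrons, %d orbitals, %s):\n",
              x$n_elec, x$n_orb, x$basis))
  cat(sprintf("  qubits:            %d\n", x$qubits))
  cat(sprintf("  Givens-SWAP gates: %d\n", x$givens_swap_gates))
  cat(sprintf("  Pauli terms:       %d\n", x$pauli_terms))
  cat(sprintf("  shots/group:       %.3g\n", x$shots_per_group))
  cat(sprintf("  total shots:       %.3g\n", x$total_shots))
  cat(sprintf("  wall time:         %.3g s\n", x$wall_time_seconds))
  invisible(x)
}
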