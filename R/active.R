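# Frozen-core active-space reduction: fold doubly-occupied orbitals into an
# effective one-electron potential and a scalar core energy, leaving a small
# correlated Hamiltonian over the active orbitals.

#' Select an active space around the HOMO-LUMO gap
#'
#' Chooses `n_orb` spatial orbitals centered on the HOMO-LUMO frontier:
#' the `n_elec/2` highest doubly-occupied orbitals and the lowest virtuals.
#' Orbitals are taken in canonical (ascending-energy) order; energy ties keep
#' ascending orbital index.
#'
#' @param ints a [mol_integrals()] object.
#' @param n_elec number of active electrons (even).
#' @param n_orb number of active spatial orbitals.
#' @return An `active_space_spec` with `frozen_set` and `active_set`
#'   (1-based orbital indices), `n_active_orb`, `n_active_elec`.
#' @export
active_space <- function(ints, n_elec = 2, n_orb = 2) {
  if (n_elec %% 2 != 0) stop("active electron count must be even (closed shell)")
  nocc <- ints$n_elec / 2
  n_act_occ <- n_elec / 2
  if (n_act_occ > nocc) stop("more active electrons than occupied orbitals")
  if (nocc + (n_orb - n_act_occ) > ints$n_orb)
    stop("active space exceeds available virtual orbitals")
  frozen <- seq_len(nocc - n_act_occ)
  active <- seq(nocc - n_act_occ + 1, nocc + n_orb - n_act_occ)
  structure(list(n_active_orb = as.integer(n_orb),
                 n_active_elec = as.integer(n_elec),
                 frozen_set = as.integer(frozen),
                 active_set = as.integer(active)),
            class = "active_space_spec")
}

#' @export
print.active_space_spec <- function(x, ...) {
  cat(sprintf("Active space (%de, %do): active orbitals [%s], %d frozen\n",
              x$n_active_elec, x$n_active_orb,
              paste(x$active_set, collapse = ", "), length(x$frozen_set)))
  invisible(x)
}

#' Fold a frozen core into an active-space Hamiltonian
#'
#' Computes the effective repulsion potential of the frozen doubly-occupied
#' orbitals, `V_eff_pq = sum_m (2[mm|pq] - [mp|qm])`, the mean-field core
#' energy `E_core = 2 sum_m h_mm + sum_mn (2[mm|nn] - [mn|nm])` (spatial,
#' closed-shell form), and slices the integral tensors over the active set.
#'
#' @param ints a [mol_integrals()] object.
#' @param spec an [active_space()] specification (or `NULL` for no frozen
#'   orbitals and all orbitals active).
#' @return An `active_hamiltonian` with `h_eff`, `eri_active` (Mulliken
#'   order), `e_core` (core energy plus nuclear repulsion), `n_active_orb`,
#'   `n_active_elec`.
#' @examples
#' h2 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
#' ah <- fold_active_space(mol_integrals(h2), NULL)
#' casci(ah)$energy
#' @export
fold_active_space <- function(ints, spec = NULL) {
  if (is.null(spec)) {
    spec <- structure(list(n_active_orb = ints$n_orb, n_active_elec = ints$n_elec,
                           frozen_set = integer(0),
                           active_set = seq_len(ints$n_orb)),
                      class = "active_space_spec")
  }
  frz <- spec$frozen_set
  act <- spec$active_set
  if (length(intersect(frz, act)))
    stop("frozen and active sets overlap")
  if (2 * length(frz) + spec$n_active_elec != ints$n_elec)
    stop("electron bookkeeping: 2*|frozen| + n_active_elec != n_elec")
  h <- ints$h_core
  eri <- ints$eri
  e_core <- 0
  V <- matrix(0, ints$n_orb, ints$n_orb)
  if (length(frz)) {
    for (m in frz) {
      V <- V + 2 * eri[m, m, , ] - eri[m, , , m]
      e_core <- e_core + 2 * h[m, m]
    }
    for (m in frz) for (k in frz)
      e_core <- e_core + 2 * eri[m, m, k, k] - eri[m, k, k, m]
  }
  structure(list(
    h_eff = (h + V)[act, act, drop = FALSE],
    eri_active = eri[act, act, act, act, drop = FALSE],
    e_core = e_core + ints$e_nuc,
    n_active_orb = spec$n_active_orb,
    n_active_elec = spec$n_active_elec,
    spec = spec
  ), class = "active_hamiltonian")
}

#' @export
print.active_hamiltonian <- function(x, ...) {
  cat(sprintf("Active-space Hamiltonian: (%de, %do), core energy %.8f Hartree\n",
              x$n_active_elec, x$n_active_orb, x$e_core))
  invisible(x)
}

# construct an active_hamiltonian directly from raw tensors (fixtures, FCIDUMP)
active_hamiltonian <- function(h_eff, eri_active, e_core, n_active_elec) {
  n <- nrow(h_eff)
  stopifnot(all(dim(eri_active) == n))
  structure(list(h_eff = h_eff, eri_active = eri_active, e_core = e_core,
                 n_active_orb = n, n_active_elec = as.integer(n_active_elec),
                 spec = NULL),
            class = "active_hamiltonian")
}
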