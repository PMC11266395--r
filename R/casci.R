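# Exact diagonalization (CASCI / full CI) of an active-space Hamiltonian in
# the Sz = 0 determinant basis. Spin-orbitals are blocked: 1..n alpha,
# n+1..2n beta. Matrix elements are generated by explicit second-quantized
# operator application on occupation vectors, which the reduced-density-matrix
# code reuses; no Slater-Condon case analysis to get wrong.

# apply a_p / a+_p to an occupation (logical) vector; NULL if annihilated
.op_ann <- function(occ, p) {
  if (!occ[p]) return(NULL)
  phase <- if (p > 1) (-1)^sum(occ[seq_len(p - 1)]) else 1
  occ[p] <- FALSE
  list(occ = occ, phase = phase)
}

.op_cre <- function(occ, p) {
  if (occ[p]) return(NULL)
  phase <- if (p > 1) (-1)^sum(occ[seq_len(p - 1)]) else 1
  occ[p] <- TRUE
  list(occ = occ, phase = phase)
}

# apply a+_p a+_q a_r a_s (read right-to-left)
.op_2body <- function(occ, p, q, r, s) {
  x <- .op_ann(occ, s); if (is.null(x)) return(NULL)
  y <- .op_ann(x$occ, r); if (is.null(y)) return(NULL)
  z <- .op_cre(y$occ, q); if (is.null(z)) return(NULL)
  w <- .op_cre(z$occ, p); if (is.null(w)) return(NULL)
  list(occ = w$occ, phase = x$phase * y$phase * z$phase * w$phase)
}

.op_1body <- function(occ, p, q) {
  x <- .op_ann(occ, q); if (is.null(x)) return(NULL)
  y <- .op_cre(x$occ, p); if (is.null(y)) return(NULL)
  list(occ = y$occ, phase = x$phase * y$phase)
}

# Sz = 0 determinant basis for n spatial orbitals and ne electrons
.ci_basis <- function(n, ne) {
  if (ne %% 2 != 0) stop("only Sz = 0 (even electron) sectors are supported")
  na <- ne / 2
  occa <- if (na == 0) list(integer(0)) else
    lapply(seq_len(choose(n, na)), function(i) NULL)
  combs <- if (na == 0) matrix(integer(0), nrow = 0, ncol = 1) else combn(n, na)
  dets <- list()
  keys <- character(0)
  ncomb <- if (na == 0) 1L else ncol(combs)
  for (ia in seq_len(ncomb)) for (ib in seq_len(ncomb)) {
    occ <- rep(FALSE, 2 * n)
    if (na > 0) {
      occ[combs[, ia]] <- TRUE
      occ[n + combs[, ib]] <- TRUE
    }
    dets[[length(dets) + 1L]] <- occ
    keys <- c(keys, paste(as.integer(occ), collapse = ""))
  }
  idx <- seq_along(keys)
  names(idx) <- keys
  list(dets = dets, index = idx, n = n, ne = ne)
}

.det_key <- function(occ) paste(as.integer(occ), collapse = "")

# spin-orbital coefficient tables from spatial tensors
# one-body: h_so[(sigma p)(sigma q)] = h[p,q]; two-body coefficient of
# a+_p a+_q a_r a_s is [ps|qr] with spin matching (p,s) and (q,r)
.build_ci_matrix <- function(h, eri, basis) {
  n <- basis$n
  nd <- length(basis$dets)
  H <- matrix(0, nd, nd)
  spat <- function(i) ((i - 1L) %% n) + 1L
  spin <- function(i) (i - 1L) %/% n
  nso <- 2L * n
  for (d in seq_len(nd)) {
    occ <- basis$dets[[d]]
    occ_idx <- which(occ)
    # one-body
    for (q in occ_idx) for (p in seq_len(nso)) {
      if (spin(p) != spin(q)) next
      hval <- h[spat(p), spat(q)]
      if (abs(hval) < 1e-300) next
      r <- .op_1body(occ, p, q)
      if (is.null(r)) next
      H[basis$index[[.det_key(r$occ)]], d] <-
        H[basis$index[[.det_key(r$occ)]], d] + r$phase * hval
    }
    # two-body: 1/2 sum_pqrs [ps|qr] a+_p a+_q a_r a_s
    for (s in occ_idx) for (r in occ_idx) {
      if (r == s) next
      for (q in seq_len(nso)) {
        if (spin(q) != spin(r)) next
        for (p in seq_len(nso)) {
          if (spin(p) != spin(s)) next
          g <- eri[spat(p), spat(s), spat(q), spat(r)]
          if (abs(g) < 1e-300) next
          x <- .op_2body(occ, p, q, r, s)
          if (is.null(x)) next
          i <- basis$index[[.det_key(x$occ)]]
          H[i, d] <- H[i, d] + 0.5 * x$phase * g
        }
      }
    }
  }
  H
}

#' Exact active-space ground state (CASCI)
#'
#' Diagonalizes the active-space Hamiltonian exactly in the Sz = 0
#' determinant basis and contracts the one- and two-body reduced density
#' matrices from the CI vector. The returned energy includes the core energy
#' (frozen-core mean field plus nuclear repulsion).
#'
#' @param ah an `active_hamiltonian` from [fold_active_space()].
#' @return list with `energy` (Hartree), `ci` (CI coefficients), `basis`
#'   (determinant list), `rdm1` (spatial, trace = electron count), `rdm2`
#'   (spatial, `rdm2[p,q,r,s] = sum_st <a+_ps a+_qt a_rt a_ss>`), and
#'   `degenerate` flag.
#' @export
casci <- function(ah) {
  if (ah$n_active_orb > 8)
    stop("dense CASCI limited to 8 active orbitals")
  basis <- .ci_basis(ah$n_active_orb, ah$n_active_elec)
  H <- .build_ci_matrix(ah$h_eff, ah$eri_active, basis)
  eig <- eigen((H + t(H)) / 2, symmetric = TRUE)
  nd <- length(eig$values)
  e0 <- eig$values[nd]
  ci <- eig$vectors[, nd]
  degenerate <- nd >= 2 && (eig$values[nd - 1] - e0) < 1e-10
  if (degenerate)
    warning("degenerate CASCI ground state; returning one lowest eigenvector")
  rdms <- ci_rdms(ci, basis)
  list(energy = e0 + ah$e_core, e_elec = e0, ci = ci, basis = basis,
       rdm1 = rdms$rdm1, rdm2 = rdms$rdm2, degenerate = degenerate,
       spectrum = rev(eig$values) + ah$e_core)
}

# spatial RDMs from a CI vector: rdm1[p,q] = sum_s <a+_ps a_qs>,
# rdm2[p,q,r,s] = sum_st <a+_ps a+_qt a_rt a_ss>
ci_rdms <- function(ci, basis) {
  n <- basis$n
  nso <- 2L * n
  nd <- length(basis$dets)
  rdm1 <- matrix(0, n, n)
  rdm2 <- array(0, c(n, n, n, n))
  spat <- function(i) ((i - 1L) %% n) + 1L
  spin <- function(i) (i - 1L) %/% n
  for (d in seq_len(nd)) {
    cd <- ci[d]
    if (abs(cd) < 1e-14) next
    occ <- basis$dets[[d]]
    occ_idx <- which(occ)
    for (q in occ_idx) for (p in seq_len(nso)) {
      if (spin(p) != spin(q)) next
      x <- .op_1body(occ, p, q)
      if (is.null(x)) next
      i <- basis$index[[.det_key(x$occ)]]
      rdm1[spat(p), spat(q)] <- rdm1[spat(p), spat(q)] + ci[i] * x$phase * cd
    }
    for (s in occ_idx) for (r in occ_idx) {
      if (r == s) next
      for (q in seq_len(nso)) {
        if (spin(q) != spin(r)) next
        for (p in seq_len(nso)) {
          if (spin(p) != spin(s)) next
          x <- .op_2body(occ, p, q, r, s)
          if (is.null(x)) next
          i <- basis$index[[.det_key(x$occ)]]
          rdm2[spat(p), spat(q), spat(r), spat(s)] <-
            rdm2[spat(p), spat(q), spat(r), spat(s)] + ci[i] * x$phase * cd
        }
      }
    }
  }
  list(rdm1 = rdm1, rdm2 = rdm2)
}

# energy from RDMs (consistency check and VQE pathway):
# E = e_core + sum h*rdm1 + 1/2 sum [ps|qr] rdm2[p,q,r,s]
rdm_energy <- function(ah, rdm1, rdm2) {
  n <- ah$n_active_orb
  e2 <- 0
  for (p in seq_len(n)) for (q in seq_len(n)) for (r in seq_len(n)) for (s in seq_len(n))
    e2 <- e2 + ah$eri_active[p, s, q, r] * rdm2[p, q, r, s]
  ah$e_core + sum(ah$h_eff * rdm1) + 0.5 * e2
}
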