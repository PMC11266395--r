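# Restricted Hartree-Fock with DIIS convergence acceleration.

# Coulomb/exchange build from the full AO ERI tensor (Mulliken order).
fock_2e <- function(eri, D) {
  n <- dim(eri)[1]
  E2 <- matrix(eri, n * n, n * n)                 # (pq) x (rs)
  J <- matrix(E2 %*% as.vector(D), n, n)
  # K_pq = sum_rs (pr|qs) D_rs
  Ek <- matrix(aperm(eri, c(1, 3, 2, 4)), n * n, n * n)
  K <- matrix(Ek %*% as.vector(D), n, n)
  J - 0.5 * K
}

# symmetric orthogonalizer S^{-1/2}
lowdin_x <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 1e-8)
    warning("near-linear dependence in basis (min overlap eigenvalue ",
            signif(min(e$values), 3), ")")
  e$vectors %*% diag(1 / sqrt(e$values), nrow = length(e$values)) %*% t(e$vectors)
}

# Solve restricted HF given AO integrals. h_extra is an additional one-electron
# operator (MM embedding or solvent reaction field) added to the core
# Hamiltonian; e_extra a scalar added to the reported electronic energy.
scf_rhf <- function(S, Hcore, eri, n_elec, h_extra = NULL,
                    conv = 1e-10, max_iter = 200) {
  if (n_elec %% 2 != 0) stop("restricted HF requires an even electron count")
  n <- nrow(S)
  nocc <- n_elec / 2
  H <- Hcore + if (is.null(h_extra)) 0 else h_extra
  X <- lowdin_x(S)
  # core guess
  Fm <- H
  D <- NULL
  err_list <- list(); fock_list <- list()
  energy <- Inf
  for (it in seq_len(max_iter)) {
    Fo <- t(X) %*% Fm %*% X
    eig <- eigen(Fo, symmetric = TRUE)
    ord <- order(eig$values)            # eigen() sorts decreasing; want ascending
    eig$values <- eig$values[ord]
    eig$vectors <- eig$vectors[, ord, drop = FALSE]
    C <- X %*% eig$vectors
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    D <- 2 * Cocc %*% t(Cocc)
    G <- fock_2e(eri, D)
    Fm_new <- H + G
    e_new <- 0.5 * sum(D * (H + Fm_new))
    # DIIS on the orbital-gradient residual FDS - SDF
    err <- Fm_new %*% D %*% S - S %*% D %*% Fm_new
    err_list[[length(err_list) + 1L]] <- err
    fock_list[[length(fock_list) + 1L]] <- Fm_new
    if (length(err_list) > 8) { err_list <- err_list[-1]; fock_list <- fock_list[-1] }
    m <- length(err_list)
    if (max(abs(err)) < conv && it > 1) {
      return(list(C = C, mo_energy = eig$values, D = D, fock = Fm_new,
                  e_elec = e_new, converged = TRUE, n_iter = it))
    }
    if (m >= 2) {
      B <- matrix(0, m + 1, m + 1)
      for (a in seq_len(m)) for (b in seq_len(m))
        B[a, b] <- sum(err_list[[a]] * err_list[[b]])
      B[m + 1, seq_len(m)] <- B[seq_len(m), m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      w <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(w)) {
        Fm <- Reduce(`+`, Map(`*`, fock_list, w))
      } else Fm <- Fm_new
    } else Fm <- Fm_new
    energy <- e_new
  }
  stop(sprintf("SCF failed to converge in %d iterations (last residual %.2e, E = %.8f)",
               max_iter, max(abs(err)), energy))
}
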