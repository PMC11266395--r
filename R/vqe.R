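# Variational quantum eigensolver on an emulated statevector backend.
# Single-layer hardware-efficient Ry ansatz (Ry rotations interleaved with a
# CNOT ladder), exact or shot-based expectation values with an optional
# readout-error model and linear-inversion mitigation, L-BFGS-B optimization
# with parameter-shift gradients, and reduced-density-matrix measurement.

# ---- statevector simulator (qubit j = bit j of the index, little-endian) ----

.apply_1q <- function(psi, j, U) {
  n2 <- length(psi)
  b <- 0:(n2 - 1)
  mask <- bitwShiftL(1L, j)
  i0 <- which(bitwAnd(b, mask) == 0L)
  i1 <- i0 + mask
  v0 <- psi[i0]; v1 <- psi[i1]
  psi[i0] <- U[1, 1] * v0 + U[1, 2] * v1
  psi[i1] <- U[2, 1] * v0 + U[2, 2] * v1
  psi
}

.apply_ry <- function(psi, j, theta) {
  c2 <- cos(theta / 2); s2 <- sin(theta / 2)
  .apply_1q(psi, j, matrix(c(c2, s2, -s2, c2), 2, 2))
}

.apply_cnot <- function(psi, ctrl, targ) {
  n2 <- length(psi)
  b <- 0:(n2 - 1)
  sel <- bitwAnd(b, bitwShiftL(1L, ctrl)) > 0L
  perm <- b
  perm[sel] <- bitwXor(b[sel], bitwShiftL(1L, targ))
  psi[perm + 1L] <- psi
  psi
}

#' Simulate the hardware-efficient Ry ansatz state
#'
#' Builds `|psi(theta)> = L_Ry^(k) ... L_CNOT^(1) L_Ry^(0) |phi>`: `k+1`
#' layers of per-qubit Ry rotations interleaved with CNOT-ladder layers
#' (control j, target j+1). Ry and CNOT preserve real amplitudes, so the
#' returned statevector is real.
#'
#' @param theta parameter vector of length `n_qubits * (n_layers + 1)`
#'   (radians); `theta[l * N + j]` rotates qubit `j` in layer `l`.
#' @param n_qubits number of qubits.
#' @param n_layers number of entangling layers `k` (default 1).
#' @param init_bits initial computational-basis bitstring (integer 0/1 vector,
#'   qubit 0 first); default all zeros.
#' @return numeric statevector of length `2^n_qubits`.
#' @export
simulate_state <- function(theta, n_qubits, n_layers = 1, init_bits = NULL) {
  N <- n_qubits
  stopifnot(length(theta) == N * (n_layers + 1))
  if (is.null(init_bits)) init_bits <- rep(0L, N)
  idx <- sum(bitwShiftL(as.integer(init_bits), seq_len(N) - 1L)) + 1L
  psi <- numeric(2^N)
  psi[idx] <- 1
  for (j in seq_len(N)) psi <- .apply_ry(psi, j - 1L, theta[j])
  if (n_layers >= 1) for (l in seq_len(n_layers)) {
    if (N >= 2) for (j in seq_len(N - 1)) psi <- .apply_cnot(psi, j - 1L, j)
    for (j in seq_len(N)) psi <- .apply_ry(psi, j - 1L, theta[l * N + j])
  }
  psi
}

# ---- measurement plans and readout error ----

#' Measurement plan for shot-based expectation values
#'
#' @param shots shots per measurement group (default 8192).
#' @param readout optional readout-error model from [readout_confusion()].
#' @param mitigate apply linear-inversion readout mitigation.
#' @param seed RNG seed for sampling.
#' @return A `measurement_plan`.
#' @export
measurement_plan <- function(shots = 8192, readout = NULL, mitigate = FALSE,
                             seed = 0) {
  if (mitigate && is.null(readout))
    stop("mitigation requested without a readout model")
  stopifnot(shots >= 1)
  structure(list(shots = as.integer(shots), readout = readout,
                 mitigate = mitigate, seed = seed),
            class = "measurement_plan")
}

#' Per-qubit readout confusion model
#'
#' Independent per-qubit column-stochastic 2x2 confusion matrices
#' `A[i, j] = P(read i | prepared j)`.
#'
#' @param n_qubits number of qubits.
#' @param p01 probability of reading 1 given 0.
#' @param p10 probability of reading 0 given 1 (defaults to `p01`).
#' @return list of 2x2 matrices, class `readout_model`.
#' @export
readout_confusion <- function(n_qubits, p01 = 0.02, p10 = p01) {
  A <- matrix(c(1 - p01, p01, p10, 1 - p10), 2, 2)
  structure(rep(list(A), n_qubits), class = "readout_model")
}

# apply per-qubit confusion (or its inverse) to a probability vector over 2^n
.apply_confusion <- function(p, mats, invert = FALSE) {
  n <- length(mats)
  arr <- array(p, rep(2, n))
  for (q in seq_len(n)) {
    A <- mats[[q]]
    if (invert) A <- solve(A)
    arr <- apply(arr, setdiff(seq_len(n), q), function(v) A %*% v)
    # apply() puts the contracted axis first; rotate it back into place
    arr <- aperm(array(arr, rep(2, n)), c(seq_len(q)[-1], 1L, seq_len(n)[-seq_len(q)]))
  }
  as.vector(arr)
}

#' Readout-error mitigation of a measured histogram
#'
#' Applies the inverse tensor-product confusion matrix to measured
#' frequencies; negative quasi-probabilities are clipped to zero and the
#' result renormalized.
#'
#' @param counts integer vector of counts over the `2^n` outcomes
#'   (outcome = bitstring read little-endian).
#' @param readout a [readout_confusion()] model.
#' @return numeric vector of corrected outcome probabilities.
#' @export
readout_mitigate <- function(counts, readout) {
  for (A in readout)
    if (abs(det(A)) < 1e-12) stop("singular confusion matrix")
  f <- counts / sum(counts)
  qp <- .apply_confusion(f, readout, invert = TRUE)
  qp[qp < 0] <- 0
  qp / sum(qp)
}

# ---- expectation values ----

# rotate psi so that measuring Z equals measuring the given letter
.rotate_to_basis <- function(psi, basis) {
  H <- matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2)
  SdgH <- H %*% diag(c(1, -1i))   # measure Y: apply S^dagger then H
  for (j in seq_along(basis)) {
    if (basis[j] == "X") psi <- .apply_1q(psi, j - 1L, H)
    else if (basis[j] == "Y") psi <- .apply_1q(psi, j - 1L, SdgH)
  }
  psi
}

# support mask (non-identity letters) of each term string
.term_masks <- function(strings) {
  vapply(strings, function(s) {
    lets <- strsplit(s, "")[[1]]
    .mask(which(lets != "I") - 1L)
  }, integer(1))
}

#' Energy expectation of an ansatz state
#'
#' Exact mode contracts the statevector with the Hamiltonian. Sampled mode
#' rotates into each measurement group's product basis, draws `shots`
#' bitstrings (through the readout-error model if given, with optional
#' mitigation), and accumulates the coefficient-weighted estimate. The
#' identity offset and core energy are always included.
#'
#' @param qh a `qubit_hamiltonian`.
#' @param psi statevector from [simulate_state()].
#' @param plan a [measurement_plan()], or `NULL` for exact evaluation.
#' @param grouping optional precomputed [group_commuting()] result.
#' @return list with `value` (Hartree), `std_error`, and (sampled mode)
#'   `per_group_counts`.
#' @export
energy_expectation <- function(qh, psi, plan = NULL, grouping = NULL) {
  offset <- qh$identity_offset + qh$e_core
  if (is.null(plan)) {
    nY <- .popcount(bitwAnd(qh$x, qh$z))
    op <- list(x = qh$x, z = qh$z, c = qh$terms$coeff * (1i)^nY, n = qh$n_qubits)
    val <- Re(pauli_expect(op, as.complex(psi)))
    return(list(value = val + offset, std_error = 0, per_group_counts = NULL))
  }
  if (is.null(grouping)) grouping <- group_commuting(qh)
  .with_seed(plan$seed, {
  K <- plan$shots
  n <- qh$n_qubits
  b <- 0:(2^n - 1)
  total <- offset
  var_tot <- 0
  hists <- list()
  masks <- .term_masks(qh$terms$string)
  for (g in seq_along(grouping$groups)) {
    idx <- grouping$groups[[g]]
    phi <- .rotate_to_basis(as.complex(psi), grouping$basis[[g]])
    p <- Mod(phi)^2
    p <- p / sum(p)
    if (!is.null(plan$readout)) p <- .apply_confusion(p, plan$readout)
    counts <- as.vector(rmultinom(1, K, p))
    f <- if (plan$mitigate) readout_mitigate(counts, plan$readout) else counts / K
    # per-outcome value of the group: sum_j coeff_j * (-1)^{|outcome & mask_j|}
    v <- numeric(2^n)
    for (t in idx)
      v <- v + qh$terms$coeff[t] * (-1)^.popcount(bitwAnd(b, masks[t]))
    Eg <- sum(f * v)
    var_g <- max(sum(f * v^2) - Eg^2, 0) / K
    total <- total + Eg
    var_tot <- var_tot + var_g
    hists[[g]] <- counts
  }
  list(value = total, std_error = sqrt(var_tot), per_group_counts = hists)
  })
}

# expectation of arbitrary Pauli-sum operators sharing one sampling run.
# ops: list of operators, each a list(x=, z=, c= complex internal rep).
# Returns complex expectations (exact) or sampled estimates of each.
.measure_ops <- function(ops, psi, n_qubits, plan = NULL) {
  if (is.null(plan)) {
    return(vapply(ops, function(op) {
      op$n <- n_qubits
      pauli_expect(op, as.complex(psi))
    }, complex(1)))
  }
  # collect unique strings over all operators (standard letters)
  allx <- integer(0); allz <- integer(0)
  for (op in ops) { allx <- c(allx, op$x); allz <- c(allz, op$z) }
  key <- paste(allx, allz)
  ux <- allx[!duplicated(key)]; uz <- allz[!duplicated(key)]
  nontriv <- !(ux == 0L & uz == 0L)
  strings <- vapply(which(nontriv),
                    function(i) pauli_letters(ux[i], uz[i], n_qubits), "")
  pseudo <- structure(list(
    n_qubits = n_qubits,
    terms = data.frame(coeff = rep(1, sum(nontriv)), string = strings,
                       stringsAsFactors = FALSE),
    x = ux[nontriv], z = uz[nontriv]), class = "qubit_hamiltonian")
  grouping <- group_commuting(pseudo)
  est <- .with_seed(plan$seed, {
  K <- plan$shots
  b <- 0:(2^n_qubits - 1)
  masks <- .term_masks(pseudo$terms$string)
  est <- numeric(length(masks))
  for (g in seq_along(grouping$groups)) {
    idx <- grouping$groups[[g]]
    phi <- .rotate_to_basis(as.complex(psi), grouping$basis[[g]])
    p <- Mod(phi)^2; p <- p / sum(p)
    if (!is.null(plan$readout)) p <- .apply_confusion(p, plan$readout)
    counts <- as.vector(rmultinom(1, K, p))
    f <- if (plan$mitigate) readout_mitigate(counts, plan$readout) else counts / K
    for (t in idx)
      est[t] <- sum(f * (-1)^.popcount(bitwAnd(b, masks[t])))
  }
  est
  })
  skey <- paste(pseudo$x, pseudo$z)
  lookup <- c(est, 1)  # identity expectation is 1
  names(lookup) <- c(skey, "0 0")
  vapply(ops, function(op) {
    nY <- .popcount(bitwAnd(op$x, op$z))
    # <c * X^x Z^z> = c * (-i)^nY * <P_std>
    sum(op$c * (-1i)^nY * lookup[paste(op$x, op$z)])
  }, complex(1))
}

# ---- the fitting function ----

#' Fit a variational quantum eigensolver
#'
#' Minimizes the exact-expectation energy of the hardware-efficient Ry ansatz
#' over its rotation angles with L-BFGS-B and parameter-shift gradients
#' (classical pre-optimization; shot noise enters only through
#' [simulate.vqe()] afterwards, mirroring hardware practice). The initial
#' state defaults to the Hartree-Fock bitstring of the Hamiltonian's sector
#' when that context is available.
#'
#' @param qh a `qubit_hamiltonian`.
#' @param n_layers entangling layers `k` (default 1).
#' @param init_bits initial basis state (default: HF bitstring if the
#'   Hamiltonian carries sector context, else all zeros).
#' @param theta0 starting parameters (default zeros).
#' @param restarts additional random restarts (best result kept).
#' @param maxit optimizer iteration cap.
#' @param grad_tol gradient-norm convergence target.
#' @param seed RNG seed for restart draws.
#' @return An object of class `vqe` with the optimal angles (`coef()`), the
#'   variational energy (`$energy`, Hartree), the optimized statevector, and
#'   the optimization trace.
#' @examples
#' h2 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
#' ah <- fold_active_space(mol_integrals(h2), NULL)
#' fit <- vqe(parity_transform(ah))
#' summary(fit)
#' @export
vqe <- function(qh, n_layers = 1, init_bits = NULL, theta0 = NULL,
                restarts = 2, maxit = 1000, grad_tol = 1e-6, seed = 0) {
  N <- qh$n_qubits
  npar <- N * (n_layers + 1)
  if (is.null(init_bits)) {
    ctx <- qh$context
    init_bits <- if (!is.null(ctx))
      hf_bitstring(ctx$n_orb, ctx$n_elec_sector, ctx$mapping, ctx$reduced)
    else rep(0L, N)
  }
  Hm <- qubit_matrix(qh, include_identity = TRUE, include_core = TRUE)
  Hm <- (Hm + Conj(t(Hm))) / 2
  trace_env <- new.env()
  trace_env$vals <- numeric(0)
  efun <- function(theta) {
    psi <- simulate_state(theta, N, n_layers, init_bits)
    e <- Re(crossprod(psi, Re(Hm) %*% psi))[1]
    trace_env$vals <- c(trace_env$vals, e)
    e
  }
  gfun <- function(theta) {
    # parameter-shift rule: dE/dt_i = (E(t + pi/2 e_i) - E(t - pi/2 e_i)) / 2
    g <- numeric(length(theta))
    for (i in seq_along(theta)) {
      tp <- theta; tp[i] <- tp[i] + pi / 2
      tm <- theta; tm[i] <- tm[i] - pi / 2
      psip <- simulate_state(tp, N, n_layers, init_bits)
      psim <- simulate_state(tm, N, n_layers, init_bits)
      g[i] <- (Re(crossprod(psip, Re(Hm) %*% psip))[1] -
               Re(crossprod(psim, Re(Hm) %*% psim))[1]) / 2
    }
    g
  }
  starts <- .with_seed(seed, {
    s <- list(if (is.null(theta0)) rep(0, npar) else theta0)
    if (restarts > 0)
      for (r in seq_len(restarts)) s <- c(s, list(rnorm(npar, 0, 0.5)))
    s
  })
  best <- NULL
  for (th0 in starts) {
    trace_env$vals <- numeric(0)
    res <- optim(th0, efun, gfun, method = "L-BFGS-B",
                 control = list(maxit = maxit, factr = 10))
    gn <- sqrt(sum(gfun(res$par)^2))
    cand <- list(par = res$par, value = res$value, grad_norm = gn,
                 trace = trace_env$vals, counts = res$counts,
                 convergence = res$convergence)
    if (is.null(best) || cand$value < best$value - 1e-12 ||
        (abs(cand$value - best$value) <= 1e-12 && cand$grad_norm < best$grad_norm))
      best <- cand
  }
  if (best$grad_norm > grad_tol)
    warning(sprintf("VQE gradient norm %.2e above target %.1e; returning best found",
                    best$grad_norm, grad_tol))
  psi <- simulate_state(best$par, N, n_layers, init_bits)
  structure(list(
    theta = best$par, energy = best$value, statevector = psi,
    grad_norm = best$grad_norm, trace = best$trace,
    qh = qh, n_layers = n_layers, init_bits = init_bits,
    n_qubits = N, counts = best$counts, seed = seed
  ), class = "vqe")
}

#' @export
print.vqe <- function(x, ...) {
  cat(sprintf("VQE fit: %d qubits, %d layers, E = %.10f Hartree\n",
              x$n_qubits, x$n_layers, x$energy))
  cat(sprintf("  |grad| = %.2e, %d parameters\n", x$grad_norm, length(x$theta)))
  invisible(x)
}

#' @export
coef.vqe <- function(object, ...) object$theta

#' @export
summary.vqe <- function(object, ...) {
  ed <- eigen(qubit_matrix(object$qh, TRUE, TRUE), symmetric = TRUE,
              only.values = TRUE)$values
  out <- list(energy = object$energy, exact_ground = min(ed),
              gap_to_exact = object$energy - min(ed),
              grad_norm = object$grad_norm, theta = object$theta,
              n_qubits = object$n_qubits, n_layers = object$n_layers,
              n_terms = nrow(object$qh$terms))
  class(out) <- "summary.vqe"
  out
}

#' @export
print.summary.vqe <- function(x, ...) {
  cat(sprintf("VQE summary (%d qubits, %d layers, %d Pauli terms)\n",
              x$n_qubits, x$n_layers, x$n_terms))
  cat(sprintf("  E(VQE)   = %.10f Hartree\n", x$energy))
  cat(sprintf("  E(exact) = %.10f Hartree (diagonalization)\n", x$exact_ground))
  cat(sprintf("  gap      = %.3e Hartree (variational, >= 0)\n", x$gap_to_exact))
  invisible(x)
}

#' @export
predict.vqe <- function(object, theta = NULL, ...) {
  if (is.null(theta)) return(object$energy)
  psi <- simulate_state(theta, object$n_qubits, object$n_layers, object$init_bits)
  energy_expectation(object$qh, psi)$value
}

#' Repeat the sampled measurement pipeline of a fitted VQE
#'
#' Re-measures the optimized state `nsim` times with the full shot-based
#' pipeline (grouped sampling, readout error, optional mitigation), the way
#' repeated hardware experiments are aggregated into mean and standard
#' deviation.
#'
#' @param object a fitted [vqe()] model.
#' @param nsim number of independent repeats (default 4).
#' @param seed RNG seed.
#' @param shots shots per measurement group.
#' @param readout optional [readout_confusion()] model.
#' @param mitigate apply readout mitigation.
#' @param ... unused.
#' @return data.frame with one row per repeat: `energy`, `std_error`.
#' @export
simulate.vqe <- function(object, nsim = 4, seed = 0, shots = 8192,
                         readout = NULL, mitigate = FALSE, ...) {
  grouping <- group_commuting(object$qh)
  out <- data.frame(energy = numeric(nsim), std_error = numeric(nsim))
  for (r in seq_len(nsim)) {
    plan <- measurement_plan(shots, readout, mitigate, seed = seed + r - 1)
    est <- energy_expectation(object$qh, object$statevector, plan, grouping)
    out$energy[r] <- est$value
    out$std_error[r] <- est$std_error
  }
  out
}

#' @export
plot.vqe <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "l",
                 xlab = "energy evaluation", ylab = "E (Hartree)",
                 main = "VQE optimization trace", ...)
  invisible(x)
}

# ---- reduced density matrices from the optimized state ----

#' Measure active-space reduced density matrices
#'
#' Assembles the spatial one- and two-body RDMs of the optimized ansatz state
#' from Pauli expectations under the same fermion-to-qubit mapping (including
#' the two-qubit reduction). Exact mode contracts the statevector; sampled
#' mode shares one grouped sampling run across all RDM elements.
#'
#' @param fit a fitted [vqe()] model whose Hamiltonian carries mapping
#'   context (from [parity_transform()] or [jordan_wigner()]).
#' @param plan a [measurement_plan()] or `NULL` for exact contraction.
#' @return list with `rdm1` (n x n, trace = active electrons) and `rdm2`
#'   (`rdm2[p,q,r,s] = sum_st <a+_ps a+_qt a_rt a_ss>`).
#' @export
measure_rdms <- function(fit, plan = NULL) {
  ctx <- fit$qh$context
  if (is.null(ctx)) stop("Hamiltonian carries no mapping context")
  n <- ctx$n_orb
  nso <- 2L * n
  L <- ladder_ops(nso, if (ctx$mapping == "parity") "parity" else "jordan-wigner")
  red <- function(op) {
    if (ctx$reduced)
      .reduce_two_qubits(op, n_alpha = ctx$n_elec_sector / 2,
                         n_elec = ctx$n_elec_sector)
    else op
  }
  psi <- fit$statevector
  ops1 <- list(); keys1 <- list()
  for (p in seq_len(n)) for (q in seq_len(n)) {
    acc <- pauli_zero(nso)
    for (sg in c(0L, n))
      acc <- pauli_add(acc, pauli_mult(L$ad[[p + sg]], L$a[[q + sg]]))
    ops1[[length(ops1) + 1L]] <- red(acc)
    keys1[[length(keys1) + 1L]] <- c(p, q)
  }
  ops2 <- list(); keys2 <- list()
  for (p in seq_len(n)) for (q in seq_len(n)) for (r in seq_len(n)) for (s in seq_len(n)) {
    acc <- pauli_zero(nso)
    for (sg1 in c(0L, n)) for (sg2 in c(0L, n)) {
      pp <- p + sg1; ss <- s + sg1; qq <- q + sg2; rr <- r + sg2
      if (pp == qq || rr == ss) next
      acc <- pauli_add(acc, pauli_mult(pauli_mult(L$ad[[pp]], L$ad[[qq]]),
                                       pauli_mult(L$a[[rr]], L$a[[ss]])))
    }
    ops2[[length(ops2) + 1L]] <- red(acc)
    keys2[[length(keys2) + 1L]] <- c(p, q, r, s)
  }
  est <- .measure_ops(c(ops1, ops2), psi, fit$n_qubits, plan)
  rdm1 <- matrix(0, n, n)
  for (i in seq_along(ops1)) {
    k <- keys1[[i]]
    rdm1[k[1], k[2]] <- Re(est[i])
  }
  rdm2 <- array(0, c(n, n, n, n))
  for (i in seq_along(ops2)) {
    k <- keys2[[i]]
    rdm2[k[1], k[2], k[3], k[4]] <- Re(est[length(ops1) + i])
  }
  rdm1 <- (rdm1 + t(rdm1)) / 2
  list(rdm1 = rdm1, rdm2 = rdm2)
}
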