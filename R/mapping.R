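# Fermion-to-qubit mappings. Spin-orbitals are blocked (all alpha, then all
# beta) and qubit j corresponds to spin-orbital j. The parity mapping stores
# cumulative occupation parities, which localizes the total-alpha and
# total-electron parity symmetries on qubits n/2-1 and n-1 so both can be
# replaced by their sector eigenvalues ("two-qubit reduction").

.bit <- function(mask, j) bitwAnd(mask, bitwShiftL(1L, j)) > 0L

.mask <- function(js) {
  m <- 0L
  for (j in js) m <- bitwOr(m, bitwShiftL(1L, j))
  m
}

pauli_adjoint <- function(op) {
  sgn <- (-1)^.popcount(bitwAnd(op$x, op$z))
  op$c <- Conj(op$c) * sgn
  op
}

# annihilation operator for mode j (0-based) on n modes
.ladder_jw <- function(j, n) {
  zl <- if (j > 0) .mask(0:(j - 1)) else 0L
  xj <- bitwShiftL(1L, j)
  # (X + iY)/2 = (X - XZ)/2 with Z string on lower modes
  list(x = c(xj, xj), z = c(zl, bitwOr(zl, xj)),
       c = c(0.5 + 0i, -0.5 + 0i), n = as.integer(n))
}

.ladder_parity <- function(j, n) {
  xj <- bitwShiftL(1L, j)
  xup <- if (j < n - 1) .mask((j + 1):(n - 1)) else 0L
  cj  <- pauli_term(n, c(xj, xj), c(0L, xj), c(0.5, -0.5))        # (X+iY)/2
  cdj <- pauli_term(n, c(xj, xj), c(0L, xj), c(0.5, +0.5))        # (X-iY)/2
  if (j == 0) {
    op <- cj
  } else {
    zjm1 <- bitwShiftL(1L, j - 1L)
    p0 <- pauli_term(n, c(0L, 0L), c(0L, zjm1), c(0.5, 0.5))      # |0><0|_{j-1}
    p1 <- pauli_term(n, c(0L, 0L), c(0L, zjm1), c(0.5, -0.5))     # |1><1|_{j-1}
    op <- pauli_add(pauli_mult(cj, p0), pauli_scale(pauli_mult(cdj, p1), -1))
  }
  xop <- pauli_term(n, xup, 0L, 1)
  pauli_mult(op, xop)
}

ladder_ops <- function(n_modes, mapping = c("parity", "jordan-wigner")) {
  mapping <- match.arg(mapping)
  f <- if (mapping == "parity") .ladder_parity else .ladder_jw
  a <- lapply(0:(n_modes - 1), f, n = n_modes)
  list(a = a, ad = lapply(a, pauli_adjoint))
}

# map an active-space fermionic Hamiltonian to a sum of Pauli terms
.fermion_to_pauli <- function(ah, mapping) {
  n <- ah$n_active_orb
  nso <- 2L * n
  L <- ladder_ops(nso, mapping)
  acc <- pauli_zero(nso)
  # one-body: sum_sigma h[p,q] ad_{p sigma} a_{q sigma}
  for (p in seq_len(n)) for (q in seq_len(n)) {
    hval <- ah$h_eff[p, q]
    if (abs(hval) < 1e-14) next
    for (sg in c(0L, n)) {
      acc <- pauli_add(acc, pauli_scale(
        pauli_mult(L$ad[[p + sg]], L$a[[q + sg]]), hval), simplify = FALSE)
    }
  }
  acc <- pauli_simplify(acc)
  # two-body: 1/2 sum [ps|qr] ad_p ad_q a_r a_s with spin(p)=spin(s), spin(q)=spin(r)
  for (p in seq_len(n)) for (q in seq_len(n)) for (r in seq_len(n)) for (s in seq_len(n)) {
    g <- ah$eri_active[p, s, q, r]
    if (abs(g) < 1e-14) next
    for (sg1 in c(0L, n)) for (sg2 in c(0L, n)) {
      pp <- p + sg1; ss <- s + sg1; qq <- q + sg2; rr <- r + sg2
      if (pp == qq || rr == ss) next  # ad_p ad_q (a_r a_s) vanish for equal modes
      t1 <- pauli_mult(L$ad[[pp]], L$ad[[qq]])
      t2 <- pauli_mult(L$a[[rr]], L$a[[ss]])
      acc <- pauli_add(acc, pauli_scale(pauli_mult(t1, t2), 0.5 * g),
                       simplify = FALSE)
    }
    acc <- pauli_simplify(acc)
  }
  acc
}

# drop two symmetry qubits, substituting their Z eigenvalues
.reduce_two_qubits <- function(op, n_alpha, n_elec) {
  n <- op$n
  q1 <- n %/% 2L - 1L   # alpha-parity qubit
  q2 <- n - 1L          # total-parity qubit
  s1 <- (-1)^(n_alpha %% 2)
  s2 <- (-1)^(n_elec %% 2)
  keep <- !( .bit(op$x, q1) | .bit(op$x, q2) )
  x <- op$x[keep]; z <- op$z[keep]; cc <- op$c[keep]
  cc <- cc * ifelse(.bit(z, q1), s1, 1) * ifelse(.bit(z, q2), s2, 1)
  # remove bit positions q1 and q2 (q2 is the top bit)
  strip <- function(m) {
    low <- bitwAnd(m, bitwShiftL(1L, q1) - 1L)
    mid <- bitwAnd(bitwShiftR(m, q1 + 1L), bitwShiftL(1L, q2 - q1 - 1L) - 1L)
    bitwOr(low, bitwShiftL(mid, q1))
  }
  list(x = strip(x), z = strip(z), c = cc, n = n - 2L)
}

.make_qubit_hamiltonian <- function(op, e_core, mapping, truncation = 1e-10) {
  op <- pauli_simplify(op)
  std <- pauli_std_coeff(op)
  if (length(std) && max(abs(Im(std))) > 1e-8)
    stop("mapped Hamiltonian is not Hermitian (max imaginary coefficient ",
         signif(max(abs(Im(std))), 3), ")")
  coeff <- Re(std)
  keep <- abs(coeff) > truncation
  x <- op$x[keep]; z <- op$z[keep]; coeff <- coeff[keep]
  id <- x == 0L & z == 0L
  identity_offset <- if (any(id)) sum(coeff[id]) else 0
  x <- x[!id]; z <- z[!id]; coeff <- coeff[!id]
  strings <- vapply(seq_along(coeff),
                    function(i) pauli_letters(x[i], z[i], op$n), "")
  ord <- order(-abs(coeff), strings)
  structure(list(
    n_qubits = op$n,
    terms = data.frame(coeff = coeff[ord], string = strings[ord],
                       stringsAsFactors = FALSE),
    x = x[ord], z = z[ord],
    identity_offset = identity_offset,
    e_core = e_core,
    mapping = mapping
  ), class = "qubit_hamiltonian")
}

#' Map an active-space Hamiltonian to qubits via the parity transformation
#'
#' Applies the parity fermion-to-qubit mapping with blocked spin ordering
#' (all alpha spin-orbitals, then all beta). With `two_qubit_reduction`, the
#' alpha-parity and total-parity qubits are replaced by their sector
#' eigenvalues, reducing a `(2e,2o)` problem to 2 qubits. Coefficients below
#' `truncation` (Hartree) are dropped.
#'
#' @param ah an `active_hamiltonian`.
#' @param two_qubit_reduction logical; substitute the two parity symmetries.
#' @param n_elec_sector electron count of the target sector (defaults to the
#'   active electron count; must be even, with `N_alpha = N_beta`).
#' @param truncation coefficient truncation threshold in Hartree.
#' @return A `qubit_hamiltonian`: Pauli terms (`terms$coeff`, `terms$string`),
#'   `n_qubits`, `identity_offset` (coefficient of the identity string) and
#'   `e_core` carried from the active Hamiltonian.
#' @export
parity_transform <- function(ah, two_qubit_reduction = TRUE,
                             n_elec_sector = ah$n_active_elec,
                             truncation = 1e-10) {
  if (n_elec_sector %% 2 != 0)
    stop("sector must have even electron count (N_alpha = N_beta)")
  op <- .fermion_to_pauli(ah, "parity")
  if (two_qubit_reduction) {
    if (op$n < 4) stop("two-qubit reduction needs at least 4 spin-orbitals")
    op <- .reduce_two_qubits(op, n_alpha = n_elec_sector / 2,
                             n_elec = n_elec_sector)
  }
  qh <- .make_qubit_hamiltonian(op, ah$e_core, "parity", truncation)
  qh$context <- list(n_orb = ah$n_active_orb, n_elec_sector = n_elec_sector,
                     reduced = two_qubit_reduction, mapping = "parity")
  qh
}

#' Jordan-Wigner mapping of an active-space Hamiltonian
#'
#' Reference mapping without qubit reduction; spectrally equivalent to the
#' parity mapping and used as a cross-check.
#'
#' @inheritParams parity_transform
#' @return A `qubit_hamiltonian` on `2 * n_active_orb` qubits.
#' @export
jordan_wigner <- function(ah, truncation = 1e-10) {
  qh <- .make_qubit_hamiltonian(.fermion_to_pauli(ah, "jordan-wigner"),
                                ah$e_core, "jordan-wigner", truncation)
  qh$context <- list(n_orb = ah$n_active_orb, n_elec_sector = ah$n_active_elec,
                     reduced = FALSE, mapping = "jordan-wigner")
  qh
}

#' @export
print.qubit_hamiltonian <- function(x, n = 10, ...) {
  cat(sprintf("Qubit Hamiltonian (%s): %d qubits, %d Pauli terms, offset %.8f\n",
              x$mapping, x$n_qubits, nrow(x$terms),
              x$identity_offset + x$e_core))
  print(head(x$terms, n))
  if (nrow(x$terms) > n) cat("  ...\n")
  invisible(x)
}

# dense matrix of the qubit Hamiltonian (without e_core unless asked)
qubit_matrix <- function(qh, include_identity = TRUE, include_core = FALSE) {
  nY <- .popcount(bitwAnd(qh$x, qh$z))
  op <- list(x = qh$x, z = qh$z, c = qh$terms$coeff * (1i)^nY, n = qh$n_qubits)
  M <- pauli_matrix(op)
  if (include_identity)
    M <- M + diag(qh$identity_offset + if (include_core) qh$e_core else 0,
                  2^qh$n_qubits)
  M
}

#' Count measurable Pauli terms
#'
#' Number of non-identity Pauli strings with coefficient above the mapping
#' truncation threshold -- the strings that must be measured on hardware.
#'
#' @param qh a `qubit_hamiltonian`.
#' @return integer count.
#' @export
count_measurable_terms <- function(qh) {
  sum(abs(qh$terms$coeff) > 0)
}

#' Group Pauli terms by qubit-wise commutation
#'
#' Greedy first-fit partition: terms are processed in order of decreasing
#' coefficient magnitude (ties broken lexicographically) and placed in the
#' first group whose strings are compatible letter-by-letter (at each qubit,
#' at most one non-identity letter). All strings in a group are diagonal in
#' one product measurement basis.
#'
#' @param qh a `qubit_hamiltonian`.
#' @return A `measurement_grouping`: `groups` (list of row indices into
#'   `qh$terms`) and `basis` (per group, the measurement letter per qubit,
#'   `Z` where unconstrained).
#' @export
group_commuting <- function(qh) {
  n <- qh$n_qubits
  strings <- qh$terms$string
  m <- length(strings)
  groups <- list()
  basis <- list()
  # terms are already sorted by decreasing |coeff| then string
  for (i in seq_len(m)) {
    lets <- strsplit(strings[i], "")[[1]]
    placed <- FALSE
    for (g in seq_along(groups)) {
      bg <- basis[[g]]
      ok <- all(lets == "I" | bg == "I" | lets == bg)
      if (ok) {
        groups[[g]] <- c(groups[[g]], i)
        bg[lets != "I"] <- lets[lets != "I"]
        basis[[g]] <- bg
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1L]] <- i
      basis[[length(basis) + 1L]] <- lets
    }
  }
  basis <- lapply(basis, function(b) { b[b == "I"] <- "Z"; b })
  structure(list(groups = groups, basis = basis, n_qubits = n),
            class = "measurement_grouping")
}

#' @export
print.measurement_grouping <- function(x, ...) {
  cat(sprintf("Measurement grouping: %d groups over %d qubits\n",
              length(x$groups), x$n_qubits))
  for (g in seq_along(x$groups))
    cat(sprintf("  group %d [basis %s]: %d terms\n", g,
                paste(x$basis[[g]], collapse = ""), length(x$groups[[g]])))
  invisible(x)
}

# Hartree-Fock occupation bitstring in a given encoding (qubit j value),
# for the closed-shell sector with blocked spins
hf_bitstring <- function(n_orb, n_elec, mapping = "parity", reduced = TRUE) {
  na <- n_elec %/% 2L
  occ <- c(as.integer(seq_len(n_orb) <= na), as.integer(seq_len(n_orb) <= na))
  if (mapping == "jordan-wigner") return(occ)
  par <- cumsum(occ) %% 2L
  if (reduced) par <- par[-c(n_orb, 2L * n_orb)]
  par
}

#' Serialize Pauli terms as JSON lines
#'
#' One JSON object per line: `{"coeff": ..., "string": "XZ"}`. The identity
#' offset and core energy are written as a leading object with an empty
#' string.
#'
#' @param qh a `qubit_hamiltonian`.
#' @param path output file.
#' @export
write_pauli_jsonl <- function(qh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('{"coeff": %.16g, "string": "%s", "n_qubits": %d, "e_core": %.16g}',
                     qh$identity_offset, "", qh$n_qubits, qh$e_core), con)
  for (i in seq_len(nrow(qh$terms)))
    writeLines(sprintf('{"coeff": %.16g, "string": "%s"}',
                       qh$terms$coeff[i], qh$terms$string[i]), con)
  invisible(path)
}

#' @rdname write_pauli_jsonl
#' @export
read_pauli_jsonl <- function(path) {
  lines <- readLines(path)
  objs <- lapply(lines, jsonlite::fromJSON)
  hdr <- objs[[1]]
  rest <- objs[-1]
  strings <- vapply(rest, function(o) o$string, "")
  coeff <- vapply(rest, function(o) o$coeff, 0)
  n <- hdr$n_qubits
  xz <- t(vapply(strings, function(s) {
    lets <- strsplit(s, "")[[1]]
    c(.mask(which(lets %in% c("X", "Y")) - 1L), .mask(which(lets %in% c("Y", "Z")) - 1L))
  }, integer(2)))
  structure(list(n_qubits = n,
                 terms = data.frame(coeff = coeff, string = strings,
                                    stringsAsFactors = FALSE),
                 x = as.integer(xz[, 1]), z = as.integer(xz[, 2]),
                 identity_offset = hdr$coeff, e_core = hdr$e_core,
                 mapping = "file"), class = "qubit_hamiltonian")
}
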