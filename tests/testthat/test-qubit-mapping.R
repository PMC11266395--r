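# Parity / Jordan-Wigner mappings against the dense fermionic-matrix oracle,
# term counting, and qubit-wise-commuting measurement grouping.

.dense <- function(qh) {
  M <- vqemol:::qubit_matrix(qh, include_identity = TRUE, include_core = TRUE)
  (M + Conj(t(M))) / 2
}

test_that("a (2e,2o) active space maps to a 2-qubit Hamiltonian", {
  qh <- parity_transform(random_active_integrals(2, 2, seed = 1))
  expect_equal(qh$n_qubits, 2L)
})

test_that("mapped spectra equal brute-force fermionic spectra", {
  sizes <- c(rep(2, 8), rep(3, 8), rep(4, 4))
  for (i in seq_along(sizes)) {
    n <- sizes[i]
    ah <- random_active_integrals(n, 2, seed = 100 + i, symmetric = i %% 5 == 0)
    Ho <- oracle_fermion_matrix(ah) + diag(ah$e_core, 4^n)
    ev_oracle <- sort(eigen(Ho, symmetric = TRUE, only.values = TRUE)$values)
    # Jordan-Wigner: identical full spectrum
    ev_jw <- sort(Re(eigen(.dense(jordan_wigner(ah)),
                           only.values = TRUE)$values))
    expect_equal(ev_jw, ev_oracle, tolerance = 1e-9)
    # parity without reduction: identical full spectrum (cross-mapping)
    qp <- parity_transform(ah, two_qubit_reduction = FALSE)
    ev_par <- sort(Re(eigen(.dense(qp), only.values = TRUE)$values))
    expect_equal(ev_par, ev_oracle, tolerance = 1e-9)
    # parity with reduction: spectrum of the (N_alpha odd, N even) symmetry
    # sector of the oracle
    qr <- parity_transform(ah, two_qubit_reduction = TRUE, n_elec_sector = 2)
    ev_red <- sort(Re(eigen(.dense(qr), only.values = TRUE)$values))
    occ <- oracle_occupations(2 * n)
    sector <- (rowSums(occ[, seq_len(n), drop = FALSE]) %% 2 == 1) &
      (rowSums(occ) %% 2 == 0)
    ev_sec <- sort(eigen(Ho[sector, sector], symmetric = TRUE,
                         only.values = TRUE)$values)
    expect_equal(ev_red, ev_sec, tolerance = 1e-9)
  }
})

test_that("mapped ladder operators obey the fermionic anticommutators", {
  for (mapping in c("parity", "jordan-wigner")) {
    L <- vqemol:::ladder_ops(3, mapping)
    for (p in 1:3) for (q in 1:3) {
      anti <- vqemol:::pauli_add(
        vqemol:::pauli_mult(L$a[[p]], L$ad[[q]]),
        vqemol:::pauli_mult(L$ad[[q]], L$a[[p]]))
      anti <- vqemol:::pauli_simplify(anti, tol = 1e-12)
      if (p == q) {
        expect_equal(length(anti$c), 1L)
        expect_equal(anti$x, 0L); expect_equal(anti$z, 0L)
        expect_equal(anti$c, as.complex(1))
      } else {
        expect_equal(length(anti$c), 0L)
      }
      # a_p a_p = 0
      sq <- vqemol:::pauli_simplify(vqemol:::pauli_mult(L$a[[p]], L$a[[p]]),
                                    tol = 1e-12)
      expect_equal(length(sq$c), 0L)
    }
  }
})

test_that("an asymmetric (2e,2o) fixture yields the generic 8-string Hamiltonian", {
  qh <- parity_transform(random_active_integrals(2, 2, symmetric = FALSE,
                                                 seed = 42))
  expect_equal(count_measurable_terms(qh), 8L)
  expect_setequal(qh$terms$string,
                  c("ZI", "IZ", "ZZ", "XX", "XI", "IX", "XZ", "ZX"))
  # greedy qubit-wise-commuting first-fit packs these into four product bases
  g <- group_commuting(qh)
  expect_equal(length(g$groups), 4L)
})

test_that("point-group symmetry reduces the measurable term count", {
  # H2 at equilibrium: g/u selection rules kill half the strings
  ah <- fold_active_space(mol_integrals(h2_geom()), NULL)
  n_sym <- count_measurable_terms(parity_transform(ah))
  n_asym <- count_measurable_terms(
    parity_transform(random_active_integrals(2, 2, symmetric = FALSE, seed = 1)))
  expect_lt(n_sym, n_asym)
  expect_equal(n_sym, 4L)  # recorded from the explicit construction
})

test_that("degenerate and trivial grouping cases behave", {
  mk_qh <- function(coeff, strings, n) {
    lets <- strsplit(strings, "")
    x <- vapply(lets, function(l) vqemol:::.mask(which(l %in% c("X", "Y")) - 1L), 1L)
    z <- vapply(lets, function(l) vqemol:::.mask(which(l %in% c("Y", "Z")) - 1L), 1L)
    structure(list(n_qubits = n,
                   terms = data.frame(coeff = coeff, string = strings,
                                      stringsAsFactors = FALSE),
                   x = x, z = z, identity_offset = 0, e_core = 0,
                   mapping = "manual"), class = "qubit_hamiltonian")
  }
  # identity only: zero measurable terms
  qh0 <- parity_transform(active_hamiltonian(matrix(0, 2, 2),
                                             array(0, c(2, 2, 2, 2)),
                                             1.0, 2))
  expect_equal(count_measurable_terms(qh0), 0L)
  # all-Z Hamiltonian: one group
  qz <- mk_qh(c(0.5, 0.3, 0.2), c("ZI", "IZ", "ZZ"), 2)
  expect_equal(length(group_commuting(qz)$groups), 1L)
  # single term: one group
  q1 <- mk_qh(1.0, "XY", 2)
  expect_equal(length(group_commuting(q1)$groups), 1L)
})

test_that("grouping is a valid partition with joint measurability", {
  qh <- parity_transform(random_active_integrals(3, 2, seed = 8),
                         two_qubit_reduction = TRUE)
  g <- group_commuting(qh)
  idx <- sort(unlist(g$groups))
  expect_equal(idx, seq_len(nrow(qh$terms)))  # covers all terms exactly once
  for (k in seq_along(g$groups)) {
    basis <- g$basis[[k]]
    for (t in g$groups[[k]]) {
      lets <- strsplit(qh$terms$string[t], "")[[1]]
      expect_true(all(lets == "I" | lets == basis))
    }
  }
})

test_that("Pauli term serialization round-trips through JSON lines", {
  qh <- parity_transform(random_active_integrals(2, 2, seed = 4))
  path <- tempfile(fileext = ".jsonl")
  write_pauli_jsonl(qh, path)
  back <- read_pauli_jsonl(path)
  expect_equal(back$terms$coeff, qh$terms$coeff, tolerance = 1e-14)
  expect_equal(back$terms$string, qh$terms$string)
  expect_equal(back$e_core, qh$e_core, tolerance = 1e-14)
  expect_equal(sort(Re(eigen(.dense(back), only.values = TRUE)$values)),
               sort(Re(eigen(.dense(qh), only.values = TRUE)$values)),
               tolerance = 1e-12)
})
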