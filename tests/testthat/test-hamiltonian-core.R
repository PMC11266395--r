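# Integrals, active-space folding and CASCI against independent oracles.

test_that("minimal H2 produces the smallest closed-shell problem", {
  ints <- mol_integrals(h2_geom())
  expect_equal(ints$n_orb, 2L)
  expect_equal(ints$n_elec, 2)
  expect_lt(abs(ints$e_hf - (-1.1167)), 2e-4)  # textbook RHF/STO-3G value
})

test_that("integral tensors satisfy their structural invariants", {
  for (g in list(h2_geom(), water_geom())) {
    ints <- mol_integrals(g)
    expect_equal(ints$h_core, t(ints$h_core), tolerance = 1e-10)
    e <- ints$eri
    expect_equal(e, aperm(e, c(2, 1, 3, 4)), tolerance = 1e-10)
    expect_equal(e, aperm(e, c(3, 4, 1, 2)), tolerance = 1e-10)
    expect_equal(e, aperm(e, c(2, 1, 4, 3)), tolerance = 1e-10)
    ortho <- t(ints$mo_coeff) %*% ints$ao_overlap %*% ints$mo_coeff
    expect_equal(ortho, diag(ints$n_orb), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("FCIDUMP files round-trip the integral tensors", {
  ah <- random_active_integrals(3, 2, seed = 11)
  path <- tempfile(fileext = ".fcidump")
  write_fcidump(ah, path)
  back <- read_fcidump(path)
  expect_equal(back$h_eff, ah$h_eff, tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(back$eri_active, ah$eri_active, tolerance = 1e-14)
  expect_equal(back$e_core, ah$e_core, tolerance = 1e-14)
  expect_equal(back$n_active_elec, ah$n_active_elec)
})

test_that("empty frozen set folds to the identity transformation", {
  ints <- mol_integrals(water_geom())
  ah <- fold_active_space(ints, NULL)
  expect_equal(ah$h_eff, ints$h_core, ignore_attr = TRUE)
  expect_equal(ah$eri_active, ints$eri)
  expect_equal(ah$e_core, ints$e_nuc)
})

test_that("frozen-core folding matches the determinant-restricted oracle", {
  # freeze orbital 1 of random 4-orbital instances; the folded (n-2 e, 3o)
  # ground state + e_core must equal the lowest eigenvalue of the full
  # fermionic Hamiltonian restricted to determinants with orbital 1 doubly
  # occupied
  for (seed in c(2, 7, 19)) {
    ah4 <- random_active_integrals(4, 4, seed = seed)
    full <- structure(list(n_orb = 4L, n_elec = 4, h_core = ah4$h_eff,
                           eri = ah4$eri_active, e_nuc = ah4$e_core),
                      class = "mol_integrals")
    spec <- structure(list(n_active_orb = 3L, n_active_elec = 2L,
                           frozen_set = 1L, active_set = 2:4),
                      class = "active_space_spec")
    folded <- fold_active_space(full, spec)
    e_folded <- casci(folded)$energy
    H <- oracle_fermion_matrix(ah4)
    occ <- oracle_occupations(8)
    sector <- occ[, 1] & occ[, 5] &              # orbital 1 doubly occupied
      rowSums(occ) == 4                          # 4 electrons total
    e_oracle <- min(eigen(H[sector, sector], symmetric = TRUE,
                          only.values = TRUE)$values) + ah4$e_core
    expect_equal(e_folded, e_oracle, tolerance = 1e-10)
  }
})

test_that("CASCI reduces to a single determinant without couplings", {
  h <- diag(c(-2, -1))
  eri <- array(0, c(2, 2, 2, 2))
  eri[1, 1, 1, 1] <- 0.5; eri[2, 2, 2, 2] <- 0.6
  eri[1, 1, 2, 2] <- eri[2, 2, 1, 1] <- 0.3
  ah <- active_hamiltonian(h, eri, e_core = 1.25, n_active_elec = 2)
  cs <- casci(ah)
  expect_equal(cs$energy, 1.25 + 2 * h[1, 1] + eri[1, 1, 1, 1],
               tolerance = 1e-12)
})

test_that("CASCI spectrum equals the dense singlet-sector oracle", {
  for (seed in 1:4) {
    ah <- random_active_integrals(2, 2, seed = seed)
    cs <- casci(ah)
    H <- oracle_fermion_matrix(ah)
    occ <- oracle_occupations(4)
    sector <- rowSums(occ[, 1:2, drop = FALSE]) == 1 &
      rowSums(occ[, 3:4, drop = FALSE]) == 1     # N_alpha = N_beta = 1
    ev <- sort(eigen(H[sector, sector], symmetric = TRUE,
                     only.values = TRUE)$values) + ah$e_core
    expect_equal(sort(cs$spectrum), ev, tolerance = 1e-10)
    expect_equal(sum(diag(cs$rdm1)), 2, tolerance = 1e-10)
  }
})

test_that("correlation never raises the energy below the mean field", {
  for (g in list(h2_geom(), water_geom())) {
    ints <- mol_integrals(g)
    spec <- active_space(ints, 2, 2)
    cs <- casci(fold_active_space(ints, spec))
    expect_lte(cs$energy, ints$e_hf + 1e-10)
  }
})

test_that("RDM contraction reconstructs the CASCI energy", {
  ah <- random_active_integrals(3, 2, seed = 5)
  cs <- casci(ah)
  expect_equal(vqemol:::rdm_energy(ah, cs$rdm1, cs$rdm2), cs$energy,
               tolerance = 1e-10)
})
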