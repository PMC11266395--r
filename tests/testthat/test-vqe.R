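# Ry-ansatz statevector simulation, exact and shot-based expectation values,
# parameter optimization, readout mitigation, and RDM measurement.

.manual_qh <- function(coeff, strings, n, offset = 0) {
  lets <- strsplit(strings, "")
  x <- vapply(lets, function(l) vqemol:::.mask(which(l %in% c("X", "Y")) - 1L), 1L)
  z <- vapply(lets, function(l) vqemol:::.mask(which(l %in% c("Y", "Z")) - 1L), 1L)
  structure(list(n_qubits = n,
                 terms = data.frame(coeff = coeff, string = strings,
                                    stringsAsFactors = FALSE),
                 x = x, z = z, identity_offset = offset, e_core = 0,
                 mapping = "manual"), class = "qubit_hamiltonian")
}

test_that("the ansatz circuit has the expected closed forms", {
  # zero angles leave |00> untouched (identity rotations, CNOT inert)
  psi <- simulate_state(rep(0, 4), 2, 1, c(0L, 0L))
  expect_equal(psi, c(1, 0, 0, 0))
  # with a set control bit the zero-angle CNOT ladder flips the target
  psi10 <- simulate_state(rep(0, 4), 2, 1, c(1L, 0L))
  expect_equal(psi10, c(0, 0, 0, 1))
  # single qubit, no entangling layer: Ry(theta)|0> = (cos t/2, sin t/2)
  psi1 <- simulate_state(pi / 2, 1, 0, 0L)
  expect_equal(psi1, c(cos(pi / 4), sin(pi / 4)))
})

test_that("Ry + CNOT circuits preserve real amplitudes", {
  set.seed(7)
  for (rep in 1:10) {
    th <- runif(6, -pi, pi)
    psi <- simulate_state(th, 3, 1)
    expect_true(is.numeric(psi))
    expect_equal(sum(psi^2), 1, tolerance = 1e-12)
  }
})

test_that("exact expectation equals the dense-matrix quadratic form", {
  qh <- parity_transform(random_active_integrals(2, 2, seed = 3))
  M <- vqemol:::qubit_matrix(qh, TRUE, TRUE)
  set.seed(11)
  for (rep in 1:5) {
    th <- runif(4, -pi, pi)
    psi <- simulate_state(th, 2, 1)
    e <- energy_expectation(qh, psi)$value
    expect_equal(e, Re(t(psi) %*% M %*% psi)[1], tolerance = 1e-12)
  }
})

test_that("VQE recovers the CASCI energy on (2e,2o) fixtures", {
  for (seed in 1:20) {
    ah <- random_active_integrals(2, 2, seed = seed,
                                  symmetric = seed %% 4 == 0)
    e_exact <- casci(ah)$energy
    fit <- suppressWarnings(vqe(parity_transform(ah), restarts = 4,
                                seed = seed))
    expect_gte(fit$energy, e_exact - 1e-9)      # variational bound
    expect_lte(fit$energy - e_exact, 1e-6)      # single layer is expressive
  }
})

test_that("trivial single-qubit Hamiltonians optimize to the closed form", {
  qh <- .manual_qh(-1, "Z", 1)
  fit <- vqe(qh, restarts = 1)
  expect_equal(fit$energy, -1, tolerance = 1e-8)
})

test_that("parameter-shift gradients match finite differences", {
  qh <- parity_transform(random_active_integrals(2, 2, seed = 9))
  M <- Re(vqemol:::qubit_matrix(qh, TRUE, TRUE))
  efun <- function(th) {
    psi <- simulate_state(th, 2, 1)
    drop(t(psi) %*% M %*% psi)
  }
  set.seed(2)
  th <- runif(4, -pi, pi)
  ps <- vapply(1:4, function(i) {
    tp <- th; tp[i] <- tp[i] + pi / 2
    tm <- th; tm[i] <- tm[i] - pi / 2
    (efun(tp) - efun(tm)) / 2
  }, 0)
  h <- 1e-5
  fd <- vapply(1:4, function(i) {
    tp <- th; tp[i] <- tp[i] + h
    tm <- th; tm[i] <- tm[i] - h
    (efun(tp) - efun(tm)) / (2 * h)
  }, 0)
  expect_equal(ps, fd, tolerance = 1e-7)
})

test_that("sampled expectations are unbiased with shot-noise scaling", {
  ah <- random_active_integrals(2, 2, seed = 5)
  qh <- parity_transform(ah)
  fit <- suppressWarnings(vqe(qh, restarts = 2))
  grouping <- group_commuting(qh)
  sds <- vapply(c(8192, 16 * 8192), function(K) {
    vals <- vapply(1:30, function(r) {
      energy_expectation(qh, fit$statevector,
                         measurement_plan(K, seed = r), grouping)$value
    }, 0)
    sd(vals)
  }, 0)
  # std shrinks as K^{-1/2}: factor 4 within 20 percent
  expect_gt(sds[1] / sds[2], 4 * 0.8)
  expect_lt(sds[1] / sds[2], 4 * 1.2)
  # and the sampled mean is consistent with the exact energy
  expect_lt(abs(mean(vapply(1:30, function(r)
    energy_expectation(qh, fit$statevector,
                       measurement_plan(8192, seed = r), grouping)$value, 0)) -
    fit$energy), 5e-3)
})

test_that("reported std_error matches the per-term variance model", {
  # paper-style bound: eps^2 ~ (1/K) sum_j |alpha_j|^2 within a factor 2,
  # checked against the empirical spread of repeated estimates
  for (seed in c(4, 13)) {
    qh <- parity_transform(random_active_integrals(2, 2, seed = seed))
    th <- runif(4, -pi, pi)
    psi <- simulate_state(th, 2, 1)
    K <- 4096
    vals <- vapply(1:40, function(r)
      energy_expectation(qh, psi, measurement_plan(K, seed = r))$value, 0)
    model <- sqrt(sum(qh$terms$coeff^2) / K)
    expect_lt(sd(vals), 2 * model)
    expect_gt(sd(vals), model / 2)
  }
})

test_that("readout mitigation inverts a known confusion model", {
  # identity confusion: histogram unchanged
  ro_id <- readout_confusion(2, 0)
  counts <- c(10, 20, 30, 40)
  expect_equal(readout_mitigate(counts, ro_id), counts / 100)
  # known symmetric 2 percent flips, mitigated vs unmitigated <Z1> estimate
  qh <- .manual_qh(1, "ZI", 2)
  th <- c(0.7, 0.3, 0.4, 0.2)
  psi <- simulate_state(th, 2, 1)
  truth <- energy_expectation(qh, psi)$value
  ro <- readout_confusion(2, 0.02)
  est_mit <- energy_expectation(qh, psi,
                                measurement_plan(8192, ro, TRUE, seed = 1))
  expect_lt(abs(est_mit$value - truth), 2 * max(est_mit$std_error, 1e-3))
  # mitigated estimator has smaller bias than unmitigated over many trials
  vals_mit <- vapply(1:100, function(r) energy_expectation(
    qh, psi, measurement_plan(4096, ro, TRUE, seed = r))$value, 0)
  vals_raw <- vapply(1:100, function(r) energy_expectation(
    qh, psi, measurement_plan(4096, ro, FALSE, seed = r))$value, 0)
  expect_lt(abs(mean(vals_mit) - truth), abs(mean(vals_raw) - truth))
})

test_that("measured RDMs agree with the CI-vector contraction", {
  ah <- random_active_integrals(2, 2, seed = 6)
  cs <- casci(ah)
  fit <- suppressWarnings(vqe(parity_transform(ah), restarts = 4))
  rd <- measure_rdms(fit)
  expect_equal(sum(diag(rd$rdm1)), 2, tolerance = 1e-8)
  expect_equal(rd$rdm1, cs$rdm1, tolerance = 1e-6)
  expect_equal(rd$rdm2, cs$rdm2, tolerance = 1e-6)
  # HF bitstring with no entangling layer is the single-determinant limit
  fit0 <- fit
  fit0$n_layers <- 0
  fit0$theta <- rep(0, 2)
  fit0$statevector <- simulate_state(rep(0, 2), 2, 0, fit$init_bits)
  rd0 <- measure_rdms(fit0)
  expect_equal(rd0$rdm1, diag(c(2, 0)), tolerance = 1e-10)
})

test_that("repeated sampled pipelines aggregate like hardware experiments", {
  ah <- fold_active_space(mol_integrals(h2_geom()), NULL)
  fit <- vqe(parity_transform(ah))
  reps <- simulate(fit, nsim = 4, seed = 2, shots = 8192,
                   readout = readout_confusion(2, 0.02), mitigate = TRUE)
  expect_equal(nrow(reps), 4L)
  ag <- aggregate_repeats(reps$energy)
  expect_lt(abs(ag$mean - fit$energy), 0.02)
  expect_gt(ag$sd, 0)
})
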