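# Analytic nuclear gradients: finite-difference oracle, conservation laws,
# and the VQE force pipeline.

test_that("the force vanishes at the variational equilibrium bond length", {
  ener <- function(r) casci(fold_active_space(mol_integrals(h2_geom(r)),
                                              NULL))$energy
  r_eq <- optimize(ener, c(0.6, 0.9))$minimum
  fc <- casci_forces(mol_integrals(h2_geom(r_eq)), NULL)
  expect_lt(max(abs(fc$total)), 1e-4)
})

test_that("analytic forces match 5-point finite differences", {
  # mixed fixtures: full-active-space and frozen-core, displaced geometries
  fixtures <- list(
    list(geom = h2_geom(0.81), basis = "6-31g", spec = function(i) NULL),
    list(geom = h2_geom(0.68), basis = "sto-3g", spec = function(i) NULL),
    list(geom = water_geom(jitter = 0.02, seed = 1), basis = "sto-3g",
         spec = function(i) active_space(i, 2, 2)),
    list(geom = water_geom(jitter = 0.03, seed = 2), basis = "sto-3g",
         spec = function(i) active_space(i, 2, 2)),
    list(geom = water_geom(jitter = 0.02, seed = 3), basis = "sto-3g",
         spec = function(i) active_space(i, 4, 3))
  )
  probes <- list(c(1, 3), c(2, 3), c(2, 2), c(3, 3), c(1, 2))
  for (k in seq_along(fixtures)) {
    fx <- fixtures[[k]]
    ints <- mol_integrals(fx$geom, fx$basis)
    fc <- casci_forces(ints, fx$spec(ints))
    pr <- probes[[k]]
    a <- min(pr[1], nrow(fx$geom$coords)); d <- pr[2]
    fd <- fd_casci_force(fx$geom, fx$basis, fx$spec, a, d)
    expect_lt(abs(fc$total[a, d] - fd), 1e-4)
    # conservation: net force and net torque vanish for isolated molecules
    expect_lt(max(abs(colSums(fc$total))), 1e-6)
    xyz <- fx$geom$coords / 0.529177210903
    torque <- colSums(cbind(
      xyz[, 2] * fc$total[, 3] - xyz[, 3] * fc$total[, 2],
      xyz[, 3] * fc$total[, 1] - xyz[, 1] * fc$total[, 3],
      xyz[, 1] * fc$total[, 2] - xyz[, 2] * fc$total[, 1]))
    expect_lt(max(abs(torque)), 1e-5)
  }
})

test_that("the decomposition sums to the total force", {
  ints <- mol_integrals(water_geom(jitter = 0.02, seed = 5))
  fc <- casci_forces(ints, active_space(ints, 2, 2))
  expect_equal(fc$total,
               fc$f_nuc + fc$f_elec + fc$f_density + fc$f_integral)
  expect_true(all(is.finite(fc$total)))
})

test_that("exact-mode VQE forces equal CASCI forces", {
  ints <- mol_integrals(water_geom(jitter = 0.02, seed = 4))
  spec <- active_space(ints, 2, 2)
  fc <- casci_forces(ints, spec)
  fv <- suppressWarnings(forces_from_vqe(ints, spec, restarts = 3))
  expect_lt(max(abs(fv$total - fc$total)), 1e-6)
})

test_that("sampled-RDM force noise shrinks as K^{-1/2}", {
  ints <- mol_integrals(h2_geom(0.8))
  spec <- NULL
  ah <- fold_active_space(ints, spec)
  fit <- vqe(parity_transform(ah))
  comp <- function(K, r) {
    rd <- measure_rdms(fit, measurement_plan(K, seed = r))
    assemble_forces(force_inputs(ints, spec, rd$rdm1, rd$rdm2))$total[2, 3]
  }
  f_lo <- vapply(1:25, function(r) comp(2048, r), 0)
  f_hi <- vapply(1:25, function(r) comp(16 * 2048, r), 0)
  ratio <- sd(f_lo) / sd(f_hi)
  expect_gt(ratio, 4 * 0.55)
  expect_lt(ratio, 4 * 1.8)
})
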