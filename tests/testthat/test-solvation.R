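# Conductor-like continuum solvation: Born closed form, dielectric limits,
# density interface, and the single-pass quantum-classical coupling.

born_config <- function(eps, R_bohr) {
  solvent_config(epsilon = eps, radii = c(H = R_bohr * 0.529177210903),
                 radii_scale = 1)
}
unit_charge <- data.frame(x = 0, y = 0, z = 0, q = 1)
h_center <- geometry("H", matrix(0, 1, 3))

test_that("a centered charge reproduces the conductor Born energy within 1%", {
  for (R in c(1.5, 2, 3)) {
    sr <- solve_reaction_field(h_center, born_config(1e8, R),
                               solute_charges = unit_charge)
    expect_lt(abs(sr$e_solv - (-1 / (2 * R))) / (1 / (2 * R)), 0.01)
  }
})

test_that("the vacuum limit switches the reaction field off", {
  sr <- solve_reaction_field(h_center, born_config(1 + 1e-9, 2),
                             solute_charges = unit_charge)
  expect_lt(abs(sr$e_solv), 1e-9)
})

test_that("|E_s| grows monotonically with the permittivity", {
  eps_grid <- c(2, 5, 10, 40, 80, 500)
  es <- vapply(eps_grid, function(e)
    solve_reaction_field(h_center, born_config(e, 2),
                         solute_charges = unit_charge)$e_solv, 0)
  expect_true(all(diff(abs(es)) > 0))
  expect_true(all(es < 0))
})

test_that("the large-eps limit converges to the conductor result", {
  e6 <- solve_reaction_field(h_center, born_config(1e6, 2),
                             solute_charges = unit_charge)$e_solv
  ec <- solve_reaction_field(h_center, born_config(1e12, 2),
                             solute_charges = unit_charge)$e_solv
  expect_lt(abs(e6 / ec - 1), 1e-3)
})

test_that("solvation stabilizes neutral molecules (E_s <= 0)", {
  for (g in list(h2_geom(), water_geom())) {
    ints <- mol_integrals(g)
    sr <- solve_reaction_field(g, solvent_config(), ints = ints)
    expect_lte(sr$e_solv, 0)
  }
})

test_that("the RDM density interface conserves electrons and the HF limit", {
  ints <- mol_integrals(water_geom())
  spec <- active_space(ints, 2, 2)
  # HF-state active density: doubly occupied HOMO
  D_hf <- density_from_rdm(diag(c(2, 0)), ints, spec)
  expect_equal(D_hf, ints$ao$D_hf, tolerance = 1e-10)
  cs <- casci(fold_active_space(ints, spec))
  D <- density_from_rdm(cs$rdm1, ints, spec)
  expect_equal(sum(D * ints$ao_overlap), ints$n_elec, tolerance = 1e-8)
  expect_error(density_from_rdm(diag(c(1.5, 0)), ints, spec), "trace")
})

test_that("the solvated mean field lowers the energy of polar molecules", {
  mf <- solvated_scf(water_geom())
  gas <- mol_integrals(water_geom())
  expect_lt(mf$e_total, gas$e_hf)
  expect_lt(mf$solvation$e_solv, 0)
})

test_that("single-pass and iterated solvation agree below shot noise", {
  sp <- solvated_energy_single_pass(water_geom(), engine = "casci")
  it <- solvated_energy_single_pass(water_geom(), engine = "casci",
                                    iterate = TRUE)
  # 8192-shot sampling std for these Hamiltonians is of order 3e-3 Hartree
  expect_lt(abs(sp$e_total - it$e_total), 3e-3)
  expect_gt(it$iterations, 1)
})

test_that("CASCI and exact-mode VQE engines give identical solvated energies", {
  sp_c <- solvated_energy_single_pass(water_geom(), engine = "casci")
  sp_v <- solvated_energy_single_pass(water_geom(), engine = "vqe",
                                      restarts = 2)
  expect_equal(sp_v$e_total, sp_c$e_total, tolerance = 1e-6)
})

test_that("switching the solvent off recovers the gas phase exactly", {
  gas <- gas_phase_energy(water_geom(), engine = "casci")
  near_vac <- solvated_energy_single_pass(
    water_geom(), engine = "casci",
    config = solvent_config(epsilon = 1 + 1e-12))
  expect_equal(near_vac$e_total, gas$e_total, tolerance = 1e-9)
})
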