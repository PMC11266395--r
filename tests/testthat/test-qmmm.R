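# Electrostatic embedding, the BAOAB Langevin integrator, hybrid-engine
# trajectories, and geometry monitoring.

test_that("zero MM charges reproduce the gas phase exactly", {
  g <- h2_geom()
  mm0 <- mm_environment(data.frame(x = c(4, -4), y = 0, z = 0, q = c(0, 0)))
  ints0 <- embed_point_charges(g, mm0)
  gas <- mol_integrals(g)
  expect_equal(ints0$e_hf, gas$e_hf, tolerance = 1e-12)
})

test_that("a distant charge sees the monopole qQ/d interaction", {
  # HeH+ carries net charge +1; probe at 50 Bohr perpendicular to the
  # molecular axis so the dipole term vanishes
  g <- geometry(c("He", "H"), rbind(c(0, 0, 0), c(0, 0, 0.9)))
  d_bohr <- 50
  Q <- 0.5
  mm <- mm_environment(data.frame(x = d_bohr * 0.529177210903, y = 0, z = 0,
                                  q = Q))
  e_emb <- embed_point_charges(g, mm, charge = 1)$e_hf
  e_gas <- mol_integrals(g, charge = 1)$e_hf
  e_int <- e_emb - e_gas
  expect_lt(abs(e_int - Q / d_bohr) / (Q / d_bohr), 0.01)
})

test_that("mirror-symmetric charges exert no net transverse force", {
  g <- h2_geom()  # H2 along z
  mm <- mm_environment(data.frame(x = c(3, -3), y = c(0, 0), z = c(0.37, 0.37),
                                  q = c(0.2, 0.2)))
  ints <- embed_point_charges(g, mm)
  cs <- casci(fold_active_space(ints, NULL))
  fd <- assemble_forces(force_inputs(ints, NULL, cs$rdm1, cs$rdm2))
  # x-forces on the two H atoms cancel by symmetry
  expect_lt(abs(sum(fd$total[, 1])), 1e-8)
  expect_lt(abs(sum(fd$total[, 2])), 1e-8)
})

test_that("QM and MM forces balance for the embedded system", {
  sys <- toy_solvated_system("H2", bath_size = 6, seed = 9)
  ints <- embed_point_charges(sys$geom, sys$mm)
  cs <- casci(fold_active_space(ints, NULL))
  fd <- assemble_forces(force_inputs(ints, NULL, cs$rdm1, cs$rdm2))
  net <- colSums(fd$total) + colSums(fd$mm_forces)
  expect_lt(max(abs(net)), 1e-6)
  # MM electrostatic force against finite differences of the total energy
  ener <- function(dz) {
    mm2 <- sys$mm
    mm2$charges$z[1] <- mm2$charges$z[1] + dz * 0.529177210903
    casci(fold_active_space(embed_point_charges(sys$geom, mm2), NULL))$energy
  }
  h <- 1e-3
  fd_mm <- -(ener(h) - ener(-h)) / (2 * h)
  expect_lt(abs(fd$mm_forces[1, 3] - fd_mm), 1e-6)
})

test_that("the symplectic limit conserves energy for a harmonic oscillator", {
  # gamma = 0, T = 0: BAOAB reduces to velocity Verlet, whose energy error
  # stays bounded (no secular drift) over long runs
  k <- 0.01; m <- 18 * 1822.888486209
  force_fn <- function(x) {
    f <- -k * x
    attr(f, "energy") <- 0.5 * k * sum(x^2)
    f
  }
  cfg <- integrator_config(timestep_fs = 0.5, temperature_K = 0,
                           friction_ps = 0)
  state <- list(x = matrix(c(0.3, 0, 0), 1, 3), v = matrix(0, 1, 3),
                m = matrix(m, 1, 3))
  state$f <- force_fn(state$x)
  e0 <- 0.5 * k * sum(state$x^2)
  etot <- numeric(10000)
  for (s in seq_along(etot)) {
    state <- langevin_step(state, force_fn, cfg)
    etot[s] <- attr(state$f, "energy") + 0.5 * sum(state$m * state$v^2)
  }
  drift <- abs(mean(tail(etot, 500)) - mean(head(etot, 500))) / e0
  expect_lt(drift, 1e-5)
  expect_lt((max(etot) - min(etot)) / e0, 1e-4)  # bounded fluctuation
})

test_that("the thermostat equilibrates to equipartition", {
  k <- 0.2; m <- 18 * 1822.888486209
  Tset <- 300
  force_fn <- function(x) -k * x
  cfg <- integrator_config(timestep_fs = 2, temperature_K = Tset,
                           friction_ps = 10, seed = 4)
  set.seed(cfg$seed)
  state <- list(x = matrix(0, 1, 3), v = matrix(0, 1, 3),
                m = matrix(m, 1, 3))
  state$f <- force_fn(state$x)
  ke <- numeric(100000)
  for (s in seq_along(ke)) {
    state <- langevin_step(state, force_fn, cfg)
    ke[s] <- 0.5 * sum(state$m * state$v^2)
  }
  ke_dof <- mean(ke[-(1:5000)]) / 3
  expect_lt(abs(ke_dof - 0.5 * 3.166811563e-6 * Tset) /
            (0.5 * 3.166811563e-6 * Tset), 0.03)
  # and the positional variance matches kT / k_spring within 10 percent
  xs <- numeric(100000)
  set.seed(11)
  for (s in seq_along(xs)) {
    state <- langevin_step(state, force_fn, cfg)
    xs[s] <- state$x[1, 1]
  }
  expect_lt(abs(var(xs[-(1:5000)]) - 3.166811563e-6 * Tset / k) /
            (3.166811563e-6 * Tset / k), 0.1)
})

test_that("zero forces with no friction give uniform linear motion", {
  force_fn <- function(x) matrix(0, nrow(x), 3)
  cfg <- integrator_config(timestep_fs = 1, temperature_K = 0, friction_ps = 0)
  state <- list(x = matrix(0, 2, 3), v = matrix(1e-4, 2, 3),
                m = matrix(1822.9, 2, 3), f = matrix(0, 2, 3))
  for (s in 1:100) state <- langevin_step(state, force_fn, cfg)
  expect_equal(state$x, matrix(100 * cfg$dt * 1e-4, 2, 3), tolerance = 1e-12)
  expect_equal(state$v, matrix(1e-4, 2, 3))
})

test_that("exact-mode quantum and classical engines give identical trajectories", {
  sys <- toy_solvated_system("H2", bath_size = 8, seed = 3)
  system <- list(geom = sys$geom, mm = sys$mm,
                 engines = list(
                   classical = qm_engine("casci", active = c(2, 2)),
                   quantum = qm_engine("vqe-exact", active = c(2, 2),
                                       restarts = 0)))
  cfg <- integrator_config(0.5, 300, 1, seed = 5)
  tr_c <- run_hybrid_trajectory(system, "classical", 15, cfg)
  tr_q <- run_hybrid_trajectory(system, "quantum", 15, cfg)
  expect_lt(max(abs(tr_c$coords - tr_q$coords)), 1e-8)
  # mid-trajectory engine hand-off leaves the trajectory unchanged
  sched <- c(rep("classical", 5), rep("quantum", 5), rep("classical", 5))
  tr_h <- run_hybrid_trajectory(system, sched, 15, cfg)
  expect_lt(max(abs(tr_c$coords - tr_h$coords)), 1e-8)
})

test_that("sampled-engine segments stay within the statistical envelope", {
  sys <- toy_solvated_system("H2", bath_size = 6, seed = 13)
  plan <- measurement_plan(shots = 8192, seed = 0)
  system <- list(geom = sys$geom, mm = sys$mm,
                 engines = list(
                   classical = qm_engine("casci", active = c(2, 2)),
                   sampled = qm_engine("vqe-sampled", active = c(2, 2),
                                       plan = plan, restarts = 0)))
  cfg <- integrator_config(0.5, 300, 1, seed = 2)
  n <- 14
  sched <- c(rep("classical", 5), rep("sampled", 4), rep("classical", 5))
  tr_c <- run_hybrid_trajectory(system, "classical", n, cfg)
  tr_h <- run_hybrid_trajectory(system, sched, n, cfg)
  # shot noise on a (2e,2o) energy at 8192 shots is ~3e-3 Hartree ~ 2 kcal/mol
  sigma_kcal <- 3e-3 * 627.5095
  dev <- abs(tr_h$record$etot_kcal - tr_c$record$etot_kcal)
  expect_lt(max(dev), 3 * sigma_kcal)
  expect_equal(tr_h$record$engine, sched)
})

test_that("trajectory bookkeeping and geometry monitors behave", {
  expect_equal(nrow(run_hybrid_trajectory(
    list(geom = h2_geom(), mm = mm_environment(NULL),
         engines = list(classical = qm_engine("casci"))),
    "classical", 0)$record), 0L)
  # frozen geometry: zero spread, mean equals the constant
  fake <- structure(list(coords = array(rep(rbind(c(0, 0, 0), c(0, 0, 0.74)),
                                            each = 1),
                                        c(5, 2, 3))), class = "trajectory_record")
  for (s in 1:5) fake$coords[s, , ] <- rbind(c(0, 0, 0), c(0, 0, 0.74))
  mon <- monitor_geometry(fake, bonds = list(c(1, 2)))
  expect_equal(mon$bond_1_2$sd, 0)
  expect_equal(mon$bond_1_2$mean, 0.74)
  expect_error(monitor_geometry(fake, bonds = list(c(1, 7))), "invalid")
})

test_that("kinetic energy is non-negative and records are complete", {
  sys <- toy_solvated_system("H2", bath_size = 4, seed = 21)
  system <- list(geom = sys$geom, mm = sys$mm,
                 engines = list(classical = qm_engine("casci", active = c(2, 2))))
  tr <- run_hybrid_trajectory(system, "classical", 10,
                              integrator_config(0.5, 300, 2, seed = 1))
  expect_equal(nrow(tr$record), 10L)
  expect_true(all(tr$record$ekin_kcal >= 0))
  expect_true(all(is.finite(tr$record$etot_kcal)))
})
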