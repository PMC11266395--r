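# Gibbs-profile assembly from the packaged per-species energy table,
# repeat aggregation, and spontaneity classification.

test_that("repeat aggregation gives the sample mean and sd", {
  ag <- aggregate_repeats(c(-1221.240, -1221.243, -1221.227, -1221.242))
  expect_equal(ag$mean, -1221.238, tolerance = 1e-10)
  expect_equal(aggregate_repeats(c(2, 2, 2))$sd, 0)
  expect_equal(aggregate_repeats(c(5 - 0.3, 5 + 0.3))$mean, 5)
  expect_error(aggregate_repeats(numeric(0)))
})

test_that("the deterministic profile entries reproduce the published table", {
  prof <- function(m, s) assemble_profile(prodrug_species(m, s), "4", "TS",
                                          c("5", "6", "H2O"))
  hf_w <- prof("HF", "with")
  expect_equal(round(hf_w$dG_barrier, 1), 13.1)
  expect_equal(round(hf_w$dG_reaction, 1), -41.1)
  ca_w <- prof("CASCI", "with")
  expect_equal(round(ca_w$dG_barrier, 1), 11.8)
  expect_equal(round(ca_w$dG_reaction, 1), -49.5)
  hf_o <- prof("HF", "without")
  expect_equal(round(hf_o$dG_barrier, 1), 2.6)
  expect_equal(round(hf_o$dG_reaction, 1), -59.3)
  ca_o <- prof("CASCI", "without")
  # printed per-species precision limits this entry: 1.3 vs the published 1.4
  expect_lt(abs(ca_o$dG_barrier - 1.4), 0.1 + 1e-9)
  expect_equal(round(ca_o$dG_reaction, 1), -68.0)
})

test_that("VQE repeats propagate into the published uncertainty", {
  pv <- assemble_profile(prodrug_species("VQE", "with"), "4", "TS",
                         c("5", "6", "H2O"))
  expect_equal(round(pv$dG_barrier), 7)
  expect_equal(round(pv$dG_barrier_sd), 5)
  expect_equal(round(pv$dG_reaction), -51)
  cls <- classify_spontaneity(pv)
  expect_true(cls$accessible)   # < 20 kcal/mol: biologically accessible
  expect_true(cls$favorable)
})

test_that("trivial and boundary profiles behave as defined", {
  sp <- list(species_energy("A", -10), species_energy("Ats", -10),
             species_energy("B", -10.1))
  p0 <- assemble_profile(sp, "A", "Ats", "B")
  expect_equal(p0$dG_barrier, 0)
  # a barrier of exactly 20 kcal/mol is not accessible (strict inequality)
  sp20 <- list(species_energy("A", 0), species_energy("Ats", 20 / 627.5095),
               species_energy("B", -1))
  expect_false(classify_spontaneity(assemble_profile(sp20, "A", "Ats", "B"))$accessible)
  # negative barrier flags as non-physical
  spn <- list(species_energy("A", 0), species_energy("Ats", -0.01),
              species_energy("B", -1))
  expect_warning(cl <- classify_spontaneity(assemble_profile(spn, "A", "Ats", "B")),
                 "non-physical")
  expect_true(cl$nonphysical_barrier)
})

test_that("unit conversion round-trips exactly", {
  x <- c(-51.234, 0, 13.1)
  expect_equal(kcal_to_hartree(hartree_to_kcal(x)), x, tolerance = 1e-12)
})

test_that("stoichiometry mass balance is enforced when formulas are given", {
  sp <- list(species_energy("A", -1, formula = "C2H6O"),
             species_energy("Ats", -0.99, formula = "C2H6O"),
             species_energy("B", -0.5, formula = "C2H4"),
             species_energy("W", -0.6, formula = "H2O"),
             species_energy("X", -0.6, formula = "CH4"))
  expect_s3_class(assemble_profile(sp, "A", "Ats", c("B", "W")),
                  "reaction_profile")
  expect_error(assemble_profile(sp, "A", "Ats", c("B", "X")), "mass-balanced")
  expect_error(assemble_profile(sp, "A", "Ats", "missing"), "missing")
})

test_that("species tables round-trip through CSV", {
  df <- data.frame(label = c("A", "B", "B", "B"),
                   energy = c(-1.0, -2.0, -2.01, -1.99),
                   gibbs_correction = c(0.01, 0, 0, 0))
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  sp <- read_species_csv(path)
  labs <- vapply(sp, `[[`, "", "label")
  expect_setequal(labs, c("A", "B"))
  b <- sp[[which(labs == "B")]]
  expect_equal(sort(b$repeats), sort(c(-2.0, -2.01, -1.99)))
  a <- sp[[which(labs == "A")]]
  expect_equal(a$energy, -1.0)
  expect_equal(a$gibbs_correction, 0.01)
})
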