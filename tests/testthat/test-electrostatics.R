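# reference electrolyte: the solution conditions used throughout (20 mM 1:1
# ions, eps 78, 300 K) with the screening length pinned at 2.1508 nm
ref_solvent <- electrolyte(78, 300, 0.020, kappa = 1 / 2.1508)
ref_particle <- patchy_particle(-16, 1200, 4.0)

test_that("Debye screening length matches the closed form and its scaling", {
  expect_equal(1 / debye_kappa(electrolyte(78, 300, 0.020)), 2.1508,
               tolerance = 1e-4)
  expect_equal(debye_kappa(electrolyte(78, 300, 0)), 0)  # unscreened limit
  # quadrupling I halves the screening length
  expect_equal(1 / debye_kappa(electrolyte(78, 300, 0.080)),
               0.5 / debye_kappa(electrolyte(78, 300, 0.020)),
               tolerance = 1e-12)
  # independent evaluation of the formula
  cst <- patchylat_constants()
  kap <- sqrt(2 * cst$e_C^2 * cst$N_A * 20 /
                (cst$eps0_F_m * 78 * cst$k_B * 300)) * 1e-9
  expect_equal(debye_kappa(electrolyte(78, 300, 0.020)), kap,
               tolerance = 1e-12)
})

test_that("boundary factors C0, C1 match limits and direct evaluation", {
  # kappa a = 0: C0 = 1 and C1 = 3 / (2 + 1/eps) from the C1 expression
  free <- electrolyte(78, 300, 0)
  gf0 <- geometry_factors(free, ref_particle)
  expect_equal(unname(gf0["C0"]), 1)
  expect_equal(unname(gf0["C1"]), 3 / (2 + 1 / 78), tolerance = 1e-12)
  # eps -> infinity with kappa a = 0: C1 -> 3/2
  gf_inf <- geometry_factors(electrolyte(1e12, 300, 0), ref_particle)
  expect_equal(unname(gf_inf["C1"]), 1.5, tolerance = 1e-9)
  # direct evaluation at kappa a = 4 / 2.1508
  gf <- geometry_factors(ref_solvent, ref_particle)
  ka <- 4 / 2.1508
  expect_equal(unname(gf["C0"]), exp(ka) / (1 + ka), tolerance = 1e-12)
  expect_equal(unname(gf["C1"]),
               3 * exp(ka) / (2 + 2 * ka + ka^2 + (1 + ka) / 78),
               tolerance = 1e-12)
  expect_equal(unname(gf), c(2.2457, 2.0908), tolerance = 1e-4)
})

test_that("full potential reduces exactly to the in-plane form at theta 90", {
  set.seed(11)
  for (k in 1:1000) {
    particle <- patchy_particle(charge = runif(1, -40, 40),
                                dipole = runif(1, 0, 4000),
                                radius = runif(1, 1, 8))
    solvent <- electrolyte(runif(1, 2, 120), runif(1, 250, 370),
                           runif(1, 0, 0.5))
    r <- runif(1, 2, 20)
    dphi <- runif(1, -360, 360)
    full <- pair_energy_full(r, 90, 90, dphi, particle, solvent = solvent)
    red <- pair_energy_reduced(r, dphi, particle, solvent)
    expect_lt(abs(full - red), 1e-12 * max(abs(red), 1e-300))
  }
})

test_that("term structure: charge-only, vanishing dipolar coupling, parity", {
  solvent <- ref_solvent
  # mu = 0: only the screened Coulomb term survives; repulsive for like
  # charges
  mono <- patchy_particle(-16, 0, 4)
  U <- pair_energy_reduced(8, 0, mono, solvent)
  expect_gt(U, 0)
  expect_equal(pair_energy_reduced(8, 180, mono, solvent), U)
  # dphi = 90 at theta = 90: the dipole-dipole term vanishes entirely
  expect_equal(pair_energy_full(8, 90, 90, 90, ref_particle,
                                solvent = solvent),
               U, tolerance = 1e-12)
  expect_equal(pair_energy_reduced(8, 90, ref_particle, solvent), U,
               tolerance = 1e-12)
  # unscreened charge term -> bare Coulomb k_e q^2 / r
  cst <- patchylat_constants()
  bare <- pair_energy_reduced(8, 0, mono, electrolyte(78, 300, 0))
  ke <- 1 / (4 * pi * cst$eps0_F_m * 78)
  expect_equal(bare,
               ke * (16 * cst$e_C)^2 / 8e-9 * cst$N_A / cst$kcal_J,
               tolerance = 1e-12)
})

test_that("energies scale as q^2 (charge term) and mu^2 (dipolar term)", {
  s <- ref_solvent
  q2 <- patchy_particle(-32, 0, 4)
  q1 <- patchy_particle(-16, 0, 4)
  expect_equal(pair_energy_reduced(7, 0, q2, s),
               4 * pair_energy_reduced(7, 0, q1, s), tolerance = 1e-12)
  m2 <- patchy_particle(0, 2400, 4)
  m1 <- patchy_particle(0, 1200, 4)
  expect_equal(pair_energy_reduced(7, 60, m2, s),
               4 * pair_energy_reduced(7, 60, m1, s), tolerance = 1e-12)
  # the parallel-antiparallel difference is independent of q
  d_a <- pair_energy_reduced(7, 0, ref_particle, s) -
    pair_energy_reduced(7, 180, ref_particle, s)
  d_b <- pair_energy_reduced(7, 0, patchy_particle(5, 1200, 4), s) -
    pair_energy_reduced(7, 180, patchy_particle(5, 1200, 4), s)
  expect_equal(d_a, d_b, tolerance = 1e-12)
})

test_that("unit reporting: kcal/mol vs kBT vs joules", {
  s <- electrolyte(78, 300, 0.020)
  U_kcal <- pair_energy_reduced(7, 0, ref_particle, s)
  U_kBT <- pair_energy_reduced(7, 0, ref_particle, s, units = "kBT")
  U_J <- pair_energy_reduced(7, 0, ref_particle, s, units = "J")
  expect_equal(U_kcal / U_kBT, 0.59616, tolerance = 1e-4)  # 1 kBT at 300 K
  cst <- patchylat_constants()
  expect_equal(U_J * cst$N_A / cst$kcal_J, U_kcal, tolerance = 1e-12)
})

test_that("dihedral landscape is a funnel towards antiparallel packing", {
  ls <- dihedral_landscape(seq(7, 10, 0.5), seq(0, 180, 5),
                           ref_particle, ref_solvent)
  # argmin over dphi is 180 for every r; strictly decreasing on (0, 180)
  for (i in seq_along(ls$r)) {
    expect_equal(which.min(ls$energy[i, ]), length(ls$dphi))
    expect_true(all(diff(ls$energy[i, ]) < 0))
  }
  # the spread across dphi shrinks monotonically with r
  spread <- ls$energy[, 1] - ls$energy[, ncol(ls$energy)]
  expect_true(all(diff(spread) < 0))
  expect_true(all(spread > 0))
  # symmetry under dphi -> -dphi
  ls2 <- dihedral_landscape(8, c(-45, 45), ref_particle, ref_solvent)
  expect_equal(ls2$energy[1, 1], ls2$energy[1, 2], tolerance = 1e-15)
  # long format table
  df <- as.data.frame(ls)
  expect_named(df, c("r", "dphi", "U_kcal", "U_kBT"))
  expect_equal(nrow(df), length(ls$r) * length(ls$dphi))
  expect_error(dihedral_landscape(numeric(0), 1:3), "non-empty")
})
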