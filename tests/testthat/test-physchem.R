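test_that("overpotential is E_appl minus the O2/H2O standard potential", {
  expect_equal(overpotential(1.23, window = NULL), 0)
  expect_equal(overpotential(0.5), -0.73)
  expect_equal(overpotential(0.2), -1.03)
  expect_error(overpotential(0.1), "window")
  expect_error(overpotential(0.7), "window")
})

test_that("Tafel channel current is linear in [O2], cathodic, and matches the closed form", {
  pc <- phys_constants()
  ch <- catalyst_kinetics("pt")$channels[[1]]
  # unity exponential and concentration factors at eta = 0, c = C_bulk
  expect_equal(channel_current_density(ch, 0, pc$C_O2_bulk, pc), -ch$i0)
  # no reactant, no current
  expect_equal(channel_current_density(ch, -0.73, 0, pc), 0)
  # closed form evaluated independently: i0 * exp(0.5 * F * 0.73 / (R T))
  expect_equal(abs(channel_current_density(ch, -0.73, pc$C_O2_bulk, pc)),
               4.435048, tolerance = 1e-6)
  # linearity in concentration
  i1 <- channel_current_density(ch, -0.5, 0.1, pc)
  i2 <- channel_current_density(ch, -0.5, 0.2, pc)
  expect_equal(i2, 2 * i1)
  # cathodic for any non-negative concentration
  expect_true(all(channel_current_density(ch, -0.73, c(0, 0.1, 0.246), pc) <= 0))
  expect_error(channel_current_density(ch, -0.5, -0.1, pc), "non-physical")
})

test_that("surface fluxes respect sign conventions and stoichiometric bookkeeping", {
  pc <- phys_constants()
  pt <- catalyst_kinetics("pt")
  au <- catalyst_kinetics("au")
  # no reactant -> no fluxes
  expect_equal(surface_fluxes(au, -0.73, 0, pc), list(J_O2 = 0, J_H2O2 = 0))
  # Pt produces no H2O2 at any potential
  for (eta in c(-0.63, -0.73, -1.03))
    expect_identical(surface_fluxes(pt, eta, 0.2, pc)$J_H2O2, 0)
  # Au: consumption negative, production positive
  fx <- surface_fluxes(au, -0.73, 0.2, pc)
  expect_lt(fx$J_O2, 0)
  expect_gt(fx$J_H2O2, 0)
  # electron conservation: F * (4 |J_4e| + 2 |J_2e|) = |i_4e| + |i_2e|,
  # checked via independent per-channel evaluation
  i4 <- channel_current_density(au$channels[[1]], -0.73, 0.2, pc)
  i2 <- channel_current_density(au$channels[[2]], -0.73, 0.2, pc)
  expect_equal(fx$J_O2, i4 / (4 * pc$F) + i2 / (2 * pc$F))
  expect_equal(fx$J_H2O2, -i2 / (2 * pc$F))
  expect_equal(pc$F * (4 * abs(i4 / (4 * pc$F)) + 2 * abs(i2 / (2 * pc$F))),
               abs(i4) + abs(i2))
})

test_that("|J_O2| increases strictly as the potential becomes more reductive", {
  pc <- phys_constants()
  for (cat in c("pt", "au")) {
    kin <- catalyst_kinetics(cat)
    J <- vapply(seq(0.6, 0.2, by = -0.1),
                function(E) abs(surface_fluxes(kin, overpotential(E), 0.2, pc)$J_O2),
                numeric(1))
    expect_true(all(diff(J) > 0))
  }
})

test_that("effective rate constants reproduce the fluxes exactly", {
  pc <- phys_constants()
  pt <- catalyst_kinetics("pt")
  au <- catalyst_kinetics("au")
  expect_identical(effective_rate_constants(pt, -0.73, pc)$k_gen, 0)
  # algebraic identity on random (eta, c) pairs
  set.seed(42)
  for (i in 1:100) {
    eta <- runif(1, -1.03, -0.63)
    cc <- runif(1, 0, 0.246)
    ks <- effective_rate_constants(au, eta, pc)
    fx <- surface_fluxes(au, eta, cc, pc)
    expect_equal(-ks$k_O2 * cc, fx$J_O2, tolerance = 1e-12)
    expect_equal(ks$k_gen * cc, fx$J_H2O2, tolerance = 1e-12)
  }
  # 2e- current share at eta = -0.73 recomputed from per-channel currents
  ks <- effective_rate_constants(au, -0.73, pc)
  expect_equal(ks$k_gen / ks$k_O2, 0.52998787, tolerance = 1e-7)
})

test_that("catalyst kinetics round-trip through JSON and enforce invariants", {
  au <- catalyst_kinetics("au")
  tmp <- tempfile(fileext = ".json")
  write_catalyst_json(au, tmp)
  au2 <- read_catalyst_json(tmp)
  expect_equal(au2$dD, 50)
  expect_equal(au2$channels[[2]]$i0, 8e-7)
  expect_equal(au2$channels[[2]]$n_rds, 0.7)
  expect_error(orr_channel(-1, 1, 4), "i0")
  expect_error(orr_channel(1e-6, 1, 3))
  expect_error(phys_constants(T_K = -5), "positive")
})
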