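pc <- phys_constants()

test_that("inert electrode propagates the bulk O2 concentration everywhere", {
  inert <- structure(list(name = "inert",
                          channels = list(orr_channel(0, 1, 4)), dD = 20),
                     class = "catalyst_kinetics")
  g <- build_grid(morphology(15, 4, 50), inert)
  f <- solve_o2(g, inert, 0.5)
  expect_equal(f$values, rep(0.246, g$n), tolerance = 1e-12)
  prof <- extract_profile(f)
  expect_equal(prof$values, rep(0.246, 20), tolerance = 1e-12)
})

test_that("solver reproduces the 1D planar closed form", {
  # flat active plane at z = 0 under a Dirichlet plane at z = dD:
  # c(0) = C_bulk D / (D + k dD), linear in between
  kin <- catalyst_kinetics("pt")
  ks <- effective_rate_constants(kin, overpotential(0.5), pc)
  g <- planar_reference_grid(20, 60)
  f <- solve_o2(g, kin, 0.5, pc)
  c_surf <- pc$C_O2_bulk * pc$D_O2 / (pc$D_O2 + ks$k_O2 * 20e-6)
  analytic <- c_surf + (pc$C_O2_bulk - c_surf) * g$layer_z / 20
  expect_lt(max(abs(f$values - analytic) / analytic), 0.005)
})

test_that("O2 field obeys the discrete maximum principle and H2O2 is non-negative", {
  set.seed(7)
  cond <- sample_conditions(50, seed = 7)
  for (i in seq_len(nrow(cond))) {
    cat_name <- if (i %% 2 == 0) "pt" else "au"
    kin <- catalyst_kinetics(cat_name)
    g <- build_grid(morphology(cond$P[i], cond$D[i], cond$L[i]), kin)
    fo <- solve_o2(g, kin, cond$E_appl[i])
    expect_true(all(fo$values >= -1e-12))
    expect_true(all(fo$values <= 0.246 + 1e-12))
    fh <- solve_h2o2(g, kin, cond$E_appl[i], fo)
    expect_true(all(fh$values >= -1e-12))
  }
})

test_that("steady-state fluxes balance within 0.5 percent", {
  for (k in list(c(15, 4, 50), c(46, 6, 20), c(60, 8, 100))) {
    au <- catalyst_kinetics("au")
    g <- build_grid(morphology(k[1], k[2], k[3]), au)
    fo <- solve_o2(g, au, 0.3)
    fb <- flux_balance(fo)
    expect_lt(fb$rel_imbalance, 0.005)
    fh <- solve_h2o2(g, au, 0.3, fo)
    hb <- h2o2_flux_balance(fh, fo)
    expect_lt(hb$rel_imbalance, 0.005)
  }
})

test_that("Pt yields an identically zero H2O2 field", {
  pt <- catalyst_kinetics("pt")
  g <- build_grid(morphology(15, 4, 50), pt)
  fo <- solve_o2(g, pt, 0.5)
  fh <- solve_h2o2(g, pt, 0.5, fo)
  expect_identical(fh$values, numeric(g$n))
})

test_that("H2O2 field scales with the 2e- Tafel exponential in the weak-depletion limit", {
  # sparse short array on Au: negligible O2 depletion, so lowering E_appl
  # by 0.05 V multiplies the field by exp(0.5 F 0.05 * 0.7 / (R T))
  au <- catalyst_kinetics("au")
  g <- build_grid(morphology(80, 1, 5), au)
  f1o <- solve_o2(g, au, 0.55)
  f1h <- solve_h2o2(g, au, 0.55, f1o)
  f2o <- solve_o2(g, au, 0.5)
  f2h <- solve_h2o2(g, au, 0.5, f2o)
  ratio <- f2h$values / f1h$values
  expect_equal(mean(ratio), 1.97611052, tolerance = 0.01)
})

test_that("grid mismatch between the O2 field and the H2O2 solve is caught", {
  au <- catalyst_kinetics("au")
  g1 <- build_grid(morphology(15, 4, 50), au)
  g2 <- build_grid(morphology(17, 3, 30), au)
  fo <- solve_o2(g1, au, 0.5)
  expect_error(solve_h2o2(g2, au, 0.5, fo), "different grid")
})

test_that("lateral averaging is the area-weighted mean", {
  # 2-cell toy cross-section, areas (1, 3), values (0.1, 0.2) -> 0.175
  expect_equal(gradientforge:::.area_weighted_mean(c(0.1, 0.2), c(1, 3)), 0.175)
})

test_that("extracted profiles follow the 20-point ladder and its invariants", {
  au <- catalyst_kinetics("au")
  sim <- simulate_gradients(c(17, 3, 30), "au", 0.45)
  for (p in list(sim$o2, sim$h2o2)) {
    expect_length(p$values, 20)
    expect_equal(p$z, seq(5, 100, 5))
  }
  # O2 non-decreasing in z; H2O2 non-increasing above the wire top
  expect_true(all(diff(sim$o2$values) >= -1e-9))
  above <- sim$h2o2$z >= 30
  expect_true(all(diff(sim$h2o2$values[above]) <= 1e-9))
  # heights at or above z_bulk report the Dirichlet values
  expect_equal(sim$o2$values[sim$o2$z >= 80], rep(0.246, sum(sim$o2$z >= 80)))
  expect_equal(sim$h2o2$values[sim$h2o2$z >= 80], rep(0, sum(sim$h2o2$z >= 80)))
})

test_that("simulate_gradients is deterministic", {
  a <- simulate_gradients(c(30, 3, 50), "pt", 0.5)
  b <- simulate_gradients(c(30, 3, 50), "pt", 0.5)
  expect_identical(a$o2$values, b$o2$values)
})

test_that("depletion deepens monotonically at lower applied potential", {
  E <- c(0.6, 0.5, 0.4, 0.3, 0.2)
  profs <- lapply(E, function(e) simulate_gradients(c(30, 3, 50), "pt", e)$o2$values)
  for (i in seq_len(length(E) - 1))
    expect_true(all(profs[[i + 1]] <= profs[[i]] + 1e-12))
})

test_that("longer wires and denser arrays deepen the base depletion", {
  base <- simulate_gradients(c(30, 3, 50), "pt", 0.5)$o2$values[1]
  longer <- simulate_gradients(c(30, 3, 80), "pt", 0.5)$o2$values[1]
  denser <- simulate_gradients(c(15, 3, 50), "pt", 0.5)$o2$values[1]
  expect_lt(longer, base)
  expect_lt(denser, base)
})

test_that("halving the grid spacing changes the profile by less than 2 percent", {
  p1 <- simulate_gradients(c(15, 4, 50), "pt", 0.5, resolution = 1)$o2$values
  p2 <- simulate_gradients(c(15, 4, 50), "pt", 0.5, resolution = 2)$o2$values
  expect_lt(max(abs(p1 - p2) / p2), 0.02)
})

test_that("axisymmetric and 3D solutions agree on the averaged profile", {
  for (k in list(c(20, 6, 30), c(46, 6, 20))) {
    pa <- simulate_gradients(k, "pt", 0.5, mode = "axisym")$o2$values
    p3 <- simulate_gradients(k, "pt", 0.5, mode = "cartesian3d")$o2$values
    expect_lt(max(abs(pa - p3) / pa), 0.05)
  }
})

test_that("the anoxic worked example: k = (15, 4, 50) Pt at 0.5 V is O2-free at the base", {
  sim <- simulate_gradients(c(15, 4, 50), "pt", 0.5)
  expect_lt(sim$o2$values[1], 0.05)
})
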