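test_that("similarity score identities hold at the anchors", {
  tgt <- target_profile("O2", 0.5, c_mM = c(0.15, 0.16, 0.17, 0.19, 0.21, 0.23, 0.246))
  ladder <- seq(5, 100, 5)
  # exact match scores 1
  exact <- approx(tgt$z, tgt$c, xout = ladder, rule = 2)$y
  expect_equal(similarity_score(exact, tgt), 1)
  # uniform 10% overshoot scores 0.9
  expect_equal(similarity_score(1.1 * exact, tgt), 0.9)
  # all-zero profile scores 0
  expect_equal(similarity_score(rep(0, 20), tgt), 0)
  # score strictly decreases as one anchor's error grows
  worse <- exact
  worse[1] <- worse[1] * 1.5
  expect_lt(similarity_score(worse, tgt), 1)
})

test_that("targets validate anchors and potential window", {
  expect_error(target_profile("O2", 0.5, c(0.1, 0.2, 0, 0.1, 0.1, 0.1, 0.1)),
               "strictly positive")
  expect_error(target_profile("O2", 0.9, rep(0.1, 7)), "window")
  expect_equal(default_anchors("O2"), c(5, 10, 15, 25, 35, 45, 70))
  expect_equal(default_anchors("H2O2"), c(5, 20, 30, 40, 55, 70, 80))
})

test_that("targets round-trip through JSON and CSV", {
  tgt <- target_profile("H2O2", 0.45, c_mM = seq(0.015, 0.003, length.out = 7))
  f <- tempfile(fileext = ".json")
  write_target_profile(tgt, f)
  t2 <- read_target_profile(f)
  expect_equal(t2$c, tgt$c)
  expect_equal(t2$E_appl, 0.45)
  expect_equal(t2$species, "H2O2")
  fc <- tempfile(fileext = ".csv")
  write.csv(data.frame(species = "H2O2", E_appl_V = 0.45,
                       z_um = tgt$z, c_mM = tgt$c), fc, row.names = FALSE)
  t3 <- read_target_profile(fc)
  expect_equal(t3$c, tgt$c)
})

test_that("search returns ranked candidates, capped at 10,000, deterministically", {
  fx <- shared_pt_surrogate()
  sim <- simulate_gradients(c(30, 3, 50), "pt", 0.5)
  tgt <- target_from_profile(sim$o2, 0.5)
  r5 <- search_morphologies(fx$model, tgt, n_eval = 5, seed = 3)
  expect_equal(nrow(r5$candidates), 5)
  big <- search_morphologies(fx$model, tgt, n_eval = 20000, seed = 3)
  expect_equal(nrow(big$candidates), 10000)
  expect_true(all(diff(big$candidates$score) <= 0))
  big2 <- search_morphologies(fx$model, tgt, n_eval = 20000, seed = 3)
  expect_identical(big$candidates, big2$candidates)
  # species mismatch caught
  th <- target_profile("H2O2", 0.45, rep(0.01, 7))
  expect_error(search_morphologies(fx$model, th, 10), "target is H2O2")
})

test_that("closed-loop design recovery: a simulated target is found and re-simulates", {
  fx <- shared_pt_surrogate()
  k_star <- c(30, 3, 50)
  sim <- simulate_gradients(k_star, "pt", 0.5)
  tgt <- target_from_profile(sim$o2, 0.5)
  res <- search_morphologies(fx$model, tgt, n_eval = 20000, seed = 17)
  expect_gt(res$candidates$score[1], 0.9)
  top <- res$candidates[1, ]
  ver <- verify_design(c(top$P, top$D, top$L), tgt, catalyst = "pt")
  expect_gt(ver$score, 0.9)
  # the retained set spans multiple distinct morphologies (multimodality)
  top_set <- res$candidates[res$candidates$score > 0.9, ]
  expect_gt(diff(range(top_set$P)), 10)
})

test_that("verifying the generating morphology closes the loop exactly", {
  # L = 40 keeps the bulk plane (z_bulk = 90 um) above the outermost
  # H2O2 anchor at 80 um, so every anchor concentration is positive
  sim <- simulate_gradients(c(17, 3, 40), "au", 0.45)
  tgt <- target_from_profile(sim$h2o2, 0.45)
  ver <- verify_design(c(17, 3, 40), tgt, catalyst = "au")
  expect_gt(ver$score, 0.999)
  expect_lt(ver$mse, 1e-10)
})

test_that("sliced maps follow band membership and bin averaging", {
  # single candidate at L = 25 falls only in the 20-um band
  r1 <- fake_design_result(P = 30, D = 3, L = 25, score = 0.8)
  m1 <- slice_score_map(r1)
  expect_equal(m1$L_band, 20)
  # two candidates in one (P, D, band) bin average their scores
  r2 <- fake_design_result(P = c(30.1, 30.9), D = c(3.1, 3.3), L = c(25, 28),
                           score = c(0.8, 0.6))
  m2 <- slice_score_map(r2)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$score, 0.7)
  expect_equal(m2$n, 2L)
  # all six default bands appear when candidates cover the L range
  r3 <- fake_design_result(P = rep(50, 6), D = rep(5, 6),
                           L = c(5, 20, 40, 60, 80, 95), score = rep(0.5, 6))
  m3 <- slice_score_map(r3)
  expect_setequal(m3$L_band, c(5, 20, 40, 60, 80, 95))
  # empty bins are absent, not zero
  expect_equal(nrow(m3), 6)
})
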