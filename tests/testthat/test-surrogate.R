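test_that("splits are disjoint, exhaustive, correctly sized and reproducible", {
  ds <- make_fake_dataset(100)
  sp <- split_dataset(ds, seed = 9)
  expect_equal(nrow(sp$train$data), 65)
  expect_equal(nrow(sp$val$data), 15)
  expect_equal(nrow(sp$test$data), 20)
  all_rows <- rbind(sp$train$data, sp$val$data, sp$test$data)
  expect_equal(nrow(all_rows), 100)
  # every original row appears exactly once
  key <- function(df) do.call(paste, df)
  expect_setequal(key(all_rows), key(ds$data))
  expect_equal(anyDuplicated(key(all_rows)), 0)
  sp2 <- split_dataset(ds, seed = 9)
  expect_identical(sp$test$data, sp2$test$data)
  # 10,000 rows -> 6,500 / 1,500 / 2,000
  dsl <- make_fake_dataset(10000)
  spl <- split_dataset(dsl, seed = 1)
  expect_equal(vapply(spl, function(s) nrow(s$data), numeric(1)),
               c(train = 6500, val = 1500, test = 2000))
  expect_error(split_dataset(make_fake_dataset(10)), "at least 20")
})

test_that("the trainer drives a learnable constant function to near-zero error", {
  ds <- make_fake_dataset(80, seed = 3)
  ds$data[, 5:24] <- matrix(0.1, 80, 20)   # constant profiles
  sp <- split_dataset(ds, seed = 3)
  m <- train_surrogate(sp$train, sp$val, epochs = 50, seed = 3)
  r <- evaluate_surrogate(m, sp$test)
  expect_lt(r$amse, 1e-8)
})

test_that("the trainer recovers a smooth analytic response surface", {
  # truth: profiles generated from a closed-form function of the inputs
  N <- 600
  ds <- make_fake_dataset(N, seed = 11)
  X <- as.matrix(ds$data[, 1:4])
  z <- seq(5, 100, 5)
  for (i in seq_len(N))
    ds$data[i, 5:24] <- 0.246 * plogis((z / 50 - X[i, 2] / 60) * 4) *
      X[i, 1] / 0.6
  sp <- split_dataset(ds, seed = 11)
  m <- train_surrogate(sp$train, sp$val, epochs = 150, seed = 11)
  r <- evaluate_surrogate(m, sp$test)
  expect_lt(r$amse, 1e-4)   # RMS error < ~4% of the profile scale
  expect_gt(r$r2, 0.95)
})

test_that("training is deterministic under a fixed seed and logs epochs", {
  ds <- make_fake_dataset(60, seed = 4)
  sp <- split_dataset(ds, seed = 4)
  m1 <- train_surrogate(sp$train, sp$val, epochs = 12, seed = 5)
  m2 <- train_surrogate(sp$train, sp$val, epochs = 12, seed = 5)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$log, m2$log)
  expect_equal(nrow(m1$log), 12)
  expect_true(all(is.finite(m1$log$train_amse)))
})

test_that("predictions have 20 points, physical bounds, and are deterministic", {
  fx <- shared_pt_surrogate()
  p <- predict_profile(fx$model, 0.5, morphology(30, 3, 50))
  expect_length(p$values, 20)
  expect_equal(p$z, seq(5, 100, 5))
  expect_true(all(p$values >= 0 & p$values <= 0.246))
  p2 <- predict_profile(fx$model, 0.5, c(30, 3, 50))
  expect_identical(p$values, p2$values)
  expect_warning(predict_profile(fx$model, 0.6, c(50000, 3, 50)),
                 "extrapolation")
})

test_that("evaluation metrics match hand computations", {
  ds <- make_fake_dataset(40, seed = 6)
  sp <- split_dataset(ds, seed = 6)
  m <- train_surrogate(sp$train, NULL, epochs = 5, seed = 6)
  # prediction == truth -> all metrics perfect
  perfect <- sp$test
  perfect$data[, 5:24] <- gradientforge:::.predict_matrix(
    m, as.matrix(perfect$data[, 1:4]))
  r <- evaluate_surrogate(m, perfect)
  expect_equal(r$amse, 0)
  expect_equal(r$sd, 0)
  expect_equal(r$r2, 1)
  # constant offset of 0.01 mM -> AMSE = 1e-4 mM^2, SD = 0
  offset <- perfect
  offset$data[, 5:24] <- offset$data[, 5:24] - 0.01
  r2 <- evaluate_surrogate(m, offset)
  expect_equal(r2$amse, 1e-4, tolerance = 1e-10)
  expect_equal(r2$sd, 0, tolerance = 1e-12)
  # two-row toy set against a spreadsheet-style hand computation
  toy <- ds
  toy$data <- toy$data[1:2, ]
  pred <- gradientforge:::.predict_matrix(m, as.matrix(toy$data[, 1:4]))
  truth <- as.matrix(toy$data[, 5:24])
  mse_hand <- c(mean((pred[1, ] - truth[1, ])^2), mean((pred[2, ] - truth[2, ])^2))
  r3 <- evaluate_surrogate(m, toy)
  expect_equal(as.numeric(r3$mse), mse_hand)
  expect_equal(r3$amse, mean(mse_hand))
  expect_equal(r3$sd, sqrt(mean((mse_hand - mean(mse_hand))^2)))
})

test_that("surrogate round-trips through disk bit-identically", {
  fx <- shared_pt_surrogate()
  dir <- tempfile()
  save_surrogate(fx$model, dir)
  m2 <- load_surrogate(dir)
  X <- as.matrix(fx$splits$test$data[1:50, 1:4])
  expect_identical(gradientforge:::.predict_matrix(fx$model, X),
                   gradientforge:::.predict_matrix(m2, X))
  expect_true(file.exists(file.path(dir, "scaler.json")))
  expect_true(file.exists(file.path(dir, "training_log.csv")))
})

test_that("validation tracks training without overfitting on simulated data", {
  fx <- shared_pt_surrogate()
  log <- fx$model$log
  final <- log[nrow(log), ]
  expect_lt(final$val_amse, 2 * final$train_amse)
  expect_lt(final$val_amse, log$val_amse[1])
})
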