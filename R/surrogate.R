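# Multilayer-perceptron surrogate of the reaction-diffusion simulator:
# maps (E_appl, P, D, L) to the 20-point laterally averaged profile.
#
# The network is small (two ReLU hidden layers by default) and trained
# with minibatch Adam on standardized inputs and min-max scaled outputs.
# Written with plain matrix algebra so training is exactly reproducible
# from a seed.

#' Split a dataset into train/validation/test partitions
#'
#' The held-out test fraction is drawn first from the whole table; the
#' remainder is then split into training and validation rows. Fractions
#' refer to the whole dataset (default 65/15/20) and sizes are rounded
#' with any remainder going to the training set. The partition is
#' disjoint, exhaustive and reproducible from the seed.
#'
#' @param ds a \code{gradient_dataset}.
#' @param fractions train/val/test fractions summing to 1.
#' @param seed RNG seed for the permutation.
#' @return named list \code{train}, \code{val}, \code{test} of
#'   \code{gradient_dataset} objects.
#' @export
split_dataset <- function(ds, fractions = c(0.65, 0.15, 0.20), seed = 1) {
  stopifnot(inherits(ds, "gradient_dataset"), length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-9)
  N <- nrow(ds$data)
  if (N < 20L) stop("need at least 20 rows to split, got ", N)
  n_test <- round(fractions[3] * N)
  n_val <- round(fractions[2] * N)
  idx <- .with_seed(seed, sample.int(N))
  test_i <- idx[seq_len(n_test)]
  val_i <- idx[n_test + seq_len(n_val)]
  train_i <- idx[-seq_len(n_test + n_val)]
  take <- function(i, role) {
    out <- ds
    out$data <- ds$data[sort(i), , drop = FALSE]
    rownames(out$data) <- NULL
    out$meta$split <- role
    out$meta$split_seed <- seed
    out
  }
  list(train = take(train_i, "train"), val = take(val_i, "val"),
       test = take(test_i, "test"))
}

.relu <- function(x) pmax(x, 0)

.mlp_init <- function(sizes, seed) {
  .with_seed(seed, {
    W <- list(); b <- list()
    nlay <- length(sizes) - 1L
    for (l in seq_len(nlay)) {
      # He-style initialisation for rectified layers; the output layer
      # starts at zero so the initial prediction is the scaled-space
      # origin (constant functions are fit immediately)
      W[[l]] <- if (l == nlay) matrix(0, sizes[l], sizes[l + 1L])
      else matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                               sd = sqrt(2 / sizes[l])),
                  sizes[l], sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    list(W = W, b = b)
  })
}

# forward pass in scaled space; returns activations when grad = TRUE
.mlp_forward <- function(par, X, grad = FALSE) {
  L <- length(par$W)
  H <- X
  acts <- if (grad) vector("list", L) else NULL
  for (l in seq_len(L)) {
    Z <- sweep(H %*% par$W[[l]], 2, par$b[[l]], "+")
    H <- if (l < L) .relu(Z) else Z
    if (grad) acts[[l]] <- H
  }
  if (grad) list(out = H, acts = acts) else H
}

#' Train the MLP surrogate
#'
#' Trains a multilayer perceptron mapping the 4 condition inputs
#' (E_appl, P, D, L) to the 20 profile concentrations. The geometric
#' inputs P, D, L span two decades, so they are log-transformed before
#' standardization (\code{log_inputs}); outputs are min-max scaled per
#' column using training-set statistics. The loss is the mean squared
#' error in scaled space,
#' minimised by minibatch Adam. One epoch is one full pass over the
#' training rows. After every epoch the average per-profile MSE (AMSE,
#' mM^2) is logged on the training and validation sets. Training is
#' fully reproducible from the seed.
#'
#' @param train training \code{gradient_dataset}.
#' @param val validation \code{gradient_dataset} (may be \code{NULL}).
#' @param hidden hidden-layer widths.
#' @param epochs number of passes over the training set (protocol
#'   default 10; extend if the accuracy target is unmet).
#' @param batch minibatch size.
#' @param lr initial Adam learning rate.
#' @param lr_decay multiplicative learning-rate decay applied at 60\%
#'   and 85\% of the scheduled epochs (set to 1 for a constant rate).
#' @param log_inputs log-transform the geometric inputs P, D, L before
#'   standardization.
#' @param seed RNG seed for initialisation and shuffling.
#' @param verbose print the per-epoch AMSE.
#' @return a \code{gradient_surrogate}: weights, scalers, config and the
#'   training log (data.frame epoch / train_amse / val_amse).
#' @export
train_surrogate <- function(train, val = NULL, hidden = c(64, 64),
                            epochs = 10, batch = 32, lr = 1e-3,
                            lr_decay = 0.2, log_inputs = TRUE, seed = 1,
                            verbose = FALSE) {
  stopifnot(inherits(train, "gradient_dataset"), nrow(train$data) > 0)
  X <- as.matrix(train$data[, 1:4])
  if (log_inputs) X[, 2:4] <- log(X[, 2:4])
  Y <- as.matrix(train$data[, 5:24])
  x_mu <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  x_sd[x_sd < 1e-12] <- 1
  y_min <- apply(Y, 2, min)
  y_rng <- apply(Y, 2, max) - y_min
  y_rng[y_rng < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, x_mu), 2, x_sd, "/")
  Ys <- sweep(sweep(Y, 2, y_min), 2, y_rng, "/")

  sizes <- c(4L, hidden, 20L)
  par <- .mlp_init(sizes, seed)
  nL <- length(par$W)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(Xs)
  step <- 0L

  model_env <- list(W = par$W, b = par$b)
  amse_of <- function(dset) {
    if (is.null(dset)) return(NA_real_)
    Xd <- as.matrix(dset$data[, 1:4])
    if (log_inputs) Xd[, 2:4] <- log(Xd[, 2:4])
    Xd <- sweep(sweep(Xd, 2, x_mu), 2, x_sd, "/")
    Yh <- .mlp_forward(model_env, Xd)
    pred <- sweep(sweep(Yh, 2, y_rng, "*"), 2, y_min, "+")
    mean((pred - as.matrix(dset$data[, 5:24]))^2)
  }

  log <- data.frame(epoch = integer(0), train_amse = numeric(0),
                    val_amse = numeric(0))
  .with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      lr_ep <- lr * lr_decay^((ep > 0.60 * epochs) + (ep > 0.85 * epochs))
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch)) {
        ii <- ord[start:min(start + batch - 1L, n)]
        Xb <- Xs[ii, , drop = FALSE]
        Yb <- Ys[ii, , drop = FALSE]
        fw <- .mlp_forward(model_env, Xb, grad = TRUE)
        m <- nrow(Xb)
        delta <- 2 * (fw$out - Yb) / (m * ncol(Yb))
        gW <- vector("list", nL); gb <- vector("list", nL)
        for (l in nL:1) {
          Hprev <- if (l == 1L) Xb else fw$acts[[l - 1L]]
          gW[[l]] <- crossprod(Hprev, delta)
          gb[[l]] <- colSums(delta)
          if (l > 1L) delta <- (delta %*% t(model_env$W[[l]])) * (fw$acts[[l - 1L]] > 0)
        }
        step <- step + 1L
        c1 <- 1 - beta1^step
        c2 <- 1 - beta2^step
        for (l in seq_len(nL)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
          model_env$W[[l]] <- model_env$W[[l]] -
            lr_ep * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
          model_env$b[[l]] <- model_env$b[[l]] -
            lr_ep * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
        }
      }
      tr_amse <- amse_of(train)
      if (!is.finite(tr_amse)) stop("training diverged (non-finite loss) at epoch ", ep)
      va_amse <- amse_of(val)
      log[ep, ] <- list(ep, tr_amse, va_amse)
      if (verbose)
        message(sprintf("epoch %3d  train AMSE %.3e  val AMSE %.3e",
                        ep, tr_amse, va_amse))
    }
  })
  if (!is.null(val) && nrow(log) > 1 &&
      is.finite(log$val_amse[1]) && log$val_amse[nrow(log)] > log$val_amse[1])
    warning("validation AMSE did not improve over training; inspect the training log")

  structure(list(species = train$species,
                 W = model_env$W, b = model_env$b,
                 x_log = log_inputs,
                 x_mu = x_mu, x_sd = x_sd, y_min = y_min, y_rng = y_rng,
                 config = list(hidden = hidden, epochs = epochs, batch = batch,
                               lr = lr, seed = seed,
                               n_train = n,
                               n_val = if (is.null(val)) 0L else nrow(val$data)),
                 log = log),
            class = "gradient_surrogate")
}

# vectorized prediction on an n x 4 matrix of raw inputs; returns n x 20
# matrix in mM, clipped to physical bounds
.predict_matrix <- function(model, X, constants = phys_constants()) {
  if (isTRUE(model$x_log)) X[, 2:4] <- log(X[, 2:4])
  Xs <- sweep(sweep(X, 2, model$x_mu), 2, model$x_sd, "/")
  Yh <- .mlp_forward(list(W = model$W, b = model$b), Xs)
  pred <- sweep(sweep(Yh, 2, model$y_rng, "*"), 2, model$y_min, "+")
  pred[pred < 0] <- 0
  if (model$species == "O2") pred[pred > constants$C_O2_bulk] <- constants$C_O2_bulk
  pred
}

#' Predict a gradient profile with the surrogate
#'
#' Deterministic forward pass of the trained MLP; predictions are
#' clipped to physical bounds (non-negative, and at most the bulk
#' concentration for O2). Inputs outside the training ranges trigger a
#' warning, not an error.
#'
#' @param model a \code{gradient_surrogate}.
#' @param E_appl applied potential, V vs RHE.
#' @param morph a \code{\link{morphology}} or numeric \code{c(P, D, L)}.
#' @param constants a \code{\link{phys_constants}}.
#' @return a \code{gradient_profile}.
#' @export
predict_profile <- function(model, E_appl, morph,
                            constants = phys_constants()) {
  stopifnot(inherits(model, "gradient_surrogate"))
  if (inherits(morph, "morphology")) morph <- c(morph$P, morph$D, morph$L)
  x <- c(E_appl, morph)
  xt <- x
  if (isTRUE(model$x_log)) xt[2:4] <- log(xt[2:4])
  lo <- model$x_mu - 4 * model$x_sd
  hi <- model$x_mu + 4 * model$x_sd
  if (any(xt < lo | xt > hi))
    warning("inputs far outside the training distribution; prediction is an extrapolation")
  pred <- .predict_matrix(model, matrix(x, 1, 4), constants)
  structure(list(species = model$species, z = profile_heights(),
                 values = as.numeric(pred)),
            class = "gradient_profile")
}

#' Evaluate the surrogate on a held-out dataset
#'
#' Per-profile MSE is the mean over the 20 heights of the squared
#' concentration error (mM^2); AMSE is the mean of the per-profile MSEs;
#' SD is the population standard deviation of the per-profile MSEs about
#' the AMSE; R^2 is the coefficient of determination pooled over all
#' (profile, height) pairs.
#'
#' @param model a \code{gradient_surrogate}.
#' @param test a \code{gradient_dataset}.
#' @param constants a \code{\link{phys_constants}}.
#' @return an \code{eval_report}: list \code{mse} (per-row vector),
#'   \code{amse}, \code{sd}, \code{r2}, \code{n}.
#' @export
evaluate_surrogate <- function(model, test, constants = phys_constants()) {
  stopifnot(inherits(model, "gradient_surrogate"),
            inherits(test, "gradient_dataset"), nrow(test$data) > 0)
  pred <- .predict_matrix(model, as.matrix(test$data[, 1:4]), constants)
  truth <- as.matrix(test$data[, 5:24])
  mse <- rowMeans((pred - truth)^2)
  amse <- mean(mse)
  sdv <- sqrt(mean((mse - amse)^2))
  r2 <- 1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2)
  structure(list(mse = mse, amse = amse, sd = sdv, r2 = r2,
                 n = nrow(truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d profiles\n  AMSE = %.4e mM^2, SD = %.4e mM^2, R^2 = %.5f\n",
              x$n, x$amse, x$sd, x$r2))
  invisible(x)
}

#' Save a trained surrogate to a directory
#'
#' Writes \code{weights.rds} (layer weights), \code{scaler.json}
#' (input/output normalisation statistics), \code{config.json} and
#' \code{training_log.csv}. Loading reproduces predictions bit-for-bit.
#'
#' @param model a \code{gradient_surrogate}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
save_surrogate <- function(model, dir) {
  stopifnot(inherits(model, "gradient_surrogate"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # weights.rds is the authoritative artifact (bit-exact doubles);
  # scaler.json duplicates the normalisation statistics for readability
  saveRDS(list(W = model$W, b = model$b, x_log = isTRUE(model$x_log),
               x_mu = model$x_mu, x_sd = model$x_sd,
               y_min = model$y_min, y_rng = model$y_rng,
               species = model$species),
          file.path(dir, "weights.rds"))
  jsonlite::write_json(list(species = model$species,
                            x_log = isTRUE(model$x_log),
                            x_mu = model$x_mu, x_sd = model$x_sd,
                            y_min = model$y_min, y_rng = model$y_rng),
                       file.path(dir, "scaler.json"), digits = NA)
  jsonlite::write_json(model$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(model$log, file.path(dir, "training_log.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load a surrogate saved by \code{\link{save_surrogate}}
#' @param dir model directory.
#' @return a \code{gradient_surrogate}.
#' @export
load_surrogate <- function(dir) {
  w <- readRDS(file.path(dir, "weights.rds"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  log <- utils::read.csv(file.path(dir, "training_log.csv"))
  structure(list(species = w$species, W = w$W, b = w$b,
                 x_log = isTRUE(w$x_log),
                 x_mu = w$x_mu, x_sd = w$x_sd,
                 y_min = w$y_min, y_rng = w$y_rng,
                 config = cfg, log = log),
            class = "gradient_surrogate")
}

#' @export
print.gradient_surrogate <- function(x, ...) {
  cat(sprintf("<gradient_surrogate> %s, hidden = (%s), %d epochs, %d training rows\n",
              x$species, paste(x$config$hidden, collapse = ", "),
              nrow(x$log), x$config$n_train))
  if (nrow(x$log))
    cat(sprintf("  final AMSE: train %.3e, val %.3e mM^2\n",
                x$log$train_amse[nrow(x$log)], x$log$val_amse[nrow(x$log)]))
  invisible(x)
}
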