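# Shared fixtures. The trained surrogates are expensive (minutes), so they
# are built lazily on first request and memoised for the rest of the run.

.fixtures <- new.env(parent = emptyenv())

# O2 surrogate trained on a 2,000-row Pt dataset (desk-scale stand-in for
# the 10,000 finite-element runs)
shared_pt_surrogate <- function() {
  if (!exists("pt", envir = .fixtures)) {
    samples <- sample_conditions(2000, seed = 101)
    ds <- generate_dataset(samples, "pt")$o2
    sp <- split_dataset(ds, seed = 102)
    model <- train_surrogate(sp$train, sp$val, epochs = 200, seed = 103)
    assign("pt", list(dataset = ds, splits = sp, model = model),
           envir = .fixtures)
  }
  get("pt", envir = .fixtures)
}

# H2O2 surrogate trained on a 10,000-row Au dataset (the H2O2 response
# surface spans three decades of amplitude and needs reference-scale
# coverage to reach the reference accuracy)
shared_au_surrogate <- function() {
  if (!exists("au", envir = .fixtures)) {
    samples <- sample_conditions(10000, seed = 201)
    ds <- generate_dataset(samples, "au")$h2o2
    sp <- split_dataset(ds, seed = 202)
    model <- train_surrogate(sp$train, sp$val, epochs = 500, seed = 203)
    assign("au", list(dataset = ds, splits = sp, model = model),
           envir = .fixtures)
  }
  get("au", envir = .fixtures)
}

# synthetic dataset with the correct schema but made-up profile values;
# used where no physics is needed (splits, metric identities, round-trips)
make_fake_dataset <- function(N, species = "O2", seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    X <- data.frame(E_appl_V = runif(N, 0.2, 0.6), P_um = runif(N, 1, 100),
                    D_um = runif(N, 0.2, 10), L_um = runif(N, 1, 150))
    Y <- matrix(runif(N * 20, 0, 0.246), N, 20)
    colnames(Y) <- sprintf("c_z%03d", seq(5, 100, 5))
    structure(list(species = species, data = cbind(X, as.data.frame(Y)),
                   meta = list(seed = seed, catalyst = "fake")),
              class = "gradient_dataset")
  })
}

# a design_result wrapper around hand-picked candidates, for map tests
fake_design_result <- function(P, D, L, score, species = "O2", E = 0.5) {
  tgt <- target_profile(species, E, rep(0.1, 7))
  structure(list(candidates = data.frame(rank = seq_along(P), P = P, D = D,
                                         L = L, score = score),
                 target = tgt,
                 meta = list(n_eval = length(P), seed = 0, keep = 10000,
                             species = species, E_appl = E)),
            class = "design_result")
}
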