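# Batch sampling of {E_appl, k = (P, D, L)} conditions and generation of
# the simulated gradient tables the surrogate is trained on.

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.default_ranges <- function() {
  list(E_appl = c(0.2, 0.6), P = c(1, 100), D = c(0.2, 10), L = c(1, 150))
}

#' Sample simulation conditions uniformly over the design block
#'
#' Draws \code{n} conditions independently and uniformly over each of
#' \code{E_appl}, \code{P}, \code{D}, \code{L} within the given ranges.
#' Draws violating the geometric constraint \code{D < P} are rejected
#' and redrawn, so the accepted sample is uniform on the feasible
#' region. Identical \code{(n, seed, ranges)} reproduce the identical
#' table.
#'
#' @param n number of conditions (>= 1).
#' @param seed RNG seed.
#' @param ranges named list of 2-vectors \code{E_appl}, \code{P},
#'   \code{D}, \code{L}; defaults to the full operating window and
#'   morphology block.
#' @return data.frame with columns \code{E_appl}, \code{P}, \code{D},
#'   \code{L} and attribute \code{seed}.
#' @export
sample_conditions <- function(n, seed = 1, ranges = .default_ranges()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count")
  n <- as.integer(n)
  r <- utils::modifyList(.default_ranges(), ranges)
  if (r$D[1] >= r$P[2])
    stop("empty feasible region: every D in the range is >= every P")
  out <- .with_seed(seed, {
    draw <- function(m) data.frame(
      E_appl = stats::runif(m, r$E_appl[1], r$E_appl[2]),
      P = stats::runif(m, r$P[1], r$P[2]),
      D = stats::runif(m, r$D[1], r$D[2]),
      L = stats::runif(m, r$L[1], r$L[2]))
    s <- draw(n)
    bad <- which(s$D >= s$P)
    while (length(bad)) {
      s[bad, ] <- draw(length(bad))
      bad <- bad[s$D[bad] >= s$P[bad]]
    }
    s
  })
  attr(out, "seed") <- seed
  out
}

.profile_colnames <- function() sprintf("c_z%03d", profile_heights())

#' Generate a simulated gradient dataset
#'
#' Runs the full reaction-diffusion simulator for every sampled
#' condition and collects the 20-point laterally averaged profiles into
#' regression tables: one table for O2 and, when the catalyst carries a
#' 2-electron channel (Au), a paired table for H2O2. Row order follows
#' sample order. Conditions whose solve fails are recorded and excluded
#' with a message, never silently dropped; more than 1\% failures aborts
#' the run.
#'
#' @param samples a \code{\link{sample_conditions}} table (or any
#'   data.frame with columns \code{E_appl}, \code{P}, \code{D},
#'   \code{L}).
#' @param catalyst \code{"pt"}, \code{"au"} or a
#'   \code{catalyst_kinetics}.
#' @param resolution,mode,include_base,constants passed to
#'   \code{\link{simulate_gradients}}.
#' @param progress print a progress message every 500 rows.
#' @return named list of \code{gradient_dataset} objects (\code{o2} and,
#'   for Au, \code{h2o2}); each holds \code{species}, \code{data} (a
#'   24-column data.frame: \code{E_appl_V}, \code{P_um}, \code{D_um},
#'   \code{L_um}, \code{c_z005} ... \code{c_z100} in mM) and
#'   \code{meta}.
#' @export
generate_dataset <- function(samples, catalyst, resolution = 1,
                             mode = "axisym", include_base = TRUE,
                             constants = phys_constants(),
                             progress = FALSE) {
  stopifnot(is.data.frame(samples),
            all(c("E_appl", "P", "D", "L") %in% names(samples)))
  kin <- if (inherits(catalyst, "catalyst_kinetics")) catalyst else catalyst_kinetics(catalyst)
  has_h2o2 <- any(vapply(kin$channels, function(c) c$n_stoich == 2, logical(1)))
  n <- nrow(samples)
  o2 <- matrix(NA_real_, n, 20L)
  h2 <- if (has_h2o2) matrix(NA_real_, n, 20L) else NULL
  failed <- integer(0)
  for (i in seq_len(n)) {
    sim <- tryCatch(
      simulate_gradients(c(samples$P[i], samples$D[i], samples$L[i]), kin,
                         samples$E_appl[i], resolution = resolution,
                         mode = mode, include_base = include_base,
                         constants = constants),
      error = function(e) e)
    if (inherits(sim, "error")) {
      failed <- c(failed, i)
      message(sprintf("solve failed for row %d (E=%.3f, k=(%.2f,%.2f,%.2f)): %s",
                      i, samples$E_appl[i], samples$P[i], samples$D[i],
                      samples$L[i], conditionMessage(sim)))
      next
    }
    o2[i, ] <- sim$o2$values
    if (has_h2o2) h2[i, ] <- sim$h2o2$values
    if (progress && i %% 500L == 0L) message(i, "/", n, " simulated")
  }
  if (length(failed) > 0.01 * n)
    stop(sprintf("%d of %d solves failed (> 1%%); aborting (rows: %s ...)",
                 length(failed), n, paste(utils::head(failed, 5), collapse = ", ")))
  keep <- setdiff(seq_len(n), failed)
  meta <- list(seed = attr(samples, "seed"), resolution = resolution,
               mode = mode, include_base = include_base,
               catalyst = kin$name, n_requested = n, n_failed = length(failed),
               failed_rows = failed,
               code_version = as.character(utils::packageVersion("gradientforge")))
  mk <- function(species, Y) {
    df <- cbind(data.frame(E_appl_V = samples$E_appl[keep], P_um = samples$P[keep],
                           D_um = samples$D[keep], L_um = samples$L[keep]),
                stats::setNames(as.data.frame(Y[keep, , drop = FALSE]),
                                .profile_colnames()))
    rownames(df) <- NULL
    m <- meta
    m$species <- species
    structure(list(species = species, data = df, meta = m),
              class = "gradient_dataset")
  }
  out <- list(o2 = mk("O2", o2))
  if (has_h2o2) out$h2o2 <- mk("H2O2", h2)
  out
}

#' @export
print.gradient_dataset <- function(x, ...) {
  cat(sprintf("<gradient_dataset> %s, %d rows, catalyst %s (seed %s)\n",
              x$species, nrow(x$data), x$meta$catalyst,
              if (is.null(x$meta$seed)) "?" else x$meta$seed))
  invisible(x)
}

#' Write a gradient dataset to CSV with sidecar metadata
#'
#' @param ds a \code{gradient_dataset}.
#' @param path CSV output path; metadata goes to \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_gradient_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "gradient_dataset"))
  utils::write.csv(ds$data, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(ds$meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a gradient dataset written by \code{\link{write_gradient_dataset}}
#'
#' @param path CSV path.
#' @param species species label, used if no sidecar metadata is found.
#' @return a \code{gradient_dataset}.
#' @export
read_gradient_dataset <- function(path, species = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  expect <- c("E_appl_V", "P_um", "D_um", "L_um", .profile_colnames())
  if (!identical(names(df), expect))
    stop("unexpected dataset schema in ", path)
  if (anyNA(df)) stop("dataset contains missing values: ", path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  sp <- species %||% meta$species %||% "O2"
  structure(list(species = sp, data = df, meta = meta),
            class = "gradient_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
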