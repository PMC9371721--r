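# Similarity-score inverse design: score candidate morphologies against a
# target gradient, search the morphology space through the surrogate, and
# aggregate sliced (P, D) score maps per wire-length band.

#' Default anchor heights for similarity scoring
#'
#' Seven heights (um) at which predicted and target profiles are
#' compared: \code{c(5, 10, 15, 25, 35, 45, 70)} for O2 and
#' \code{c(5, 20, 30, 40, 55, 70, 80)} for H2O2.
#'
#' @param species \code{"O2"} or \code{"H2O2"}.
#' @return numeric vector of heights, um.
#' @export
default_anchors <- function(species = c("O2", "H2O2")) {
  species <- match.arg(species)
  if (species == "O2") c(5, 10, 15, 25, 35, 45, 70)
  else c(5, 20, 30, 40, 55, 70, 80)
}

#' Define a target gradient profile
#'
#' A design target: the species, the fixed applied potential at which
#' the design will operate, and the desired concentrations at a set of
#' anchor heights. All anchor concentrations must be strictly positive
#' (the similarity score divides by them).
#'
#' @param species \code{"O2"} or \code{"H2O2"}.
#' @param E_appl applied potential for the design task, V vs RHE.
#' @param c_mM target concentrations at the anchors, mM.
#' @param z_um anchor heights, um; defaults to
#'   \code{\link{default_anchors}} for the species.
#' @return a \code{target_profile} object.
#' @export
target_profile <- function(species, E_appl, c_mM,
                           z_um = default_anchors(species)) {
  species <- match.arg(species, c("O2", "H2O2"))
  stopifnot(length(c_mM) == length(z_um), all(is.finite(c_mM)),
            all(is.finite(z_um)), all(z_um > 0))
  if (any(c_mM <= 0))
    stop("target concentrations must be strictly positive at every anchor ",
         "(relative error is undefined at zero)")
  overpotential(E_appl)  # window check
  structure(list(species = species, E_appl = E_appl,
                 z = as.numeric(z_um), c = as.numeric(c_mM)),
            class = "target_profile")
}

#' Build a target from a simulated or predicted profile
#'
#' Samples a \code{gradient_profile} at the anchor heights to define a
#' design target, e.g. for closed-loop validation where the target is
#' generated from a known morphology.
#'
#' @param profile a \code{gradient_profile}.
#' @param E_appl applied potential of the design task, V vs RHE.
#' @param z_um anchor heights, um.
#' @return a \code{target_profile}.
#' @export
target_from_profile <- function(profile, E_appl,
                                z_um = default_anchors(profile$species)) {
  stopifnot(inherits(profile, "gradient_profile"))
  c_mM <- stats::approx(profile$z, profile$values, xout = z_um, rule = 2)$y
  target_profile(profile$species, E_appl, c_mM, z_um)
}

#' Read a target profile from JSON or CSV
#'
#' JSON layout: \code{{"species": "O2", "E_appl_V": 0.5, "anchors":
#' [{"z_um": 5, "c_mM": 0.146}, ...]}}. CSV layout: columns
#' \code{species}, \code{E_appl_V}, \code{z_um}, \code{c_mM} (species
#' and potential repeated on every row).
#'
#' @param path file path (extension decides the format).
#' @return a \code{target_profile}.
#' @export
read_target_profile <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    target_profile(x$species, x$E_appl_V, x$anchors$c_mM, x$anchors$z_um)
  } else {
    df <- utils::read.csv(path)
    target_profile(df$species[1], df$E_appl_V[1], df$c_mM, df$z_um)
  }
}

#' Write a target profile to JSON
#' @param target a \code{target_profile}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_target_profile <- function(target, path) {
  stopifnot(inherits(target, "target_profile"))
  jsonlite::write_json(list(species = target$species, E_appl_V = target$E_appl,
                            anchors = data.frame(z_um = target$z, c_mM = target$c)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Similarity score between a profile and a target
#'
#' One minus the mean relative concentration error over the anchor
#' heights:
#' \deqn{S = 1 - \frac{1}{|C|}\sum_{z \in C} \frac{|c_{pred}(z) - c_T(z)|}{c_T(z)}.}
#' A perfect match scores 1; a uniform 10\% error scores 0.9; the score
#' is not clamped and goes negative for wildly wrong profiles. Rendered
#' as a percentage only in reports.
#'
#' @param predicted a \code{gradient_profile}, or a numeric vector of 20
#'   concentrations on the standard ladder.
#' @param target a \code{target_profile}.
#' @return dimensionless score (1 = perfect).
#' @export
similarity_score <- function(predicted, target) {
  stopifnot(inherits(target, "target_profile"))
  if (inherits(predicted, "gradient_profile")) {
    z <- predicted$z
    v <- predicted$values
  } else {
    z <- profile_heights()
    v <- as.numeric(predicted)
    stopifnot(length(v) == length(z))
  }
  if (min(target$z) < min(z) || max(target$z) > max(z))
    stop("predicted profile does not cover all anchor heights")
  p <- stats::approx(z, v, xout = target$z)$y
  1 - mean(abs(p - target$c) / target$c)
}

# anchor column indices in a 20-column profile matrix (exact ladder hits)
.anchor_cols <- function(target) {
  idx <- match(target$z, profile_heights())
  if (anyNA(idx)) NULL else idx
}

#' Search the morphology space for a target gradient
#'
#' Random search through the surrogate: draws \code{n_eval} morphologies
#' uniformly from the morphology block (with \code{D < P} rejection),
#' predicts each profile at the target's fixed potential in one
#' vectorised forward pass, scores every candidate against the target,
#' and retains the top \code{min(n_eval, 10000)} scorers. Ties break
#' deterministically by score (descending), then P, D, L (ascending).
#'
#' @param model a \code{gradient_surrogate} of the target's species.
#' @param target a \code{target_profile}.
#' @param n_eval number of random morphologies to evaluate.
#' @param seed RNG seed.
#' @param ranges morphology ranges (list with \code{P}, \code{D},
#'   \code{L}); defaults to the full block.
#' @param keep maximum number of candidates retained (10,000).
#' @return a \code{design_result}: \code{candidates} (data.frame rank,
#'   P, D, L, score, sorted descending) and \code{meta}.
#' @export
search_morphologies <- function(model, target, n_eval = 10000, seed = 1,
                                ranges = NULL, keep = 10000) {
  stopifnot(inherits(model, "gradient_surrogate"),
            inherits(target, "target_profile"), n_eval >= 1)
  if (!identical(model$species, target$species))
    stop(sprintf("model predicts %s but the target is %s",
                 model$species, target$species))
  r <- .default_ranges()
  if (!is.null(ranges)) r <- utils::modifyList(r, ranges)
  r$E_appl <- c(target$E_appl, target$E_appl)
  cand <- sample_conditions(n_eval, seed = seed, ranges = r)
  cand$E_appl <- target$E_appl
  pred <- .predict_matrix(model, as.matrix(cand[, c("E_appl", "P", "D", "L")]))
  cols <- .anchor_cols(target)
  if (is.null(cols)) {
    score <- apply(pred, 1, function(v) similarity_score(v, target))
  } else {
    rel <- abs(sweep(pred[, cols, drop = FALSE], 2, target$c)) /
      matrix(target$c, nrow(pred), length(cols), byrow = TRUE)
    score <- 1 - rowMeans(rel)
  }
  ord <- order(-score, cand$P, cand$D, cand$L)
  ord <- ord[seq_len(min(length(ord), keep))]
  out <- data.frame(rank = seq_along(ord), P = cand$P[ord], D = cand$D[ord],
                    L = cand$L[ord], score = score[ord])
  structure(list(candidates = out,
                 target = target,
                 meta = list(n_eval = n_eval, seed = seed, keep = keep,
                             species = target$species, E_appl = target$E_appl,
                             model_config = model$config)),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("<design_result> %s target at E_appl = %g V, %d of %d candidates retained\n",
              x$meta$species, x$meta$E_appl, nrow(x$candidates), x$meta$n_eval))
  cat(sprintf("  best: k = (%.1f, %.2f, %.1f) um, score %.1f%%\n",
              x$candidates$P[1], x$candidates$D[1], x$candidates$L[1],
              100 * x$candidates$score[1]))
  invisible(x)
}

.default_L_bands <- function() {
  data.frame(label = c(5, 20, 40, 60, 80, 95),
             lo = c(0, 10, 30, 50, 70, 90),
             hi = c(10, 30, 50, 70, 90, 100))
}

#' Sliced similarity-score maps over (P, D) per wire-length band
#'
#' Partitions the retained candidates into wire-length bands (default
#' labels 5, 20, 40, 60, 80, 95 um covering [0,10), [10,30), [30,50),
#' [50,70), [70,90), [90,100] um), bins each band's candidates on a
#' (P, D) grid and averages the scores per bin. Empty bins are simply
#' absent, never zero-filled.
#'
#' @param result a \code{design_result}.
#' @param bands data.frame with columns \code{label}, \code{lo},
#'   \code{hi} (um).
#' @param P_width,D_width bin widths, um.
#' @return data.frame with columns \code{L_band}, \code{P_bin},
#'   \code{D_bin} (bin centres, um), \code{score} (mean), \code{n}.
#' @export
slice_score_map <- function(result, bands = .default_L_bands(),
                            P_width = 2, D_width = 0.5) {
  stopifnot(inherits(result, "design_result"), nrow(result$candidates) > 0)
  cc <- result$candidates
  out <- list()
  for (b in seq_len(nrow(bands))) {
    last <- b == nrow(bands)
    sel <- cc$L >= bands$lo[b] & (if (last) cc$L <= bands$hi[b] else cc$L < bands$hi[b])
    if (!any(sel)) next
    sub <- cc[sel, ]
    pb <- floor(sub$P / P_width) * P_width + P_width / 2
    db <- floor(sub$D / D_width) * D_width + D_width / 2
    key <- paste(pb, db)
    agg <- tapply(sub$score, key, mean)
    cnt <- tapply(sub$score, key, length)
    kk <- strsplit(names(agg), " ", fixed = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      L_band = bands$label[b],
      P_bin = as.numeric(vapply(kk, `[`, "", 1L)),
      D_bin = as.numeric(vapply(kk, `[`, "", 2L)),
      score = as.numeric(agg), n = as.integer(cnt))
  }
  if (!length(out)) return(data.frame(L_band = numeric(0), P_bin = numeric(0),
                                      D_bin = numeric(0), score = numeric(0),
                                      n = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$L_band, res$P_bin, res$D_bin), ]
  rownames(res) <- NULL
  res
}

#' Verify a candidate design with the full simulator
#'
#' Closes the design loop independently of the surrogate: re-simulates
#' the candidate morphology with the finite-volume solver at the
#' target's potential and reports the resulting profile, its MSE
#' against the target at the anchor heights (mM^2), and its similarity
#' score.
#'
#' @param candidate a \code{\link{morphology}} or numeric c(P, D, L).
#' @param target a \code{target_profile}.
#' @param catalyst \code{"pt"}, \code{"au"} or \code{catalyst_kinetics};
#'   defaults to pt for O2 targets and au for H2O2 targets.
#' @param resolution,mode,include_base passed to
#'   \code{\link{simulate_gradients}}.
#' @return list \code{profile} (simulated \code{gradient_profile} of the
#'   target species), \code{mse} (mM^2 at the anchors), \code{score}.
#' @export
verify_design <- function(candidate, target, catalyst = NULL,
                          resolution = 1, mode = "axisym",
                          include_base = TRUE) {
  stopifnot(inherits(target, "target_profile"))
  if (is.null(catalyst))
    catalyst <- if (target$species == "O2") "pt" else "au"
  sim <- simulate_gradients(candidate, catalyst, target$E_appl,
                            resolution = resolution, mode = mode,
                            include_base = include_base)
  prof <- if (target$species == "O2") sim$o2 else sim$h2o2
  p <- stats::approx(prof$z, prof$values, xout = target$z)$y
  list(profile = prof,
       mse = mean((p - target$c)^2),
       score = similarity_score(prof, target))
}
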