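# Steady-state diffusion solves on a unit-cell grid.
#
# Both species obey Laplace's equation on the electrolyte cells. The
# electrode enters as a Robin condition for O2 (Tafel flux linear in the
# local concentration) and as a slaved production flux for H2O2. Each
# solve is one sparse symmetric positive-definite linear system.

# assemble the Laplacian + Dirichlet part; returns list(A, b, gdir)
.assemble_base <- function(grid, Dm, bulk_value) {
  n <- grid$n
  f <- grid$faces
  g <- f$g * Dm
  i <- c(f$i, f$j, f$i, f$j)
  j <- c(f$j, f$i, f$i, f$j)
  x <- c(-g, -g, g, g)
  gd <- grid$dirichlet$g * Dm
  i <- c(i, grid$dirichlet$cell)
  j <- c(j, grid$dirichlet$cell)
  x <- c(x, gd)
  A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  b <- numeric(n)
  b[grid$dirichlet$cell] <- b[grid$dirichlet$cell] + gd * bulk_value
  list(A = A, b = b)
}

.solve_checked <- function(A, b, what) {
  fac <- tryCatch(Matrix::lu(A),
                  error = function(e) stop("linear solve failed for ", what,
                                           " (", conditionMessage(e), ")"))
  x <- as.numeric(Matrix::solve(fac, b))
  # normwise backward error ||b - Ax|| / (||A|| ||x|| + ||b||); one round
  # of iterative refinement for high-aspect-ratio cells
  nrmA <- max(abs(A))
  backward <- function(x) {
    r <- sqrt(sum((b - as.numeric(A %*% x))^2))
    r / (nrmA * sqrt(sum(x^2)) + sqrt(sum(b^2)) + 1e-300)
  }
  if (backward(x) > 1e-12)
    x <- x + as.numeric(Matrix::solve(fac, b - as.numeric(A %*% x)))
  if (!all(is.finite(x)) || backward(x) > 1e-10)
    stop(sprintf("%s solve did not converge: backward error %.3g", what, backward(x)))
  x
}

# O2 surface concentration on each electrode patch, from the cell value
# through the half-cell diffusive resistance in series with the Tafel
# rate constant: c_surf = c_cell * (D/dh) / (D/dh + k_O2)
.surface_o2 <- function(grid, c_o2, k_O2, D_O2) {
  e <- grid$electrode
  c_o2[e$cell] * (D_O2 / e$dh) / (D_O2 / e$dh + k_O2)
}

#' Solve the steady-state O2 diffusion problem
#'
#' Solves \code{div(D_O2 grad c) = 0} on the electrolyte cells of the
#' unit cell with the bulk concentration imposed on the plane
#' \code{z >= z_bulk}, zero-flux symmetry on the lateral faces, and the
#' Robin electrode condition \code{D_O2 dc/dn = -k_O2 c} on every
#' electrode patch, where \code{k_O2} is the effective Tafel rate
#' constant at the applied potential (see
#' \code{\link{effective_rate_constants}}). Electrode patches couple
#' through the half-cell diffusive resistance in series with the surface
#' kinetics, and carry their true-area correction factors.
#'
#' @param grid a \code{\link{build_grid}} result.
#' @param kin a \code{\link{catalyst_kinetics}}.
#' @param E_appl applied potential, V vs RHE (within the operating
#'   window).
#' @param constants a \code{\link{phys_constants}}.
#' @return a \code{concentration_field} with fields \code{species}
#'   (\code{"O2"}), \code{values} (mol/m^3 per cell), \code{bulk},
#'   \code{k_O2}, \code{k_gen}, \code{E_appl}, and the grid.
#' @export
solve_o2 <- function(grid, kin, E_appl, constants = phys_constants()) {
  stopifnot(inherits(grid, "unit_cell_grid"))
  eta <- overpotential(E_appl, constants)
  ks <- effective_rate_constants(kin, eta, constants)
  sys <- .assemble_base(grid, constants$D_O2, constants$C_O2_bulk)
  e <- grid$electrode
  if (ks$k_O2 > 0) {
    ge <- (e$area * e$corr) / (1 / ks$k_O2 + e$dh / constants$D_O2)
    dg <- tapply(ge, e$cell, sum)
    cells <- as.integer(names(dg))
    sys$A <- sys$A + Matrix::sparseMatrix(i = cells, j = cells, x = as.numeric(dg),
                                          dims = c(grid$n, grid$n))
  }
  vals <- .solve_checked(sys$A, sys$b, "O2")
  structure(list(species = "O2", values = vals, grid = grid,
                 bulk = constants$C_O2_bulk, E_appl = E_appl,
                 k_O2 = ks$k_O2, k_gen = ks$k_gen, constants = constants),
            class = "concentration_field")
}

#' Solve the steady-state H2O2 diffusion problem
#'
#' H2O2 is produced on the electrode at the rate \code{k_gen * c_O2}
#' given by the 2-electron ORR channel and the already-solved local O2
#' surface concentration, diffuses with \code{D_H2O2}, and is held at
#' zero on the bulk plane (the flowing medium carries no H2O2). There is
#' no H2O2 sink at the electrode. Catalysts without a 2-electron channel
#' (Pt) return the identically zero field.
#'
#' @inheritParams solve_o2
#' @param o2_field the \code{\link{solve_o2}} solution on the same grid.
#' @return a \code{concentration_field} with species \code{"H2O2"}.
#' @export
solve_h2o2 <- function(grid, kin, E_appl, o2_field,
                       constants = phys_constants()) {
  stopifnot(inherits(grid, "unit_cell_grid"),
            inherits(o2_field, "concentration_field"))
  if (!identical(o2_field$grid$n, grid$n) ||
      !isTRUE(all.equal(o2_field$grid$morph, grid$morph)))
    stop("o2_field was solved on a different grid")
  eta <- overpotential(E_appl, constants)
  ks <- effective_rate_constants(kin, eta, constants)
  if (ks$k_gen == 0) {
    return(structure(list(species = "H2O2", values = numeric(grid$n),
                          grid = grid, bulk = 0, E_appl = E_appl,
                          k_O2 = ks$k_O2, k_gen = 0, constants = constants),
                     class = "concentration_field"))
  }
  sys <- .assemble_base(grid, constants$D_H2O2, 0)
  e <- grid$electrode
  c_surf <- .surface_o2(grid, o2_field$values, ks$k_O2, constants$D_O2)
  src <- ks$k_gen * c_surf * e$area * e$corr          # mol/s per patch
  add <- tapply(src, e$cell, sum)
  sys$b[as.integer(names(add))] <- sys$b[as.integer(names(add))] + as.numeric(add)
  vals <- .solve_checked(sys$A, sys$b, "H2O2")
  structure(list(species = "H2O2", values = vals, grid = grid,
                 bulk = 0, E_appl = E_appl,
                 k_O2 = ks$k_O2, k_gen = ks$k_gen, constants = constants),
            class = "concentration_field")
}

#' Steady-state flux balance of a solved field
#'
#' Conservation diagnostic: at steady state the molar rate of species
#' exchange at the electrode must equal the rate through the bulk
#' (Dirichlet) plane. For O2 the electrode consumes and the bulk plane
#' supplies; for H2O2 the electrode produces and the bulk plane removes.
#'
#' @param field a \code{concentration_field}.
#' @return named list \code{electrode}, \code{bulk_plane} (mol/s, both
#'   reported as positive magnitudes) and \code{rel_imbalance}.
#' @export
flux_balance <- function(field) {
  stopifnot(inherits(field, "concentration_field"))
  grid <- field$grid
  cst <- field$constants
  e <- grid$electrode
  if (field$species == "O2") {
    Dm <- cst$D_O2
    elec <- if (field$k_O2 > 0)
      sum((e$area * e$corr) / (1 / field$k_O2 + e$dh / Dm) * field$values[e$cell])
    else 0
    bulk <- sum(grid$dirichlet$g * Dm * (field$bulk - field$values[grid$dirichlet$cell]))
  } else {
    # production needs the companion O2 field; see h2o2_flux_balance()
    Dm <- cst$D_H2O2
    elec <- NA_real_
    bulk <- sum(grid$dirichlet$g * Dm * (field$values[grid$dirichlet$cell] - field$bulk))
  }
  list(electrode = abs(elec), bulk_plane = abs(bulk),
       rel_imbalance = if (is.na(elec) || abs(bulk) == 0) NA_real_
                       else abs(abs(elec) - abs(bulk)) / abs(bulk))
}

#' H2O2 production/efflux balance
#'
#' Like \code{\link{flux_balance}} but for the H2O2 field, which needs
#' the companion O2 solution to evaluate the electrode production term.
#'
#' @param h2o2_field the H2O2 \code{concentration_field}.
#' @param o2_field the O2 field solved on the same grid.
#' @return named list \code{production}, \code{efflux} (mol/s),
#'   \code{rel_imbalance}.
#' @export
h2o2_flux_balance <- function(h2o2_field, o2_field) {
  stopifnot(h2o2_field$species == "H2O2", o2_field$species == "O2")
  grid <- h2o2_field$grid
  cst <- h2o2_field$constants
  e <- grid$electrode
  c_surf <- .surface_o2(grid, o2_field$values, h2o2_field$k_O2, cst$D_O2)
  prod <- sum(h2o2_field$k_gen * c_surf * e$area * e$corr)
  out <- sum(grid$dirichlet$g * cst$D_H2O2 * h2o2_field$values[grid$dirichlet$cell])
  list(production = prod, efflux = out,
       rel_imbalance = if (prod == 0) NA_real_ else abs(prod - out) / prod)
}

# area-weighted mean; the primitive behind lateral averaging
.area_weighted_mean <- function(values, areas) {
  stopifnot(length(values) == length(areas), all(areas >= 0), sum(areas) > 0)
  sum(values * areas) / sum(areas)
}

# heights of the standard 20-point profile ladder, um
profile_heights <- function() seq(5, 100, by = 5)

#' Extract the laterally averaged z-profile of a solved field
#'
#' At each of the 20 standard heights z = 5, 10, ..., 100 um (measured
#' from the wire base plane), computes the mean concentration over the
#' electrolyte cross-section of the unit cell at that height (the wire
#' interior is excluded below the wire top). Cross-section averages are
#' area-weighted per grid layer and interpolated linearly onto the
#' 5-um ladder; heights at or above the bulk plane report the bulk value
#' (the bulk O2 concentration, or zero for H2O2).
#'
#' @param field a \code{concentration_field}.
#' @return a \code{gradient_profile}: list with \code{species},
#'   \code{z} (um), \code{values} (mM).
#' @export
extract_profile <- function(field) {
  stopifnot(inherits(field, "concentration_field"))
  grid <- field$grid
  nlayer <- length(grid$layer_z)
  means <- vapply(seq_len(nlayer), function(l) {
    sel <- grid$layer == l
    .area_weighted_mean(field$values[sel], grid$xarea[sel])
  }, numeric(1))
  zs <- c(grid$layer_z, grid$z_bulk)
  ms <- c(means, field$bulk)
  zq <- profile_heights()
  vals <- numeric(length(zq))
  below <- zq < grid$z_bulk
  if (any(below))
    vals[below] <- stats::approx(zs, ms, xout = zq[below], rule = 2)$y
  vals[!below] <- field$bulk
  structure(list(species = field$species, z = zq, values = vals),
            class = "gradient_profile")
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat(sprintf("<gradient_profile> %s, %d points, z = %g..%g um\n",
              x$species, length(x$z), min(x$z), max(x$z)))
  print(round(stats::setNames(x$values, paste0("z", x$z)), 5))
  invisible(x)
}

#' Simulate the O2 and H2O2 gradient profiles for one condition
#'
#' One-call convenience: builds the unit-cell grid, solves the O2
#' problem, solves the H2O2 problem (identically zero for catalysts
#' without a 2-electron channel), and extracts both 20-point laterally
#' averaged profiles. Fully deterministic: identical inputs give
#' bit-identical outputs.
#'
#' @param morph a \code{\link{morphology}} (or numeric c(P, D, L)).
#' @param catalyst \code{"pt"}, \code{"au"}, or a
#'   \code{\link{catalyst_kinetics}} object.
#' @param E_appl applied potential, V vs RHE.
#' @param resolution passed to \code{\link{build_grid}}.
#' @param mode \code{"axisym"} (default) or \code{"cartesian3d"}.
#' @param include_base is the substrate base active? Default TRUE.
#' @param constants a \code{\link{phys_constants}}.
#' @param keep_fields also return the full concentration fields.
#' @return list with \code{o2}, \code{h2o2} (both
#'   \code{gradient_profile}) and, if requested, \code{o2_field},
#'   \code{h2o2_field}, \code{grid}.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_gradients(morphology(15, 4, 50), "pt", 0.5)
#' sim$o2$values   # strongly depleted inside the array
#' }
simulate_gradients <- function(morph, catalyst, E_appl, resolution = 1,
                               mode = c("axisym", "cartesian3d"),
                               include_base = TRUE,
                               constants = phys_constants(),
                               keep_fields = FALSE) {
  if (!inherits(morph, "morphology")) morph <- morphology(morph[1], morph[2], morph[3])
  kin <- if (inherits(catalyst, "catalyst_kinetics")) catalyst else catalyst_kinetics(catalyst)
  mode <- match.arg(mode)
  grid <- build_grid(morph, kin, resolution = resolution, mode = mode,
                     include_base = include_base)
  fo <- solve_o2(grid, kin, E_appl, constants)
  fh <- solve_h2o2(grid, kin, E_appl, fo, constants)
  out <- list(o2 = extract_profile(fo), h2o2 = extract_profile(fh))
  if (keep_fields) {
    out$o2_field <- fo
    out$h2o2_field <- fh
    out$grid <- grid
  }
  out
}

#' One-dimensional planar reference grid
#'
#' A quasi-1D column grid for validating the solver against the closed
#' form for a flat active plane at z = 0 beneath a bulk (Dirichlet)
#' plane at z = dD: the steady profile is linear with surface value
#' \code{c(0) = C_bulk * D / (D + k_O2 * dD)}.
#'
#' @param dD_um column height (bulk-plane distance), um.
#' @param n number of cells.
#' @return a \code{unit_cell_grid} whose only electrode patch is the
#'   base plane.
#' @export
planar_reference_grid <- function(dD_um = 20, n = 60) {
  um <- 1e-6
  zf <- seq(0, dD_um, length.out = n + 1L)
  zc <- (zf[-1] + zf[-length(zf)]) / 2
  A <- 1  # m^2; cancels everywhere
  faces <- data.frame(i = seq_len(n - 1L), j = seq_len(n - 1L) + 1L,
                      g = A / (diff(zc) * um))
  dirichlet <- data.frame(cell = n, g = A / ((dD_um - zc[n]) * um))
  electrode <- data.frame(cell = 1L, area = A, dh = zc[1] * um,
                          group = "base", corr = 1)
  structure(list(mode = "planar1d", n = n, faces = faces,
                 dirichlet = dirichlet, electrode = electrode,
                 layer = seq_len(n), layer_z = zc, xarea = rep(1, n),
                 cell_z = zc, z_bulk = dD_um, height = dD_um,
                 include_base = TRUE, kin_name = "custom", dD = dD_um,
                 morph = structure(list(P = NA, D = NA, L = 0),
                                   class = "morphology")),
            class = "unit_cell_grid")
}
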