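#' Wire-array morphology vector
#'
#' The morphology of a periodic microwire-array electrode is described by
#' three lengths in micrometers: the lattice periodicity \code{P}, the
#' wire diameter \code{D} and the wire length \code{L}. The admissible
#' morphology block is \code{P} in [1, 100], \code{D} in [0.2, 10],
#' \code{L} in [1, 150], with \code{D < P} so neighbouring wires do not
#' touch.
#'
#' @param P lattice periodicity, um.
#' @param D wire diameter, um.
#' @param L wire length, um.
#' @return a \code{morphology} object (named list \code{P}, \code{D},
#'   \code{L}).
#' @export
#' @examples
#' morphology(15, 4, 50)
morphology <- function(P, D, L) {
  stopifnot(is.numeric(P), is.numeric(D), is.numeric(L),
            length(P) == 1L, length(D) == 1L, length(L) == 1L)
  P <- unname(P); D <- unname(D); L <- unname(L)
  if (!(P >= 1 && P <= 100)) stop("P must be in [1, 100] um, got ", P)
  if (!(D >= 0.2 && D <= 10)) stop("D must be in [0.2, 10] um, got ", D)
  if (!(L >= 1 && L <= 150)) stop("L must be in [1, 150] um, got ", L)
  if (D >= P) stop(sprintf("wire diameter D = %g must be smaller than the periodicity P = %g", D, P))
  structure(list(P = P, D = D, L = L), class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("<morphology> k = (P, D, L) = (%g, %g, %g) um\n", x$P, x$D, x$L))
  invisible(x)
}

#' Analytic electrode surface area of one unit cell
#'
#' Closed-form surface area of one wire (lateral surface plus top disc),
#' optionally plus the exposed base annulus of the unit cell when the
#' substrate between wires is catalytically active. Serves as the oracle
#' for the discretized electrode area carried by a grid.
#'
#' @param morph a \code{\link{morphology}}.
#' @param include_base logical; add the base area \code{P^2 - pi D^2/4}.
#' @return area in um^2.
#' @export
#' @examples
#' analytic_electrode_area(morphology(15, 4, 50))  # ~ 641 um^2 + base
analytic_electrode_area <- function(morph, include_base = TRUE) {
  stopifnot(inherits(morph, "morphology"))
  a <- pi * morph$D * morph$L + pi * morph$D^2 / 4
  if (include_base) a <- a + morph$P^2 - pi * morph$D^2 / 4
  a
}

# Resolve resolution argument into per-segment cell counts.
# `resolution` is either a single positive refinement factor (1 = default
# density) or a named list overriding any of nr_in, nr_out, nz_wire,
# nz_top, nxy directly.
.grid_counts <- function(resolution) {
  cnt <- list(nr_in = 3L, nr_out = 14L, nz_wire = 22L, nz_top = 6L, nxy = 10L)
  if (is.numeric(resolution)) {
    stopifnot(length(resolution) == 1L, is.finite(resolution))
    if (resolution <= 0) stop("resolution factor must be positive")
    f <- resolution
    cnt <- list(nr_in = max(2L, as.integer(ceiling(3 * f))),
                nr_out = max(6L, as.integer(ceiling(14 * f))),
                nz_wire = max(20L, as.integer(ceiling(22 * f))),
                nz_top = max(4L, as.integer(ceiling(6 * f))),
                nxy = max(6L, as.integer(ceiling(10 * f))))
  } else if (is.list(resolution)) {
    for (nm in names(resolution)) {
      if (!nm %in% names(cnt)) stop("unknown resolution field: ", nm)
      cnt[[nm]] <- as.integer(resolution[[nm]])
    }
    if (cnt$nz_wire < 20L)
      stop(sprintf("resolution too coarse: need >= 20 cells along the wire (got %d); use nz_wire >= 20", cnt$nz_wire))
    if (cnt$nz_top < 4L)
      stop(sprintf("resolution too coarse: need >= 4 cells across the boundary layer dD (got %d); use nz_top >= 4", cnt$nz_top))
  } else stop("resolution must be a numeric factor or a list of cell counts")
  cnt
}

#' Build the discretized unit-cell domain for one wire
#'
#' Discretizes the periodic unit cell of the wire array into a
#' finite-volume grid and classifies each location as wire interior
#' (excluded from the solve), electrolyte, electrode surface patch, bulk
#' (Dirichlet) boundary, or zero-flux symmetry face. Two modes:
#' \describe{
#'   \item{axisym}{the default. The square unit cell is replaced by the
#'     equal-area disk of radius \code{P/sqrt(pi)} around the centred
#'     wire and the problem solved in cylindrical (r, z) coordinates.
#'     Grid lines conform exactly to the wire wall and top, so electrode
#'     patch areas are analytic.}
#'   \item{cartesian3d}{a full 3-D solve on the quarter unit cell
#'     (both in-cell mirror planes exploited). The cylindrical wire is
#'     voxelised; electrode patches carry true-area/discretized-area
#'     correction factors so the total electrode area is exact at any
#'     resolution.}
#' }
#' Bulk conditions are imposed on the plane \code{z_bulk = min(L + dD,
#' height)}: every cell at or above it holds the bulk concentration. The
#' periodic lateral boundary is realised as zero-flux mirror faces, which
#' is exact for a square lattice with centred wires.
#'
#' @param morph a \code{\link{morphology}}.
#' @param kin a \code{\link{catalyst_kinetics}} (supplies dD).
#' @param resolution refinement factor (default 1) or a list of explicit
#'   cell counts (\code{nr_in}, \code{nr_out}, \code{nz_wire},
#'   \code{nz_top}, \code{nxy}).
#' @param mode \code{"axisym"} or \code{"cartesian3d"}.
#' @param include_base is the substrate between wires electrochemically
#'   active? The sputtered catalyst coats the exposed base conformally,
#'   so the default is \code{TRUE}.
#' @param height domain height, um.
#' @return a \code{unit_cell_grid} object; see Details in the package
#'   vignette. Key fields: \code{n} (number of unknown cells),
#'   \code{faces} (interior conductances), \code{dirichlet} (bulk-plane
#'   couplings), \code{electrode} (surface patches with areas, m^2, and
#'   correction factors), \code{layer}/\code{layer_z}/\code{xarea}
#'   (lateral-averaging metadata), \code{z_bulk}.
#' @export
build_grid <- function(morph, kin, resolution = 1,
                       mode = c("axisym", "cartesian3d"),
                       include_base = TRUE, height = 200) {
  stopifnot(inherits(morph, "morphology"), inherits(kin, "catalyst_kinetics"))
  mode <- match.arg(mode)
  cnt <- .grid_counts(resolution)
  z_bulk <- min(morph$L + kin$dD, height)
  g <- if (mode == "axisym")
    .build_grid_axisym(morph, z_bulk, cnt, include_base)
  else
    .build_grid_cart3d(morph, z_bulk, cnt, include_base)
  g$mode <- mode
  g$morph <- morph
  g$kin_name <- kin$name
  g$dD <- kin$dD
  g$include_base <- include_base
  g$height <- height
  g$z_bulk <- z_bulk
  g$counts <- cnt
  class(g) <- "unit_cell_grid"
  g
}

# axisymmetric (r, z) finite-volume grid on the equal-area disk
.build_grid_axisym <- function(morph, z_bulk, cnt, include_base) {
  um <- 1e-6
  rw <- morph$D / 2
  R <- morph$P / sqrt(pi)
  L <- morph$L

  rf <- c(seq(0, rw, length.out = cnt$nr_in + 1L),
          seq(rw, R, length.out = cnt$nr_out + 1L)[-1])
  zf <- c(seq(0, L, length.out = cnt$nz_wire + 1L),
          seq(L, z_bulk, length.out = cnt$nz_top + 1L)[-1])
  nr <- length(rf) - 1L
  nz <- length(zf) - 1L
  rc <- (rf[-1] + rf[-length(rf)]) / 2
  zc <- (zf[-1] + zf[-length(zf)]) / 2
  dr <- diff(rf)
  dz <- diff(zf)
  iw <- cnt$nr_in          # wire occupies ir <= iw for iz <= izL
  izL <- cnt$nz_wire       # wire top at zf[izL + 1] == L

  is_wire <- outer(seq_len(nr) <= iw, seq_len(nz) <= izL, "&")
  id <- matrix(NA_integer_, nr, nz)
  id[!is_wire] <- seq_len(sum(!is_wire))
  n <- sum(!is_wire)

  # interior radial faces: between (ir, iz) and (ir+1, iz)
  ir <- rep(seq_len(nr - 1L), nz)
  iz <- rep(seq_len(nz), each = nr - 1L)
  ok <- !is_wire[cbind(ir, iz)] & !is_wire[cbind(ir + 1L, iz)]
  A_r <- 2 * pi * (rf[ir + 1L] * um) * (dz[iz] * um)
  d_r <- (rc[ir + 1L] - rc[ir]) * um
  fr <- data.frame(i = id[cbind(ir, iz)][ok], j = id[cbind(ir + 1L, iz)][ok],
                   g = (A_r / d_r)[ok])

  # interior axial faces: between (ir, iz) and (ir, iz+1)
  ir2 <- rep(seq_len(nr), nz - 1L)
  iz2 <- rep(seq_len(nz - 1L), each = nr)
  ok2 <- !is_wire[cbind(ir2, iz2)] & !is_wire[cbind(ir2, iz2 + 1L)]
  A_z <- pi * ((rf[ir2 + 1L]^2 - rf[ir2]^2) * um^2)
  d_z <- (zc[iz2 + 1L] - zc[iz2]) * um
  fz <- data.frame(i = id[cbind(ir2, iz2)][ok2], j = id[cbind(ir2, iz2 + 1L)][ok2],
                   g = (A_z / d_z)[ok2])

  faces <- rbind(fr, fz)

  # Dirichlet couplings on the bulk plane z = z_bulk (top row of cells)
  topcells <- id[, nz]
  g_dir <- pi * ((rf[-1]^2 - rf[-length(rf)]^2) * um^2) / ((z_bulk - zc[nz]) * um)
  dirichlet <- data.frame(cell = topcells, g = g_dir)

  # electrode patches (areas conform exactly; correction factors unity)
  elec <- list()
  # lateral wall at r = rw, electrolyte cell ir = iw + 1, iz <= izL
  elec$lat <- data.frame(cell = id[cbind(rep(iw + 1L, izL), seq_len(izL))],
                         area = 2 * pi * (rw * um) * (dz[seq_len(izL)] * um),
                         dh = (rc[iw + 1L] - rw) * um,
                         group = "lateral", corr = 1)
  # wire top at z = L, electrolyte cells ir <= iw, iz = izL + 1
  elec$top <- data.frame(cell = id[cbind(seq_len(iw), rep(izL + 1L, iw))],
                         area = pi * ((rf[2:(iw + 1L)]^2 - rf[seq_len(iw)]^2) * um^2),
                         dh = (zc[izL + 1L] - L) * um,
                         group = "top", corr = 1)
  if (include_base) {
    irb <- (iw + 1L):nr
    elec$base <- data.frame(cell = id[cbind(irb, rep(1L, length(irb)))],
                            area = pi * ((rf[irb + 1L]^2 - rf[irb]^2) * um^2),
                            dh = zc[1] * um,
                            group = "base", corr = 1)
  }
  electrode <- do.call(rbind, elec)
  rownames(electrode) <- NULL

  # lateral-averaging metadata: layer index per cell, z centers, cross areas
  layer <- integer(n)
  xarea <- numeric(n)
  cell_xa <- pi * (rf[-1]^2 - rf[-length(rf)]^2)   # um^2, relative weights
  for (izz in seq_len(nz)) {
    cc <- id[, izz]
    sel <- !is.na(cc)
    layer[cc[sel]] <- izz
    xarea[cc[sel]] <- cell_xa[sel]
  }
  list(n = n, faces = faces, dirichlet = dirichlet, electrode = electrode,
       layer = layer, layer_z = zc, xarea = xarea,
       cell_z = zc[layer])
}

# quarter-cell 3-D cartesian finite-volume grid (voxelised wire)
.build_grid_cart3d <- function(morph, z_bulk, cnt, include_base) {
  um <- 1e-6
  rw <- morph$D / 2
  half <- morph$P / 2
  L <- morph$L

  xf <- seq(0, half, length.out = cnt$nxy + 1L)
  zf <- c(seq(0, L, length.out = cnt$nz_wire + 1L),
          seq(L, z_bulk, length.out = cnt$nz_top + 1L)[-1])
  nx <- length(xf) - 1L
  nz <- length(zf) - 1L
  xc <- (xf[-1] + xf[-length(xf)]) / 2
  zc <- (zf[-1] + zf[-length(zf)]) / 2
  dx <- diff(xf)
  dz <- diff(zf)
  izL <- cnt$nz_wire

  # wire classification by cell-centre radius from the corner (0, 0);
  # guarantee at least the corner column so thin wires keep a surface
  inside <- outer(xc, xc, function(a, b) sqrt(a^2 + b^2)) <= rw
  if (!any(inside)) inside[1, 1] <- TRUE

  is_wire3 <- array(FALSE, c(nx, nx, nz))
  for (izz in seq_len(izL)) is_wire3[, , izz] <- inside
  id <- array(NA_integer_, c(nx, nx, nz))
  id[!is_wire3] <- seq_len(sum(!is_wire3))
  n <- sum(!is_wire3)

  idx3 <- function(ix, iy, iz) cbind(ix, iy, iz)
  faces <- list()
  elec_lat <- list()

  # x-direction neighbours (and symmetric y by transposition)
  for (dir in c("x", "y")) {
    ia <- rep(seq_len(nx - 1L), times = nx * nz)
    ib <- rep(rep(seq_len(nx), each = nx - 1L), times = nz)
    iz <- rep(seq_len(nz), each = (nx - 1L) * nx)
    if (dir == "x") { ix1 <- ia; iy1 <- ib } else { ix1 <- ib; iy1 <- ia }
    ix2 <- if (dir == "x") ix1 + 1L else ix1
    iy2 <- if (dir == "y") iy1 + 1L else iy1
    w1 <- is_wire3[idx3(ix1, iy1, iz)]
    w2 <- is_wire3[idx3(ix2, iy2, iz)]
    Af <- (if (dir == "x") dx[iy1] else dx[ix1]) * dz[iz] * um^2
    dd <- (if (dir == "x") (xc[ix2] - xc[ix1]) else (xc[iy2] - xc[iy1])) * um
    both <- !w1 & !w2
    faces[[dir]] <- data.frame(i = id[idx3(ix1, iy1, iz)][both],
                               j = id[idx3(ix2, iy2, iz)][both],
                               g = (Af / dd)[both])
    # electrode: wire on one side, electrolyte on the other (lateral wall)
    e12 <- w1 & !w2
    e21 <- !w1 & w2
    elec_lat[[dir]] <- data.frame(
      cell = c(id[idx3(ix2, iy2, iz)][e12], id[idx3(ix1, iy1, iz)][e21]),
      area = c(Af[e12], Af[e21]),
      dh = c(dd[e12] / 2, dd[e21] / 2))
  }

  # z-direction neighbours
  ix <- rep(seq_len(nx), times = nx * (nz - 1L))
  iy <- rep(rep(seq_len(nx), each = nx), times = nz - 1L)
  iz <- rep(seq_len(nz - 1L), each = nx * nx)
  w1 <- is_wire3[idx3(ix, iy, iz)]
  w2 <- is_wire3[idx3(ix, iy, iz + 1L)]
  Af <- dx[ix] * dx[iy] * um^2
  dd <- (zc[iz + 1L] - zc[iz]) * um
  both <- !w1 & !w2
  faces$z <- data.frame(i = id[idx3(ix, iy, iz)][both],
                        j = id[idx3(ix, iy, iz + 1L)][both],
                        g = (Af / dd)[both])
  # wire-top electrode: wire below, electrolyte above
  etop <- w1 & !w2
  elec_top <- data.frame(cell = id[idx3(ix, iy, iz + 1L)][etop],
                         area = Af[etop],
                         dh = dd[etop] / 2)

  faces <- do.call(rbind, faces)

  # Dirichlet couplings on the bulk plane
  ixd <- rep(seq_len(nx), nx)
  iyd <- rep(seq_len(nx), each = nx)
  dirichlet <- data.frame(cell = id[idx3(ixd, iyd, rep(nz, nx * nx))],
                          g = dx[ixd] * dx[iyd] * um^2 / ((z_bulk - zc[nz]) * um))

  # area-correction factors per patch group (quarter cell)
  lat <- do.call(rbind, elec_lat)
  true_lat <- (pi / 2) * (rw * um) * (L * um)
  lat$group <- "lateral"
  lat$corr <- true_lat / sum(lat$area)
  foot_disc <- sum((dx[rep(seq_len(nx), nx)] * dx[rep(seq_len(nx), each = nx)])[inside]) * um^2
  true_top <- (pi / 4) * (rw * um)^2
  elec_top$group <- "top"
  elec_top$corr <- true_top / sum(elec_top$area)
  electrode <- rbind(lat, elec_top)
  if (include_base) {
    base_ok <- !inside
    ixb <- rep(seq_len(nx), nx)[base_ok]
    iyb <- rep(seq_len(nx), each = nx)[base_ok]
    eb <- data.frame(cell = id[idx3(ixb, iyb, rep(1L, length(ixb)))],
                     area = dx[ixb] * dx[iyb] * um^2,
                     dh = zc[1] * um, group = "base")
    eb$corr <- ((half * um)^2 - true_top) / sum(eb$area)
    electrode <- rbind(electrode, eb)
  }
  rownames(electrode) <- NULL

  layer <- integer(n)
  xarea <- numeric(n)
  xa2 <- outer(dx, dx)   # um^2 weights
  for (izz in seq_len(nz)) {
    cc <- id[, , izz]
    sel <- !is.na(cc)
    layer[cc[sel]] <- izz
    xarea[cc[sel]] <- xa2[sel]
  }
  list(n = n, faces = faces, dirichlet = dirichlet, electrode = electrode,
       layer = layer, layer_z = zc, xarea = xarea, cell_z = zc[layer])
}

#' Discretized electrode area carried by a grid
#'
#' Sum of (patch area x correction factor) over all electrode patches, in
#' um^2. Matches \code{\link{analytic_electrode_area}} by construction.
#'
#' @param grid a \code{unit_cell_grid}.
#' @return area in um^2 (full unit cell).
#' @export
grid_electrode_area <- function(grid) {
  stopifnot(inherits(grid, "unit_cell_grid"))
  a <- sum(grid$electrode$area * grid$electrode$corr) * 1e12
  if (grid$mode == "cartesian3d") a <- a * 4   # quarter cell solved
  a
}

#' @export
print.unit_cell_grid <- function(x, ...) {
  cat(sprintf("<unit_cell_grid> %s, k = (%g, %g, %g) um, %s catalyst\n",
              x$mode, x$morph$P, x$morph$D, x$morph$L, x$kin_name))
  cat(sprintf("  %d cells, z_bulk = %g um, base %s, %d electrode patches\n",
              x$n, x$z_bulk, if (x$include_base) "active" else "inert",
              nrow(x$electrode)))
  invisible(x)
}
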