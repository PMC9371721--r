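#' Physical constants for gradient simulations
#'
#' Returns the set of physical constants used throughout the package:
#' Faraday and gas constants, temperature, diffusivities of O2 and H2O2 in
#' aqueous solution, the air-saturated bulk O2 concentration, and the
#' standard potential of the O2/H2O couple. Any field can be overridden,
#' e.g. for sensitivity studies at a different temperature.
#'
#' @param T_K temperature in kelvin. Room temperature by default.
#' @param D_O2 O2 diffusivity, m^2/s.
#' @param D_H2O2 H2O2 diffusivity, m^2/s.
#' @param C_O2_bulk air-saturated O2 concentration, mol/m^3 (numerically
#'   equal to mM).
#' @param E0_O2_H2O standard potential of the O2/H2O couple, V vs RHE.
#' @return an object of class \code{phys_constants}: a named list with
#'   fields \code{F}, \code{R}, \code{T}, \code{D_O2}, \code{D_H2O2},
#'   \code{C_O2_bulk}, \code{E0_O2_H2O}.
#' @export
#' @examples
#' pc <- phys_constants()
#' pc$C_O2_bulk   # 0.246 mol/m^3 = 246 uM
phys_constants <- function(T_K = 298.15,
                           D_O2 = 2.2e-9,
                           D_H2O2 = 1.5e-9,
                           C_O2_bulk = 0.246,
                           E0_O2_H2O = 1.23) {
  vals <- list(F = 96485.33212, R = 8.314462618, T = T_K,
               D_O2 = D_O2, D_H2O2 = D_H2O2,
               C_O2_bulk = C_O2_bulk, E0_O2_H2O = E0_O2_H2O)
  bad <- names(vals)[!vapply(vals, function(v) is.numeric(v) && length(v) == 1L &&
                               is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("physical constants must be strictly positive finite scalars: ",
         paste(bad, collapse = ", "))
  structure(vals, class = "phys_constants")
}

# Operating potential window, V vs RHE (ORR window used for all runs).
.EAPPL_WINDOW <- c(0.2, 0.6)

#' Cathodic overpotential of the oxygen reduction reaction
#'
#' The overpotential is the applied potential minus the standard potential
#' of the O2/H2O couple (1.23 V vs RHE); it is negative throughout the
#' operating window, i.e. the electrode runs cathodically.
#'
#' @param E_appl applied potential, V vs RHE.
#' @param constants a \code{\link{phys_constants}} object.
#' @param window allowed potential window, V vs RHE; pass \code{NULL} to
#'   skip the check (used when evaluating at the standard potential).
#' @return overpotential eta in volts.
#' @export
#' @examples
#' overpotential(0.5)   # -0.73 V
overpotential <- function(E_appl, constants = phys_constants(),
                          window = .EAPPL_WINDOW) {
  stopifnot(is.numeric(E_appl), all(is.finite(E_appl)))
  if (!is.null(window) && any(E_appl < window[1] - 1e-12 | E_appl > window[2] + 1e-12))
    stop(sprintf("E_appl = %g V vs RHE outside the operating window [%g, %g] V",
                 E_appl[which(E_appl < window[1] | E_appl > window[2])[1]],
                 window[1], window[2]))
  E_appl - constants$E0_O2_H2O
}

#' Define one ORR reaction channel
#'
#' A channel is one parallel pathway of the oxygen reduction reaction at
#' the electrode surface, parameterised by concentration-dependent Tafel
#' kinetics: exchange current density \code{i0}, electron-transfer number
#' before the rate-determining step \code{n_rds}, total electrons consumed
#' per O2 \code{n_stoich} (4 for reduction to water, 2 for reduction to
#' H2O2), and cathodic transfer coefficient \code{alpha_c}.
#'
#' @param i0 exchange current density, A/m^2 (>= 0; zero makes the
#'   channel, and hence the electrode, inert).
#' @param n_rds electron-transfer number before the rate-determining step.
#' @param n_stoich total electrons per O2; must be 2 or 4.
#' @param alpha_c cathodic transfer coefficient in (0, 1].
#' @return an \code{orr_channel} object.
#' @export
orr_channel <- function(i0, n_rds, n_stoich, alpha_c = 0.5) {
  stopifnot(is.numeric(i0), length(i0) == 1L, i0 >= 0,
            is.numeric(n_rds), length(n_rds) == 1L, n_rds > 0,
            n_stoich %in% c(2, 4),
            is.numeric(alpha_c), alpha_c > 0, alpha_c <= 1)
  structure(list(i0 = i0, n_rds = n_rds, n_stoich = as.numeric(n_stoich),
                 alpha_c = alpha_c),
            class = "orr_channel")
}

#' Catalyst kinetics: the set of ORR channels on one electrocatalyst
#'
#' Bundles the reaction channels active on a catalyst surface together
#' with the diffusion-boundary-layer distance \code{dD} above the wire
#' tops at which bulk conditions are imposed. Shipped defaults:
#' \describe{
#'   \item{pt}{a single 4-electron channel, i0 = 3.0e-6 A/m^2, n_rds = 1;
#'     dD = 20 um. Pt reduces O2 fully to water, generating pure O2
#'     depletion gradients.}
#'   \item{au}{a 4-electron channel (i0 = 2.0e-8 A/m^2, n_rds = 1) in
#'     parallel with a 2-electron channel (i0 = 8.0e-7 A/m^2,
#'     n_rds = 0.7) producing H2O2; dD = 50 um.}
#' }
#'
#' @param name \code{"pt"}, \code{"au"}, or a path to a catalyst JSON file
#'   with fields \code{name}, \code{dD_um}, \code{channels} (each channel
#'   carrying \code{i0_A_per_m2}, \code{n_rds}, \code{n_stoich},
#'   \code{alpha_c}).
#' @return a \code{catalyst_kinetics} object with fields \code{name},
#'   \code{channels} (list of \code{\link{orr_channel}}), \code{dD} (um).
#' @export
#' @examples
#' catalyst_kinetics("pt")$dD    # 20
#' length(catalyst_kinetics("au")$channels)  # 2
catalyst_kinetics <- function(name = c("pt", "au")) {
  if (length(name) == 1L && file.exists(name)) return(read_catalyst_json(name))
  name <- match.arg(tolower(name[1]), c("pt", "au"))
  path <- system.file("extdata", paste0(name, ".json"), package = "gradientforge")
  if (nzchar(path)) return(read_catalyst_json(path))
  # fallback when called from a source tree without installation
  if (name == "pt") {
    structure(list(name = "pt",
                   channels = list(orr_channel(3.0e-6, 1, 4)),
                   dD = 20), class = "catalyst_kinetics")
  } else {
    structure(list(name = "au",
                   channels = list(orr_channel(2.0e-8, 1, 4),
                                   orr_channel(8.0e-7, 0.7, 2)),
                   dD = 50), class = "catalyst_kinetics")
  }
}

#' Read catalyst kinetics from a JSON file
#' @param path file path.
#' @return a \code{catalyst_kinetics} object.
#' @export
read_catalyst_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$name) || is.null(x$dD_um) || is.null(x$channels))
    stop("catalyst JSON must carry fields name, dD_um, channels: ", path)
  ch <- lapply(x$channels, function(c)
    orr_channel(i0 = c$i0_A_per_m2, n_rds = c$n_rds,
                n_stoich = c$n_stoich,
                alpha_c = if (is.null(c$alpha_c)) 0.5 else c$alpha_c))
  structure(list(name = x$name, channels = ch, dD = x$dD_um),
            class = "catalyst_kinetics")
}

#' Write catalyst kinetics to a JSON file
#' @param kin a \code{catalyst_kinetics} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_catalyst_json <- function(kin, path) {
  stopifnot(inherits(kin, "catalyst_kinetics"))
  x <- list(name = kin$name, dD_um = kin$dD,
            channels = lapply(kin$channels, function(c)
              list(i0_A_per_m2 = c$i0, n_rds = c$n_rds,
                   n_stoich = c$n_stoich, alpha_c = c$alpha_c)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Tafel current density of a single ORR channel
#'
#' Concentration-dependent Tafel law: the cathodic current density is
#' proportional to the local O2 concentration and exponential in the
#' overpotential,
#' \deqn{i = -i_0 \frac{[O_2]}{C_{O_2}} \exp\!\left(-\frac{\alpha_c F \eta\, n_{rds}}{RT}\right).}
#' The sign convention is electrochemical: cathodic (reducing) current is
#' negative.
#'
#' @param ch an \code{\link{orr_channel}}.
#' @param eta overpotential, V (negative under cathodic operation).
#' @param c_O2 local O2 concentration, mol/m^3 (>= 0).
#' @param constants a \code{\link{phys_constants}} object.
#' @return current density, A/m^2 (<= 0 for c_O2 >= 0).
#' @export
channel_current_density <- function(ch, eta, c_O2, constants = phys_constants()) {
  stopifnot(inherits(ch, "orr_channel"), is.finite(eta))
  if (any(c_O2 < 0)) stop("negative O2 concentration is non-physical")
  -ch$i0 * (c_O2 / constants$C_O2_bulk) *
    exp(-ch$alpha_c * constants$F * eta * ch$n_rds / (constants$R * constants$T))
}

#' Species fluxes at the electrode surface
#'
#' Converts the per-channel Tafel currents into molar fluxes of O2 and
#' H2O2 through the electrode surface. The convention is that a positive
#' flux is directed into the electrolyte, so O2 (consumed) always has
#' \code{J_O2 <= 0} and H2O2 (produced by 2-electron channels)
#' \code{J_H2O2 >= 0}. Each channel contributes \code{i/(n_stoich F)} to
#' the O2 flux; 2-electron channels additionally inject
#' \code{-i/(2F)} of H2O2.
#'
#' @param kin a \code{\link{catalyst_kinetics}} object.
#' @param eta overpotential, V.
#' @param c_O2 local O2 concentration, mol/m^3.
#' @param constants a \code{\link{phys_constants}} object.
#' @return named list \code{J_O2}, \code{J_H2O2} in mol/(m^2 s).
#' @export
surface_fluxes <- function(kin, eta, c_O2, constants = phys_constants()) {
  stopifnot(inherits(kin, "catalyst_kinetics"))
  J_O2 <- 0
  J_H2O2 <- 0
  for (ch in kin$channels) {
    i <- channel_current_density(ch, eta, c_O2, constants)
    J_O2 <- J_O2 + i / (ch$n_stoich * constants$F)
    if (ch$n_stoich == 2) J_H2O2 <- J_H2O2 - i / (2 * constants$F)
  }
  list(J_O2 = J_O2, J_H2O2 = J_H2O2)
}

#' Effective first-order surface rate constants
#'
#' Because the Tafel currents are linear in the local O2 concentration,
#' the boundary condition on every electrode patch can be written as
#' \code{J_O2 = -k_O2 * c_O2} and \code{J_H2O2 = +k_gen * c_O2}, with rate
#' constants (m/s) that depend only on the catalyst and the overpotential.
#' This factorisation is what makes the steady-state diffusion problem a
#' single sparse linear solve per species.
#'
#' @inheritParams surface_fluxes
#' @return named list \code{k_O2}, \code{k_gen}, both in m/s, both >= 0.
#' @export
#' @examples
#' effective_rate_constants(catalyst_kinetics("pt"), overpotential(0.5))
effective_rate_constants <- function(kin, eta, constants = phys_constants()) {
  stopifnot(inherits(kin, "catalyst_kinetics"), is.finite(eta))
  k_O2 <- 0
  k_gen <- 0
  for (ch in kin$channels) {
    ex <- ch$i0 * exp(-ch$alpha_c * constants$F * eta * ch$n_rds /
                        (constants$R * constants$T))
    k_O2 <- k_O2 + ex / (ch$n_stoich * constants$F * constants$C_O2_bulk)
    if (ch$n_stoich == 2)
      k_gen <- k_gen + ex / (2 * constants$F * constants$C_O2_bulk)
  }
  list(k_O2 = k_O2, k_gen = k_gen)
}

#' @export
print.catalyst_kinetics <- function(x, ...) {
  cat(sprintf("<catalyst_kinetics> %s, dD = %g um, %d channel(s)\n",
              x$name, x$dD, length(x$channels)))
  for (ch in x$channels)
    cat(sprintf("  %de- channel: i0 = %g A/m^2, n_rds = %g, alpha_c = %g\n",
                ch$n_stoich, ch$i0, ch$n_rds, ch$alpha_c))
  invisible(x)
}
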