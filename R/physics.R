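# Proton stopping-power physics: Bethe-Bloch evaluation, CSDA ranges,
# WEPL <-> energy conversion, and the Highland multiple-scattering model.

#' Squared proton velocity relative to c
#'
#' Relativistic kinematics: `beta^2 = 1 - (m_p c^2 / (E + m_p c^2))^2` for
#' kinetic energy `E`.
#'
#' @param E proton kinetic energy, MeV (vectorised).
#' @param constants a [pct_constants()] object.
#' @return beta^2, dimensionless, in (0, 1).
#' @export
beta_sq <- function(E, constants = pct_constants()) {
  if (any(E <= 0)) stop("beta_sq: kinetic energy must be positive")
  1 - (constants$m_p_c2 / (E + constants$m_p_c2))^2
}

#' Bethe-Bloch stopping power
#'
#' Evaluates `-dE/dx = eta_e * K/beta^2 * (ln(2 m_e c^2 beta^2 / (I (1 - beta^2))) - beta^2)`
#' in MeV/cm. The prefactor `K` absorbs the material-independent physical
#' constants for unit relative electron density; material dependence enters
#' through `eta_e` and the mean excitation energy `I`. No shell or density
#' corrections are applied.
#'
#' @param mat a `pct_material` (or material name resolved via [pct_materials()]).
#' @param E proton kinetic energy, MeV (vectorised).
#' @param constants a [pct_constants()] object.
#' @param check if `TRUE` (default), error outside the validity range.
#' @return stopping power, MeV/cm.
#' @export
stopping_power <- function(mat, E, constants = pct_constants(), check = TRUE) {
  if (is.character(mat)) mat <- pct_materials(mat)
  if (check && any(E < constants$E_floor | E > constants$E_max))
    stop(sprintf("stopping_power: E outside validity range [%g, %g] MeV",
                 constants$E_floor, constants$E_max))
  b2 <- beta_sq(E, constants)
  I_MeV <- mat$mean_excitation_I * 1e-6
  f <- constants$K / b2 * (log(2 * constants$m_e_c2 * b2 / (I_MeV * (1 - b2))) - b2)
  mat$eta_e * f
}

# Cumulative range-energy table for a material, cached by material identity.
# Fixed-step trapezoid on a 0.05 MeV grid from the validity floor to E_max;
# the integral below the floor is closed with the constant-stopping-power
# remainder E_floor / S(E_floor).
.range_table <- function(mat, constants = pct_constants(), step = 0.05) {
  if (is.character(mat)) mat <- pct_materials(mat)
  key <- paste0("rt:", mat$name, ":", mat$eta_e, ":", mat$mean_excitation_I,
                ":", constants$K, ":", constants$E_floor, ":", step)
  tab <- .pct_cache[[key]]
  if (!is.null(tab)) return(tab)
  E <- seq(constants$E_floor, constants$E_max, by = step)
  invS <- 1 / stopping_power(mat, E, constants)
  r0 <- constants$E_floor / stopping_power(mat, constants$E_floor, constants)
  r <- r0 + c(0, cumsum((invS[-1] + invS[-length(invS)]) / 2 * diff(E)))
  tab <- list(E = E, r = r,
              range_of_E = stats::approxfun(E, r, rule = 2),
              E_of_range = stats::approxfun(r, E, rule = 2),
              r_floor = r0)
  assign(key, tab, envir = .pct_cache)
  tab
}

#' CSDA range
#'
#' Continuous-slowing-down-approximation range: numerical quadrature of
#' `dE / (dE/dx)` from the Bethe-Bloch validity floor to `E0`, plus the
#' constant-stopping-power remainder below the floor.
#'
#' @param mat a `pct_material` or material name.
#' @param E0 initial kinetic energy, MeV (vectorised).
#' @param constants a [pct_constants()] object.
#' @return range in cm.
#' @seealso [csda_range_mass()] for the areal (g/cm^2) range that stopping
#'   tables conventionally tabulate.
#' @export
csda_range <- function(mat, E0, constants = pct_constants()) {
  if (is.character(mat)) mat <- pct_materials(mat)
  if (any(E0 < constants$E_floor))
    stop("csda_range: E0 below the Bethe-Bloch validity floor")
  .range_table(mat, constants)$range_of_E(E0)
}

#' CSDA range as areal density
#'
#' `csda_range(mat, E0) * density`, in g/cm^2 — the unit in which standard
#' stopping-power tables (e.g. PSTAR) print CSDA ranges.
#'
#' @inheritParams csda_range
#' @return range in g/cm^2.
#' @export
csda_range_mass <- function(mat, E0, constants = pct_constants()) {
  if (is.character(mat)) mat <- pct_materials(mat)
  csda_range(mat, E0, constants) * mat$density
}

#' Water-equivalent path length from entry/exit energies
#'
#' The per-proton line integral of relative stopping power:
#' `integral of dE / S_water(E)` between `E_out` and `E_in`, evaluated as the
#' difference of water CSDA ranges.
#'
#' @param E_in entry kinetic energy, MeV (vectorised).
#' @param E_out exit (residual) kinetic energy, MeV (vectorised).
#' @param constants a [pct_constants()] object.
#' @return WEPL in cm of water. `NA` where `E_out` is at/below the validity
#'   floor (proton effectively stopped; the event is unusable).
#' @export
wepl_from_energies <- function(E_in, E_out, constants = pct_constants()) {
  if (any(E_out > E_in, na.rm = TRUE))
    stop("wepl_from_energies: E_out exceeds E_in (invalid event)")
  tab <- .range_table("water", constants)
  w <- tab$range_of_E(E_in) - tab$range_of_E(E_out)
  w[!is.na(E_out) & E_out <= constants$E_floor] <- NA_real_
  w[is.na(E_out)] <- NA_real_
  w
}

#' Residual energy after a water-equivalent path
#'
#' Inverse companion of [wepl_from_energies()]: solves
#' `integral_{E_out}^{E_in} dE / S_water(E) = w` via the water range-energy
#' table.
#'
#' @param E_in entry kinetic energy, MeV (vectorised).
#' @param w water-equivalent path length, cm (vectorised).
#' @param constants a [pct_constants()] object.
#' @return residual energy in MeV; `NA` where the proton's residual range is
#'   exhausted (stopped).
#' @export
energy_after_wepl <- function(E_in, w, constants = pct_constants()) {
  if (any(w < 0)) stop("energy_after_wepl: negative WEPL")
  tab <- .range_table("water", constants)
  r <- tab$range_of_E(E_in) - w
  out <- ifelse(r <= tab$r_floor, NA_real_, tab$E_of_range(pmax(r, tab$r_floor)))
  out
}

#' Projected multiple-Coulomb-scattering angle (Highland formula)
#'
#' Standard deviation of the projected scattering angle after traversing
#' `thickness` of a material:
#' `sigma = 13.6 MeV / (beta c p) * sqrt(x/X0) * (1 + 0.038 ln(x/X0))`,
#' with `x` the areal thickness in g/cm^2 and `X0` the radiation length.
#'
#' @param mat a `pct_material` or material name.
#' @param thickness path length in the material, cm (vectorised).
#' @param E proton kinetic energy, MeV (vectorised).
#' @param constants a [pct_constants()] object.
#' @return sigma of the projected angle, rad.
#' @export
scattering_angle_sigma <- function(mat, thickness, E, constants = pct_constants()) {
  if (is.character(mat)) mat <- pct_materials(mat)
  if (any(thickness <= 0)) stop("scattering_angle_sigma: thickness must be > 0")
  t_rel <- thickness * mat$density / mat$radiation_length
  pc2 <- E * (E + 2 * constants$m_p_c2)     # (pc)^2
  beta_pc <- pc2 / (E + constants$m_p_c2)   # beta * p * c, MeV
  13.6 / beta_pc * sqrt(t_rel) * pmax(1 + 0.038 * log(t_rel), 0)
}

#' Relative stopping power of a material at a given energy
#'
#' `S_mat(E) / S_water(E)`; equals `eta_e` up to the slow logarithmic
#' I-dependence of the Bethe-Bloch bracket.
#'
#' @inheritParams stopping_power
#' @return dimensionless RSP (vectorised over `E`).
#' @export
rsp <- function(mat, E, constants = pct_constants()) {
  stopping_power(mat, E, constants) / stopping_power("water", E, constants)
}

#' Bohr energy-straggling width
#'
#' Gaussian approximation to energy-loss straggling over a water-equivalent
#' path: `sigma_E^2 = 0.1569 * 0.55509 * eta_e-weighted pathlength *
#' (1 - beta^2/2) / (1 - beta^2)` MeV^2, with the path expressed as cm of
#' water (eta_e * length already folded in).
#'
#' @param wepl traversed water-equivalent path length, cm (vectorised).
#' @param E proton kinetic energy, MeV (vectorised; evaluated at the given E).
#' @param constants a [pct_constants()] object.
#' @return sigma of the energy loss, MeV.
#' @export
straggling_sigma <- function(wepl, E, constants = pct_constants()) {
  b2 <- beta_sq(pmax(E, constants$E_floor), constants)
  sqrt(pmax(0.1569 * 0.55509 * wepl * (1 - b2 / 2) / (1 - b2), 0))
}
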