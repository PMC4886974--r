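# Material definitions and physics constants.

# Package-level cache (range-energy tables, system matrices, material table).
.pct_cache <- new.env(parent = emptyenv())

#' Physics constants used by the stopping-power model
#'
#' `K` is the Bethe-Bloch prefactor of the water-normalised stopping-power
#' parameterization (MeV/cm for unit relative electron density); `m_e_c2` and
#' `m_p_c2` are the electron and proton rest energies in MeV; `E_floor` is the
#' validity floor of the Bethe-Bloch model (MeV) below which the CSDA integral
#' is closed with a constant-stopping-power remainder; `E_max` is the upper
#' validity bound.
#'
#' @param K Bethe-Bloch prefactor, MeV/cm.
#' @param m_e_c2 electron rest energy, MeV.
#' @param m_p_c2 proton rest energy, MeV.
#' @param E_floor low-energy validity floor, MeV.
#' @param E_max high-energy validity bound, MeV.
#' @return A named list of class `pct_constants`.
#' @export
pct_constants <- function(K = 0.17, m_e_c2 = 0.510998928, m_p_c2 = 938.272,
                          E_floor = 1, E_max = 330) {
  stopifnot(K > 0, m_e_c2 > 0, m_p_c2 > 0, E_floor > 0, E_max > E_floor)
  structure(list(K = K, m_e_c2 = m_e_c2, m_p_c2 = m_p_c2,
                 E_floor = E_floor, E_max = E_max),
            class = "pct_constants")
}

#' Define a material
#'
#' @param name material name.
#' @param density mass density, g/cm^3.
#' @param eta_e electron density relative to water (dimensionless); this is
#'   the relative stopping power scale and the quantity pCT reconstructs.
#' @param mean_excitation_I mean excitation energy, eV.
#' @param radiation_length radiation length X0, g/cm^2 (used only by the
#'   multiple-scattering model).
#' @return An object of class `pct_material`.
#' @examples
#' water <- material("water", 1.0, 1.0, 75, 36.08)
#' @export
material <- function(name, density, eta_e, mean_excitation_I, radiation_length) {
  stopifnot(is.character(name), length(name) == 1L,
            density > 0, eta_e >= 0, mean_excitation_I > 0, radiation_length > 0)
  structure(list(name = name, density = density, eta_e = eta_e,
                 mean_excitation_I = mean_excitation_I,
                 radiation_length = radiation_length),
            class = "pct_material")
}

#' @export
print.pct_material <- function(x, ...) {
  cat(sprintf("<pct_material> %s: rho = %g g/cm^3, eta_e = %g, I = %g eV, X0 = %g g/cm^2\n",
              x$name, x$density, x$eta_e, x$mean_excitation_I, x$radiation_length))
  invisible(x)
}

#' Load a material table from a YAML file
#'
#' The file maps material names to the fields of [material()]. The packaged
#' defaults cover water, A150 tissue-equivalent plastic, silicon, cortical
#' bone, adipose, air and CsI.
#'
#' @param path path to a YAML materials file; default is the packaged table.
#' @return A named list of `pct_material` objects.
#' @export
load_materials <- function(path = system.file("extdata", "materials.yaml",
                                              package = "protonCT")) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    m <- raw[[nm]]
    material(nm, m$density, m$eta_e, m$mean_excitation_I, m$radiation_length)
  })
  names(out) <- names(raw)
  out
}

#' Packaged default materials (cached)
#'
#' @param name optional material name; if given, returns that single material.
#' @return A named list of `pct_material` objects, or one `pct_material`.
#' @export
pct_materials <- function(name = NULL) {
  if (is.null(.pct_cache$materials))
    .pct_cache$materials <- load_materials()
  if (is.null(name)) return(.pct_cache$materials)
  m <- .pct_cache$materials[[name]]
  if (is.null(m)) stop("unknown material: ", name)
  m
}
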