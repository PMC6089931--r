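#' Default material optical constants
#'
#' Per-material refractive-index decrement (`delta`) and absorption index
#' (`beta`) used by the phantom generators. The values are plausible
#' soft-tissue / embedding-medium constants for a monochromatic 25 keV beam,
#' constrained so that (i) beta ordering follows air < wax <= epoxy < agar <
#' tissue < stained tissue < insulation < copper and (ii) a 3 mm wax path
#' absorbs roughly 30 percent of the beam under Beer-Lambert attenuation
#' `exp(-4 pi beta L / lambda)`. They are configuration defaults, not ground
#' truth, and can be overridden per material.
#'
#' For energies other than 25 keV, `delta` is scaled as `(25/E)^2` and `beta`
#' as `(25/E)^3` (the leading far-from-edge energy dependence).
#'
#' @param energy_keV photon energy in keV.
#' @param overrides optional named list; each element is `c(delta, beta)` and
#'   replaces the default for that material name.
#' @return A data frame with columns `name`, `delta`, `beta`.
#' @examples
#' material_table(25)
#' @export
material_table <- function(energy_keV = 25, overrides = NULL) {
  tab <- data.frame(
    name = c("air", "agar", "wax", "epoxy", "tissue", "tissue_grey_li",
             "vessel", "soma", "insulation", "copper"),
    delta = c(4.0e-10, 3.6e-07, 3.1e-07, 3.4e-07, 3.0e-07, 3.0e-07,
              2.5e-07, 3.2e-07, 4.5e-07, 1.7e-06),
    beta = c(2.0e-13, 6.72e-10, 4.69e-10, 5.10e-10, 7.5e-10, 2.25e-09,
             5.2e-10, 2.8e-09, 1.5e-09, 8.8e-08),
    stringsAsFactors = FALSE
  )
  if (energy_keV != 25) {
    if (energy_keV <= 0) .stopf("energy_keV must be positive")
    tab$delta <- tab$delta * (25 / energy_keV)^2
    tab$beta <- tab$beta * (25 / energy_keV)^3
  }
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      i <- match(nm, tab$name)
      if (is.na(i)) .stopf("unknown material '%s'", nm)
      tab$delta[i] <- overrides[[nm]][1]
      tab$beta[i] <- overrides[[nm]][2]
    }
  }
  tab
}

material_lookup <- function(materials, name) {
  i <- match(name, materials$name)
  if (is.na(i)) .stopf("unknown material '%s'", name)
  i
}

#' Linear attenuation coefficient of a material
#'
#' `mu = 4 pi beta / lambda`, in inverse metres.
#'
#' @param beta absorption index.
#' @param beam a [beam_spec()].
#' @return Attenuation coefficient in 1/m.
#' @export
attenuation_coefficient <- function(beta, beam = beam_spec(25)) {
  4 * pi * beta / beam$wavelength_m
}
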