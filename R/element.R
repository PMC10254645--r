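#' Element and particle-composition constants
#'
#' Physical constants needed to turn an analyte mass into a
#' spherical-equivalent particle diameter and to assemble the element
#' factor K_M = A * N_Av / M_M of the size-detection-limit model. Defaults
#' describe a metallic zero-valent iron (Fe0) core monitored at 56Fe:
#' density 7.87 g/cm3, analyte mass fraction 1, isotopic abundance 0.917,
#' molar mass 55.85 g/mol. An oxide shell would lower `mass_fraction_X`.
#'
#' @param density_rho Particle density, g/cm3.
#' @param mass_fraction_X Mass fraction of the measured element in the
#'   particle, in (0, 1].
#' @param isotope_abundance_A Atomic abundance of the monitored isotope,
#'   in (0, 1].
#' @param molar_mass_M Atomic mass of the element, g/mol.
#' @return An object of class `element_params`.
#' @export
#' @examples
#' element_params()                      # nZVI / 56Fe defaults
#' element_params(density_rho = 19.30)   # gold reference particles
element_params <- function(density_rho = 7.87,
                           mass_fraction_X = 1.0,
                           isotope_abundance_A = 0.917,
                           molar_mass_M = 55.85) {
  vals <- c(density_rho, mass_fraction_X, isotope_abundance_A, molar_mass_M)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All element parameters must be finite and > 0.")
  }
  if (mass_fraction_X > 1 || isotope_abundance_A > 1) {
    abort("`mass_fraction_X` and `isotope_abundance_A` must be <= 1.")
  }
  structure(
    list(density_rho = density_rho,
         mass_fraction_X = mass_fraction_X,
         isotope_abundance_A = isotope_abundance_A,
         molar_mass_M = molar_mass_M,
         avogadro_N = 6.02214076e23),
    class = "element_params"
  )
}

#' @export
print.element_params <- function(x, ...) {
  cat(sprintf("<element_params> rho=%g g/cm3, X=%g, A=%g, M=%g g/mol\n",
              x$density_rho, x$mass_fraction_X, x$isotope_abundance_A,
              x$molar_mass_M))
  invisible(x)
}

#' Element factor K_M of the detection-efficiency product
#'
#' K_M = A * N_Av / M_M (atoms of the monitored isotope per gram of
#' element). Exposed so that users holding an instrument-independent
#' detection efficiency K_ICPMS can split the product
#' [detection_efficiency_product()] returns.
#'
#' @param elem An [element_params()] object.
#' @return Atoms per gram of element (1/g).
#' @export
element_factor_km <- function(elem) {
  stopifnot(inherits(elem, "element_params"))
  elem$isotope_abundance_A * elem$avogadro_N / elem$molar_mass_M
}

#' Convert analyte mass to spherical-equivalent diameter
#'
#' d = (6 m / (pi * rho * X))^(1/3) for a compact sphere: `m` is the mass
#' of the measured element, so dividing by the mass fraction `X` recovers
#' the whole-particle mass before applying the sphere model.
#'
#' @param mass_ug Analyte mass per particle, micrograms (vectorised).
#' @param elem An [element_params()] object.
#' @return Diameter in nanometres.
#' @export
#' @examples
#' mass_to_diameter(5.15e-10, element_params())  # ~50 nm Fe
mass_to_diameter <- function(mass_ug, elem = element_params()) {
  stopifnot(inherits(elem, "element_params"))
  if (any(mass_ug < 0, na.rm = TRUE)) abort("`mass_ug` must be >= 0.")
  # m [ug] * 1e-6 -> g; / (rho X) -> cm3; sphere -> cm; * 1e7 -> nm
  vol_cm3 <- mass_ug * 1e-6 / (elem$density_rho * elem$mass_fraction_X)
  (6 * vol_cm3 / pi)^(1 / 3) * 1e7
}

#' Convert spherical-equivalent diameter to analyte mass
#'
#' Inverse of [mass_to_diameter()]: m = rho * X * (pi/6) d^3.
#'
#' @param diameter_nm Diameter in nanometres (vectorised).
#' @param elem An [element_params()] object.
#' @return Analyte mass in micrograms.
#' @export
diameter_to_mass <- function(diameter_nm, elem = element_params()) {
  stopifnot(inherits(elem, "element_params"))
  if (any(diameter_nm < 0, na.rm = TRUE)) abort("`diameter_nm` must be >= 0.")
  vol_cm3 <- (pi / 6) * (diameter_nm * 1e-7)^3
  vol_cm3 * elem$density_rho * elem$mass_fraction_X * 1e6
}
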