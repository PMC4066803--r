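# Physical parameter containers for the elasticity and energetics modules.

#' @rdname wlc_params
#' @format NULL
#' @export
BOLTZMANN_PN_NM <- 0.0138065  # pN nm / K

#' Conversion between pN nm per molecule and kcal/mol
#'
#' 1 kcal/mol = 4184 J / N_A = 6.9477 pN nm per molecule.
#' @export
PN_NM_PER_KCAL_MOL <- 6.9477

#' Worm-like-chain parameters of the double-stranded tether
#'
#' Defaults are the handle elasticity used throughout: persistence length
#' P = 50.9 nm, stretch modulus S = 1168 pN, at 23 degrees C (296.15 K), which
#' gives a thermal energy k_B T = 4.089 pN nm.
#'
#' @param persistence_length Persistence length P in nm.
#' @param stretch_modulus Stretch (enthalpic) modulus S in pN.
#' @param temperature Absolute temperature in K.
#' @return An object of class `wlc_params`.
#' @examples
#' wlc_params()$thermal_energy  # ~4.089 pN nm
#' @export
wlc_params <- function(persistence_length = 50.9, stretch_modulus = 1168,
                       temperature = 296.15) {
  check_number(persistence_length, "persistence_length", positive = TRUE)
  check_number(stretch_modulus, "stretch_modulus", positive = TRUE)
  check_number(temperature, "temperature", positive = TRUE)
  structure(
    list(
      persistence_length = persistence_length,
      stretch_modulus = stretch_modulus,
      temperature = temperature,
      thermal_energy = BOLTZMANN_PN_NM * temperature
    ),
    class = "wlc_params"
  )
}

#' Contour-length to nucleotide-count conversion constants
#'
#' Calibrated so that the release of 1.8, 3.8 and 6.0 nm of contour length maps
#' to 9, 14 and 19 nt under nearest-integer rounding: the unfolded strand
#' contributes 0.44 nm of contour per nucleotide and the folded structure has a
#' width of 2.3 nm that is recovered on unfolding.
#'
#' @param contour_per_nt Contour length per nucleotide, nm/nt.
#' @param folded_width Extension footprint of the folded structure, nm.
#' @return An object of class `nt_conversion`.
#' @export
nt_conversion <- function(contour_per_nt = 0.44, folded_width = 2.3) {
  check_number(contour_per_nt, "contour_per_nt", positive = TRUE)
  check_number(folded_width, "folded_width", positive = TRUE)
  structure(
    list(contour_per_nt = contour_per_nt, folded_width = folded_width),
    class = "nt_conversion"
  )
}

#' Single-stranded DNA stretching parameters
#'
#' Used for the stretching-energy correction of the Jarzynski estimate:
#' an inextensible WLC with a short persistence length (1.0 nm) and 0.44 nm of
#' contour per nucleotide, standard single-strand values.
#'
#' @param persistence_length ssDNA persistence length, nm.
#' @param contour_per_nt ssDNA contour length per nucleotide, nm/nt.
#' @return An object of class `ss_stretch_params`.
#' @export
ss_stretch_params <- function(persistence_length = 1.0, contour_per_nt = 0.44) {
  check_number(persistence_length, "persistence_length", positive = TRUE)
  check_number(contour_per_nt, "contour_per_nt", positive = TRUE)
  structure(
    list(persistence_length = persistence_length, contour_per_nt = contour_per_nt),
    class = "ss_stretch_params"
  )
}
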