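# Polymer-elasticity core: extensible-WLC extension ratio, contour-length
# extraction from rupture jumps, nucleotide-count conversion, and the
# single-strand stretching energy used by the Jarzynski correction.

#' Extensible worm-like-chain extension ratio
#'
#' Ratio of extension change to contour-length change at force F for an
#' extensible WLC:
#' \deqn{\Delta x/\Delta L = 1 - \tfrac12\sqrt{k_BT/(FP)} + F/S.}
#' This is also the relative extension of the double-stranded tether at
#' force F in the high-force interpolation regime.
#'
#' @param force Force in pN (vectorised, strictly positive).
#' @param params A [wlc_params()] object.
#' @return Dimensionless ratio, same length as `force`.
#' @examples
#' wlc_ratio(31)  # ~1.0011
#' @export
wlc_ratio <- function(force, params = wlc_params()) {
  check_number(force, "force", positive = TRUE)
  1 - 0.5 * sqrt(params$thermal_energy / (force * params$persistence_length)) +
    force / params$stretch_modulus
}

# Derivative of wlc_ratio with respect to force (per pN); used for the local
# tether compliance when correcting flanking points to a common force.
wlc_ratio_deriv <- function(force, params = wlc_params()) {
  0.25 * sqrt(params$thermal_energy / params$persistence_length) * force^(-1.5) +
    1 / params$stretch_modulus
}

#' Contour-length change from an extension jump
#'
#' Converts the extension difference between the stretch and relax branches at
#' the rupture force into the released contour length:
#' \eqn{\Delta L = \Delta x / (\Delta x/\Delta L)(F)}.
#'
#' @param force_at_rupture Rupture force in pN (> 0).
#' @param delta_x Extension jump in nm (>= 0).
#' @param params A [wlc_params()] object.
#' @return Contour-length change in nm.
#' @export
delta_L_from_jump <- function(force_at_rupture, delta_x, params = wlc_params()) {
  check_number(force_at_rupture, "force_at_rupture", positive = TRUE)
  check_number(delta_x, "delta_x", non_negative = TRUE)
  delta_x / wlc_ratio(force_at_rupture, params)
}

#' Nucleotide count of an unfolded structure
#'
#' Nearest-integer count \eqn{n = \mathrm{round}((\Delta L + w)/c)} where `w`
#' is the folded width and `c` the contour per nucleotide.
#'
#' @param delta_L Contour-length change in nm (> 0).
#' @param conv An [nt_conversion()] object.
#' @return Integer nucleotide count.
#' @examples
#' nt_count(c(1.8, 3.8, 6.0))  # 9 14 19
#' @export
nt_count <- function(delta_L, conv = nt_conversion()) {
  check_number(delta_L, "delta_L", positive = TRUE)
  as.integer(round((delta_L + conv$folded_width) / conv$contour_per_nt))
}

# Relative extension z = x/L of an inextensible Marko-Siggia WLC at force F,
# obtained by inverting F(z) = (kT/P) (1/(4(1-z)^2) - 1/4 + z) on a fine grid.
ss_relative_extension <- function(force, persistence_length, thermal_energy) {
  z <- seq(0, 0.9995, length.out = 5000)
  fz <- thermal_energy / persistence_length * (0.25 / (1 - z)^2 - 0.25 + z)
  out <- approx(fz, z, xout = force, rule = 2)$y
  out[force <= 0] <- 0
  out
}

#' Single-strand stretching energy
#'
#' Conjugate work \eqn{\int_0^F x(F')\,dF'} of stretching an inextensible WLC
#' of contour length `n_nt * contour_per_nt` from zero force to `force`,
#' evaluated by composite-trapezoid quadrature over force. This is the
#' correction subtracted from rupture works before Jarzynski averaging.
#'
#' @param n_nt Number of released nucleotides (>= 1).
#' @param force Final force in pN (>= 0); vectorised.
#' @param ss An [ss_stretch_params()] object.
#' @param thermal_energy Thermal energy k_B T in pN nm.
#' @param n_steps Number of quadrature steps (default 1000).
#' @return Energy in pN nm.
#' @export
ss_stretch_energy <- function(n_nt, force, ss = ss_stretch_params(),
                              thermal_energy = wlc_params()$thermal_energy,
                              n_steps = 1000) {
  if (any(n_nt < 1)) abort_domain("`n_nt` must be >= 1.")
  check_number(force, "force", non_negative = TRUE)
  contour <- n_nt * ss$contour_per_nt
  ss_stretch_energy_contour(contour, force, ss, thermal_energy, n_steps)
}

# Same integral for an arbitrary released contour length (nm). The Jarzynski
# correction uses the net released contour delta_L rather than the full
# nucleotide contour, so that unfolding works remain referenced to the folded
# state's extension footprint.
ss_stretch_energy_contour <- function(contour_nm, force,
                                      ss = ss_stretch_params(),
                                      thermal_energy = wlc_params()$thermal_energy,
                                      n_steps = 1000) {
  check_number(contour_nm, "contour_nm", non_negative = TRUE)
  n <- max(length(contour_nm), length(force))
  contour_nm <- rep_len(contour_nm, n)
  force <- rep_len(force, n)
  unit <- vapply(force, function(f) {
    if (f <= 0) return(0)
    grid <- seq(0, f, length.out = n_steps + 1)
    z <- ss_relative_extension(grid, ss$persistence_length, thermal_energy)
    trapz(grid, z)
  }, numeric(1))
  unit * contour_nm
}
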