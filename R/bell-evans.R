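# Bell-Evans rupture-force model at constant loading rate.
#
# Escape rate k(F) = k0 exp(F x / kT); at loading rate r the survival to
# force F is S(F) = exp(-(k0 kT)/(r x) (exp(F x / kT) - 1)), which gives a
# closed-form inverse CDF used for sampling.

#' Bell-Evans most probable rupture force
#'
#' Closed-form mode \eqn{F^* = (k_BT/x^\ddagger)\,\ln(r x^\ddagger /(k_0 k_BT))}
#' of the rupture-force density at constant loading rate.
#'
#' @param k0 Intrinsic (zero-force) unfolding rate, 1/s.
#' @param barrier_distance Distance to the transition state x-dagger, nm.
#' @param loading_rate Loading rate r, pN/s.
#' @param thermal_energy k_B T, pN nm.
#' @return Mode of the rupture-force distribution, pN.
#' @export
bell_evans_mode <- function(k0, barrier_distance, loading_rate,
                            thermal_energy = wlc_params()$thermal_energy) {
  (thermal_energy / barrier_distance) *
    log(loading_rate * barrier_distance / (k0 * thermal_energy))
}

#' Bell-Evans mean rupture force
#'
#' Mean of the rupture-force distribution at constant loading rate, computed
#' as the integral of the survival function.
#'
#' @inheritParams bell_evans_mode
#' @return Mean rupture force, pN.
#' @export
bell_evans_mean <- function(k0, barrier_distance, loading_rate,
                            thermal_energy = wlc_params()$thermal_energy) {
  a <- k0 * thermal_energy / (loading_rate * barrier_distance)
  b <- barrier_distance / thermal_energy
  surv <- function(f) exp(-a * expm1(b * f))
  upper <- bell_evans_mode(k0, barrier_distance, loading_rate, thermal_energy) +
    30 / b
  integrate(surv, 0, max(upper, 10), rel.tol = 1e-9)$value
}

#' Calibrate the intrinsic rate to a target mean rupture force
#'
#' Solves for k0 such that the Bell-Evans mean rupture force at the given
#' loading rate equals `mean_force`.
#'
#' @param mean_force Target mean rupture force, pN.
#' @inheritParams bell_evans_mode
#' @return Intrinsic rate k0, 1/s.
#' @export
calibrate_bell_evans <- function(mean_force, barrier_distance = 2.0,
                                 loading_rate = 5.5,
                                 thermal_energy = wlc_params()$thermal_energy) {
  f <- function(log10_k0) {
    bell_evans_mean(10^log10_k0, barrier_distance, loading_rate, thermal_energy) -
      mean_force
  }
  10^uniroot(f, c(-30, 4), tol = 1e-10)$root
}

#' Sample rupture forces from the Bell-Evans first-passage density
#'
#' Inverse-CDF sampling of the rupture-force distribution at constant loading
#' rate: \eqn{F = (k_BT/x)\,\log(1 - \log(1-U)\, r x/(k_0 k_BT))}.
#'
#' @param n Number of draws.
#' @param k0 Intrinsic unfolding rate, 1/s (alternatively pass `species`).
#' @param barrier_distance Barrier distance, nm.
#' @param loading_rate Loading rate, pN/s (> 0).
#' @param thermal_energy k_B T, pN nm.
#' @param seed Optional integer seed; when given the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @return Numeric vector of rupture forces, pN.
#' @export
sample_rupture_force <- function(n, k0, barrier_distance = 2.0,
                                 loading_rate = 5.5,
                                 thermal_energy = wlc_params()$thermal_energy,
                                 seed = NULL) {
  check_number(loading_rate, "loading_rate", positive = TRUE)
  draw <- function() {
    u <- runif(n)
    a <- k0 * thermal_energy / (loading_rate * barrier_distance)
    (thermal_energy / barrier_distance) * log1p(-log1p(-u) / a)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
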