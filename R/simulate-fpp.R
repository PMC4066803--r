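# Force-pump-probe (FPP) generator: unfold at high force, relax to 0 pN,
# incubate for time t, probe with the next ramp. A species refolds during the
# incubation with probability prevalence * (1 - exp(-t / tau)), so that
# t -> Inf recovers the condition's steady-state prevalences.

#' Simulate a force-pump-probe series
#'
#' Generates per-probe-cycle outcomes of the FPP protocol for one condition:
#' for each incubation time and cycle, whether a structure was present at the
#' probe, which species, and the measured contour-length change and rupture
#' force of its unfolding (species-level truth plus measurement noise).
#'
#' @param condition A [make_condition()] object (or name).
#' @param incubation_times Incubation times at 0 pN, s (non-empty, >= 0).
#' @param n_cycles Probe cycles per incubation time.
#' @param protocol A [protocol_spec()] object (probe ramp loading rate).
#' @param seed Integer seed.
#' @param delta_L_meas_sd Measurement noise of delta-L at the probe, nm.
#' @param force_meas_sd Measurement noise of the rupture force, pN.
#' @return Tibble: `cycle_id`, `incubation_time_s`, `species_true`, `event`,
#'   `delta_L`, `rupture_force`; class `fpp_events`.
#' @examples
#' fpp <- simulate_fpp_series(make_condition("transcription"),
#'                            incubation_times = c(0.02, 5), n_cycles = 50)
#' dplyr::summarise(fpp, mean(event), .by = incubation_time_s)
#' @export
simulate_fpp_series <- function(condition,
                                incubation_times = c(0.02, 0.05, 0.1, 0.2,
                                                     0.5, 1, 2, 5),
                                n_cycles = 500, protocol = protocol_spec(),
                                seed = 1, delta_L_meas_sd = 0.1,
                                force_meas_sd = 0.2) {
  if (is.character(condition)) condition <- make_condition(condition)
  if (length(incubation_times) == 0 || any(incubation_times < 0)) {
    abort_domain("`incubation_times` must be non-empty and all >= 0.")
  }
  if (n_cycles < 1) abort_domain("`n_cycles` must be >= 1.")
  sp <- condition$species
  folded <- sp$species != "none"
  withr::with_seed(seed, {
    out <- purrr::map_dfr(seq_along(incubation_times), function(j) {
      t <- incubation_times[j]
      p_fold <- sp$prevalence[folded] * (1 - exp(-t / sp$fold_tau[folded]))
      prob <- c(p_fold, 1 - sum(p_fold))
      labels <- c(sp$species[folded], "none")
      idx <- sample.int(length(prob), n_cycles, replace = TRUE, prob = prob)
      species <- labels[idx]
      ev <- species != "none"
      dl <- rep(NA_real_, n_cycles)
      f <- rep(NA_real_, n_cycles)
      if (any(ev)) {
        row <- match(species[ev], sp$species)
        dl[ev] <- rnorm_pos(sum(ev), sp$delta_L_mean[row],
                            pmax(sp$delta_L_sd[row], 1e-6)) +
          rnorm(sum(ev), 0, delta_L_meas_sd)
        f[ev] <- sample_rupture_force(sum(ev), sp$intrinsic_rate[row],
                                      sp$barrier_distance[row],
                                      protocol$loading_rate,
                                      condition$thermal_energy) +
          rnorm(sum(ev), 0, force_meas_sd)
      }
      tibble(
        cycle_id = (j - 1L) * n_cycles + seq_len(n_cycles),
        incubation_time_s = t,
        species_true = species,
        event = ev,
        delta_L = dl,
        rupture_force = f
      )
    })
    class(out) <- c("fpp_events", class(out))
    attr(out, "condition") <- condition$name
    attr(out, "n_cycles") <- n_cycles
    out
  })
}
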