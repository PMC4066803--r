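# Experimental-condition catalogue for the synthetic-data generator.
#
# Each condition carries a species table (prevalence, contour-length-change
# distribution, Bell-Evans force calibration, zero-force refolding time
# constant). Prevalences are the per-condition percent-formation table of the
# stalled-transcription assay; curves with no folded structure ("none") are
# the dsDNA / R-loop class.

condition_names <- c("transcription", "deaza", "no_transcription",
                     "mutant", "spacer", "lithium")

# species, prevalence, delta_L mean/sd (nm), mean rupture force (pN),
# zero-force folding time constant (s)
condition_catalog <- function() {
  list(
    transcription = tibble(
      species     = c("2G-HQ", "3G-HQ", "GT", "GQ", "none"),
      prevalence  = c(0.173, 0.094, 0.038, 0.122, 0.573),
      delta_L_mean = c(1.8, 3.8, 3.8, 6.0, 0),
      delta_L_sd   = c(0.2, 0.5, 0.5, 0.6, 0),
      force_mean   = c(31, 31, 25, 25, NA),
      force_sd     = c(1, 1, 2, 2, NA),
      fold_tau     = c(0.030, 0.030, 0.030, 0.010, NA)
    ),
    deaza = tibble(
      species     = c("GT", "GQ", "none"),
      prevalence  = c(0.081, 0.259, 0.660),
      delta_L_mean = c(3.8, 6.0, 0),
      delta_L_sd   = c(0.5, 0.6, 0),
      force_mean   = c(25, 25, NA),
      force_sd     = c(2, 2, NA),
      fold_tau     = c(0.150, 0.150, NA)
    ),
    no_transcription = tibble(
      species     = c("GT", "GQ", "none"),
      prevalence  = c(0.147, 0.096, 0.757),
      delta_L_mean = c(3.8, 6.0, 0),
      delta_L_sd   = c(0.5, 0.6, 0),
      force_mean   = c(25, 25, NA),
      force_sd     = c(2, 2, NA),
      fold_tau     = c(0.150, 0.150, NA)
    ),
    mutant = tibble(
      species     = c("GT", "none"),
      prevalence  = c(0.020, 0.980),
      delta_L_mean = c(4.0, 0),
      delta_L_sd   = c(1.5, 0),
      force_mean   = c(25, NA),
      force_sd     = c(2, NA),
      fold_tau     = c(0.150, NA)
    ),
    spacer = tibble(
      species     = c("GT", "none"),
      prevalence  = c(0.079, 0.921),
      delta_L_mean = c(4.0, 0),
      delta_L_sd   = c(1.5, 0),
      force_mean   = c(25, NA),
      force_sd     = c(2, NA),
      fold_tau     = c(0.150, NA)
    ),
    lithium = tibble(
      species     = c("GQ", "none"),
      prevalence  = c(0.067, 0.933),
      delta_L_mean = c(6.0, 0),
      delta_L_sd   = c(0.6, 0),
      force_mean   = c(25, NA),
      force_sd     = c(2, NA),
      fold_tau     = c(0.150, NA)
    )
  )
}

#' Build an experimental-condition specification
#'
#' Returns the species table of one experimental condition: prevalences,
#' contour-length-change (delta-L) distributions, Bell-Evans rupture-force
#' calibration, and zero-force folding time constants. The Bell-Evans pair
#' (x-dagger, k0) is solved per species so that the rupture-force
#' distribution at the given loading rate reproduces the species' calibrated
#' mean and width: the distribution is Gumbel-like with scale
#' k_BT / x-dagger, so x-dagger = pi k_BT / (sqrt(6) sigma_F), and k0 is then
#' solved for the mean.
#'
#' Conditions: `transcription` (regular stalled transcription), `deaza`
#' (7-deaza-GTP transcription, no hybrid quadruplexes), `no_transcription`,
#' plus the `mutant`, `spacer` and `lithium` controls.
#'
#' @param name Condition name.
#' @param loading_rate Loading rate used for the force calibration, pN/s.
#' @param wlc A [wlc_params()] object (thermal energy for the calibration).
#' @return A `condition_spec`: list with `name` and a `species` tibble.
#' @examples
#' make_condition("transcription")$species
#' @export
make_condition <- function(name, loading_rate = 5.5, wlc = wlc_params()) {
  if (!is.character(name) || length(name) != 1 || !(name %in% condition_names)) {
    abort_config(sprintf(
      "Unknown condition '%s'. Known conditions: %s.",
      paste(name, collapse = ","), paste(condition_names, collapse = ", ")
    ))
  }
  sp <- condition_catalog()[[name]]
  stopifnot(abs(sum(sp$prevalence) - 1) < 1e-9)
  sp$barrier_distance <- pi * wlc$thermal_energy / (sqrt(6) * sp$force_sd)
  sp$intrinsic_rate <- vapply(seq_len(nrow(sp)), function(i) {
    if (is.na(sp$force_mean[i])) return(NA_real_)
    calibrate_bell_evans(sp$force_mean[i], sp$barrier_distance[i],
                         loading_rate, wlc$thermal_energy)
  }, numeric(1))
  structure(
    list(name = name, species = sp, loading_rate = loading_rate,
         thermal_energy = wlc$thermal_energy),
    class = "condition_spec"
  )
}

#' @export
print.condition_spec <- function(x, ...) {
  cat("<condition_spec>", x$name, "\n")
  print(x$species)
  invisible(x)
}

#' Pulling/force-jump protocol parameters
#'
#' Acquisition and protocol constants of the synthetic assay: 5.5 pN/s ramps
#' to 45 pN, force jumps to 45 pN with relaxation to 0 pN, probe ramps starting
#' at 10 pN, 1000 Hz acquisition, Gaussian channel noise, and the
#' double-stranded handle contour (4718 bp x 0.338 nm/bp ~ 1595 nm).
#' `trap_stiffness` is the effective trap-tether stiffness converting the
#' extension released at rupture into the observed force drop.
#'
#' @param loading_rate pN/s.
#' @param force_max Maximum ramp force, pN.
#' @param jump_high Unfolding jump force, pN.
#' @param jump_low Incubation force, pN.
#' @param probe_start Start force of the probe ramp, pN.
#' @param jump_duration Jump/relaxation time, s.
#' @param sample_rate Acquisition rate, Hz.
#' @param noise_sd_force Force channel noise SD, pN.
#' @param noise_sd_extension Extension channel noise SD, nm.
#' @param handle_contour Tether contour length, nm.
#' @param trap_stiffness Effective stiffness, pN/nm.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(loading_rate = 5.5, force_max = 45, jump_high = 45,
                          jump_low = 0, probe_start = 10, jump_duration = 0.02,
                          sample_rate = 1000, noise_sd_force = 0.5,
                          noise_sd_extension = 1.0, handle_contour = 1595,
                          trap_stiffness = 1.0) {
  if (!(jump_low >= 0 && jump_low < probe_start && probe_start < jump_high &&
        jump_high <= force_max)) {
    abort_config("Require 0 <= jump_low < probe_start < jump_high <= force_max.")
  }
  check_number(sample_rate, "sample_rate", positive = TRUE)
  check_number(loading_rate, "loading_rate", positive = TRUE)
  structure(
    list(loading_rate = loading_rate, force_max = force_max,
         jump_high = jump_high, jump_low = jump_low, probe_start = probe_start,
         jump_duration = jump_duration, sample_rate = sample_rate,
         noise_sd_force = noise_sd_force,
         noise_sd_extension = noise_sd_extension,
         handle_contour = handle_contour, trap_stiffness = trap_stiffness),
    class = "protocol_spec"
  )
}

# Species assignment by prevalence; used by both generators.
draw_species <- function(condition, n) {
  sp <- condition$species
  idx <- sample.int(nrow(sp), n, replace = TRUE, prob = sp$prevalence)
  sp$species[idx]
}

#' Construct core sequences bundled with the package
#'
#' Reads the FASTA file of construct core sequences (the G-core
#' 5'-(GGGGA)4 flanked by TT, the G-less mutant core and the spacer variant
#' with an ATTTTA insert between two G-tracts; the latter two reconstructed
#' from their described composition).
#'
#' @return A tibble with columns `name` and `sequence`.
#' @export
construct_sequences <- function() {
  path <- system.file("extdata", "constructs.fasta", package = "quadtrace")
  seqs <- Biostrings::readDNAStringSet(path)
  tibble(name = names(seqs), sequence = as.character(seqs))
}
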