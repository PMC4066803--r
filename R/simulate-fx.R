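# Seeded generator of synthetic force-extension pulling datasets.
#
# Per curve: a species is assigned by the condition prevalences; the stretch
# ramp is linear in time at the loading rate; tether extension follows the
# extensible WLC applied to the handle contour; a Bell-Evans rupture at force
# F_r releases a delta_L-sized contour increment and drops the measured force
# by trap_stiffness * delta_x; the relax ramp carries the unfolded contour.
# Channel noise is i.i.d. Gaussian at the acquisition rate.

#' Simulate a force-extension pulling dataset
#'
#' Generates `n_curves` stretch/relax cycles for one experimental condition,
#' together with a ground-truth manifest (species, true delta-L, true rupture
#' force per cycle) for benchmarking the detection pipeline. Identical seeds
#' give identical datasets.
#'
#' @param condition A [make_condition()] object (or condition name).
#' @param n_curves Number of pulling cycles (>= 1).
#' @param protocol A [protocol_spec()] object.
#' @param seed Integer seed (default 1).
#' @return An `fx_dataset`: list with `trace` (tibble: `time_s`, `force_pN`,
#'   `extension_nm`, `cycle_id`, `phase`) and `truth` (tibble: `cycle_id`,
#'   `species`, `true_delta_L_nm`, `true_rupture_force_pN`, `censored`).
#' @examples
#' d <- simulate_fx_dataset(make_condition("transcription"), n_curves = 2, seed = 7)
#' dplyr::count(d$trace, cycle_id, phase)
#' @export
simulate_fx_dataset <- function(condition, n_curves, protocol = protocol_spec(),
                                seed = 1) {
  if (is.character(condition)) condition <- make_condition(condition)
  if (n_curves < 1) abort_domain("`n_curves` must be >= 1.")
  withr::with_seed(seed, simulate_fx_batch(condition, n_curves, protocol))
}

simulate_fx_batch <- function(condition, n_curves, protocol,
                              cycle_offset = 0L) {
  wlc <- wlc_params()
  sp <- condition$species
  p <- protocol
  n_s <- round(p$force_max / p$loading_rate * p$sample_rate)
  f_up <- p$loading_rate * seq_len(n_s) / p$sample_rate

  # per-cycle truth
  idx <- sample.int(nrow(sp), n_curves, replace = TRUE, prob = sp$prevalence)
  species <- sp$species[idx]
  folded <- species != "none"
  dl <- numeric(n_curves)
  fr <- rep(Inf, n_curves)
  if (any(folded)) {
    dl[folded] <- rnorm_pos(sum(folded), sp$delta_L_mean[idx[folded]],
                            pmax(sp$delta_L_sd[idx[folded]], 1e-6))
    fr[folded] <- sample_rupture_force(
      sum(folded), sp$intrinsic_rate[idx[folded]],
      sp$barrier_distance[idx[folded]], p$loading_rate, wlc$thermal_energy
    )
  }
  censored <- folded & fr >= p$force_max
  fr[censored] <- Inf

  ratio_up <- wlc_ratio(pmax(f_up, 1e-8), wlc)
  rows_per_cycle <- 2L * n_s
  total <- rows_per_cycle * n_curves

  force <- numeric(total)
  ext <- numeric(total)
  for (i in seq_len(n_curves)) {
    off <- (i - 1L) * rows_per_cycle
    ruptured <- f_up >= fr[i]
    if (is.finite(fr[i])) {
      dF <- p$trap_stiffness * dl[i] * wlc_ratio(fr[i], wlc)
      f_str <- f_up - dF * ruptured
    } else {
      f_str <- f_up
    }
    contour_str <- p$handle_contour + dl[i] * ruptured
    ext_str <- contour_str * pmax(wlc_ratio(pmax(f_str, 1e-8), wlc), 0)
    f_rel <- rev(f_up)
    contour_rel <- p$handle_contour + dl[i] * any(ruptured)
    ext_rel <- contour_rel * pmax(rev(ratio_up), 0)
    force[off + seq_len(n_s)] <- f_str
    force[off + n_s + seq_len(n_s)] <- f_rel
    ext[off + seq_len(n_s)] <- ext_str
    ext[off + n_s + seq_len(n_s)] <- ext_rel
  }
  force <- force + rnorm(total, 0, p$noise_sd_force)
  ext <- ext + rnorm(total, 0, p$noise_sd_extension)

  cycle_id <- rep(cycle_offset + seq_len(n_curves), each = rows_per_cycle)
  trace <- tibble(
    time_s = (seq_len(total) - 1L) / p$sample_rate,
    force_pN = force,
    extension_nm = ext,
    cycle_id = cycle_id,
    phase = rep(rep(c("stretch", "relax"), each = n_s), n_curves)
  )
  truth <- tibble(
    cycle_id = cycle_offset + seq_len(n_curves),
    species = species,
    true_delta_L_nm = dl,
    true_rupture_force_pN = ifelse(is.finite(fr), fr, NA_real_),
    censored = censored
  )
  structure(list(trace = trace, truth = truth, protocol = p,
                 condition = condition$name),
            class = "fx_dataset")
}

#' @export
print.fx_dataset <- function(x, ...) {
  cat("<fx_dataset>", x$condition, "-", nrow(x$truth), "cycles,",
      nrow(x$trace), "samples\n")
  invisible(x)
}

#' Write a trace dataset and its truth manifest to disk
#'
#' The trace is written as UTF-8 TSV (`time_s`, `force_pN`, `extension_nm`,
#' `cycle_id`, `phase`) and the manifest as a JSON array.
#'
#' @param dataset An `fx_dataset`.
#' @param trace_path Path of the TSV trace file.
#' @param manifest_path Optional path of the JSON truth manifest.
#' @return `trace_path`, invisibly.
#' @export
write_fx_dataset <- function(dataset, trace_path, manifest_path = NULL) {
  readr::write_tsv(dataset$trace, trace_path)
  if (!is.null(manifest_path)) {
    jsonlite::write_json(dataset$truth, manifest_path, digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(trace_path)
}

#' Read a trace dataset written by [write_fx_dataset()]
#'
#' @param trace_path Path of the TSV trace file.
#' @return A trace tibble.
#' @export
read_fx_trace <- function(trace_path) {
  readr::read_tsv(trace_path, show_col_types = FALSE)
}
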