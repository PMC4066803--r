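# Rupture-event detection on filtered force-extension cycles.
#
# An event is a drop of at least `drop_min` pN within at most `gap_max`
# consecutive filtered samples during the stretch phase. delta-L is measured
# two ways: from the two data points flanking the rupture (corrected to a
# common force through the local tether compliance) and from the difference
# of one-parameter WLC contour-length fits to the stretch segment before the
# rupture and to the relax curve.

#' Detect rupture events in one filtered cycle
#'
#' @param cycle One cycle tibble (filtered; columns `time_s`, `force_pN`,
#'   `extension_nm`, `phase`, `cycle_id`).
#' @param wlc A [wlc_params()] object.
#' @param conv An [nt_conversion()] object.
#' @param handle_contour Nominal tether contour length in nm (fallback for
#'   the compliance slope when the relax fit is unavailable).
#' @param drop_min Minimum force drop, pN.
#' @param gap_max Maximum span of the drop, filtered samples.
#' @param delta_L_window Accepted delta-L range in nm; events outside are
#'   flagged as artifacts (`accepted = FALSE`).
#' @param fit_fmin Lower force bound of the WLC contour fits, pN.
#' @return Tibble of events (possibly empty): `cycle_id`, `rupture_force`,
#'   `delta_x`, `delta_L_flank`, `delta_L_wlcfit`, `delta_L`, `nt`,
#'   `accepted`. At most one accepted event (the largest delta-L) is retained
#'   per cycle; additional detections are dropped with attribute `n_multi`.
#' @export
detect_ruptures <- function(cycle, wlc = wlc_params(), conv = nt_conversion(),
                            handle_contour = 1595, drop_min = 1.0,
                            gap_max = 3, delta_L_window = c(0.5, 10),
                            fit_fmin = 10) {
  s <- cycle[cycle$phase == "stretch", , drop = FALSE]
  if (nrow(s) < 5) abort_data("Cycle has no usable stretch phase.")
  r <- cycle[cycle$phase == "relax", , drop = FALSE]
  f <- s$force_pN
  x <- s$extension_nm
  n <- length(f)
  id <- cycle$cycle_id[1]

  # candidate drop start indices over gaps 1..gap_max
  starts <- integer(0)
  for (g in seq_len(gap_max)) {
    d <- f[(1 + g):n] - f[seq_len(n - g)]
    starts <- c(starts, which(d <= -drop_min))
  }
  empty <- tibble(
    cycle_id = integer(0), rupture_force = numeric(0), delta_x = numeric(0),
    delta_L_flank = numeric(0), delta_L_wlcfit = numeric(0),
    delta_L = numeric(0), nt = integer(0), accepted = logical(0)
  )
  if (length(starts) == 0) return(empty)
  starts <- sort(unique(starts))
  cluster <- cumsum(c(1L, diff(starts) > gap_max + 2L))

  # relax-branch contour fit: closed-form least squares of x = L * ratio(F)
  L_relax <- wlc_contour_fit(r$force_pN, r$extension_nm, wlc,
                             fmin = fit_fmin, fmax = max(f) - 1)
  ramp_step <- median(diff(f))

  ev <- purrr::map_dfr(split(starts, cluster), function(ix) {
    i0 <- ix[1]
    lo <- max(1L, i0 - 2L)
    pre <- lo - 1L + which.max(f[lo:min(i0 + 1L, n)])
    hi <- min(n, pre + gap_max + 4L)
    post <- pre + which.min(f[(pre + 1L):hi])
    # flanking points sit one smoothing window clear of the transition so the
    # filter's step response does not bias them
    pre1 <- max(1L, pre - 2L)
    post1 <- min(n, post + 2L)
    f_rupt <- f[pre1] + ramp_step * (pre - pre1)
    if (f_rupt <= 0) return(empty)
    # translate both flanking points to the rupture force along the tether's
    # WLC curve (exact ratio difference, not a linearised slope: the drop can
    # span several pN and the WLC compliance is curved)
    slope_contour <- if (is.finite(L_relax)) L_relax else handle_contour
    shift <- function(fi) {
      slope_contour * (wlc_ratio(f_rupt, wlc) - wlc_ratio(max(fi, 1e-3), wlc))
    }
    dx <- (x[post1] + shift(f[post1])) - (x[pre1] + shift(f[pre1]))
    dl_flank <- max(dx, 0) / wlc_ratio(f_rupt, wlc)
    L_stretch <- wlc_contour_fit(f[seq_len(max(pre1 - 1L, 2L))],
                                 x[seq_len(max(pre1 - 1L, 2L))], wlc,
                                 fmin = fit_fmin, fmax = f_rupt - 1.5)
    dl_fit <- if (is.finite(L_stretch) && is.finite(L_relax))
      L_relax - L_stretch else NA_real_
    dl <- if (is.finite(dl_fit)) dl_fit else dl_flank
    tibble(
      cycle_id = id,
      rupture_force = f_rupt,
      delta_x = dx,
      delta_L_flank = dl_flank,
      delta_L_wlcfit = dl_fit,
      delta_L = dl,
      nt = if (dl > 0) nt_count(dl, conv) else NA_integer_,
      accepted = dl >= delta_L_window[1] & dl <= delta_L_window[2]
    )
  })
  if (nrow(ev) == 0) return(empty)
  acc <- ev[ev$accepted, , drop = FALSE]
  n_multi <- max(0L, nrow(acc) - 1L)
  if (nrow(acc) > 1) {
    acc <- acc[which.max(acc$delta_L), , drop = FALSE]
  }
  out <- acc
  attr(out, "n_multi") <- n_multi
  out
}

# One-parameter WLC contour fit L = sum(x * rho) / sum(rho^2), rho = ratio(F),
# over samples with force in [fmin, fmax].
wlc_contour_fit <- function(force, extension, wlc, fmin, fmax) {
  ok <- is.finite(force) & force >= fmin & force <= fmax
  if (sum(ok) < 10) return(NA_real_)
  rho <- wlc_ratio(pmax(force[ok], 1e-8), wlc)
  sum(extension[ok] * rho) / sum(rho^2)
}

#' Detect events across a whole dataset
#'
#' Filters a raw trace, segments it into cycles, and runs rupture detection
#' on every cycle.
#'
#' @param dataset An `fx_dataset` (from [simulate_fx_dataset()]) or a raw
#'   trace tibble.
#' @param window,polyorder,decimate_to Passed to [filter_trace()].
#' @param ... Passed to [detect_ruptures()].
#' @return Tibble of accepted events (one row per event-bearing cycle) with
#'   attributes `n_curves` and `n_multi`.
#' @export
detect_events <- function(dataset, window = 21, polyorder = 2,
                          decimate_to = 100, ...) {
  trace <- if (inherits(dataset, "fx_dataset")) dataset$trace else dataset
  filtered <- filter_trace(trace, window, polyorder, decimate_to)
  cycles <- segment_cycles(filtered)
  evs <- purrr::map(cycles, detect_ruptures, ...)
  n_multi <- sum(vapply(evs, function(e) attr(e, "n_multi") %||% 0L,
                        integer(1)))
  out <- dplyr::bind_rows(evs)
  if (n_multi > 0) {
    warn(sprintf(
      "%d cycle(s) had multiple accepted events; kept the largest delta-L.",
      n_multi))
  }
  attr(out, "n_curves") <- length(cycles)
  attr(out, "n_multi") <- n_multi
  out
}

#' Simulate and detect in batches
#'
#' Memory-bounded convenience wrapper for large datasets: simulates cycles in
#' batches, runs the filter/segment/detect pipeline on each batch, discards
#' the raw samples and accumulates events and truth.
#'
#' @param condition A [make_condition()] object or condition name.
#' @param n_curves Total number of cycles.
#' @param protocol A [protocol_spec()] object.
#' @param seed Integer seed.
#' @param batch_size Cycles per batch.
#' @param ... Passed to [detect_ruptures()].
#' @return List with `events` (tibble), `truth` (tibble), `n_curves`.
#' @export
simulate_and_detect <- function(condition, n_curves,
                                protocol = protocol_spec(), seed = 1,
                                batch_size = 100, ...) {
  if (is.character(condition)) condition <- make_condition(condition)
  offsets <- seq(0L, n_curves - 1L, by = batch_size)
  pieces <- withr::with_seed(seed, {
    lapply(offsets, function(off) {
      nb <- min(batch_size, n_curves - off)
      ds <- simulate_fx_batch(condition, nb, protocol, cycle_offset = off)
      ev <- suppressWarnings(detect_events(ds,
        handle_contour = protocol$handle_contour, ...))
      list(events = ev, truth = ds$truth)
    })
  })
  events <- dplyr::bind_rows(lapply(pieces, `[[`, "events"))
  truth <- dplyr::bind_rows(lapply(pieces, `[[`, "truth"))
  list(events = events, truth = truth, n_curves = n_curves,
       condition = condition$name)
}
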