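# Savitzky-Golay filtering and cycle segmentation of raw traces.

#' Savitzky-Golay filter and decimate a trace
#'
#' Smooths the force and extension channels with a Savitzky-Golay filter
#' (polynomial reproduction up to `polyorder`, so constants and linear ramps
#' pass unchanged) and decimates from the acquisition rate to `decimate_to`.
#' Filtering is applied per cycle so that cycle boundaries do not bleed.
#'
#' @param trace Trace tibble with `time_s`, `force_pN`, `extension_nm` and
#'   optionally `cycle_id`.
#' @param window Odd filter window length in samples (> `polyorder`).
#' @param polyorder Polynomial order of the filter.
#' @param decimate_to Output rate, Hz.
#' @return Filtered, decimated trace tibble with attribute `sample_rate`.
#' @export
filter_trace <- function(trace, window = 21, polyorder = 2, decimate_to = 100) {
  if (window %% 2 == 0 || window <= polyorder) {
    abort_config("`window` must be odd and greater than `polyorder`.")
  }
  dt <- median(diff(head(trace$time_s, 1000)))
  rate <- round(1 / dt)
  if (rate < decimate_to) {
    abort_config("Input rate is below the requested decimation rate.")
  }
  k <- max(1L, round(rate / decimate_to))
  ids <- if ("cycle_id" %in% names(trace)) trace$cycle_id else
    rep(1L, nrow(trace))
  pieces <- split(seq_len(nrow(trace)), ids)
  f <- trace$force_pN
  x <- trace$extension_nm
  keep <- integer(0)
  for (ix in pieces) {
    if (length(ix) > window) {
      f[ix] <- signal::sgolayfilt(f[ix], p = polyorder, n = window)
      x[ix] <- signal::sgolayfilt(x[ix], p = polyorder, n = window)
    }
    keep <- c(keep, ix[seq(1L, length(ix), by = k)])
  }
  out <- trace
  out$force_pN <- f
  out$extension_nm <- x
  out <- out[sort(keep), , drop = FALSE]
  attr(out, "sample_rate") <- rate / k
  out
}

# RMS attenuation of white noise by a Savitzky-Golay smoother: sqrt of the
# sum of squared central-row coefficients. Used by tests as the closed-form
# oracle for the filtered noise SD.
sg_noise_attenuation <- function(window, polyorder) {
  m <- (window - 1) / 2
  A <- outer(-m:m, 0:polyorder, `^`)
  h <- A %*% solve(crossprod(A), t(A))[, m + 1]
  sqrt(sum(h^2))
}

#' Segment a trace into force-extension cycles
#'
#' Splits a trace into stretch/relax cycles. When a `cycle_id` column is
#' present it is authoritative; otherwise cycles are inferred from the turning
#' points of the (lightly smoothed) force channel: each rising run is a
#' stretch phase, each falling run a relax phase, and one cycle is a stretch
#' followed by its relax.
#'
#' @param trace Trace tibble.
#' @return A list of cycle tibbles, each with contiguous `phase` labels.
#' @export
segment_cycles <- function(trace) {
  if (nrow(trace) < 2) abort_data("Trace too short to segment.")
  if ("cycle_id" %in% names(trace)) {
    return(unname(split(trace, trace$cycle_id)))
  }
  f <- as.numeric(trace$force_pN)
  if (length(f) > 51) {
    sm <- stats::filter(f, rep(1 / 11, 11), sides = 2)
    f <- zoo_fill(as.numeric(sm))
  }
  dir <- sign(diff(f))
  dir[dir == 0] <- NA
  dir <- zoo_fill(dir)
  dir <- sign(dir)
  r <- rle(dir)
  # merge noise-induced micro-runs into their longer neighbours
  min_run <- max(2L, floor(length(f) * 0.02))
  while (length(r$lengths) > 1 && min(r$lengths) < min_run) {
    i <- which.min(r$lengths)
    j <- if (i == 1) 2L else i - 1L
    r$lengths[j] <- r$lengths[j] + r$lengths[i]
    r$lengths <- r$lengths[-i]
    r$values <- r$values[-i]
    r <- rle(inverse.rle(r))
  }
  run_end <- cumsum(r$lengths) + 1L  # sample index ending each run
  run_start <- c(1L, head(run_end, -1))
  phase_of <- ifelse(r$values > 0, "stretch", "relax")
  # group runs into cycles: a new cycle starts at each stretch run
  cyc <- cumsum(phase_of == "stretch")
  if (cyc[1] == 0) cyc <- cyc + 1L
  cycles <- vector("list", max(cyc))
  cycle_rows <- trace
  cycle_rows$cycle_id <- NA_integer_
  cycle_rows$phase <- NA_character_
  for (k in seq_along(r$lengths)) {
    rows <- run_start[k]:min(run_end[k], nrow(trace))
    cycle_rows$cycle_id[rows] <- cyc[k]
    cycle_rows$phase[rows] <- phase_of[k]
  }
  unname(split(cycle_rows, cycle_rows$cycle_id))
}

zoo_fill <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0) return(rep(0, length(x)))
  approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}
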