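# PoDNano: kernel-density population deconvolution with bootstrap support.
#
# A Gaussian KDE (Silverman bandwidth, reused across resamples for stability)
# is computed on the pooled values; its local maxima are candidate population
# peaks. Each bootstrap resample recomputes the KDE peaks on the same grid;
# resampled peaks are matched to pooled peaks by nearest centre within a
# matching radius. Peaks supported by fewer than `min_support` of the
# resamples are dropped; percentile intervals of the matched centres give the
# bootstrap CI of each peak.

#' Population deconvolution by KDE and bootstrap (PoDNano)
#'
#' @param values Numeric vector of measurements (delta-L in nm or force in
#'   pN); at least 20 values.
#' @param n_boot Number of bootstrap resamples (default 3000).
#' @param seed Integer seed.
#' @param bw Kernel bandwidth; default Silverman's rule on the pooled sample.
#' @param match_radius Peak-matching radius across resamples (same units as
#'   `values`).
#' @param min_support Minimum fraction of resamples that must reproduce a
#'   peak for it to be retained.
#' @param min_height Minimum density of a candidate peak, as a fraction of
#'   the tallest peak (suppresses stray-outlier bumps).
#' @param grid_n KDE grid size.
#' @return Object of class `podnano` with the KDE grid and a peak table
#'   (`center`, `support`, `ci_lo`, `ci_hi`, `retained`).
#' @examples
#' set.seed(1)
#' p <- podnano(rnorm(200, 5.5, 0.2), n_boot = 200)
#' tidy(p)
#' @export
podnano <- function(values, n_boot = 3000, seed = 1, bw = NULL,
                    match_radius = 1.0, min_support = 0.5, min_height = 0.05,
                    grid_n = 512) {
  values <- values[is.finite(values)]
  if (length(values) < 20) {
    abort_data("PoDNano needs at least 20 values.")
  }
  if (n_boot < 1) abort_config("`n_boot` must be >= 1.")
  bw <- bw %||% stats::bw.nrd0(values)
  if (!is.finite(bw) || bw <= 0) {
    spread <- diff(range(values))
    bw <- if (spread > 0) spread / 100 else 0.01
  }
  from <- min(values) - 3 * bw
  to <- max(values) + 3 * bw
  den <- density(values, bw = bw, from = from, to = to, n = grid_n)
  peaks0 <- kde_peaks(den$x, den$y, min_height)
  n <- length(values)
  k <- nrow(peaks0)
  matched <- vector("list", k)
  hit <- matrix(FALSE, n_boot, max(k, 1))
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      vb <- values[sample.int(n, n, replace = TRUE)]
      db <- density(vb, bw = bw, from = from, to = to, n = grid_n)
      pb <- kde_peaks(db$x, db$y, min_height)
      if (k == 0 || nrow(pb) == 0) next
      for (j in seq_len(nrow(pb))) {
        d <- abs(peaks0$center - pb$center[j])
        i <- which.min(d)
        if (d[i] <= match_radius) {
          hit[b, i] <- TRUE
          matched[[i]] <- c(matched[[i]], pb$center[j])
        }
      }
    }
  })
  peaks <- peaks0
  if (k > 0) {
    peaks$support <- colMeans(hit[, seq_len(k), drop = FALSE])
    cis <- t(vapply(matched, function(v) {
      if (length(v) < 2) return(c(NA_real_, NA_real_))
      quantile(v, c(0.025, 0.975), names = FALSE)
    }, numeric(2)))
    peaks$ci_lo <- cis[, 1]
    peaks$ci_hi <- cis[, 2]
    peaks$retained <- peaks$support >= min_support
  } else {
    peaks$support <- numeric(0)
    peaks$ci_lo <- numeric(0)
    peaks$ci_hi <- numeric(0)
    peaks$retained <- logical(0)
  }
  structure(
    list(kde = tibble(x = den$x, density = den$y),
         peaks = peaks, bw = bw, n = n, n_boot = n_boot, seed = seed,
         match_radius = match_radius, min_support = min_support),
    class = "podnano"
  )
}

kde_peaks <- function(x, y, min_height = 0.05) {
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
               FALSE)
  # boundary maxima count as peaks too (degenerate single-value data)
  if (y[1] > y[2]) is_peak[1] <- TRUE
  if (y[n] > y[n - 1]) is_peak[n] <- TRUE
  is_peak <- is_peak & y >= min_height * max(y)
  tibble(center = x[is_peak], density = y[is_peak]) |>
    dplyr::arrange(center)
}

#' @export
print.podnano <- function(x, ...) {
  cat("<podnano> n =", x$n, ", bw =", signif(x$bw, 3),
      ",", sum(x$peaks$retained), "retained peak(s)\n")
  print(x$peaks)
  invisible(x)
}

#' @rdname podnano
#' @param x,object A `podnano` object.
#' @param ... Unused.
#' @export
tidy.podnano <- function(x, ...) {
  x$peaks |>
    dplyr::filter(retained) |>
    dplyr::select(center, support, ci_lo, ci_hi)
}

#' @rdname podnano
#' @export
glance.podnano <- function(x, ...) {
  tibble(n = x$n, bw = x$bw, n_boot = x$n_boot,
         n_peaks = sum(x$peaks$retained))
}
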