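# Force-pump-probe kinetics: folded fraction versus incubation time and
# single-exponential time-constant fits with a detection-floor flag.

#' Folded-fraction series from FPP probe events
#'
#' Assigns each probe event to a delta-L mixture component (maximum
#' posterior), groups components into species classes, and tabulates the
#' folded fraction per incubation time and group with binomial standard
#' errors.
#'
#' Default grouping by component centre: components below 4.9 nm form the
#' hybrid-quadruplex ("HQ") group (2G-HQ and 3G-HQ; under conditions without
#' transcription this delta-L range holds the G-triplex instead), components
#' at or above 4.9 nm form the "GQ" group.
#'
#' @param fpp_events Tibble from [simulate_fpp_series()] (columns
#'   `incubation_time_s`, `event`, `delta_L`).
#' @param model Optional `gmm_fit` over the event delta-L values; fitted
#'   internally when `NULL` (k from a PoDNano peak scan).
#' @param groups Optional named list mapping group label to component
#'   indices, e.g. `list(HQ = 1:2, GQ = 3)`.
#' @param n_boot_podnano Bootstrap resamples of the internal peak scan.
#' @param seed Seed for the internal peak scan.
#' @return `fpp_series` tibble: `group`, `incubation_time_s`, `fraction`,
#'   `n_cycles`, `se`.
#' @export
folded_fraction_series <- function(fpp_events, model = NULL, groups = NULL,
                                   n_boot_podnano = 200, seed = 1) {
  if (!all(c("incubation_time_s", "event", "delta_L") %in% names(fpp_events))) {
    abort_domain("`fpp_events` needs incubation_time_s, event, delta_L.")
  }
  ev <- fpp_events[fpp_events$event & is.finite(fpp_events$delta_L), ,
                   drop = FALSE]
  totals <- fpp_events |>
    dplyr::count(incubation_time_s, name = "n_cycles")
  if (any(totals$n_cycles == 0)) {
    warn("Incubation times with zero cycles omitted.")
    totals <- totals[totals$n_cycles > 0, , drop = FALSE]
  }
  if (nrow(ev) == 0) {
    out <- totals |>
      dplyr::mutate(group = "all", fraction = 0,
                    se = sqrt(0.5 * 0.5 / n_cycles)) |>
      dplyr::select(group, incubation_time_s, fraction, n_cycles, se)
    class(out) <- c("fpp_series", class(out))
    return(out)
  }
  if (is.null(model)) {
    pk <- podnano(ev$delta_L, n_boot = n_boot_podnano, seed = seed)
    centers <- tidy(pk)$center
    model <- fit_gaussian_mixture(ev$delta_L, k = max(length(centers), 1),
                                  init = centers)
  }
  post <- gmm_posterior(model, ev$delta_L)
  comp <- max.col(post, ties.method = "first")
  if (is.null(groups)) {
    centers <- model$components$mean
    groups <- list(HQ = which(centers < 4.9), GQ = which(centers >= 4.9))
    groups <- groups[vapply(groups, length, integer(1)) > 0]
  }
  out <- purrr::imap_dfr(groups, function(comps, label) {
    ev_g <- ev[comp %in% comps, , drop = FALSE]
    counts <- ev_g |>
      dplyr::count(incubation_time_s, name = "k")
    totals |>
      dplyr::left_join(counts, by = "incubation_time_s") |>
      dplyr::mutate(
        k = dplyr::coalesce(k, 0L),
        group = label,
        fraction = k / n_cycles,
        se = sqrt(pmax(fraction * (1 - fraction), 0.25 / n_cycles) / n_cycles)
      ) |>
      dplyr::select(group, incubation_time_s, fraction, n_cycles, se)
  }) |>
    dplyr::arrange(group, incubation_time_s)
  attr(out, "model") <- model
  class(out) <- c("fpp_series", class(out))
  out
}

#' Fit single-exponential folding kinetics
#'
#' Weighted least-squares fit of \eqn{f(t) = A (1 - e^{-t/\tau})} to a
#' folded-fraction series, with inverse binomial-variance weights
#' (+0.5 continuity correction at 0/1 fractions), grid restarts over tau
#' decades on non-convergence, and a seeded parametric bootstrap CI. When the
#' fitted tau falls below the smallest incubation time the series has
#' saturated within the protocol's resolution and `floor_flag` is set
#' (report tau as "< t_min").
#'
#' @param points Tibble with `incubation_time_s`, `fraction`, `n_cycles`
#'   (one group of a [folded_fraction_series()]).
#' @param n_boot Parametric bootstrap replicates.
#' @param seed Integer seed.
#' @param conf Confidence level for the percentile CI.
#' @return `fpp_fit` object: `A`, `tau` (s), `tau_ci`, `A_ci`, `floor_flag`,
#'   plus the points and bootstrap draws.
#' @examples
#' t <- c(0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5)
#' pts <- tibble::tibble(incubation_time_s = t,
#'                       fraction = 0.27 * (1 - exp(-t / 0.03)),
#'                       n_cycles = 500)
#' fit_exponential(pts)
#' @export
fit_exponential <- function(points, n_boot = 200, seed = 1, conf = 0.95) {
  need <- c("incubation_time_s", "fraction")
  if (!all(need %in% names(points))) {
    abort_domain("`points` needs incubation_time_s and fraction columns.")
  }
  if (nrow(points) < 4) abort_data("Need at least 4 time points.")
  t <- points$incubation_time_s
  y <- points$fraction
  n <- if ("n_cycles" %in% names(points)) points$n_cycles else
    rep(100, length(t))
  w <- exp_weights(y, n)
  fit <- fit_exp_once(t, y, w)
  if (is.null(fit)) abort_data("Exponential fit failed to converge.")
  A <- fit[["A"]]
  tau <- fit[["tau"]]
  p_hat <- pmin(pmax(A * (1 - exp(-t / tau)), 0), 1)
  boots <- withr::with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      yb <- rbinom(length(t), n, p_hat) / n
      fb <- fit_exp_once(t, yb, exp_weights(yb, n))
      if (is.null(fb)) c(NA_real_, NA_real_) else fb
    }, numeric(2)))
  })
  alpha <- (1 - conf) / 2
  tau_ci <- quantile(boots[, 2], c(alpha, 1 - alpha), na.rm = TRUE,
                     names = FALSE)
  A_ci <- quantile(boots[, 1], c(alpha, 1 - alpha), na.rm = TRUE,
                   names = FALSE)
  structure(
    list(A = A, tau = tau, tau_ci = tau_ci, A_ci = A_ci,
         floor_flag = tau < min(t), t_min = min(t),
         points = tibble(incubation_time_s = t, fraction = y, n_cycles = n),
         boots = boots, n_boot = n_boot, seed = seed, conf = conf),
    class = "fpp_fit"
  )
}

exp_weights <- function(y, n) {
  p <- (y * n + 0.5) / (n + 1)
  n / (p * (1 - p))
}

fit_exp_once <- function(t, y, w) {
  A0 <- max(max(y), 1e-3)
  i63 <- which(y >= 0.63 * A0)
  tau0 <- if (length(i63) > 0) max(t[min(i63)], min(t[t > 0])) else median(t)
  starts <- unique(c(tau0, 10^seq(-3, 1, by = 1)))
  best <- NULL
  best_ss <- Inf
  for (tau_s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * (1 - exp(-t / tau)),
        start = list(A = A0, tau = tau_s),
        weights = w,
        lower = c(A = 0, tau = 1e-6),
        upper = c(A = 1.5, tau = 1e4),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL, warning = function(e) NULL
    )
    if (!is.null(fit)) {
      ss <- sum(w * stats::resid(fit)^2)
      if (is.finite(ss) && ss < best_ss) {
        best_ss <- ss
        best <- coef(fit)
      }
    }
  }
  if (is.null(best)) NULL else c(A = unname(best["A"]), tau = unname(best["tau"]))
}

#' @export
print.fpp_fit <- function(x, ...) {
  tau_txt <- if (x$floor_flag) {
    sprintf("< %g s (below the protocol floor)", x$t_min)
  } else {
    sprintf("%.4g s [%.4g, %.4g]", x$tau, x$tau_ci[1], x$tau_ci[2])
  }
  cat(sprintf("<fpp_fit> A = %.3f, tau = %s\n", x$A, tau_txt))
  invisible(x)
}

#' @rdname fit_exponential
#' @param x A `fpp_fit` object.
#' @param ... Unused.
#' @export
tidy.fpp_fit <- function(x, ...) {
  tibble(
    term = c("A", "tau"),
    estimate = c(x$A, x$tau),
    conf_low = c(x$A_ci[1], x$tau_ci[1]),
    conf_high = c(x$A_ci[2], x$tau_ci[2])
  )
}

#' @rdname fit_exponential
#' @export
glance.fpp_fit <- function(x, ...) {
  tibble(A = x$A, tau_s = x$tau, tau_lo = x$tau_ci[1], tau_hi = x$tau_ci[2],
         floor_flag = x$floor_flag, n_points = nrow(x$points))
}
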