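# ggplot2 visualisations of the result objects.

#' Plot one force-extension cycle
#'
#' @param cycle A cycle tibble (columns `extension_nm`, `force_pN`, `phase`).
#' @return A ggplot object.
#' @export
plot_fx_cycle <- function(cycle) {
  ggplot(cycle, aes(x = extension_nm, y = force_pN, colour = phase)) +
    geom_path(alpha = 0.8) +
    labs(x = "extension (nm)", y = "force (pN)", colour = NULL) +
    theme_minimal()
}

#' @rdname podnano
#' @param object A `podnano` object.
#' @export
autoplot.podnano <- function(object, ...) {
  pk <- object$peaks[object$peaks$retained, , drop = FALSE]
  ggplot(object$kde, aes(x = x, y = density)) +
    geom_area(fill = "grey85") +
    geom_line() +
    geom_vline(data = pk, aes(xintercept = center), linetype = 2,
               colour = "firebrick") +
    geom_rect(data = pk,
              aes(xmin = ci_lo, xmax = ci_hi, ymin = -Inf, ymax = Inf),
              inherit.aes = FALSE, alpha = 0.15, fill = "firebrick") +
    labs(x = "value", y = "density",
         title = sprintf("PoDNano: %d retained peak(s), %d resamples",
                         nrow(pk), object$n_boot)) +
    theme_minimal()
}

#' @rdname fit_gaussian_mixture
#' @export
autoplot.gmm_fit <- function(object, ...) {
  grid <- seq(min(object$data), max(object$data), length.out = 400)
  comp_df <- purrr::imap_dfr(seq_len(nrow(object$components)), function(j, i) {
    co <- object$components
    tibble(x = grid, component = factor(j),
           density = co$weight[j] * dnorm(grid, co$mean[j], co$sd[j]))
  })
  total <- comp_df |>
    dplyr::summarise(density = sum(density), .by = x)
  ggplot(tibble(x = object$data), aes(x = x)) +
    geom_histogram(aes(y = ggplot2::after_stat(density)), bins = 40,
                   fill = "grey85", colour = "grey60") +
    geom_line(data = comp_df, aes(y = density, colour = component),
              linetype = 2) +
    geom_line(data = total, aes(y = density), linewidth = 0.8) +
    labs(x = "value", y = "density") +
    theme_minimal()
}

#' @rdname random_force_deconvolution
#' @param object A `force_deconv` object.
#' @export
autoplot.force_deconv <- function(object, ...) {
  d <- tibble(force = object$forces,
              class = factor(object$labels))
  ggplot(d, aes(x = force, fill = class)) +
    geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    labs(x = "rupture force (pN)", y = "count", fill = "class") +
    theme_minimal()
}

#' @rdname fit_exponential
#' @param object An `fpp_fit` object.
#' @export
autoplot.fpp_fit <- function(object, ...) {
  pts <- object$points
  grid <- tibble(
    incubation_time_s = exp(seq(log(min(pts$incubation_time_s)),
                                log(max(pts$incubation_time_s)),
                                length.out = 200))
  )
  grid$fraction <- object$A * (1 - exp(-grid$incubation_time_s / object$tau))
  ggplot(pts, aes(x = incubation_time_s, y = fraction)) +
    geom_point() +
    geom_line(data = grid, colour = "steelblue") +
    scale_x_log10() +
    labs(x = "incubation time (s)", y = "folded fraction",
         subtitle = if (object$floor_flag)
           sprintf("tau < %g s (protocol floor)", object$t_min)
         else sprintf("tau = %.3g s", object$tau)) +
    theme_minimal()
}
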