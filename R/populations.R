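# Percent-formation accounting, the GT/HQ ratio deconvolution, and random
# deconvolution of overlapping rupture-force populations.

delta_class_label <- function(center) {
  dplyr::case_when(
    center < 2.8 ~ "2G-HQ",
    center < 4.9 ~ "3G-HQ/GT",
    TRUE ~ "GQ"
  )
}

table1_classes <- c("2G-HQ", "3G-HQ/GT", "GQ", "none")

#' Percent formation of delta-L populations
#'
#' Assigns each event-bearing curve to the nearest Gaussian-mixture component
#' (maximum posterior over delta-L), labels components by their centre
#' (2G-HQ < 2.8 nm, 3G-HQ/GT < 4.9 nm, GQ otherwise), and reports percent
#' formation against the total number of curves; curves without an event form
#' the "none" (dsDNA / R-loop) class. Percentages are reported to one decimal
#' and sum exactly to 100.0 (largest-remainder rounding).
#'
#' @param events Events tibble (one accepted event per curve, column
#'   `delta_L`), e.g. from [detect_events()].
#' @param n_total_curves Total number of curves in the dataset.
#' @param model A `gmm_fit` over the event delta-L values.
#' @param condition Optional condition label carried into the summary.
#' @return `condition_summary` tibble: `condition`, `class`, `n`, `percent`;
#'   attributes `n_curves`, `n_events`.
#' @export
percent_formation <- function(events, n_total_curves, model,
                              condition = NA_character_) {
  n_events <- nrow(events)
  if (n_total_curves < n_events) {
    abort_domain("`n_total_curves` must be >= the number of event curves.")
  }
  labels <- character(0)
  if (n_events > 0) {
    post <- gmm_posterior(model, events$delta_L)
    comp <- max.col(post, ties.method = "first")
    co <- model$components
    outside <- vapply(seq_len(n_events), function(i) {
      all(abs(events$delta_L[i] - co$mean) > 4 * co$sd)
    }, logical(1))
    labels <- delta_class_label(co$mean[comp])
    labels[outside] <- "unassigned"
    if (any(outside)) {
      warn(sprintf("%d event(s) outside all components' 4-SD range.",
                   sum(outside)))
    }
  }
  classes <- table1_classes
  if (any(labels == "unassigned")) classes <- c(classes, "unassigned")
  counts <- setNames(integer(length(classes)), classes)
  tab <- table(labels)
  counts[names(tab)] <- as.integer(tab)
  counts["none"] <- n_total_curves - n_events
  pct <- unname(largest_remainder_percent(counts, n_total_curves, digits = 1))
  out <- tibble(
    condition = condition,
    class = classes,
    n = as.integer(counts),
    percent = pct
  )
  attr(out, "n_curves") <- n_total_curves
  attr(out, "n_events") <- n_events
  class(out) <- c("condition_summary", class(out))
  out
}

#' Split the mixed ~4-nm population into 3G-HQ and GT (worked arithmetic)
#'
#' The regular-transcription ~4-nm delta-L population mixes the three-G-tract
#' hybrid quadruplex (3G-HQ) and the G-triplex (GT). In the 7-deaza-GTP
#' transcription no hybrid forms, so its GT/GQ ratio is pure; assuming the
#' same GT/GQ ratio under regular transcription,
#' GT_reg = GQ_reg x (GT_deaza / GQ_deaza) and 3G-HQ = peak_total - GT_reg,
#' with one-decimal rounding and negative 3G-HQ clipped to zero.
#'
#' @param gq_reg GQ percent under regular transcription.
#' @param gt_deaza,gq_deaza GT and GQ percent under deaza transcription
#'   (`gq_deaza` > 0).
#' @param peak_total Total percent of the mixed ~4-nm population under
#'   regular transcription.
#' @return Tibble with `gt` and `hq3` percents (one decimal).
#' @examples
#' gt_hq_split(12.2, 8.1, 25.9, 13.2)  # GT 3.8, 3G-HQ 9.4
#' @export
gt_hq_split <- function(gq_reg, gt_deaza, gq_deaza, peak_total) {
  if (gq_deaza <= 0) abort_domain("`gq_deaza` must be > 0.")
  gt <- round1(gq_reg * gt_deaza / gq_deaza)
  hq3 <- round1(peak_total - gt)
  if (hq3 < 0) {
    warn("GT estimate exceeds the mixed-peak total; 3G-HQ clipped to 0.")
    hq3 <- 0
  }
  tibble(gt = gt, hq3 = hq3)
}

#' Deconvolve GT from 3G-HQ in a transcription summary
#'
#' Applies [gt_hq_split()] to a regular-transcription [percent_formation()]
#' summary using the deaza-transcription summary as the HQ-free reference,
#' replacing the mixed "3G-HQ/GT" row by separate "3G-HQ" and "GT" rows.
#'
#' @param summary_transcription,summary_deaza `condition_summary` tibbles.
#' @return The updated transcription summary.
#' @export
deconvolve_gt_hq <- function(summary_transcription, summary_deaza) {
  get <- function(s, cls) {
    v <- s$percent[s$class == cls]
    if (length(v) == 0) 0 else v
  }
  split <- gt_hq_split(
    gq_reg = get(summary_transcription, "GQ"),
    gt_deaza = get(summary_deaza, "3G-HQ/GT"),
    gq_deaza = get(summary_deaza, "GQ"),
    peak_total = get(summary_transcription, "3G-HQ/GT")
  )
  mixed <- which(summary_transcription$class == "3G-HQ/GT")
  row <- summary_transcription[mixed, , drop = FALSE]
  hq_row <- row
  hq_row$class <- "3G-HQ"
  hq_row$percent <- split$hq3
  hq_row$n <- NA_integer_
  gt_row <- row
  gt_row$class <- "GT"
  gt_row$percent <- split$gt
  gt_row$n <- NA_integer_
  out <- dplyr::bind_rows(
    summary_transcription[seq_len(mixed - 1), , drop = FALSE],
    hq_row, gt_row,
    summary_transcription[-seq_len(mixed), , drop = FALSE]
  )
  for (a in c("n_curves", "n_events")) {
    attr(out, a) <- attr(summary_transcription, a)
  }
  class(out) <- class(summary_transcription)
  out
}

#' Table-style aggregates of a deconvolved summary
#'
#' HQ total (2G-HQ + 3G-HQ), GQ/GT total, and the combined quadruplex
#' percentage rounded to an integer (text convention).
#'
#' @param summary A deconvolved `condition_summary` (rows 2G-HQ, 3G-HQ, GT,
#'   GQ, none) or an undeconvolved one (HQ total then spans the mixed row
#'   only when 3G-HQ is absent).
#' @return Tibble with `hq_total`, `gq_gt_total`, `quadruplex_total_rounded`.
#' @export
quad_aggregates <- function(summary) {
  get <- function(cls) {
    v <- summary$percent[summary$class %in% cls]
    if (length(v) == 0) 0 else sum(v)
  }
  hq <- get(c("2G-HQ", "3G-HQ"))
  gqgt <- get(c("GQ", "GT"))
  total <- get(c("2G-HQ", "3G-HQ", "GT", "GQ", "3G-HQ/GT"))
  tibble(
    hq_total = round1(hq),
    gq_gt_total = round1(gqgt),
    quadruplex_total = round1(total),
    quadruplex_total_rounded = round(total)
  )
}

#' Random deconvolution of two overlapping force populations
#'
#' Fits a two-component Gaussian mixture to rupture forces and assigns each
#' event to a class by a seeded Bernoulli draw with probability equal to its
#' posterior membership, the randomised assignment used for overlapping
#' populations. Returns per-event labels, class summaries and the fitted
#' mixture.
#'
#' @param forces Rupture forces in pN (>= 20 values).
#' @param k Number of classes (default 2).
#' @param seed Integer seed for the membership draws.
#' @return Object of class `force_deconv`: `labels` (1 = lowest-mean class),
#'   `classes` tibble (`class`, `n`, `mean_force`, `sd_force`,
#'   `component_mean`), and `fit`.
#' @export
random_force_deconvolution <- function(forces, k = 2, seed = 1) {
  forces <- forces[is.finite(forces)]
  if (length(forces) < 20) abort_data("Need at least 20 forces.")
  fit <- tryCatch(
    fit_gaussian_mixture(forces, k = k,
                         init = quantile(forces, (seq_len(k) - 0.5) / k,
                                         names = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$loglik)) {
    warn("Mixture fit failed; falling back to a single class.")
    labels <- rep(1L, length(forces))
    classes <- tibble(class = 1L, n = length(forces),
                      mean_force = mean(forces), sd_force = sd(forces),
                      component_mean = mean(forces))
    return(structure(list(labels = labels, classes = classes, fit = NULL,
                          forces = forces, seed = seed),
                     class = "force_deconv"))
  }
  post <- gmm_posterior(fit, forces)
  labels <- withr::with_seed(seed, sample_categorical(post))
  classes <- purrr::map_dfr(seq_len(k), function(j) {
    sel <- labels == j
    tibble(class = j, n = sum(sel),
           mean_force = if (any(sel)) mean(forces[sel]) else NA_real_,
           sd_force = if (sum(sel) > 1) sd(forces[sel]) else NA_real_,
           component_mean = fit$components$mean[j])
  })
  structure(list(labels = labels, classes = classes, fit = fit,
                 forces = forces, seed = seed),
            class = "force_deconv")
}

#' @export
print.force_deconv <- function(x, ...) {
  cat("<force_deconv>", length(x$forces), "events\n")
  print(x$classes)
  invisible(x)
}

#' @rdname random_force_deconvolution
#' @param x A `force_deconv` object.
#' @param ... Unused.
#' @export
tidy.force_deconv <- function(x, ...) x$classes
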