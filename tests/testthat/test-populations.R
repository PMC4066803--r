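# Population deconvolution: PoDNano, Gaussian mixtures, percent formation,
# the GT/3G-HQ ratio split and random force deconvolution.

test_that("PoDNano resolves the three delta-L populations", {
  devs <- NULL
  for (s in 101:110) {
    vals <- withr::with_seed(s, draw_delta_L_mixture(400, weights = rep(1, 3)))
    pk <- podnano(vals, n_boot = 200, seed = 1)
    peaks <- tidy(pk)
    expect_equal(nrow(peaks), 3)
    expect_true(all(abs(peaks$center - c(1.8, 3.8, 6.0)) < 0.35))
    expect_true(all(peaks$ci_lo <= peaks$center & peaks$center <= peaks$ci_hi))
    devs <- rbind(devs, abs(peaks$center - c(1.8, 3.8, 6.0)))
  }
  # typical deviation stays within the KDE's nanometre resolution
  expect_true(all(apply(devs, 2, median) < 0.2))
})

test_that("PoDNano handles single and degenerate populations", {
  vals <- withr::with_seed(15, rnorm(300, 5.5, 0.2))
  pk <- podnano(vals, n_boot = 300, seed = 1)
  peaks <- tidy(pk)
  expect_equal(nrow(peaks), 1)
  expect_lt(abs(peaks$center - 5.5), 0.1)
  flat <- podnano(rep(3.3, 50), n_boot = 50, seed = 1)
  expect_equal(nrow(tidy(flat)), 1)
  expect_lt(abs(tidy(flat)$center - 3.3), 0.05)
  expect_error(podnano(rnorm(10)), class = "quadtrace_data_error")
})

test_that("PoDNano peak count matches the generator across seeded runs", {
  hits <- vapply(1:20, function(s) {
    vals <- withr::with_seed(100 + s, draw_delta_L_mixture(400))
    nrow(tidy(podnano(vals, n_boot = 100, seed = s)))
  }, numeric(1))
  expect_gte(mean(hits == 3), 0.95)
})

test_that("the mixture EM recovers components and is order-invariant", {
  vals <- withr::with_seed(16, draw_delta_L_mixture(600))
  fit <- fit_gaussian_mixture(vals, k = 3, init = c(1.8, 3.8, 6.0))
  co <- fit$components
  se <- co$sd / sqrt(co$weight * fit$n)
  expect_true(all(abs(co$mean - c(1.8, 3.8, 6.0)) < 2.5 * pmax(se, 0.05)))
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  # k = 1 reduces to the sample moments
  one <- fit_gaussian_mixture(vals, k = 1)
  expect_equal(one$components$mean, mean(vals), tolerance = 1e-6)
  expect_equal(one$components$sd, sd(vals) * sqrt((length(vals) - 1) /
                                                    length(vals)),
               tolerance = 1e-3)
  # permutation invariance (canonical sorted-mean order)
  fit2 <- fit_gaussian_mixture(withr::with_seed(3, sample(vals)), k = 3,
                               init = c(1.8, 3.8, 6.0))
  expect_equal(fit$components, fit2$components, tolerance = 1e-8)
  expect_error(fit_gaussian_mixture(vals[1:10], k = 3),
               class = "quadtrace_data_error")
})

test_that("the EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  vals <- withr::with_seed(17, c(rnorm(300, 2, 0.3), rnorm(300, 6, 0.5)))
  ours <- fit_gaussian_mixture(vals, k = 2)
  ref <- mclust::Mclust(vals, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(ours$components$mean), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.05)
})

test_that("degenerate components are floored with a warning", {
  vals <- c(rep(2, 60), withr::with_seed(18, rnorm(60, 6, 0.5)))
  expect_warning(fit <- fit_gaussian_mixture(vals, k = 2, init = c(2, 6)),
                 "floor")
  expect_true(all(fit$components$sd >= 0.05 - 1e-12))
})

test_that("percent formation accounts for every curve and sums to 100", {
  vals <- withr::with_seed(19, draw_delta_L_mixture(200))
  gm <- fit_gaussian_mixture(vals, k = 3, init = c(1.8, 3.8, 6.0))
  ev <- tibble::tibble(cycle_id = seq_along(vals), delta_L = vals)
  ps <- percent_formation(ev, 500, gm)
  expect_equal(sum(ps$percent), 100, tolerance = 1e-9)
  expect_equal(ps$percent[ps$class == "none"], 100 * (500 - 200) / 500,
               tolerance = 0.11)
  # no events at all -> everything is duplex
  empty <- ev[0, ]
  ps0 <- percent_formation(empty, 100, gm)
  expect_equal(ps0$percent[ps0$class == "none"], 100)
  expect_error(percent_formation(ev, 100, gm),
               class = "quadtrace_domain_error")
  # property: random event counts still sum to 100.0 after rounding
  for (s in 1:10) {
    vals_s <- withr::with_seed(300 + s, draw_delta_L_mixture(37 + 7 * s))
    ev_s <- tibble::tibble(delta_L = vals_s)
    ps_s <- percent_formation(ev_s, 37 + 7 * s + 50, gm)
    expect_equal(sum(ps_s$percent), 100, tolerance = 1e-9)
  }
})

test_that("the GT/3G-HQ ratio split reproduces the worked arithmetic", {
  split <- gt_hq_split(12.2, 8.1, 25.9, 13.2)
  expect_identical(split$gt, 3.8)
  expect_identical(split$hq3, 9.4)
  # zero GT in the reference: the whole mixed peak is hybrid
  z <- gt_hq_split(12.2, 0, 25.9, 13.2)
  expect_identical(z$gt, 0)
  expect_identical(z$hq3, 13.2)
  # clipping when the GT estimate exceeds the peak total
  expect_warning(cl <- gt_hq_split(20, 20, 10, 13.2), "clipped")
  expect_identical(cl$hq3, 0)
  expect_error(gt_hq_split(12.2, 8.1, 0, 13.2),
               class = "quadtrace_domain_error")
})

test_that("deconvolve_gt_hq rewrites the mixed row of a summary", {
  mk <- function(cond, p) {
    s <- tibble::tibble(condition = cond,
                        class = c("2G-HQ", "3G-HQ/GT", "GQ", "none"),
                        n = NA_integer_, percent = p)
    class(s) <- c("condition_summary", class(s))
    s
  }
  trans <- mk("transcription", c(17.3, 13.2, 12.2, 57.3))
  deaza <- mk("deaza", c(0, 8.1, 25.9, 66.0))
  out <- deconvolve_gt_hq(trans, deaza)
  expect_equal(out$percent[out$class == "3G-HQ"], 9.4)
  expect_equal(out$percent[out$class == "GT"], 3.8)
  expect_equal(sum(out$percent), 100, tolerance = 1e-9)
  agg <- quad_aggregates(out)
  expect_equal(agg$hq_total, 26.7)
  expect_equal(agg$gq_gt_total, 16.0)
  expect_equal(agg$quadruplex_total_rounded, 43)
})

test_that("random force deconvolution separates and labels populations", {
  f <- withr::with_seed(20, c(rnorm(150, 20, 1), rnorm(150, 40, 1)))
  fd <- random_force_deconvolution(f, seed = 1)
  truth <- rep(1:2, each = 150)
  purity <- mean(fd$labels == truth)
  expect_gte(max(purity, 1 - purity), 0.99)
  # identical components: posterior is 1/2 everywhere, assignment a fair coin
  ident <- structure(
    list(components = tibble::tibble(weight = c(0.5, 0.5), mean = c(30, 30),
                                     sd = c(2, 2)),
         loglik = 0, n = 400, iters = 1,
         data = withr::with_seed(21, rnorm(400, 30, 2))),
    class = "gmm_fit"
  )
  post <- gmm_posterior(ident)
  expect_true(all(abs(post - 0.5) < 1e-12))
  lab <- withr::with_seed(1, quadtrace:::sample_categorical(post))
  expect_lt(abs(mean(lab == 1) - 0.5), 3 * sqrt(0.25 / 400))
  # class shares follow the fitted weights on real (overlapping) data
  g <- withr::with_seed(21, rnorm(400, 30, 2))
  fd2 <- random_force_deconvolution(g, seed = 1)
  w1 <- tidy(fd2)$n[1] / 400
  expect_lt(abs(w1 - fd2$fit$components$weight[1]), 3 * sqrt(0.25 / 400))
  # the study's two force classes at realistic weights
  h <- withr::with_seed(22, {
    comp <- rbinom(500, 1, 0.375)
    rnorm(500, ifelse(comp == 1, 25, 31), ifelse(comp == 1, 2, 1))
  })
  fd3 <- random_force_deconvolution(h, seed = 1)
  cls <- tidy(fd3)
  expect_lt(abs(min(cls$component_mean) - 25), 1)
  expect_lt(abs(max(cls$component_mean) - 31), 1)
  expect_error(random_force_deconvolution(rnorm(5)),
               class = "quadtrace_data_error")
})
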