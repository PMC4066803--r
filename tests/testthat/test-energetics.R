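# Unfolding works and the Jarzynski free-energy estimator.

test_that("work records follow the constant-force rip approximation", {
  ev <- tibble::tibble(rupture_force = 31, delta_L = 1.80, nt = 9L)
  wr <- unfolding_work(ev)
  # 31 pN x (1.80 nm x ratio(31) = 1.802 nm) = 55.86 pN nm
  expect_equal(wr$raw_work, 55.86, tolerance = 0.01)
  expect_lt(wr$stretch_correction, wr$raw_work)
  expect_equal(wr$net_work, wr$raw_work - wr$stretch_correction)
  # the zero-force limit does no work
  tiny <- unfolding_work(tibble::tibble(rupture_force = 1e-9, delta_L = 1.8,
                                        nt = 9L))
  expect_lt(tiny$raw_work, 1e-8)
  expect_error(unfolding_work(tibble::tibble(rupture_force = 31,
                                             delta_L = 1.8, nt = NA_integer_)),
               class = "quadtrace_domain_error")
  expect_error(unfolding_work(tibble::tibble(rupture_force = 31)),
               class = "quadtrace_domain_error")
})

test_that("the Jarzynski estimator has its closed-form limits", {
  # degenerate distribution: dG equals the common work
  expect_equal(jarzynski_dG(rep(40, 12), seed = 1)$dG_pn_nm, 40)
  # Gaussian works: dG = mu - sigma^2 / (2 kT), within 2 SE at n = 1e4
  kbt <- wlc_params()$thermal_energy
  w <- withr::with_seed(23, rnorm(1e4, 20 * kbt, 2 * kbt))
  j <- jarzynski_dG(w, seed = 1)
  expect_lt(abs(j$dG_pn_nm - 18 * kbt), max(2 * j$se_pn_nm, 0.1 * kbt))
  expect_error(jarzynski_dG(c(1, 2, 3)), class = "quadtrace_data_error")
})

test_that("Jensen's bound holds on every input", {
  withr::with_seed(24, {
    for (i in 1:20) {
      w <- switch(1 + i %% 4,
                  rnorm(50, 30, 10),
                  rexp(50, 1 / 20),
                  rnorm(30, 60, 1),
                  c(rnorm(25, 40, 5), rnorm(25, 10, 5)))
      j <- jarzynski_dG(w, n_half_subsamples = 20, n_boot = 20, seed = i)
      expect_lte(j$dG_pn_nm, mean(w) + 1e-9)
    }
  })
})

test_that("finite-sample bias is positive and shrinks with sample size", {
  # broad works (sigma ~ 2.5 kT) make the exponential average bias visible
  kbt <- wlc_params()$thermal_energy
  draw <- function(n) rnorm(n, 15 * kbt, 2.5 * kbt)
  true_dG <- (15 - 2.5^2 / 2) * kbt
  withr::with_seed(25, {
    est_small <- replicate(300, jarzynski_dG(draw(25), n_half_subsamples = 5,
                                             n_boot = 5)$dG_pn_nm)
    est_large <- replicate(300, jarzynski_dG(draw(400), n_half_subsamples = 5,
                                             n_boot = 5)$dG_pn_nm)
  })
  bias_small <- mean(est_small) - true_dG
  bias_large <- mean(est_large) - true_dG
  expect_gt(bias_small, 0)
  expect_gt(bias_large, 0)
  expect_lt(bias_large, bias_small)
  # the subsample-extrapolation estimate is positive on skew-penalised works
  w <- withr::with_seed(26, draw(200))
  expect_gt(jarzynski_dG(w, seed = 2)$bias_pn_nm, 0)
})

test_that("species-resolved free energies preserve the stability ordering", {
  run <- cached("small_trans_run", simulate_and_detect("transcription", 600,
                                                       seed = 27))
  ev <- run$events
  gm <- fit_gaussian_mixture(ev$delta_L, k = 3, init = c(1.8, 3.8, 6.0))
  post <- gmm_posterior(gm, ev$delta_L)
  ev$class_label <- c("2G-HQ", "3G-HQ/GT", "GQ")[max.col(post,
                                                         ties.method = "first")]
  fe <- free_energy_by_class(unfolding_work(ev), seed = 1)
  dg <- setNames(fe$dG_kcal_mol, fe$class_label)
  expect_gt(dg[["GQ"]], dg[["3G-HQ/GT"]])
  expect_gt(dg[["3G-HQ/GT"]], dg[["2G-HQ"]])
})
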