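# Trace processing: filtering, segmentation, rupture detection.

make_trace <- function(force, extension = NULL, rate = 1000) {
  n <- length(force)
  if (is.null(extension)) extension <- rep(0, n)
  tibble::tibble(
    time_s = (seq_len(n) - 1) / rate,
    force_pN = force,
    extension_nm = extension
  )
}

test_that("the filter reproduces constants and linear ramps", {
  tr <- make_trace(rep(10, 2000))
  out <- filter_trace(tr)
  expect_equal(out$force_pN, rep(10, nrow(out)), tolerance = 1e-10)
  ramp <- make_trace(seq(0, 20, length.out = 4000))
  out2 <- filter_trace(ramp)
  expect_equal(out2$force_pN, ramp$force_pN[seq(1, 4000, by = 10)],
               tolerance = 1e-9)
  expect_error(filter_trace(tr, window = 10), class = "quadtrace_config_error")
  expect_error(filter_trace(tr, window = 3, polyorder = 4),
               class = "quadtrace_config_error")
})

test_that("filtered white noise matches the Savitzky-Golay attenuation oracle", {
  # closed form: RMS gain = sqrt(sum of squared smoothing coefficients)
  att21 <- quadtrace:::sg_noise_attenuation(21, 2)
  att11 <- quadtrace:::sg_noise_attenuation(11, 2)
  withr::with_seed(8, {
    noise <- rnorm(1e5, 0, 0.5)
    tr <- make_trace(10 + noise)
    out <- filter_trace(tr, window = 21)
    expect_equal(sd(out$force_pN), 0.5 * att21, tolerance = 0.03)
    expect_lt(sd(out$force_pN), 0.2)  # the default window reaches < 0.2 pN
    out11 <- filter_trace(tr, window = 11)
    expect_equal(sd(out11$force_pN), 0.5 * att11, tolerance = 0.03)
  })
})

test_that("segmentation recovers cycles from ids and from turning points", {
  ds <- simulate_fx_dataset("transcription", n_curves = 10, seed = 21)
  cycles <- segment_cycles(filter_trace(ds$trace))
  expect_length(cycles, 10)
  expect_equal(vapply(cycles, function(cc) cc$cycle_id[1], numeric(1)),
               as.numeric(1:10))
  expect_equal(sum(vapply(cycles, nrow, integer(1))),
               nrow(filter_trace(ds$trace)))
  # monotone single ramp without ids -> one stretch cycle
  ramp <- make_trace(seq(0.1, 30, length.out = 3000))
  one <- segment_cycles(ramp)
  expect_length(one, 1)
  expect_true(all(one[[1]]$phase == "stretch"))
  # saw-tooth without ids -> two cycles
  saw <- make_trace(c(seq(0.1, 30, length.out = 1500),
                      seq(30, 0.1, length.out = 1500),
                      seq(0.1, 30, length.out = 1500),
                      seq(30, 0.1, length.out = 1500)))
  expect_length(segment_cycles(saw), 2)
})

test_that("noiseless cycles give exact events and quiet cycles give none", {
  p0 <- noiseless_protocol()
  ds <- simulate_fx_dataset("lithium", n_curves = 60, protocol = p0, seed = 5)
  ev <- detect_events(ds)
  truth <- ds$truth
  folded_ids <- truth$cycle_id[truth$species != "none" & !truth$censored]
  expect_setequal(ev$cycle_id, folded_ids)
  m <- dplyr::inner_join(ev, truth, by = "cycle_id")
  expect_true(all(abs(m$delta_L - m$true_delta_L_nm) < 0.1))
  expect_true(all(abs(m$rupture_force - m$true_rupture_force_pN) < 0.5))
  # two-method agreement on noiseless data (median relative difference <= 5%)
  rel <- abs(m$delta_L_flank - m$delta_L_wlcfit) / pmax(m$delta_L_flank, 1e-9)
  expect_lte(median(rel), 0.05)
})

test_that("detection is accurate, precise and bounded on noisy data", {
  run <- simulate_and_detect("transcription", 400, seed = 9)
  truth_ids <- run$truth$cycle_id[run$truth$species != "none" &
                                    !run$truth$censored]
  recall <- mean(truth_ids %in% run$events$cycle_id)
  false_rate <- sum(!(run$events$cycle_id %in% truth_ids)) / run$n_curves
  expect_gte(recall, 0.95)
  expect_lte(false_rate, 0.02)
  # no event above its cycle's maximum force (the ramp ceiling)
  expect_true(all(run$events$rupture_force <= 45 + 2))
  m <- dplyr::inner_join(run$events, run$truth, by = "cycle_id")
  expect_lt(abs(mean(m$delta_L - m$true_delta_L_nm)), 0.05)
})

test_that("detection is deterministic and idempotent on filtered input", {
  ds <- simulate_fx_dataset("transcription", n_curves = 20, seed = 33)
  filtered <- filter_trace(ds$trace)
  cyc <- segment_cycles(filtered)
  ev1 <- purrr::map_dfr(cyc, detect_ruptures)
  ev2 <- purrr::map_dfr(cyc, detect_ruptures)
  expect_identical(ev1, ev2)
})
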