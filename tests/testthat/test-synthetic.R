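# Synthetic-data generator: condition tables, Bell-Evans sampling, pulling
# and force-jump datasets, determinism.

test_that("condition prevalence tables match the study's percent formation", {
  tr <- make_condition("transcription")$species
  expect_equal(tr$prevalence[tr$species == "none"], 0.573)
  expect_equal(tr$prevalence[tr$species == "2G-HQ"], 0.173)
  dz <- make_condition("deaza")$species
  expect_false("2G-HQ" %in% dz$species)
  expect_equal(dz$prevalence[dz$species == "GQ"], 0.259)
  for (cond in c("transcription", "deaza", "no_transcription",
                 "mutant", "spacer", "lithium")) {
    expect_equal(sum(make_condition(cond)$species$prevalence), 1,
                 tolerance = 1e-9)
  }
  expect_error(make_condition("heavy_water"),
               class = "quadtrace_config_error")
})

test_that("empirical species frequencies follow the prevalences", {
  cond <- make_condition("transcription")
  n <- 1e5
  sp <- withr::with_seed(4, quadtrace:::draw_species(cond, n))
  for (i in seq_len(nrow(cond$species))) {
    p <- cond$species$prevalence[i]
    emp <- mean(sp == cond$species$species[i])
    expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("Bell-Evans sampler matches its closed-form mode and calibration", {
  kbt <- wlc_params()$thermal_energy
  k0 <- calibrate_bell_evans(31, barrier_distance = 2, loading_rate = 5.5)
  f <- sample_rupture_force(1e5, k0, barrier_distance = 2, seed = 11)
  mode_closed <- bell_evans_mode(k0, 2, 5.5, kbt)
  d <- density(f, n = 4096)
  expect_lt(abs(d$x[which.max(d$y)] - mode_closed), 0.5)
  expect_lt(abs(mean(f) - 31), 0.5)
  # the condition catalogue is calibrated to the printed centres
  cond <- make_condition("transcription")
  hq <- cond$species[cond$species$species == "2G-HQ", ]
  gq <- cond$species[cond$species$species == "GQ", ]
  f_hq <- sample_rupture_force(1e4, hq$intrinsic_rate, hq$barrier_distance,
                               seed = 12)
  f_gq <- sample_rupture_force(1e4, gq$intrinsic_rate, gq$barrier_distance,
                               seed = 13)
  expect_lt(abs(mean(f_hq) - 31), 0.5)
  expect_lt(abs(mean(f_gq) - 25), 0.5)
})

test_that("pulling datasets have the requested size and structure", {
  expect_error(simulate_fx_dataset("transcription", n_curves = 0),
               class = "quadtrace_domain_error")
  d1 <- simulate_fx_dataset("transcription", n_curves = 1, seed = 2)
  expect_equal(length(unique(d1$trace$cycle_id)), 1)
  expect_setequal(unique(d1$trace$phase), c("stretch", "relax"))
  expect_true(all(diff(d1$trace$time_s) > 0))
  d10 <- simulate_fx_dataset("no_transcription", n_curves = 10, seed = 2)
  expect_equal(nrow(d10$truth), 10)
})

test_that("control constructs yield few folded structures", {
  mut <- simulate_and_detect("mutant", 200, seed = 3)
  expect_lte(nrow(mut$events) / mut$n_curves, 0.05)
  # lithium folded prevalence (species assignment law at large n)
  cond <- make_condition("lithium")
  sp <- withr::with_seed(5, quadtrace:::draw_species(cond, 1e4))
  expect_lt(abs(mean(sp != "none") - 0.067), 0.01)
})

test_that("identical seeds give byte-identical datasets, different seeds differ", {
  a <- simulate_fx_dataset("transcription", n_curves = 3, seed = 42)
  b <- simulate_fx_dataset("transcription", n_curves = 3, seed = 42)
  c <- simulate_fx_dataset("transcription", n_curves = 3, seed = 43)
  expect_identical(a$trace, b$trace)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$trace$force_pN, c$trace$force_pN))
  fa <- tempfile(fileext = ".tsv")
  fb <- tempfile(fileext = ".tsv")
  write_fx_dataset(a, fa)
  write_fx_dataset(b, fb)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
  rt <- read_fx_trace(fa)
  expect_equal(nrow(rt), nrow(a$trace))
})

test_that("force-jump series follows the exponential refolding law", {
  cond <- make_condition("transcription")
  expect_error(simulate_fpp_series(cond, incubation_times = numeric(0)),
               class = "quadtrace_domain_error")
  fpp0 <- simulate_fpp_series(cond, incubation_times = 0, n_cycles = 200,
                              seed = 6)
  expect_equal(sum(fpp0$event), 0)
  fpp <- simulate_fpp_series(cond, incubation_times = c(0.03, 5),
                             n_cycles = 2000, seed = 6)
  sp <- cond$species
  hq_ss <- sum(sp$prevalence[sp$species %in% c("2G-HQ", "3G-HQ")])
  hq5 <- mean(fpp$species_true[fpp$incubation_time_s == 5] %in%
                c("2G-HQ", "3G-HQ"))
  expect_lt(abs(hq5 - hq_ss), 3 * sqrt(hq_ss * (1 - hq_ss) / 2000))
  # at t = tau the hybrid populations sit at (1 - 1/e) of steady state
  hq30 <- mean(fpp$species_true[fpp$incubation_time_s == 0.03] %in%
                 c("2G-HQ", "3G-HQ"))
  target <- hq_ss * (1 - exp(-1))
  expect_lt(abs(hq30 - target), 3 * sqrt(target * (1 - target) / 2000))
})

test_that("bundled construct sequences are readable and G-rich where expected", {
  seqs <- construct_sequences()
  expect_equal(nrow(seqs), 3)
  gcore <- seqs$sequence[grepl("^G_core", seqs$name)]
  expect_true(grepl("GGGGAGGGGAGGGGAGGGG", gcore))
  mutant <- seqs$sequence[grepl("^mutant", seqs$name)]
  expect_false(grepl("GG", mutant))
})
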