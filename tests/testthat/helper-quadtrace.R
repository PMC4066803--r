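# Shared fixtures. Heavy synthetic runs are generated once per test session
# and cached in this environment.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# Full-size regular-transcription dataset (study conditions: 2000 curves).
get_transcription_run <- function() {
  cached("trans_run", simulate_and_detect("transcription", 2000, seed = 1))
}

get_deaza_run <- function() {
  cached("deaza_run", simulate_and_detect("deaza", 2000, seed = 1))
}

get_transcription_podnano <- function() {
  cached("trans_podnano", {
    run <- get_transcription_run()
    podnano(run$events$delta_L, n_boot = 3000, seed = 1)
  })
}

# Small noiseless protocol for exactness checks.
noiseless_protocol <- function() {
  protocol_spec(noise_sd_force = 1e-9, noise_sd_extension = 1e-9)
}

# Three-component delta-L mixture mirroring the generator's populations.
draw_delta_L_mixture <- function(n, weights = c(0.45, 0.3, 0.25),
                                 means = c(1.8, 3.8, 6.0),
                                 sds = c(0.2, 0.5, 0.6)) {
  comp <- sample.int(3, n, replace = TRUE, prob = weights)
  rnorm(n, means[comp], sds[comp])
}
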