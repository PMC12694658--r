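# Shared simulation configs and lazily cached fixture objects. Sizes are
# scaled-down versions of the full protocol (fewer stimuli / shorter rest)
# so the suite stays fast; the full-protocol arithmetic is asserted
# separately where it matters.

# small but otherwise default-shaped session: 100 s rest + 60 stimuli x 5 s
small_sim <- function(seed = 101, ...) {
  sim_config(n_subjects = 2, rest_duration = 100, n_stimuli = 60,
             seed = seed, ...)
}

# idealized-coupling condition: strong common-sign coupling, near-zero
# channel noise, no intensity drift. The factor is computed on the phasic
# band; matched-band processing (short detrend window, low tonic cutoff)
# keeps the LiDAR channel in that same band, which is what makes the
# factor recoverable from LiDAR at all.
ideal_coupling_sim <- function(seed = 202, n_subjects = 2, ...) {
  sim_config(n_subjects = n_subjects, seed = seed,
             coupling_gain_mean = 3, coupling_gain_sd = 0.1,
             eda_noise_sd = 0.005, lidar_noise_sd = 0.005,
             lidar_drift_amplitude = 0, ...)
}

matched_band_params <- function() {
  preprocess_params(detrend_window = 20, tonic_cutoff = 0.01)
}

# decoupled condition: the LiDAR channel carries no arousal information
null_coupling_sim <- function(seed = 303, ...) {
  sim_config(n_subjects = 5, rest_duration = 100, n_stimuli = 60,
             seed = seed, coupling_gain_mean = 0, coupling_gain_sd = 0,
             eda_noise_sd = 0.005, lidar_noise_sd = 0.05, ...)
}

# lazily computed fixtures shared across test files
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

noiseless_recording <- function() {
  fixture("noiseless_recording", function() {
    generate_dataset(small_sim(eda_noise_sd = 0, lidar_noise_sd = 0,
                               lidar_drift_amplitude = 0))[[1]]
  })
}

small_processed <- function() {
  fixture("small_processed", function() {
    lapply(generate_dataset(small_sim()), clean_recording)
  })
}
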