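test_that("stimulus schedule follows the session protocol", {
  cfg <- sim_config()
  sched <- generate_stimulus_schedule(cfg)
  expect_length(sched$onsets, 240L)
  expect_equal(sched$onsets[1:3], c(300, 305, 310))
  expect_equal(diff(sched$onsets), rep(5, 239))

  empty <- generate_stimulus_schedule(sim_config(n_stimuli = 0))
  expect_length(empty$onsets, 0L)
  expect_equal(total_duration(sim_config(n_stimuli = 0)), 300)

  expect_error(sim_config(n_stimuli = -1), "n_stimuli")
})

test_that("config validation rejects invalid parameters", {
  expect_error(sim_config(fs = 0), "fs")
  expect_error(sim_config(scr_probability = 1.5), "scr_probability")
  expect_error(sim_config(scr_rise_tau = -1), "time constants")
  expect_error(sim_config(scr_rise_tau = 5, scr_decay_tau = 4), "rise_tau")
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(eda_noise_sd = -0.1), "eda_noise_sd")
})

test_that("EDA synthesis: tonic-only, kernel peak time, determinism", {
  # no responses, no noise: pure tonic curve, monotone non-increasing
  cfg <- small_sim(scr_probability = 0, eda_noise_sd = 0)
  set.seed(1)
  eda <- synthesize_eda(generate_stimulus_schedule(cfg), cfg)
  expect_equal(eda$eda_raw, eda$tonic)
  expect_true(all(diff(eda$eda_raw) <= 0))

  # a single elicited response, noiseless: empirical peak of the phasic
  # component sits at the kernel's analytic maximum
  cfg1 <- sim_config(n_subjects = 1, rest_duration = 10, n_stimuli = 1,
                     stimulus_duration = 30, scr_probability = 1,
                     scr_amplitude_sd = 0, eda_noise_sd = 0,
                     habituation_rate = 0)
  set.seed(2)
  eda1 <- synthesize_eda(generate_stimulus_schedule(cfg1), cfg1)
  t_star <- scr_kernel_peak_time(cfg1$scr_rise_tau, cfg1$scr_decay_tau)
  peak_t <- eda1$time[which.max(eda1$phasic)]
  response_onset <- 10 + cfg1$scr_latency
  expect_lt(abs((peak_t - response_onset) - t_star), 1 / cfg1$fs)
  # and the peak height equals the (normalized) amplitude
  expect_equal(max(eda1$phasic), eda1$amplitudes[1], tolerance = 1e-3)

  # determinism: the same seed reproduces the series bit for bit
  r1 <- generate_dataset(small_sim(seed = 5))[[1]]
  r2 <- generate_dataset(small_sim(seed = 5))[[1]]
  expect_identical(r1$eda_raw, r2$eda_raw)
  expect_identical(r1$lidar_raw, r2$lidar_raw)
})

test_that("LiDAR synthesis couples to the phasic component as specified", {
  cfg <- small_sim(coupling_lag = 0, lidar_noise_sd = 0,
                   lidar_drift_amplitude = 0, lidar_baseline = 0)
  set.seed(3)
  eda <- synthesize_eda(generate_stimulus_schedule(cfg), cfg)
  set.seed(4)
  li <- synthesize_lidar(eda$phasic, gain = 1, cfg)
  expect_equal(li, eda$phasic)

  # with a lag but no noise, the lag-shifted correlation is exactly 1
  cfg2 <- small_sim(coupling_lag = 0.5, lidar_noise_sd = 0,
                    lidar_drift_amplitude = 0)
  set.seed(5)
  li2 <- synthesize_lidar(eda$phasic, gain = 2, cfg2)
  lag <- as.integer(0.5 * cfg2$fs)
  n <- length(li2)
  expect_equal(
    cor(li2[(lag + 1):n], eda$phasic[1:(n - lag)]), 1
  )

  # zero gain: intensity is statistically independent of the phasic input
  # (no drift term, so only white noise remains)
  cfg0 <- small_sim(coupling_gain_mean = 0, coupling_gain_sd = 0,
                    lidar_drift_amplitude = 0)
  set.seed(6)
  li0 <- synthesize_lidar(eda$phasic, gain = 0, cfg0)
  expect_lt(abs(cor(li0, eda$phasic)), 0.1)
})

test_that("dataset generation: shapes, substreams, conservation", {
  cfg <- sim_config(n_subjects = 5, seed = 9)
  recs <- generate_dataset(cfg)
  expect_length(recs, 5L)
  for (r in recs) {
    expect_length(r$eda_raw, 30000L)
    expect_length(r$lidar_raw, 30000L)
    expect_equal(max(r$time), 1500 - 1 / 20)
  }
  # conservation: raw = tonic + phasic + noise exactly as stored
  r <- recs[[1]]
  expect_identical(r$eda_raw,
                   r$latent$tonic + r$latent$phasic + r$latent$noise)

  # different seeds give different noise realizations
  recs2 <- generate_dataset(sim_config(n_subjects = 5, seed = 10))
  expect_false(identical(recs[[1]]$eda_raw, recs2[[1]]$eda_raw))

  # zero gain spread: all subjects share the same coupling gain
  recs3 <- generate_dataset(small_sim(coupling_gain_sd = 0))
  gains <- vapply(recs3, function(x) x$latent$gain, numeric(1))
  expect_equal(gains, rep(gains[1], length(gains)))

  # per-subject substreams: subject 1 is unchanged when the cohort grows
  a <- generate_dataset(small_sim(seed = 77))
  cfg_big <- small_sim(seed = 77); cfg_big$n_subjects <- 4L
  b <- generate_dataset(cfg_big)
  expect_identical(a[[1]]$eda_raw, b[[1]]$eda_raw)
  expect_identical(a[[2]]$lidar_raw, b[[2]]$lidar_raw)
})

test_that("coupling strength drives the LiDAR-phasic correlation monotonically", {
  gains <- c(0, 0.5, 1, 2)
  rs <- vapply(gains, function(g) {
    cfg <- small_sim(seed = 55, coupling_gain_mean = g,
                     coupling_gain_sd = 0, lidar_noise_sd = 0.2,
                     coupling_lag = 0)
    rec <- generate_dataset(cfg)[[1]]
    abs(cor(rec$lidar_raw, rec$latent$phasic))
  }, numeric(1))
  # non-decreasing up to sampling error
  expect_true(all(diff(rs) > -0.02))
  expect_gt(rs[4], rs[1])
})

test_that("recording CSV + sidecar round-trips", {
  dir <- withr::local_tempdir()
  rec <- noiseless_recording()
  write_recording(rec, dir, config = small_sim())
  back <- read_recording(dir, rec$subject_id)
  expect_equal(back$eda_raw, rec$eda_raw, tolerance = 1e-12)
  expect_equal(back$lidar_raw, rec$lidar_raw, tolerance = 1e-12)
  expect_equal(back$stimulus_onsets, rec$stimulus_onsets)
  expect_equal(back$latent$gain, rec$latent$gain, tolerance = 1e-12)
})
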