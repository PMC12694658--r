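#' Simulation configuration for synthetic EDA + LiDAR recordings
#'
#' Defines the generative model for a multi-subject laboratory session: a
#' rest baseline followed by a block of brief visual stimuli, a tonic skin
#' conductance level (SCL) that declines slowly over the session
#' (habituation), stimulus-locked phasic skin conductance responses (SCRs)
#' with a bi-exponential kernel, and a LiDAR reflection-intensity channel
#' linearly coupled to the phasic EDA component with a subject-specific gain.
#'
#' The default protocol is a 5 min dark-screen rest followed by 240 stimuli
#' of 5 s each, both channels sampled at 20 Hz, so each subject contributes
#' 1500 s (30,000 samples per channel).
#'
#' @param n_subjects Number of subjects to simulate.
#' @param fs Sampling rate in Hz (both channels).
#' @param rest_duration Rest baseline duration in seconds.
#' @param n_stimuli Number of stimuli presented after the rest block.
#' @param stimulus_duration Presentation time of each stimulus in seconds.
#' @param scr_probability Probability that a stimulus elicits an SCR.
#' @param scr_amplitude_mean,scr_amplitude_sd Mean and SD of the elicited
#'   SCR peak amplitude (arbitrary conductance units); draws are truncated
#'   at zero.
#' @param scr_rise_tau,scr_decay_tau Time constants (s) of the
#'   bi-exponential SCR kernel `a * (exp(-t/decay) - exp(-t/rise))`,
#'   normalized so that `a` is the peak height. Requires
#'   `scr_rise_tau < scr_decay_tau`.
#' @param scr_latency Delay (s) from stimulus onset to SCR onset.
#' @param habituation_rate Per-elicited-response multiplicative amplitude
#'   decay: the j-th elicited SCR is scaled by `(1 - habituation_rate)^j`.
#' @param tonic_start Initial tonic level (a.u.).
#' @param tonic_decline_rate Exponential decline rate of the tonic level
#'   (1/s); the tonic curve is `tonic_start * exp(-rate * t)`.
#' @param eda_noise_sd,lidar_noise_sd Additive white-noise SD per channel.
#' @param coupling_gain_mean,coupling_gain_sd Mean and SD of the per-subject
#'   linear coupling gain between phasic EDA and LiDAR intensity.
#' @param coupling_lag Lag (s) of the LiDAR response behind the phasic EDA.
#' @param lidar_baseline Constant LiDAR intensity offset (a.u.).
#' @param lidar_drift_amplitude,lidar_drift_period Amplitude (a.u.) and
#'   period (s) of a slow sinusoidal intensity drift with random phase.
#' @param stimulus_weights Optional vector of per-stimulus arousal weights
#'   (length `n_stimuli`) scaling SCR amplitude; default uniform 1.
#' @param seed Integer seed; expands to per-subject substreams so adding a
#'   subject does not perturb existing ones.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_dataset()], [generate_stimulus_schedule()]
#' @export
sim_config <- function(n_subjects = 5,
                       fs = 20,
                       rest_duration = 300,
                       n_stimuli = 240,
                       stimulus_duration = 5,
                       scr_probability = 0.7,
                       scr_amplitude_mean = 0.5,
                       scr_amplitude_sd = 0.15,
                       scr_rise_tau = 0.75,
                       scr_decay_tau = 4,
                       scr_latency = 1,
                       habituation_rate = 0.005,
                       tonic_start = 8,
                       tonic_decline_rate = 2e-4,
                       eda_noise_sd = 0.02,
                       lidar_noise_sd = 0.05,
                       coupling_gain_mean = 1,
                       coupling_gain_sd = 0.2,
                       coupling_lag = 0.2,
                       lidar_baseline = 100,
                       lidar_drift_amplitude = 0.1,
                       lidar_drift_period = 600,
                       stimulus_weights = NULL,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), fs = fs,
    rest_duration = rest_duration, n_stimuli = as.integer(n_stimuli),
    stimulus_duration = stimulus_duration,
    scr_probability = scr_probability,
    scr_amplitude_mean = scr_amplitude_mean,
    scr_amplitude_sd = scr_amplitude_sd,
    scr_rise_tau = scr_rise_tau, scr_decay_tau = scr_decay_tau,
    scr_latency = scr_latency, habituation_rate = habituation_rate,
    tonic_start = tonic_start, tonic_decline_rate = tonic_decline_rate,
    eda_noise_sd = eda_noise_sd, lidar_noise_sd = lidar_noise_sd,
    coupling_gain_mean = coupling_gain_mean,
    coupling_gain_sd = coupling_gain_sd,
    coupling_lag = coupling_lag,
    lidar_baseline = lidar_baseline,
    lidar_drift_amplitude = lidar_drift_amplitude,
    lidar_drift_period = lidar_drift_period,
    stimulus_weights = stimulus_weights,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_subjects < 1L) {
    stop("sim_config: n_subjects must be >= 1", call. = FALSE)
  }
  if (!is.finite(cfg$fs) || cfg$fs <= 0) {
    stop("sim_config: fs must be > 0", call. = FALSE)
  }
  if (cfg$n_stimuli < 0L) {
    stop("sim_config: n_stimuli must be >= 0", call. = FALSE)
  }
  nonneg <- c(
    "rest_duration", "stimulus_duration", "scr_latency",
    "habituation_rate", "tonic_decline_rate", "eda_noise_sd",
    "lidar_noise_sd", "scr_amplitude_sd", "coupling_gain_sd",
    "lidar_drift_amplitude"
  )
  for (f in nonneg) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0) {
      stop("sim_config: ", f, " must be >= 0", call. = FALSE)
    }
  }
  if (cfg$scr_rise_tau <= 0 || cfg$scr_decay_tau <= 0) {
    stop("sim_config: SCR time constants must be > 0", call. = FALSE)
  }
  if (cfg$scr_rise_tau >= cfg$scr_decay_tau) {
    stop("sim_config: scr_rise_tau must be < scr_decay_tau", call. = FALSE)
  }
  if (cfg$scr_probability < 0 || cfg$scr_probability > 1) {
    stop("sim_config: scr_probability must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(cfg$stimulus_weights) &&
      length(cfg$stimulus_weights) != cfg$n_stimuli) {
    stop("sim_config: stimulus_weights must have length n_stimuli",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Total recording duration implied by a simulation config
#'
#' @param config A [sim_config()] object.
#' @return Duration in seconds: `rest_duration + n_stimuli * stimulus_duration`.
#' @export
total_duration <- function(config) {
  config$rest_duration + config$n_stimuli * config$stimulus_duration
}

#' Stimulus schedule
#'
#' Back-to-back presentation: the first stimulus starts when the rest block
#' ends and consecutive onsets are spaced `stimulus_duration` apart.
#'
#' @param config A [sim_config()] object.
#' @return A `stimulus_schedule` object with `onsets` (seconds) and
#'   `weights` (per-stimulus nominal arousal weight, default 1).
#' @export
generate_stimulus_schedule <- function(config) {
  validate_sim_config(config)
  n <- config$n_stimuli
  if (n == 0L) {
    sched <- list(onsets = numeric(0), weights = numeric(0))
  } else {
    onsets <- config$rest_duration +
      (seq_len(n) - 1) * config$stimulus_duration
    w <- config$stimulus_weights
    if (is.null(w)) w <- rep(1, n)
    sched <- list(onsets = onsets, weights = w)
  }
  class(sched) <- "stimulus_schedule"
  sched
}

# bi-exponential SCR kernel, normalized to unit peak so the amplitude
# parameter is the actual peak height
scr_kernel <- function(t, rise_tau, decay_tau) {
  raw <- exp(-t / decay_tau) - exp(-t / rise_tau)
  t_peak <- scr_kernel_peak_time(rise_tau, decay_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  out <- raw / peak
  out[t < 0] <- 0
  out
}

#' Analytic peak time of the SCR kernel
#'
#' The kernel `exp(-t/decay) - exp(-t/rise)` attains its maximum at
#' `t* = (log(decay) - log(rise)) / (1/rise - 1/decay)`.
#'
#' @param rise_tau,decay_tau Kernel time constants (s).
#' @return Peak time in seconds after response onset.
#' @export
scr_kernel_peak_time <- function(rise_tau, decay_tau) {
  (log(decay_tau) - log(rise_tau)) / (1 / rise_tau - 1 / decay_tau)
}

#' Synthesize one subject's EDA channel
#'
#' Builds `eda_raw = tonic + phasic + noise`: an exponentially declining
#' tonic level, a sum of stimulus-locked bi-exponential SCRs whose
#' amplitudes shrink by `habituation_rate` per elicited response, and
#' additive white noise. Latent components are returned so downstream
#' recovery can be tested against ground truth.
#'
#' @param schedule A [generate_stimulus_schedule()] result.
#' @param config A [sim_config()] object.
#' @return List with `eda_raw`, `tonic`, `phasic`, `noise`, `time`,
#'   `elicited` (logical per stimulus), `amplitudes` (peak height per
#'   stimulus, 0 if not elicited). Uses the current RNG stream.
#' @export
synthesize_eda <- function(schedule, config) {
  validate_sim_config(config)
  fs <- config$fs
  n <- as.integer(round(total_duration(config) * fs))
  t <- (seq_len(n) - 1) / fs
  tonic <- config$tonic_start * exp(-config$tonic_decline_rate * t)
  phasic <- numeric(n)
  n_stim <- length(schedule$onsets)
  elicited <- logical(n_stim)
  amplitudes <- numeric(n_stim)
  n_elicited <- 0L
  for (j in seq_len(n_stim)) {
    if (stats::runif(1) < config$scr_probability) {
      elicited[j] <- TRUE
      amp <- max(0, stats::rnorm(1, config$scr_amplitude_mean,
                                 config$scr_amplitude_sd))
      amp <- amp * schedule$weights[j] *
        (1 - config$habituation_rate)^n_elicited
      n_elicited <- n_elicited + 1L
      amplitudes[j] <- amp
      onset <- schedule$onsets[j] + config$scr_latency
      i0 <- as.integer(floor(onset * fs)) + 1L
      if (i0 <= n) {
        idx <- i0:n
        phasic[idx] <- phasic[idx] +
          amp * scr_kernel(t[idx] - onset, config$scr_rise_tau,
                           config$scr_decay_tau)
      }
    }
  }
  noise <- if (config$eda_noise_sd > 0) {
    stats::rnorm(n, 0, config$eda_noise_sd)
  } else {
    numeric(n)
  }
  list(eda_raw = tonic + phasic + noise, tonic = tonic, phasic = phasic,
       noise = noise, time = t, elicited = elicited,
       amplitudes = amplitudes)
}

#' Synthesize the LiDAR reflection-intensity channel
#'
#' `intensity = baseline + gain * phasic(t - lag) + drift + noise`, where
#' the drift is a slow sinusoid with random phase. The lag models the
#' delayed reflectivity change of the skin relative to electrodermal
#' activity.
#'
#' @param phasic Latent phasic EDA series on the recording grid.
#' @param gain Subject-specific coupling gain.
#' @param config A [sim_config()] object.
#' @return Numeric intensity series of the same length. Uses the current
#'   RNG stream (drift phase, noise).
#' @export
synthesize_lidar <- function(phasic, gain, config) {
  validate_sim_config(config)
  n <- length(phasic)
  fs <- config$fs
  t <- (seq_len(n) - 1) / fs
  lag_samples <- as.integer(round(config$coupling_lag * fs))
  shifted <- if (lag_samples > 0 && lag_samples < n) {
    c(numeric(lag_samples), phasic[seq_len(n - lag_samples)])
  } else {
    phasic
  }
  phase <- stats::runif(1, 0, 2 * pi)
  drift <- config$lidar_drift_amplitude *
    sin(2 * pi * t / config$lidar_drift_period + phase)
  noise <- if (config$lidar_noise_sd > 0) {
    stats::rnorm(n, 0, config$lidar_noise_sd)
  } else {
    numeric(n)
  }
  config$lidar_baseline + gain * shifted + drift + noise
}

# per-subject substream seed derived from the global seed; independent of
# how many other subjects are generated
subject_seed <- function(seed, subject_index) {
  as.integer((as.double(seed) + 1000003 * subject_index) %% 2147483629)
}

#' Generate a seeded multi-subject dataset
#'
#' One synchronized EDA + LiDAR recording per subject. Each subject uses an
#' independent RNG substream derived from `config$seed`, so recordings are
#' bit-reproducible and adding subjects does not perturb existing ones.
#' Latent components (tonic, phasic, noise, coupling gain) are stored on
#' each recording for parameter-recovery tests.
#'
#' @param config A [sim_config()] object.
#' @return A list of `signal_recording` objects, one per subject.
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  schedule <- generate_stimulus_schedule(config)
  lapply(seq_len(config$n_subjects), function(s) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit(if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(subject_seed(config$seed, s))
    gain <- stats::rnorm(1, config$coupling_gain_mean,
                         config$coupling_gain_sd)
    eda <- synthesize_eda(schedule, config)
    lidar <- synthesize_lidar(eda$phasic, gain, config)
    new_signal_recording(
      subject_id = sprintf("S%02d", s),
      fs = config$fs,
      time = eda$time,
      eda_raw = eda$eda_raw,
      lidar_raw = lidar,
      stimulus_onsets = schedule$onsets,
      latent = list(tonic = eda$tonic, phasic = eda$phasic,
                    noise = eda$noise, gain = gain,
                    elicited = eda$elicited, amplitudes = eda$amplitudes)
    )
  })
}

new_signal_recording <- function(subject_id, fs, time, eda_raw, lidar_raw,
                                 stimulus_onsets, latent = NULL) {
  n <- length(time)
  stopifnot(length(eda_raw) == n, length(lidar_raw) == n)
  if (anyNA(eda_raw) || anyNA(lidar_raw)) {
    stop("signal_recording: missing values are not allowed", call. = FALSE)
  }
  if (n > 1 && any(diff(time) <= 0)) {
    stop("signal_recording: time must be strictly increasing", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, fs = fs, time = time, eda_raw = eda_raw,
         lidar_raw = lidar_raw, stimulus_onsets = stimulus_onsets,
         latent = latent),
    class = "signal_recording"
  )
}

#' @export
print.signal_recording <- function(x, ...) {
  cat(sprintf(
    "<signal_recording> subject %s: %d samples at %g Hz (%.1f s), %d stimuli\n",
    x$subject_id, length(x$time), x$fs,
    length(x$time) / x$fs, length(x$stimulus_onsets)
  ))
  invisible(x)
}

#' Write a recording to disk
#'
#' One CSV per subject (`<subject_id>.csv`, columns `time_s, eda_raw,
#' lidar_raw, is_stimulus_onset`) plus a sidecar JSON
#' (`<subject_id>.json`) carrying subject id, sampling rate, a config echo
#' and the latent coupling gain.
#'
#' @param rec A `signal_recording`.
#' @param dir Output directory (created if missing).
#' @param config Optional [sim_config()] to echo into the sidecar.
#' @return Invisibly, the CSV path.
#' @export
write_recording <- function(rec, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  onset_idx <- as.integer(round(rec$stimulus_onsets * rec$fs)) + 1L
  is_onset <- integer(length(rec$time))
  is_onset[onset_idx[onset_idx >= 1 & onset_idx <= length(is_onset)]] <- 1L
  df <- data.frame(time_s = rec$time, eda_raw = rec$eda_raw,
                   lidar_raw = rec$lidar_raw, is_stimulus_onset = is_onset)
  csv <- file.path(dir, paste0(rec$subject_id, ".csv"))
  data.table::fwrite(df, csv)
  sidecar <- list(subject_id = rec$subject_id, fs = rec$fs)
  if (!is.null(rec$latent)) sidecar$coupling_gain <- rec$latent$gain
  if (!is.null(config)) {
    sidecar$config <- config[setdiff(names(config), "stimulus_weights")]
  }
  jsonlite::write_json(sidecar, file.path(dir, paste0(rec$subject_id, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir Directory holding `<subject_id>.csv` and its sidecar.
#' @param subject_id Subject identifier.
#' @return A `signal_recording` (without latent components other than the
#'   stored gain).
#' @export
read_recording <- function(dir, subject_id) {
  csv <- file.path(dir, paste0(subject_id, ".csv"))
  df <- data.table::fread(csv, data.table = FALSE)
  meta <- jsonlite::read_json(file.path(dir, paste0(subject_id, ".json")),
                              simplifyVector = TRUE)
  onsets <- df$time_s[df$is_stimulus_onset == 1L]
  latent <- if (!is.null(meta$coupling_gain)) {
    list(gain = meta$coupling_gain)
  } else {
    NULL
  }
  new_signal_recording(subject_id = meta$subject_id, fs = meta$fs,
                       time = df$time_s, eda_raw = df$eda_raw,
                       lidar_raw = df$lidar_raw, stimulus_onsets = onsets,
                       latent = latent)
}
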