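#' Preprocessing parameters
#'
#' Both channels are cleaned identically: zero-phase low-pass filtering
#' followed by running-mean detrending; the EDA channel is additionally
#' decomposed into tonic and phasic components before per-participant
#' z-normalization.
#'
#' @param cutoff Low-pass cutoff in Hz (default 3 Hz at 20 Hz sampling,
#'   conventional for electrodermal signals).
#' @param filter_order Butterworth order for the cleaning filter.
#' @param detrend_window Running-baseline window in seconds.
#' @param tonic_cutoff Low-pass cutoff (Hz) defining the tonic (SCL)
#'   component; the phasic component is the residual.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(cutoff = 3, filter_order = 4,
                              detrend_window = 120, tonic_cutoff = 0.05) {
  p <- list(cutoff = cutoff, filter_order = as.integer(filter_order),
            detrend_window = detrend_window, tonic_cutoff = tonic_cutoff)
  stopifnot(p$cutoff > 0, p$filter_order >= 1,
            p$detrend_window > 0, p$tonic_cutoff > 0)
  class(p) <- "preprocess_params"
  p
}

# odd (point-reflected) extension preserves value and slope at the edges,
# so filter transients do not bend ramps
reflect_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad <= 0L) return(list(x = x, pad = 0L))
  left <- 2 * x[1] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  list(x = c(left, x, right), pad = pad)
}

#' Zero-phase low-pass filter
#'
#' Butterworth design (via the signal package) applied forward-backward
#' (`filtfilt`) over an odd-reflected extension of the series, so the
#' output has no phase lag, no edge discontinuity, and the same length as
#' the input.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param cutoff Cutoff frequency (Hz); must satisfy `0 < cutoff < fs/2`.
#' @param order Butterworth order (default 4).
#' @return Filtered series, same length as `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff, order = 4) {
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= fs / 2) {
    stop("lowpass_filter: cutoff must satisfy 0 < cutoff < fs/2 (Nyquist)",
         call. = FALSE)
  }
  n <- length(x)
  if (n < 2L) return(x)
  bf <- signal::butter(order, cutoff / (fs / 2))
  # filtfilt carries no initial-condition handling; its edge transient dies
  # out within ~10 cutoff periods, so extend generously before filtering
  pad <- as.integer(min(n - 1L, ceiling(12 * fs / cutoff)))
  ext <- reflect_pad(x, pad)
  y <- signal::filtfilt(bf, ext$x)
  y[(ext$pad + 1L):(ext$pad + n)]
}

#' Remove slow baseline drift
#'
#' Subtracts a centered running-mean baseline (odd-reflected at the edges).
#' A linear ramp is removed exactly; components with period much shorter
#' than the window pass through essentially unchanged.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param window Baseline window in seconds; must not exceed the series
#'   duration.
#' @return Detrended series, same length as `x`.
#' @export
detrend_baseline <- function(x, fs, window) {
  if (!is.finite(window) || window <= 0) {
    stop("detrend_baseline: window must be > 0", call. = FALSE)
  }
  n <- length(x)
  w <- as.integer(round(window * fs))
  if (w > n) {
    stop("detrend_baseline: window longer than the series", call. = FALSE)
  }
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  ext <- reflect_pad(x, half)
  cs <- cumsum(c(0, ext$x))
  # centered mean over w samples for each original position
  idx <- seq_len(n) + ext$pad
  baseline <- (cs[idx + half + 1L] - cs[idx - half]) / w
  x - baseline
}

#' Decompose EDA into tonic and phasic components
#'
#' The tonic (SCL) component is the slow part of the signal, estimated by
#' zero-phase low-pass filtering at `tonic_cutoff`; the phasic (SCR)
#' component is the residual. The two components sum to the input exactly,
#' by construction.
#'
#' @param eda Cleaned EDA series.
#' @param fs Sampling rate (Hz).
#' @param tonic_cutoff Tonic cutoff frequency (Hz), default 0.05.
#' @return List with `phasic` and `tonic` series.
#' @export
decompose_phasic_tonic <- function(eda, fs, tonic_cutoff = 0.05) {
  min_len <- as.integer(ceiling(fs / tonic_cutoff))
  if (length(eda) < min_len) {
    stop("decompose_phasic_tonic: series shorter than the tonic smoothing ",
         "window (", min_len, " samples)", call. = FALSE)
  }
  tonic <- lowpass_filter(eda, fs, tonic_cutoff, order = 2)
  list(phasic = eda - tonic, tonic = tonic)
}

#' Z-normalize a series
#'
#' Centers and scales to mean 0, standard deviation 1, using the
#' population (1/N) standard deviation. A constant (zero-variance) series
#' is a degenerate signal and raises an error rather than returning NaN.
#'
#' @param x Numeric series.
#' @return Normalized series.
#' @export
znormalize <- function(x) {
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (!is.finite(sdev) || sdev == 0) {
    stop("znormalize: degenerate signal (zero variance)", call. = FALSE)
  }
  (x - mu) / sdev
}

#' Clean a recording
#'
#' Applies the identical cleaning chain (zero-phase low-pass, running-mean
#' detrend) to both channels, decomposes the cleaned EDA into tonic and
#' phasic components, then z-normalizes per participant. The tonic and
#' phasic components are expressed in the same normalized units
#' (`(tonic - mean)/sd` and `phasic/sd`), so
#' `eda_tonic + eda_phasic == eda_clean` holds at machine precision after
#' normalization.
#'
#' @param rec A `signal_recording`.
#' @param params A [preprocess_params()] object.
#' @return A `processed_recording` with channels `eda_clean`, `eda_tonic`,
#'   `eda_phasic`, `lidar_clean`, and a metadata echo of the parameters
#'   applied to each channel and the stage order.
#' @export
clean_recording <- function(rec, params = preprocess_params()) {
  stopifnot(inherits(rec, "signal_recording"))
  fs <- rec$fs
  clean1 <- function(x) {
    y <- lowpass_filter(x, fs, params$cutoff, order = params$filter_order)
    detrend_baseline(y, fs, params$detrend_window)
  }
  eda_c <- clean1(rec$eda_raw)
  lidar_c <- clean1(rec$lidar_raw)
  dec <- decompose_phasic_tonic(eda_c, fs, params$tonic_cutoff)
  mu <- mean(eda_c)
  sdev <- sqrt(mean((eda_c - mu)^2))
  if (!is.finite(sdev) || sdev == 0) {
    stop("clean_recording: degenerate EDA channel (zero variance)",
         call. = FALSE)
  }
  structure(
    list(
      subject_id = rec$subject_id, fs = fs, time = rec$time,
      eda_clean = (eda_c - mu) / sdev,
      eda_tonic = (dec$tonic - mu) / sdev,
      eda_phasic = dec$phasic / sdev,
      lidar_clean = znormalize(lidar_c),
      stimulus_onsets = rec$stimulus_onsets,
      latent = rec$latent,
      meta = list(
        eda_params = unclass(params), lidar_params = unclass(params),
        stage_order = c("lowpass", "detrend", "decompose", "znormalize")
      )
    ),
    class = "processed_recording"
  )
}

#' @export
print.processed_recording <- function(x, ...) {
  cat(sprintf(
    "<processed_recording> subject %s: %d samples at %g Hz; channels: %s\n",
    x$subject_id, length(x$time), x$fs,
    "eda_clean, eda_tonic, eda_phasic, lidar_clean"
  ))
  invisible(x)
}

#' Write a processed recording as CSV + sidecar JSON
#'
#' Extends the raw-recording CSV dialect with the columns `eda_clean,
#' eda_tonic, eda_phasic, lidar_clean`; the processing parameters are
#' echoed into the sidecar.
#'
#' @param proc A `processed_recording`.
#' @param dir Output directory.
#' @return Invisibly, the CSV path.
#' @export
write_processed <- function(proc, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  onset_idx <- as.integer(round(proc$stimulus_onsets * proc$fs)) + 1L
  is_onset <- integer(length(proc$time))
  is_onset[onset_idx[onset_idx >= 1 & onset_idx <= length(is_onset)]] <- 1L
  df <- data.frame(
    time_s = proc$time, eda_clean = proc$eda_clean,
    eda_tonic = proc$eda_tonic, eda_phasic = proc$eda_phasic,
    lidar_clean = proc$lidar_clean, is_stimulus_onset = is_onset
  )
  csv <- file.path(dir, paste0(proc$subject_id, "_processed.csv"))
  data.table::fwrite(df, csv)
  jsonlite::write_json(
    list(subject_id = proc$subject_id, fs = proc$fs, meta = proc$meta),
    file.path(dir, paste0(proc$subject_id, "_processed.json")),
    auto_unbox = TRUE, digits = NA
  )
  invisible(csv)
}
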