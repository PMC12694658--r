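#' Segmentation parameters
#'
#' Segments are sliding context windows of `context_len` seconds; the
#' terminal window is the last `terminal_len` seconds of each context and
#' supplies the "current value" (its mean) for the rank-percentile factor.
#' The model input is the last `input_len` seconds of the LiDAR channel.
#'
#' @param context_len Context window length in seconds (default 100).
#' @param terminal_len Terminal window length in seconds (default 10).
#' @param stride Segment advance in samples (default 10). Set to
#'   `context_len * fs` for non-overlapping segments.
#' @param input_len Model input window length in seconds (default 10).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(context_len = 100, terminal_len = 10,
                                stride = 10, input_len = 10) {
  p <- list(context_len = context_len, terminal_len = terminal_len,
            stride = as.integer(stride), input_len = input_len)
  if (!(p$terminal_len > 0 && p$terminal_len <= p$context_len)) {
    stop("segmentation_params: need 0 < terminal_len <= context_len",
         call. = FALSE)
  }
  if (p$stride < 1L) {
    stop("segmentation_params: stride must be >= 1 sample", call. = FALSE)
  }
  if (p$input_len > p$context_len) {
    stop("segmentation_params: input_len must be <= context_len",
         call. = FALSE)
  }
  class(p) <- "segmentation_params"
  p
}

#' Slide context windows over a processed recording
#'
#' Each segment ends at sample index `e` (for `e = L, L + stride, ...`
#' with `L = context_len * fs`) and consists of the phasic-EDA context
#' covering the preceding `context_len` seconds, its terminal
#' `terminal_len` seconds, and the last `input_len` seconds of the cleaned
#' LiDAR channel.
#'
#' @param proc A `processed_recording`.
#' @param params A [segmentation_params()] object.
#' @return List of segments, each a list with `subject_id`, `end_time`,
#'   `context`, `terminal`, `lidar_input`, `end_index`. A recording
#'   shorter than `context_len` yields an empty list with a warning.
#' @export
segment_stream <- function(proc, params = segmentation_params()) {
  stopifnot(inherits(proc, "processed_recording"))
  fs <- proc$fs
  n <- length(proc$time)
  len_ctx <- as.integer(round(params$context_len * fs))
  len_ter <- as.integer(round(params$terminal_len * fs))
  len_inp <- as.integer(round(params$input_len * fs))
  if (n < len_ctx) {
    warning("segment_stream: recording shorter than context_len; ",
            "no segments emitted")
    return(list())
  }
  ends <- seq.int(len_ctx, n, by = params$stride)
  lapply(ends, function(e) {
    ctx <- proc$eda_phasic[(e - len_ctx + 1L):e]
    list(
      subject_id = proc$subject_id,
      end_time = proc$time[e],
      context = ctx,
      terminal = ctx[(len_ctx - len_ter + 1L):len_ctx],
      lidar_input = proc$lidar_clean[(e - len_inp + 1L):e],
      end_index = e
    )
  })
}

#' Rank-percentile arousal factor
#'
#' The context is z-normalized (per segment), the current value is the mean
#' of the terminal window, and its empirical rank percentile is the share
#' of context values less than or equal to the current value, scaled to
#' 0-100. Subtracting a constant offset of 50 centers the scale so 0 is a
#' neutral course, +50 a strongly positive and -50 a strongly negative
#' arousal change.
#'
#' @param context Numeric context window (phasic EDA).
#' @param terminal Terminal portion of the context (its tail).
#' @param ties Tie rule: `"le"` (default) counts values `<=` the current
#'   value, matching the definition above; `"midrank"` counts ties at half
#'   weight.
#' @return The factor, a unitless value in `[-50, +50]`.
#' @export
rank_percentile_factor <- function(context, terminal,
                                   ties = c("le", "midrank")) {
  ties <- match.arg(ties)
  if (length(context) == 0L) {
    stop("rank_percentile_factor: empty context", call. = FALSE)
  }
  z <- znormalize(context)
  mu <- mean(context)
  sdev <- sqrt(mean((context - mu)^2))
  current <- (mean(terminal) - mu) / sdev
  n <- length(z)
  pct <- if (ties == "le") {
    100 * sum(z <= current) / n
  } else {
    100 * (sum(z < current) + 0.5 * sum(z == current)) / n
  }
  pct - 50
}

#' Discretize the factor into k equal-width classes
#'
#' Bins partition `[-50, +50]` into `k` equal-width intervals; bin `j`
#' covers `[-50 + 100 j / k, -50 + 100 (j + 1) / k)` and the upper
#' boundary +50 is assigned to class `k - 1`.
#'
#' @param factor Factor value(s) in `[-50, +50]`.
#' @param k Number of classes, between 2 and 10.
#' @return Integer class index/indices in `0 ... k - 1`.
#' @export
discretize_factor <- function(factor, k) {
  k <- as.integer(k)
  if (k < 2L || k > 10L) {
    stop("discretize_factor: k must be between 2 and 10", call. = FALSE)
  }
  if (any(factor < -50 - 1e-9 | factor > 50 + 1e-9)) {
    stop("discretize_factor: factor outside [-50, +50]", call. = FALSE)
  }
  j <- as.integer(floor((pmin(pmax(factor, -50), 50) + 50) * k / 100))
  j[j >= k] <- k - 1L
  j
}

#' Class imbalance ratio
#'
#' @param class_counts Vector of per-class counts, all positive.
#' @return `max(counts) / min(counts)`.
#' @export
imbalance_ratio <- function(class_counts) {
  if (length(class_counts) == 0L || any(class_counts <= 0)) {
    stop("imbalance_ratio: undefined for empty classes", call. = FALSE)
  }
  max(class_counts) / min(class_counts)
}

#' Build the labeled segment dataset
#'
#' Applies segmentation, the rank-percentile factor and k-class
#' discretization to each processed recording, pairing every LiDAR input
#' window with its continuous factor and class label.
#'
#' @param procs List of `processed_recording` objects.
#' @param params A [segmentation_params()] object.
#' @param k Number of classes for the categorical target (2-10).
#' @param ties Tie rule passed to [rank_percentile_factor()].
#' @return A `labeled_dataset`: `segments` (data.frame with `subject_id`,
#'   `end_time`, `factor`, `factor_unit`, `class_index`), `windows`
#'   (matrix, one LiDAR input window per row), `k`, `class_counts`,
#'   `params`.
#' @export
build_labeled_dataset <- function(procs, params = segmentation_params(),
                                  k = 3, ties = "le") {
  if (inherits(procs, "processed_recording")) procs <- list(procs)
  segs <- unlist(lapply(procs, segment_stream, params = params),
                 recursive = FALSE)
  if (length(segs) == 0L) {
    stop("build_labeled_dataset: no segments (recordings too short?)",
         call. = FALSE)
  }
  fac <- vapply(segs, function(s) {
    rank_percentile_factor(s$context, s$terminal, ties = ties)
  }, numeric(1))
  cls <- discretize_factor(fac, k)
  windows <- do.call(rbind, lapply(segs, `[[`, "lidar_input"))
  rownames(windows) <- NULL
  counts <- tabulate(cls + 1L, nbins = k)
  names(counts) <- paste0("C", seq_len(k))
  structure(
    list(
      segments = data.frame(
        subject_id = vapply(segs, `[[`, character(1), "subject_id"),
        end_time = vapply(segs, `[[`, numeric(1), "end_time"),
        factor = fac,
        factor_unit = fac + 50,
        class_index = cls,
        stringsAsFactors = FALSE
      ),
      windows = windows,
      k = as.integer(k),
      class_counts = counts,
      params = params
    ),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "<labeled_dataset> %d segments from %d subject(s); k = %d; imbalance ratio %.2f\n",
    nrow(x$segments), length(unique(x$segments$subject_id)), x$k,
    tryCatch(imbalance_ratio(x$class_counts), error = function(e) NA_real_)
  ))
  invisible(x)
}

#' Persist a labeled dataset as CSV
#'
#' Writes `segments.csv` (one row per segment: subject, end time, factor
#' and class label) and `windows.csv` (wide CSV of LiDAR input windows,
#' one column per sample index).
#'
#' @param dataset A `labeled_dataset`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_labeled_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(dataset$segments, file.path(dir, "segments.csv"))
  w <- as.data.frame(dataset$windows)
  names(w) <- paste0("s", seq_len(ncol(w)))
  data.table::fwrite(w, file.path(dir, "windows.csv"))
  invisible(dir)
}
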