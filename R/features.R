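#' Names of the window features
#'
#' The fixed, ordered 12-feature set computed by [extract_features()]:
#' moments (mean, variance, skewness, excess kurtosis), a least-squares
#' slope, autocorrelation structure (lags 1, 5, 10 and the first zero
#' crossing of the autocorrelation function), the zero-crossing rate of
#' the centered signal, and two spectral summaries (centroid and
#' normalized entropy).
#'
#' @return Character vector of feature names, in column order.
#' @export
feature_names <- function() {
  c("mean", "variance", "skewness", "kurtosis_excess", "ls_slope",
    "acf_lag1", "acf_lag5", "acf_lag10", "acf_first_zero",
    "zero_crossing_rate", "spectral_centroid", "spectral_entropy")
}

# unbiased-normalization autocorrelation: mean lagged product over the
# variance, so a sinusoid at a full-period lag gives ~1 regardless of n
acf_at <- function(x, lag) {
  n <- length(x)
  if (lag >= n) return(NA_real_)
  xc <- x - mean(x)
  denom <- sum(xc^2) / n
  if (denom == 0) return(NA_real_)
  sum(xc[1:(n - lag)] * xc[(lag + 1):n]) / (n - lag) / denom
}

#' Extract the feature vector of one input window
#'
#' A pure function of the window: identical windows always yield identical
#' vectors and no cross-segment state is used. Features that are undefined
#' on degenerate windows (e.g., autocorrelation of a constant) are imputed
#' as 0 and flagged in the `imputed` attribute; the feature source is
#' recorded in the `source` attribute.
#'
#' @param window Numeric series (one model input window).
#' @param fs Sampling rate (Hz), used for the slope (per second) and
#'   spectral features.
#' @return Named numeric vector of length 12 (see [feature_names()]),
#'   with attributes `imputed` (logical) and `source`.
#' @export
extract_features <- function(window, fs) {
  n <- length(window)
  if (n < 20L) {
    stop("extract_features: window must have at least 20 samples",
         call. = FALSE)
  }
  mu <- mean(window)
  v <- stats::var(window)
  xc <- window - mu
  t_s <- (seq_len(n) - 1) / fs
  slope <- {
    tc <- t_s - mean(t_s)
    sum(tc * xc) / sum(tc^2)
  }
  sk <- if (v > 0) e1071::skewness(window) else NA_real_
  ku <- if (v > 0) e1071::kurtosis(window) else NA_real_
  a1 <- acf_at(window, 1L)
  a5 <- acf_at(window, 5L)
  a10 <- acf_at(window, 10L)
  first_zero <- {
    fz <- NA_real_
    if (v > 0) {
      for (lag in seq_len(n - 1L)) {
        if (acf_at(window, lag) <= 0) { fz <- lag; break }
      }
      if (is.na(fz)) fz <- n
    }
    fz
  }
  zcr <- if (n > 1L) {
    s <- sign(xc)
    s <- s[s != 0]
    if (length(s) > 1L) sum(diff(s) != 0) / (n - 1L) else 0
  } else {
    0
  }
  spec <- Mod(stats::fft(xc))^2
  half <- spec[2:(floor(n / 2) + 1L)]  # positive frequencies, DC excluded
  freqs <- (seq_along(half)) * fs / n
  ptot <- sum(half)
  centroid <- if (ptot > 0) sum(freqs * half) / ptot else NA_real_
  entropy <- if (ptot > 0) {
    p <- half / ptot
    p <- p[p > 0]
    -sum(p * log(p)) / log(length(half))
  } else {
    NA_real_
  }
  vals <- c(mu, v, sk, ku, slope, a1, a5, a10, first_zero, zcr,
            centroid, entropy)
  names(vals) <- feature_names()
  imputed <- !is.finite(vals)
  vals[imputed] <- 0
  attr(vals, "imputed") <- imputed
  attr(vals, "source") <- "fallback12"
  vals
}

#' Build the feature matrix for a labeled dataset
#'
#' Row i of the matrix corresponds to segment i; columns are the fixed
#' feature set in [feature_names()] order. Continuous and class targets
#' are returned aligned with the rows.
#'
#' @param dataset A `labeled_dataset` (or a bare matrix of windows).
#' @param fs Sampling rate (Hz) of the windows.
#' @return A `feature_matrix` list: `X` (n x 12 matrix), `factor`,
#'   `factor_unit` and `class_index` targets (NULL when a bare window
#'   matrix is given), `feature_source`, and `zero_variance` flags per
#'   column.
#' @export
build_feature_matrix <- function(dataset, fs = 20) {
  windows <- if (inherits(dataset, "labeled_dataset")) {
    dataset$windows
  } else {
    as.matrix(dataset)
  }
  X <- t(apply(windows, 1L, extract_features, fs = fs))
  colnames(X) <- feature_names()
  zero_var <- apply(X, 2L, function(col) stats::var(col) == 0)
  out <- list(
    X = X,
    factor = if (inherits(dataset, "labeled_dataset")) {
      dataset$segments$factor
    } else {
      NULL
    },
    factor_unit = if (inherits(dataset, "labeled_dataset")) {
      dataset$segments$factor_unit
    } else {
      NULL
    },
    class_index = if (inherits(dataset, "labeled_dataset")) {
      dataset$segments$class_index
    } else {
      NULL
    },
    feature_source = "fallback12",
    zero_variance = zero_var
  )
  class(out) <- "feature_matrix"
  out
}

#' Persist a feature matrix as CSV
#'
#' Header = feature names; target columns are suffixed `__factor` and
#' `__class_k{k}`.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @param k Number of classes used for the class target column name.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(fm, path, k = NULL) {
  df <- as.data.frame(fm$X)
  if (!is.null(fm$factor)) df[["target__factor"]] <- fm$factor
  if (!is.null(fm$class_index)) {
    nm <- if (is.null(k)) "target__class" else sprintf("target__class_k%d", k)
    df[[nm]] <- fm$class_index
  }
  data.table::fwrite(df, path)
  invisible(path)
}
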