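#' Random 75/25 split of segments
#'
#' Partitions segment indices disjointly and exhaustively into a training
#' and a test side, independent of subject identity. This split estimates
#' the within-subject upper bound of performance, since segments of every
#' subject appear on both sides.
#'
#' @param n Number of segments (>= 2).
#' @param fraction Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed.
#' @return A `split_plan` with one fold (`train`, `test` index vectors).
#' @export
split_random <- function(n, fraction = 0.75, seed = 1L) {
  if (n < 2L) stop("split_random: need at least 2 segments", call. = FALSE)
  if (!(fraction > 0 && fraction < 1)) {
    stop("split_random: fraction must be in (0, 1)", call. = FALSE)
  }
  n_train <- as.integer(round(fraction * n))
  n_train <- min(max(n_train, 1L), n - 1L)
  idx <- with_seed(seed, sample.int(n))
  structure(
    list(strategy = "random",
         folds = list(list(train = sort(idx[seq_len(n_train)]),
                           test = sort(idx[(n_train + 1L):n])))),
    class = "split_plan"
  )
}

#' Leave-one-subject-out split
#'
#' One fold per subject; the test side of a fold contains exactly that
#' subject's segments, so no subject appears on both sides of any fold.
#' This measures generalization to previously unseen subjects.
#'
#' @param subject_ids Character vector, one entry per segment.
#' @return A `split_plan` with one fold per subject.
#' @export
split_loso <- function(subject_ids) {
  subjects <- unique(subject_ids)
  if (length(subjects) < 2L) {
    stop("split_loso: need at least 2 subjects", call. = FALSE)
  }
  folds <- lapply(subjects, function(s) {
    list(train = which(subject_ids != s), test = which(subject_ids == s),
         held_out = s)
  })
  names(folds) <- subjects
  structure(list(strategy = "loso", folds = folds), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s, %d fold(s)\n", x$strategy, length(x$folds)))
  invisible(x)
}

#' Balanced accuracy
#'
#' Mean of per-class recalls over classes `0..k-1`. A class absent from
#' `y_true` has undefined recall: with `absent = "error"` (default) this
#' raises an error; with `absent = "drop"` the class is excluded from the
#' mean and recorded in the `dropped_classes` attribute (needed for LOSO
#' folds that can miss extreme classes).
#'
#' @param y_true,y_pred Integer class labels in `0..k-1`.
#' @param k Number of classes.
#' @param absent Policy for classes missing from `y_true`.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred, k,
                              absent = c("error", "drop")) {
  absent <- match.arg(absent)
  k <- as.integer(k)
  if (any(y_true < 0 | y_true >= k) || any(y_pred < 0 | y_pred >= k)) {
    stop("balanced_accuracy: labels outside 0..k-1", call. = FALSE)
  }
  recalls <- vapply(0:(k - 1L), function(cls) {
    in_cls <- y_true == cls
    if (!any(in_cls)) return(NA_real_)
    mean(y_pred[in_cls] == cls)
  }, numeric(1))
  if (anyNA(recalls)) {
    if (absent == "error") {
      stop("balanced_accuracy: class(es) ",
           paste(which(is.na(recalls)) - 1L, collapse = ", "),
           " absent from y_true; recall undefined", call. = FALSE)
    }
    dropped <- which(is.na(recalls)) - 1L
    ba <- mean(recalls, na.rm = TRUE)
    attr(ba, "dropped_classes") <- dropped
    return(ba)
  }
  mean(recalls)
}

#' Normalized improvement over chance
#'
#' Chance-corrected balanced accuracy `NI = (BA - c) / (1 - c)` with
#' chance level `c = 1/k`: 0 at chance, 1 at perfect classification.
#'
#' @param ba Balanced accuracy in `[0, 1]`.
#' @param k Number of classes (>= 2).
#' @return NI as a fraction.
#' @export
normalized_improvement <- function(ba, k) {
  if (any(k < 2)) {
    stop("normalized_improvement: k must be >= 2", call. = FALSE)
  }
  if (any(ba < 0 | ba > 1)) {
    stop("normalized_improvement: BA must be in [0, 1]", call. = FALSE)
  }
  c_level <- 1 / k
  (ba - c_level) / (1 - c_level)
}

#' Chance level for k classes
#'
#' @param k Number of classes.
#' @return `1/k`.
#' @export
chance_level <- function(k) 1 / k

#' Regression error metrics
#'
#' MAE, RMSE and the coefficient of determination, reported in factor
#' units on the centered scale.
#'
#' @param y_true,y_pred Numeric vectors of equal length (n >= 2).
#' @return List with `mae`, `rmse`, `r2`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  n <- length(y_true)
  if (n < 2L || length(y_pred) != n) {
    stop("regression_metrics: need equal lengths, n >= 2", call. = FALSE)
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    stop("regression_metrics: zero-variance y_true; R^2 undefined",
         call. = FALSE)
  }
  err <- y_pred - y_true
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
       r2 = 1 - sum(err^2) / ss_tot)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `estimate - reference`; the bias is their mean, the SD
#' the sample (n-1) standard deviation, and the 95% limits of agreement
#' are `bias +/- 1.96 * SD`.
#'
#' @param reference,estimate Numeric vectors of equal length (n >= 2).
#' @return List with `bias`, `sd`, `loa_low`, `loa_high`, and the paired
#'   `diffs` and `means` for plotting.
#' @export
bland_altman <- function(reference, estimate) {
  n <- length(reference)
  if (n < 2L || length(estimate) != n) {
    stop("bland_altman: need equal lengths, n >= 2", call. = FALSE)
  }
  diffs <- estimate - reference
  bias <- mean(diffs)
  sdev <- stats::sd(diffs)
  list(bias = bias, sd = sdev,
       loa_low = bias - 1.96 * sdev, loa_high = bias + 1.96 * sdev,
       diffs = diffs, means = (estimate + reference) / 2)
}

#' Pearson correlation with p-value
#'
#' Sample correlation and its two-sided p-value from the standard t
#' transform (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors (n >= 3, both non-degenerate).
#' @return List with `r` and `p_value`.
#' @export
pearson <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) {
    stop("pearson: need equal lengths, n >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson: degenerate variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

train_one <- function(spec, dataset, fm, idx) {
  if (spec$sequence) {
    if (spec$task == "classification") {
      train_sequence_model(spec, dataset$windows[idx, , drop = FALSE],
                           dataset$segments$class_index[idx])
    } else {
      train_sequence_model(spec, dataset$windows[idx, , drop = FALSE],
                           dataset$segments$factor_unit[idx])
    }
  } else {
    if (spec$task == "classification") {
      train_feature_model(spec, fm$X[idx, , drop = FALSE],
                          dataset$segments$class_index[idx])
    } else {
      train_feature_model(spec, fm$X[idx, , drop = FALSE],
                          dataset$segments$factor_unit[idx])
    }
  }
}

predict_one <- function(model, dataset, fm, idx) {
  inputs <- if (model$spec$sequence) {
    dataset$windows[idx, , drop = FALSE]
  } else {
    fm$X[idx, , drop = FALSE]
  }
  predict(model, inputs)
}

#' Evaluate model specs on a labeled dataset under a split plan
#'
#' For each model spec and each fold, trains on the training side only and
#' predicts the held-out side; feature extraction is a pure per-window
#' function, so no cross-segment statistics leak across the split. Metrics
#' are computed on the pooled test predictions across folds (the headline
#' aggregation) and per fold (macro) for multi-fold plans. Classification
#' reports BA and NI (with absent classes dropped per fold and logged);
#' regression reports MAE/RMSE/R-squared on the centered scale plus
#' Pearson correlation and Bland-Altman agreement.
#'
#' @param specs A [model_spec()] or list of them.
#' @param dataset A `labeled_dataset`.
#' @param plan A `split_plan` from [split_random()] or [split_loso()].
#' @param fm Optional precomputed [build_feature_matrix()] result (built
#'   on demand when any spec is feature-based).
#' @return An `evaluation_report`: `metrics` (data.frame, one row per
#'   model), `predictions` (per-segment y_true/y_pred/fold), `agreement`
#'   (per regression model), `strategy`.
#' @export
evaluate_run <- function(specs, dataset, plan, fm = NULL) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  needs_features <- any(!vapply(specs, `[[`, logical(1), "sequence"))
  if (needs_features && is.null(fm)) {
    fm <- build_feature_matrix(dataset)
  }
  metrics <- list()
  predictions <- list()
  agreement <- list()
  training_logs <- list()
  for (spec in specs) {
    tag <- sprintf("%s_%s%s", spec$family, spec$task,
                   if (!is.null(spec$k)) paste0("_k", spec$k) else "")
    y_true_all <- c()
    y_pred_all <- c()
    fold_ids <- c()
    seg_ids <- c()
    fold_metrics <- list()
    for (fi in seq_along(plan$folds)) {
      fold <- plan$folds[[fi]]
      model <- train_one(spec, dataset, fm, fold$train)
      if (spec$sequence && !is.null(model$log) && nrow(model$log) > 0) {
        lg <- model$log
        lg$fold <- fi
        training_logs[[tag]] <- rbind(training_logs[[tag]], lg)
      }
      pred <- predict_one(model, dataset, fm, fold$test)
      truth <- if (spec$task == "classification") {
        dataset$segments$class_index[fold$test]
      } else {
        dataset$segments$factor[fold$test]
      }
      y_true_all <- c(y_true_all, truth)
      y_pred_all <- c(y_pred_all, pred)
      fold_ids <- c(fold_ids, rep(fi, length(fold$test)))
      seg_ids <- c(seg_ids, fold$test)
      fold_metrics[[fi]] <- if (spec$task == "classification") {
        ba <- balanced_accuracy(truth, pred, spec$k, absent = "drop")
        list(ba = as.numeric(ba), ni = normalized_improvement(ba, spec$k))
      } else {
        regression_metrics(truth, pred)
      }
    }
    row <- list(model = spec$family, task = spec$task,
                k = if (is.null(spec$k)) NA_integer_ else spec$k,
                strategy = plan$strategy)
    if (spec$task == "classification") {
      ba <- balanced_accuracy(y_true_all, y_pred_all, spec$k,
                              absent = "drop")
      dropped <- attr(ba, "dropped_classes")
      if (!is.null(dropped) && length(dropped) > 0) {
        message("evaluate_run [", tag, "]: class(es) ",
                paste(dropped, collapse = ", "),
                " absent from pooled test labels; dropped from BA")
      }
      row$ba <- as.numeric(ba)
      row$ni <- normalized_improvement(as.numeric(ba), spec$k)
      row$ba_macro <- mean(vapply(fold_metrics, `[[`, numeric(1), "ba"))
      row$ni_macro <- mean(vapply(fold_metrics, `[[`, numeric(1), "ni"))
      row$mae <- NA_real_; row$rmse <- NA_real_; row$r2 <- NA_real_
      row$pearson_r <- NA_real_; row$pearson_p <- NA_real_
    } else {
      rm_ <- regression_metrics(y_true_all, y_pred_all)
      pr <- pearson(y_true_all, y_pred_all)
      ba_stats <- bland_altman(y_true_all, y_pred_all)
      row$ba <- NA_real_; row$ni <- NA_real_
      row$ba_macro <- NA_real_; row$ni_macro <- NA_real_
      row$mae <- rm_$mae; row$rmse <- rm_$rmse; row$r2 <- rm_$r2
      row$pearson_r <- pr$r; row$pearson_p <- pr$p_value
      agreement[[tag]] <- list(
        bias = ba_stats$bias, sd = ba_stats$sd,
        loa_low = ba_stats$loa_low, loa_high = ba_stats$loa_high,
        pearson_r = pr$r, p_value = pr$p_value
      )
    }
    metrics[[tag]] <- as.data.frame(row, stringsAsFactors = FALSE)
    predictions[[tag]] <- data.frame(
      segment = seg_ids,
      subject_id = dataset$segments$subject_id[seg_ids],
      fold = fold_ids, y_true = y_true_all, y_pred = y_pred_all,
      model = spec$family, task = spec$task,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(metrics = do.call(rbind, c(metrics, make.row.names = FALSE)),
         predictions = do.call(rbind, c(predictions,
                                        make.row.names = FALSE)),
         agreement = agreement, training_logs = training_logs,
         strategy = plan$strategy, k = dataset$k),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> strategy %s, %d model(s)\n",
              x$strategy, nrow(x$metrics)))
  print(x$metrics, digits = 3)
  invisible(x)
}
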