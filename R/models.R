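FEATURE_CLASSIFIERS <- c("extra_trees", "random_forest", "knn", "lightgbm",
                         "gradient_boosting", "svm", "logistic")
FEATURE_REGRESSORS <- c("extra_trees", "random_forest", "lightgbm",
                        "gradient_boosting", "xgboost")
SEQUENCE_FAMILIES <- c("gru", "lstm", "cnn1d", "tcn")

#' Declare a model
#'
#' Validates family/task combinations: feature-based classifiers are
#' Extra Trees, Random Forest, k-NN, LightGBM, Gradient Boosting, SVM and
#' logistic regression; feature-based regressors are Extra Trees, Random
#' Forest, LightGBM, Gradient Boosting and XGBoost; the sequence families
#' (GRU, LSTM, 1D-CNN, TCN) support both tasks. Sequence models train with
#' Adam at learning rate 0.001 under cross-entropy (classification, batch
#' size 32) or mean-squared-error loss (regression, batch size 128) for 75
#' epochs by default. Feature-based models use library defaults apart from
#' the seed; they were deliberately not tuned.
#'
#' The `lightgbm` family is declared for completeness but unavailable in
#' this build (no R implementation is bundled); requesting it raises an
#' error at training time.
#'
#' @param family Model family name (see above).
#' @param task `"classification"` or `"regression"`.
#' @param k Number of classes (classification only).
#' @param learning_rate,epochs,batch_size Sequence-model training
#'   hyperparameters; `batch_size` defaults to 32 for classification and
#'   128 for regression.
#' @param seed Integer seed controlling initialization and minibatch order.
#' @param arch Optional list of architecture overrides for sequence models
#'   (e.g., `list(hidden = 16)` for GRU/LSTM).
#' @return A `model_spec` list.
#' @export
model_spec <- function(family,
                       task = c("classification", "regression"),
                       k = NULL, learning_rate = 0.001, epochs = 75L,
                       batch_size = NULL, seed = 1L, arch = NULL) {
  task <- match.arg(task)
  valid <- if (task == "classification") {
    c(FEATURE_CLASSIFIERS, SEQUENCE_FAMILIES)
  } else {
    c(FEATURE_REGRESSORS, SEQUENCE_FAMILIES)
  }
  if (!family %in% valid) {
    stop("model_spec: family '", family, "' is not available for ", task,
         call. = FALSE)
  }
  if (task == "classification") {
    if (is.null(k)) k <- 3L
    k <- as.integer(k)
    if (k < 2L || k > 10L) {
      stop("model_spec: k must be between 2 and 10", call. = FALSE)
    }
  } else {
    k <- NULL
  }
  if (is.null(batch_size)) {
    batch_size <- if (task == "classification") 32L else 128L
  }
  spec <- list(family = family, task = task, k = k,
               learning_rate = learning_rate, epochs = as.integer(epochs),
               batch_size = as.integer(batch_size),
               loss = if (task == "classification") "cross-entropy"
                      else "mean-squared-error",
               seed = as.integer(seed), arch = arch,
               sequence = family %in% SEQUENCE_FAMILIES)
  class(spec) <- "model_spec"
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s %s%s (%s)\n", x$family, x$task,
              if (!is.null(x$k)) sprintf(", k = %d", x$k) else "",
              if (x$sequence) "sequence-based" else "feature-based"))
  invisible(x)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Train a feature-based model
#'
#' Fits the requested classical learner on a feature matrix. Regression
#' targets are on the unit factor scale `[0, 100]`; [predict()] clips to
#' that range and reports on the centered scale.
#'
#' @param spec A feature-based [model_spec()].
#' @param X Numeric feature matrix (rows = segments).
#' @param y Targets: integer classes `0..k-1` (classification) or the
#'   continuous factor on the unit scale `[0, 100]` (regression; the
#'   centered factor `[-50, 50]` is accepted and shifted).
#' @return A `trained_model`.
#' @export
train_feature_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$sequence) {
    stop("train_feature_model: '", spec$family, "' is a sequence family",
         call. = FALSE)
  }
  if (spec$family == "lightgbm") {
    stop("train_feature_model: the lightgbm family is unavailable in this ",
         "build; choose another gradient-boosting family", call. = FALSE)
  }
  X <- as.matrix(X)
  if (nrow(X) != length(y)) {
    stop("train_feature_model: X and y are not aligned", call. = FALSE)
  }
  if (spec$task == "regression" && min(y) < 0) y <- y + 50
  fit <- switch(spec$family,
    extra_trees = with_seed(spec$seed, {
      df <- data.frame(X)
      df$..y <- if (spec$task == "classification") {
        factor(y, levels = 0:(spec$k - 1L))
      } else {
        y
      }
      ranger::ranger(dependent.variable.name = "..y", data = df,
                     splitrule = "extratrees", num.random.splits = 1L,
                     replace = FALSE, sample.fraction = 1,
                     seed = spec$seed, num.threads = 1L)
    }),
    random_forest = with_seed(spec$seed, {
      df <- data.frame(X)
      df$..y <- if (spec$task == "classification") {
        factor(y, levels = 0:(spec$k - 1L))
      } else {
        y
      }
      ranger::ranger(dependent.variable.name = "..y", data = df,
                     seed = spec$seed, num.threads = 1L)
    }),
    knn = list(X = X, y = y, k_neighbors = 5L,
               center = colMeans(X),
               scale = pmax(apply(X, 2L, stats::sd), 1e-12)),
    gradient_boosting = with_seed(spec$seed, {
      # classic GBM-style settings: shrinkage 0.1, depth-3 trees
      prm <- list(eta = 0.1, max_depth = 3L, subsample = 1,
                  nthread = 1L, seed = spec$seed)
      if (spec$task == "classification") {
        prm$objective <- "multi:softmax"
        prm$num_class <- spec$k
      } else {
        prm$objective <- "reg:squarederror"
      }
      xgboost::xgb.train(params = prm,
                         data = xgboost::xgb.DMatrix(X, label = y),
                         nrounds = 100L, verbose = 0)
    }),
    svm = with_seed(spec$seed, {
      e1071::svm(x = X, y = factor(y, levels = 0:(spec$k - 1L)))
    }),
    logistic = with_seed(spec$seed, {
      df <- data.frame(X)
      df$..y <- factor(y, levels = 0:(spec$k - 1L))
      nnet::multinom(..y ~ ., data = df, trace = FALSE, maxit = 200L,
                     MaxNWts = 5000L)
    }),
    xgboost = with_seed(spec$seed, {
      xgboost::xgb.train(
        params = list(objective = "reg:squarederror", nthread = 1L,
                      seed = spec$seed),
        data = xgboost::xgb.DMatrix(X, label = y),
        nrounds = 100L, verbose = 0
      )
    }),
    stop("train_feature_model: unknown family '", spec$family, "'",
         call. = FALSE)
  )
  structure(list(spec = spec, fit = fit, feature_names = colnames(X),
                 input_len = ncol(X), log = NULL),
            class = "trained_model")
}

#' Train a sequence model on raw LiDAR windows
#'
#' Trains the requested recurrent or convolutional network on single-channel
#' input windows with Adam, for exactly `spec$epochs` epochs at
#' `spec$batch_size`, under cross-entropy (classification) or MSE
#' (regression) loss. Initialization and minibatch order are seeded, so
#' training is deterministic; with `epochs = 0` the model is returned at
#' its random initialization (chance-level by contract). The per-epoch
#' training loss is recorded in the model's `log`.
#'
#' @param spec A sequence [model_spec()].
#' @param windows Matrix of input windows, one per row (e.g., 200 columns
#'   for 10 s at 20 Hz).
#' @param y Targets as in [train_feature_model()].
#' @return A `trained_model` with a `log` data.frame (epoch, loss).
#' @export
train_sequence_model <- function(spec, windows, y) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$sequence) {
    stop("train_sequence_model: '", spec$family, "' is a feature-based ",
         "family", call. = FALSE)
  }
  windows <- as.matrix(windows)
  if (nrow(windows) != length(y)) {
    stop("train_sequence_model: windows and y are not aligned",
         call. = FALSE)
  }
  if (spec$task == "regression" && min(y) < 0) y <- y + 50
  n_out <- if (spec$task == "classification") spec$k else 1L
  fit <- nn_train(spec$family, windows, y, spec$task, n_out,
                  lr = spec$learning_rate, epochs = spec$epochs,
                  batch_size = spec$batch_size, seed = spec$seed,
                  arch = spec$arch)
  structure(list(spec = spec, fit = fit, feature_names = NULL,
                 input_len = ncol(windows), log = fit$log),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s %s (%s)\n", x$spec$family, x$spec$task,
              if (x$spec$sequence) "sequence-based" else "feature-based"))
  invisible(x)
}

#' Predict from a trained model
#'
#' Classification returns integer class indices `0..k-1`. Regression
#' predictions are clipped to the valid unit range `[0, 100]` and reported
#' on the centered scale `[-50, +50]` (raw output 120 reports +50; raw -30
#' reports -50; raw 50 reports 0). The postprocessing is idempotent.
#'
#' @param object A `trained_model`.
#' @param newdata Feature matrix or window matrix matching the training
#'   input width.
#' @param ... Unused.
#' @return Numeric vector of class indices or centered factor predictions.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$input_len) {
    stop("predict: input has ", ncol(newdata), " columns but the model ",
         "was trained on ", object$input_len, call. = FALSE)
  }
  spec <- object$spec
  raw <- if (spec$sequence) {
    out <- nn_predict_raw(object$fit, newdata)
    if (spec$task == "classification") {
      max.col(out, ties.method = "first") - 1L
    } else {
      as.numeric(out)
    }
  } else {
    switch(spec$family,
      extra_trees = ,
      random_forest = {
        pr <- stats::predict(object$fit,
                             data = data.frame(newdata),
                             num.threads = 1L)$predictions
        if (spec$task == "classification") {
          as.integer(as.character(pr))
        } else {
          as.numeric(pr)
        }
      },
      knn = {
        f <- object$fit
        Xs <- sweep(sweep(f$X, 2L, f$center), 2L, f$scale, `/`)
        Ns <- sweep(sweep(newdata, 2L, f$center), 2L, f$scale, `/`)
        if (spec$task == "classification") {
          as.integer(as.character(
            class::knn(Xs, Ns, factor(f$y, levels = 0:(spec$k - 1L)),
                       k = f$k_neighbors)
          ))
        } else {
          stop("predict: knn regression is not a supported family",
               call. = FALSE)
        }
      },
      gradient_boosting = ,
      xgboost = {
        pr <- stats::predict(object$fit, xgboost::xgb.DMatrix(newdata))
        if (spec$task == "classification") as.integer(pr) else pr
      },
      svm = as.integer(as.character(stats::predict(object$fit, newdata))),
      logistic = as.integer(as.character(
        stats::predict(object$fit, data.frame(newdata))
      )),
      stop("predict: unknown family '", spec$family, "'", call. = FALSE)
    )
  }
  if (spec$task == "regression") {
    pmin(pmax(raw, 0), 100) - 50
  } else {
    raw
  }
}

#' Serialize a trained model's run artifacts
#'
#' Writes the model spec as JSON and, for sequence models, the training
#' log as CSV (epoch, loss) into a run directory. Fitted state itself is
#' kept in memory; the spec + seed + data reproduce it exactly.
#'
#' @param model A `trained_model`.
#' @param dir Output directory.
#' @param tag File-name tag (defaults to the family).
#' @return Invisibly, `dir`.
#' @export
write_model_artifacts <- function(model, dir, tag = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(tag)) tag <- model$spec$family
  spec <- model$spec
  spec$arch <- NULL
  jsonlite::write_json(unclass(spec),
                       file.path(dir, paste0(tag, "_spec.json")),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$log) && nrow(model$log) > 0) {
    data.table::fwrite(model$log,
                       file.path(dir, paste0(tag, "_training_log.csv")))
  }
  invisible(dir)
}
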