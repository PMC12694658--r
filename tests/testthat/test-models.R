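test_that("model specs enforce the family/task tables", {
  expect_s3_class(model_spec("extra_trees", "classification", k = 3),
                  "model_spec")
  expect_s3_class(model_spec("xgboost", "regression"), "model_spec")
  # classification-only and regression-only families
  expect_error(model_spec("svm", "regression"), "not available")
  expect_error(model_spec("logistic", "regression"), "not available")
  expect_error(model_spec("knn", "regression"), "not available")
  expect_error(model_spec("xgboost", "classification"), "not available")
  expect_error(model_spec("nonsense", "classification"), "not available")
  expect_error(model_spec("extra_trees", "classification", k = 1), "k must")
  # sequence batch-size defaults: 32 for classification, 128 for regression
  expect_equal(model_spec("gru", "classification")$batch_size, 32L)
  expect_equal(model_spec("gru", "regression")$batch_size, 128L)
  expect_equal(model_spec("tcn", "regression")$epochs, 75L)
  expect_error(
    train_feature_model(model_spec("lightgbm", "classification"),
                        matrix(rnorm(40), 10), rep(0:1, 5)),
    "unavailable"
  )
})

make_separable <- function(n = 120, seed = 41) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4)
  X[, 1] <- X[, 1] + 6 * y
  list(X = X, y = y)
}

test_that("feature classifiers: separable sanity, chance level, determinism", {
  d <- make_separable()
  for (fam in c("extra_trees", "random_forest", "knn", "gradient_boosting",
                "svm", "logistic")) {
    spec <- model_spec(fam, "classification", k = 2)
    m <- train_feature_model(spec, d$X, d$y)
    expect_equal(balanced_accuracy(d$y, predict(m, d$X), 2), 1.0,
                 label = paste(fam, "separable training BA"))
  }

  # pure-noise targets: held-out BA stays at chance across seeds
  bas <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(240 * 5), 240)
    y <- rep(0:1, 120)
    m <- train_feature_model(model_spec("extra_trees", "classification",
                                        k = 2, seed = s),
                             X[1:160, ], y[1:160])
    balanced_accuracy(y[161:240], predict(m, X[161:240, ]), 2)
  }, numeric(1))
  expect_gte(mean(bas), 0.4)
  expect_lte(mean(bas), 0.6)

  # seed-fixed determinism
  m1 <- train_feature_model(model_spec("extra_trees", "classification",
                                       k = 2, seed = 9), d$X, d$y)
  m2 <- train_feature_model(model_spec("extra_trees", "classification",
                                       k = 2, seed = 9), d$X, d$y)
  expect_identical(predict(m1, d$X), predict(m2, d$X))
})

test_that("feature regressors fit a noiseless linear target", {
  set.seed(42)
  X <- matrix(runif(200 * 3, 0, 1), 200)
  y <- 100 * X[, 1]  # unit-scale target
  for (fam in c("extra_trees", "random_forest", "gradient_boosting",
                "xgboost")) {
    m <- train_feature_model(model_spec(fam, "regression"), X, y)
    pred <- predict(m, X)  # centered scale
    expect_gt(regression_metrics(y - 50, pred)$r2, 0.9,
              label = paste(fam, "training fit"))
  }
})

test_that("regression predictions are clipped to [0,100] then centered", {
  # constant targets at the scale edges pin the (tree) prediction there
  set.seed(43)
  X <- matrix(rnorm(120), 40)
  m_hi <- train_feature_model(model_spec("xgboost", "regression"),
                              X, rep(100, 40))
  expect_true(all(abs(predict(m_hi, X) - 50) < 1e-6))
  m_lo <- train_feature_model(model_spec("xgboost", "regression"),
                              X, rep(0, 40))
  expect_true(all(abs(predict(m_lo, X) + 50) < 1e-6))
  m_mid <- train_feature_model(model_spec("xgboost", "regression"),
                               X, rep(50, 40))
  expect_true(all(abs(predict(m_mid, X)) < 1e-6))
  # centered targets are accepted and shifted internally
  m_c <- train_feature_model(model_spec("xgboost", "regression"),
                             X, rep(-50, 40))
  expect_true(all(abs(predict(m_c, X) + 50) < 1e-6))
})

test_that("sequence classifier learns a mean-coded class", {
  set.seed(44)
  n <- 500L; len <- 200L
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * len, sd = 0.5), n, len) + (2 * y - 1)
  tr <- 1:400; te <- 401:500
  spec <- model_spec("cnn1d", "classification", k = 2, epochs = 10L,
                     seed = 3)
  m <- train_sequence_model(spec, X[tr, ], y[tr])
  ba <- balanced_accuracy(y[te], predict(m, X[te, ]), 2)
  expect_gte(ba, 0.9)
  # training log covers every epoch
  expect_equal(m$log$epoch, 1:10)
})

test_that("sequence training is seeded-deterministic; epochs=0 is chance-level", {
  set.seed(45)
  X <- matrix(rnorm(60 * 40), 60)
  y <- rep(0:2, 20)
  spec <- model_spec("gru", "classification", k = 3, epochs = 2L, seed = 5,
                     arch = list(hidden = 8L))
  m1 <- train_sequence_model(spec, X, y)
  m2 <- train_sequence_model(spec, X, y)
  expect_identical(m1$log, m2$log)
  expect_identical(predict(m1, X), predict(m2, X))

  m0 <- train_sequence_model(
    model_spec("lstm", "classification", k = 3, epochs = 0L,
               arch = list(hidden = 4L)), X, y
  )
  p0 <- predict(m0, X)
  expect_true(all(p0 %in% 0:2))
  expect_equal(nrow(m0$log), 0L)
})

test_that("training loss is non-increasing on a noiseless learnable task", {
  set.seed(46)
  n <- 200L; len <- 64L
  X <- matrix(rnorm(n * len), n, len)
  y <- as.integer(rowMeans(X) > 0)
  spec <- model_spec("tcn", "classification", k = 2, epochs = 8L, seed = 6,
                     arch = list(kernel = 3L, dilations = c(1L, 2L, 4L),
                                 channels = 8L))
  m <- train_sequence_model(spec, X, y)
  loss <- m$log$loss
  expect_true(all(diff(loss) <= 0.05 * loss[-length(loss)]))
  expect_lt(tail(loss, 1), loss[1])
})

test_that("prediction validates input width", {
  d <- make_separable()
  m <- train_feature_model(model_spec("extra_trees", "classification",
                                      k = 2), d$X, d$y)
  expect_error(predict(m, d$X[, 1:2]), "columns")
  set.seed(47)
  ms <- train_sequence_model(
    model_spec("cnn1d", "classification", k = 2, epochs = 1L),
    matrix(rnorm(40 * 200), 40), rep(0:1, 20)
  )
  expect_error(predict(ms, matrix(rnorm(40 * 100), 40)), "columns")
})
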