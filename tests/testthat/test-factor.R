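# brute-force oracle for the rank-percentile factor: z-normalize with the
# population sd, then count values <= the terminal mean, one by one
naive_factor <- function(context, terminal) {
  mu <- mean(context)
  sdev <- sqrt(mean((context - mu)^2))
  z <- (context - mu) / sdev
  current <- (mean(terminal) - mu) / sdev
  count <- 0L
  for (v in z) if (v <= current) count <- count + 1L
  100 * count / length(z) - 50
}

test_that("segment counts match brute-force enumeration of end indices", {
  proc <- small_processed()[[1]]
  fs <- proc$fs
  n <- length(proc$time)

  count_for <- function(stride, context_len = 100) {
    len_ctx <- context_len * fs
    length(segment_stream(proc, segmentation_params(context_len = context_len,
                                                    stride = stride)))
  }
  brute <- function(stride, context_len = 100) {
    len_ctx <- context_len * fs
    sum(seq_len(n) >= len_ctx & (seq_len(n) - len_ctx) %% stride == 0)
  }
  for (stride in c(10L, 200L, 2000L)) {
    expect_equal(count_for(stride), brute(stride))
  }
  # full-protocol arithmetic: 1500 s at 20 Hz, non-overlapping 100 s
  # contexts end at samples 2000, 4000, ..., 30000
  expect_equal(length(seq.int(2000, 30000, by = 2000)), 15L)
  # dense sliding, stride 10 samples: (30000 - 2000) / 10 + 1
  expect_equal((30000 - 2000) / 10 + 1, 2801)

  # context equal to the recording: exactly one segment
  p <- segmentation_params(context_len = n / fs, stride = 10)
  expect_length(segment_stream(proc, p), 1L)

  # too-short recording: empty result with a warning
  short <- proc
  short$time <- proc$time[1:100]
  short$eda_phasic <- proc$eda_phasic[1:100]
  short$lidar_clean <- proc$lidar_clean[1:100]
  expect_warning(res <- segment_stream(short, segmentation_params()),
                 "shorter")
  expect_length(res, 0L)
})

test_that("segment geometry: terminal and input windows are context tails", {
  proc <- small_processed()[[1]]
  p <- segmentation_params(stride = 500)
  segs <- segment_stream(proc, p)
  s <- segs[[3]]
  fs <- proc$fs
  expect_length(s$context, 100 * fs)
  expect_length(s$terminal, 10 * fs)
  expect_identical(s$terminal, tail(s$context, 10 * fs))
  expect_identical(s$lidar_input,
                   proc$lidar_clean[(s$end_index - 10 * fs + 1):s$end_index])
  expect_equal(s$end_time, proc$time[s$end_index])
})

test_that("rank-percentile factor: forced cases and the counting oracle", {
  # strictly increasing ramp: the terminal mean sits at the centre of the
  # terminal stretch, so the percentile is 100 * (1 - terminal/2 / N);
  # with the terminal being the single last sample it is exactly +50
  ramp <- seq_len(1000) / 10
  expect_equal(rank_percentile_factor(ramp, tail(ramp, 1)), 50)
  fac_ramp <- rank_percentile_factor(ramp, tail(ramp, 100))
  expect_identical(fac_ramp, naive_factor(ramp, tail(ramp, 100)))
  expect_equal(fac_ramp, 45)  # strongly positive

  # symmetric context with the current value at the median: ~0
  sym <- c(seq(-1, 1, length.out = 999))
  fac0 <- rank_percentile_factor(sym, rep(0, 10))
  expect_lt(abs(fac0), 1)

  # oracle equivalence on random instances, exact
  set.seed(91)
  for (i in 1:25) {
    ctx <- rnorm(2000, sd = runif(1, 0.5, 3))
    ter <- tail(ctx, sample(50:400, 1))
    expect_identical(rank_percentile_factor(ctx, ter),
                     naive_factor(ctx, ter))
  }

  expect_error(rank_percentile_factor(rep(1, 100), rep(1, 10)),
               "degenerate")
})

test_that("factor is monotone in the terminal mean and affine-invariant", {
  set.seed(92)
  ctx <- rnorm(1500)
  currents <- seq(-2, 2, length.out = 21)
  vals <- vapply(currents, function(cv) {
    # fake a terminal whose mean is cv by passing a constant tail
    rank_percentile_factor(ctx, rep(cv * sqrt(mean((ctx - mean(ctx))^2)) +
                                      mean(ctx), 5))
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))

  # rank statistic: invariant under positive affine rescaling
  for (i in 1:10) {
    ctx2 <- rnorm(800)
    ter2 <- tail(ctx2, 80)
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 5)
    expect_equal(rank_percentile_factor(a * ctx2 + b, a * ter2 + b),
                 rank_percentile_factor(ctx2, ter2), tolerance = 1e-9)
  }
})

test_that("midrank tie handling halves the weight of ties", {
  ctx <- c(rep(0, 50), rep(1, 50))
  # terminal mean 0: le-rule counts all 50 zeros -> 0%+... percentile 50
  expect_equal(rank_percentile_factor(ctx, rep(0, 10), ties = "le"), 0)
  expect_equal(rank_percentile_factor(ctx, rep(0, 10), ties = "midrank"),
               -25)
})

test_that("discretization uses equal-width bins over [-50, 50]", {
  expect_equal(discretize_factor(-50, 2), 0L)
  expect_equal(discretize_factor(50, 2), 1L)
  expect_equal(discretize_factor(0, 3), 1L)
  expect_equal(discretize_factor(c(-50, -16.6, 16.7, 50), 3),
               c(0L, 1L, 2L, 2L))
  # uniform grid: class counts differ by at most 1, for every k
  grid <- seq(-50, 50, length.out = 2001)
  for (k in 2:10) {
    counts <- tabulate(discretize_factor(grid, k) + 1L, nbins = k)
    expect_lte(diff(range(counts)), 1)
    expect_equal(sum(counts), length(grid))
  }
  expect_error(discretize_factor(60, 3), "outside")
  expect_error(discretize_factor(0, 1), "between 2 and 10")
})

test_that("imbalance ratio is max count over min count", {
  expect_equal(imbalance_ratio(c(10, 10, 10)), 1)
  expect_equal(imbalance_ratio(c(25, 10)), 2.5)
  set.seed(93)
  counts <- tabulate(sample.int(4, 500, replace = TRUE,
                                prob = c(0.4, 0.3, 0.2, 0.1)), 4)
  expect_equal(imbalance_ratio(counts), max(counts) / min(counts))
  expect_error(imbalance_ratio(c(5, 0)), "empty")
})

test_that("labeled dataset: ranges, determinism, class bookkeeping", {
  procs <- small_processed()
  ds <- build_labeled_dataset(procs, segmentation_params(stride = 200),
                              k = 4)
  expect_true(all(ds$segments$factor >= -50 & ds$segments$factor <= 50))
  expect_equal(ds$segments$factor_unit, ds$segments$factor + 50)
  expect_equal(sum(ds$class_counts), nrow(ds$segments))
  expect_equal(nrow(ds$windows), nrow(ds$segments))
  expect_equal(ncol(ds$windows), 10 * procs[[1]]$fs)
  # every segment gets exactly one class in range
  expect_true(all(ds$segments$class_index %in% 0:3))
  # rebuilt from the same inputs: identical labels
  ds2 <- build_labeled_dataset(procs, segmentation_params(stride = 200),
                               k = 4)
  expect_identical(ds$segments, ds2$segments)
})

test_that("under ideal coupling the LiDAR channel carries the factor", {
  procs <- lapply(generate_dataset(ideal_coupling_sim()),
                  clean_recording, params = matched_band_params())
  p <- segmentation_params(stride = 40)
  ds <- build_labeled_dataset(procs, p, k = 3)
  lidar_factor <- unlist(lapply(procs, function(pr) {
    pr2 <- pr
    pr2$eda_phasic <- pr$lidar_clean
    vapply(segment_stream(pr2, p), function(s) {
      rank_percentile_factor(s$context, s$terminal)
    }, numeric(1))
  }))
  expect_gte(cor(lidar_factor, ds$segments$factor), 0.9)
})
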