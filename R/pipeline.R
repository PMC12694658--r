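#' Full run configuration
#'
#' Bundles every stage's parameters so a run is reproducible from this
#' object alone. The global `seed` overrides the simulation seed and
#' derives the split seed, so two runs with the same config are
#' byte-identical.
#'
#' @param simulation A [sim_config()].
#' @param preprocessing A [preprocess_params()].
#' @param segmentation A [segmentation_params()].
#' @param k Vector of class counts for classification (each in 2..10).
#' @param model_specs List of [model_spec()] objects. Classification specs
#'   are re-instantiated per requested `k`.
#' @param strategies Subset of `c("random", "loso")`.
#' @param out_dir Output directory for run artifacts, or `NULL` to keep
#'   everything in memory.
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = sim_config(),
                       preprocessing = preprocess_params(),
                       segmentation = segmentation_params(),
                       k = 3L,
                       model_specs = list(
                         model_spec("extra_trees", "classification"),
                         model_spec("extra_trees", "regression")
                       ),
                       strategies = "random",
                       out_dir = NULL,
                       seed = 1L) {
  k <- as.integer(k)
  if (any(k < 2L | k > 10L)) {
    stop("run_config: every k must be in 2..10", call. = FALSE)
  }
  if (!all(strategies %in% c("random", "loso"))) {
    stop("run_config: strategies must be 'random' and/or 'loso'",
         call. = FALSE)
  }
  if (inherits(model_specs, "model_spec")) model_specs <- list(model_specs)
  cfg <- list(simulation = simulation, preprocessing = preprocessing,
              segmentation = segmentation, k = k,
              model_specs = model_specs, strategies = strategies,
              out_dir = out_dir, seed = as.integer(seed))
  cfg$simulation$seed <- cfg$seed
  validate_sim_config(cfg$simulation)
  class(cfg) <- "run_config"
  cfg
}

stage_log <- function(stage, t0) {
  message(sprintf("[%s] done in %.1f s", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
}

#' Simulate a dataset and write per-subject CSVs
#'
#' @param config A [run_config()] or [sim_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the list of recordings.
#' @export
simulate_to_dir <- function(config, dir) {
  sim <- if (inherits(config, "run_config")) config$simulation else config
  recs <- generate_dataset(sim)
  for (rec in recs) write_recording(rec, dir, config = sim)
  invisible(recs)
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> label -> features -> train -> evaluate, with
#' every intermediate persisted when `out_dir` is set and the config and
#' seeds echoed into the report. Stage failures abort with a stage-tagged
#' message; per-stage wall time goes to standard error.
#'
#' @param config A [run_config()].
#' @return A `pipeline_result`: `reports` (one `evaluation_report` per
#'   strategy x k), `dataset`s per k, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  persist <- !is.null(out)
  if (persist && !dir.exists(out)) dir.create(out, recursive = TRUE)

  t0 <- Sys.time()
  recs <- tryCatch(generate_dataset(config$simulation),
                   error = function(e) stop("simulate: ",
                                            conditionMessage(e),
                                            call. = FALSE))
  if (persist) {
    for (rec in recs) {
      write_recording(rec, file.path(out, "recordings"),
                      config = config$simulation)
    }
  }
  stage_log("simulate", t0)

  t0 <- Sys.time()
  procs <- tryCatch(lapply(recs, clean_recording,
                           params = config$preprocessing),
                    error = function(e) stop("preprocess: ",
                                             conditionMessage(e),
                                             call. = FALSE))
  if (persist) {
    for (p in procs) write_processed(p, file.path(out, "processed"))
  }
  stage_log("preprocess", t0)

  if ("loso" %in% config$strategies && config$simulation$n_subjects < 2L) {
    stop("evaluate: the loso strategy needs at least 2 subjects",
         call. = FALSE)
  }

  reports <- list()
  datasets <- list()
  for (k in config$k) {
    t0 <- Sys.time()
    dataset <- tryCatch(
      build_labeled_dataset(procs, config$segmentation, k = k),
      error = function(e) stop("label: ", conditionMessage(e),
                               call. = FALSE)
    )
    datasets[[as.character(k)]] <- dataset
    if (persist) {
      write_labeled_dataset(dataset, file.path(out, sprintf("labels_k%d", k)))
    }
    stage_log(sprintf("label k=%d", k), t0)

    specs_k <- lapply(config$model_specs, function(s) {
      if (s$task == "classification") {
        model_spec(s$family, "classification", k = k,
                   learning_rate = s$learning_rate, epochs = s$epochs,
                   batch_size = s$batch_size, seed = s$seed, arch = s$arch)
      } else {
        s
      }
    })
    needs_features <- any(!vapply(specs_k, `[[`, logical(1), "sequence"))
    fm <- NULL
    if (needs_features) {
      t0 <- Sys.time()
      fm <- tryCatch(build_feature_matrix(dataset,
                                          fs = config$simulation$fs),
                     error = function(e) stop("features: ",
                                              conditionMessage(e),
                                              call. = FALSE))
      if (persist) {
        write_feature_matrix(fm,
                             file.path(out, sprintf("features_k%d.csv", k)),
                             k = k)
      }
      stage_log(sprintf("features k=%d", k), t0)
    }

    for (strategy in config$strategies) {
      t0 <- Sys.time()
      plan <- if (strategy == "random") {
        split_random(nrow(dataset$segments), 0.75,
                     seed = config$seed + 1000L)
      } else {
        split_loso(dataset$segments$subject_id)
      }
      rep_ <- tryCatch(evaluate_run(specs_k, dataset, plan, fm = fm),
                       error = function(e) stop("evaluate: ",
                                                conditionMessage(e),
                                                call. = FALSE))
      reports[[sprintf("%s_k%d", strategy, k)]] <- rep_
      if (persist) {
        data.table::fwrite(
          rep_$predictions,
          file.path(out, sprintf("predictions_%s_k%d.csv", strategy, k))
        )
        for (tag in names(rep_$training_logs)) {
          data.table::fwrite(
            rep_$training_logs[[tag]],
            file.path(out, sprintf("training_log_%s_k%d_%s.csv",
                                   strategy, k, tag))
          )
        }
      }
      stage_log(sprintf("evaluate %s k=%d", strategy, k), t0)
    }
  }

  result <- structure(
    list(reports = reports, datasets = datasets, config = config),
    class = "pipeline_result"
  )
  if (persist) {
    jsonlite::write_json(report_as_list(result),
                         file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

report_as_list <- function(result) {
  cfg <- result$config
  list(
    seed = cfg$seed,
    k = cfg$k,
    strategies = cfg$strategies,
    simulation = cfg$simulation[setdiff(names(cfg$simulation),
                                        "stimulus_weights")],
    preprocessing = unclass(cfg$preprocessing),
    segmentation = unclass(cfg$segmentation),
    results = lapply(result$reports, function(r) {
      list(strategy = r$strategy, metrics = r$metrics,
           agreement = r$agreement)
    })
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d report(s), seed %d\n",
              length(x$reports), x$config$seed))
  for (nm in names(x$reports)) {
    cat("--", nm, "--\n")
    print(x$reports[[nm]])
  }
  invisible(x)
}

#' Normalized-improvement summary table
#'
#' Rows are models, columns are class counts; the cells are the NI of each
#' classification model under the given strategy, mirroring the way
#' feasibility results are usually summarized as NI versus number of
#' classes.
#'
#' @param result A `pipeline_result` from [run_pipeline()], or a run
#'   directory containing `report.json`.
#' @param strategy `"random"` or `"loso"`.
#' @return A data.frame: one row per model family, one column per k.
#' @export
report_ni_table <- function(result, strategy = "random") {
  metrics <- if (inherits(result, "pipeline_result")) {
    do.call(rbind, lapply(result$reports, `[[`, "metrics"))
  } else {
    path <- file.path(result, "report.json")
    if (!file.exists(path)) {
      stop("report_ni_table: no report.json in '", result,
           "' (incomplete run?)", call. = FALSE)
    }
    rep_ <- jsonlite::read_json(path, simplifyVector = TRUE)
    do.call(rbind, lapply(rep_$results, `[[`, "metrics"))
  }
  cls <- metrics[metrics$task == "classification" &
                   metrics$strategy == strategy, , drop = FALSE]
  if (nrow(cls) == 0L) {
    stop("report_ni_table: no classification results for strategy '",
         strategy, "'", call. = FALSE)
  }
  ks <- sort(unique(cls$k))
  models <- unique(cls$model)
  tab <- data.frame(model = models, stringsAsFactors = FALSE)
  for (k in ks) {
    tab[[sprintf("k%d", k)]] <- vapply(models, function(m) {
      v <- cls$ni[cls$model == m & cls$k == k]
      if (length(v) == 1L) v else NA_real_
    }, numeric(1))
  }
  tab
}
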