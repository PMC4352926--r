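#' Default pipeline configuration
#'
#' Nested configuration for the end-to-end pipeline, optionally read from a
#' YAML file whose keys mirror the section fields exactly; unknown keys are
#' rejected. Sections: `corpus` (generator), `hog` (descriptor geometry),
#' `ann` (network and training), `bagging` (ensemble), `svm` (kernel),
#' `holdout` (evaluation protocol), plus a global `seed`.
#'
#' @param path Optional YAML file path.
#' @param seed Global seed fanned out to per-stage seeds.
#' @return A named list of configuration sections.
#' @export
pipeline_config <- function(path = NULL, seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    corpus = list(scale = 0.047, n_normal = 3L, unique_only = TRUE,
                  deletion_min = 3L, deletion_max = 24L),
    hog = list(n_bins = 9L, angular_range = 180, n_blocks = 9L,
               block_overlap = 0.5, norm = "L2", epsilon = 1e-5),
    ann = list(hidden = c(80L, 80L), max_epochs = 500L, patience = 6L),
    bagging = list(n_base = 50L, n_selected = 12L, threshold = 0.9475),
    svm = list(kernel = "polynomial", degree = 3L, cost = 1),
    holdout = list(n_rounds = 20L, train_frac = 0.8)
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (section in names(user)) {
      if (!section %in% names(cfg)) {
        abort(paste0("unknown configuration section: ", section))
      }
      if (section == "seed") { cfg$seed <- as.integer(user$seed); next }
      for (key in names(user[[section]])) {
        if (!key %in% names(cfg[[section]])) {
          abort(paste0("unknown configuration key: ", section, ".", key))
        }
        cfg[[section]][[key]] <- user[[section]][[key]]
      }
    }
  }
  cfg
}

config_corpus <- function(cfg) {
  corpus_config(scale = cfg$corpus$scale, n_normal = cfg$corpus$n_normal,
                unique_only = cfg$corpus$unique_only,
                deletion_length_range = c(cfg$corpus$deletion_min,
                                          cfg$corpus$deletion_max),
                seed = derive_seed(cfg$seed, 11L))
}

config_hog <- function(cfg) {
  hog_config(n_bins = cfg$hog$n_bins, angular_range = cfg$hog$angular_range,
             n_blocks = cfg$hog$n_blocks,
             block_overlap = cfg$hog$block_overlap, norm = cfg$hog$norm,
             epsilon = cfg$hog$epsilon)
}

config_kernel <- function(cfg) {
  kernel_spec(cfg$svm$kernel, degree = cfg$svm$degree, cost = cfg$svm$cost)
}

#' Simulate a corpus to disk
#'
#' Pipeline stage: generate the seeded synthetic corpus and write FASTA,
#' label and manifest files.
#'
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return The written paths, invisibly.
#' @export
cmd_simulate <- function(out_dir, config = pipeline_config()) {
  corpus <- generate_corpus(config_corpus(config))
  write_corpus(corpus, out_dir)
}

#' Extract descriptors to a table on disk
#'
#' Pipeline stage: read sequences + labels, compute HOG or LBP descriptors
#' and write them as a tab-separated table. Records too short for the block
#' layout are skipped with a message; the run continues and the skip count
#' is reported.
#'
#' @param fasta,labels Input paths (FASTA and `id`/`class` TSV).
#' @param out Output TSV path.
#' @param descriptor `"hog"` or `"lbp"`.
#' @param config A [pipeline_config()].
#' @return The descriptor tibble, invisibly.
#' @export
cmd_features <- function(fasta, labels, out, descriptor = c("hog", "lbp"),
                         config = pipeline_config()) {
  descriptor <- match.arg(descriptor)
  data <- read_labelled_fasta(fasta, labels)
  ok <- rep(TRUE, nrow(data))
  feats <- NULL
  for (i in seq_len(nrow(data))) {
    row <- data[i, , drop = FALSE]
    res <- tryCatch(
      if (descriptor == "hog") hog_features(row, config_hog(config))
      else lbp_features(row),
      error = function(e) {
        message("skipping record '", row$id, "': ", conditionMessage(e))
        NULL
      }
    )
    if (is.null(res)) ok[i] <- FALSE else feats <- dplyr::bind_rows(feats, res)
  }
  if (sum(!ok) > 0L) {
    message(sum(!ok), " record(s) skipped, ", sum(ok), " written")
  }
  if (is.null(feats)) abort("no records could be encoded")
  readr::write_tsv(feats, out)
  invisible(feats)
}

#' Train a classifier combination on a descriptor table
#'
#' Pipeline stage: fit one of the four model kinds (or run the hidden-width
#' sweep) on a descriptor table and write a self-describing model archive
#' plus a report.
#'
#' @param features Path to a descriptor TSV from [cmd_features()], or the
#'   tibble itself.
#' @param out_dir Output directory for `model.rds` and `report.yaml` (sweep
#'   mode writes `sweep.tsv` instead of a model).
#' @param mode `"single-ann"`, `"ann-ensemble"`, `"single-svm"`,
#'   `"svm-ensemble"` or `"sweep"`.
#' @param config A [pipeline_config()].
#' @return For sweep mode the sweep tibble; otherwise the
#'   [experiment_report()], invisibly.
#' @export
cmd_train <- function(features, out_dir,
                      mode = c("single-ann", "ann-ensemble", "single-svm",
                               "svm-ensemble", "sweep"),
                      config = pipeline_config()) {
  mode <- match.arg(mode)
  data <- if (is.character(features)) {
    readr::read_tsv(features, show_col_types = FALSE)
  } else features
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  descriptor <- if (any(grepl("^hog", names(data)))) "hog" else "lbp"
  seed <- derive_seed(config$seed, 31L)
  if (mode == "sweep") {
    sweep <- hidden_size_sweep(data, max_epochs = config$ann$max_epochs,
                               patience = config$ann$patience, seed = seed)
    readr::write_tsv(sweep, file.path(out_dir, "sweep.tsv"))
    return(invisible(sweep))
  }
  combo <- paste0(switch(mode,
                         "single-ann" = "single_ann",
                         "ann-ensemble" = "ensemble_ann",
                         "single-svm" = "single_svm",
                         "svm-ensemble" = "ensemble_svm"),
                  "_", descriptor)
  res <- run_experiment(data, combo = combo, config = config, seed = seed)
  saveRDS(list(mode = mode, descriptor = descriptor, model = res$model,
               config = config, seed = seed,
               train_ids = res$train_ids),
          file.path(out_dir, "model.rds"))
  report <- res$report
  yaml::write_yaml(
    list(combo = report$combo, accuracy = report$accuracy, mse = report$mse,
         n = report$n, evaluated_on = report$evaluated_on,
         seeds = as.list(report$seeds)),
    file.path(out_dir, "report.yaml"))
  readr::write_tsv(
    tibble::as_tibble(as.data.frame.table(unclass(report$confusion),
                                          responseName = "n")),
    file.path(out_dir, "confusion.tsv"))
  invisible(report)
}

#' Run one classifier-x-feature experiment in memory
#'
#' Fits the requested combination on a descriptor table and scores it on a
#' held-out portion the model never saw: the single network uses its
#' internal 70/15/15 split's test part; the other combinations hold out 20
#' percent (stratified) and fit on the remainder.
#'
#' @param data A descriptor tibble with a `class` column.
#' @param combo One of the eight tags of [combo_levels()] (the `_hog`/`_lbp`
#'   suffix is informative only; the data decide the descriptor).
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @return A list with `model`, `report` (an [experiment_report()]) and
#'   `train_ids`.
#' @export
run_experiment <- function(data, combo, config = pipeline_config(),
                           seed = 1L) {
  kind <- sub("_(hog|lbp)$", "", combo)
  ann_cfg <- config$ann
  if (kind == "single_ann") {
    fit <- fit_mlp(data, hidden = ann_cfg$hidden,
                   max_epochs = ann_cfg$max_epochs,
                   patience = ann_cfg$patience, seed = seed)
    te <- fit$splits == "test"
    test_data <- data[te, , drop = FALSE]
    out <- predict(fit, test_data, type = "raw")
    report <- experiment_report(combo, test_data$class, decode_outputs(out),
                                outputs = out, evaluated_on = "test",
                                seeds = seed, config = ann_cfg)
    return(list(model = fit, report = report,
                train_ids = data$id[fit$splits == "train"]))
  }
  parts <- split_dataset(data, fractions = c(train = 0.8, test = 0.2),
                         seed = derive_seed(seed, 1L))
  train <- parts$train
  test <- parts$test
  model <- switch(kind,
    ensemble_ann = fit_mlp_ensemble(
      train, n_base = config$bagging$n_base,
      n_selected = config$bagging$n_selected,
      threshold = config$bagging$threshold, hidden = ann_cfg$hidden,
      max_epochs = ann_cfg$max_epochs, patience = ann_cfg$patience,
      seed = derive_seed(seed, 2L)),
    single_svm = fit_ova_svm(train, kernel = config_kernel(config),
                             seed = derive_seed(seed, 2L)),
    ensemble_svm = fit_svm_bucket(
      train, kernel = config_kernel(config),
      n_models = config$bagging$n_base,
      train_frac = config$holdout$train_frac,
      seed = derive_seed(seed, 2L)),
    abort(paste0("unknown combo: ", combo))
  )
  pred <- predict(model, test)
  outputs <- if (kind == "ensemble_ann") {
    predict(model, test, type = "raw")
  } else {
    encode_targets(pred)
  }
  report <- experiment_report(combo, test$class, pred, outputs = outputs,
                              evaluated_on = "holdout", seeds = seed,
                              config = config[c("bagging", "svm")])
  list(model = model, report = report, train_ids = train$id)
}

#' Evaluate a model archive on a descriptor table
#'
#' Pipeline stage: score a trained archive against labelled descriptors,
#' producing per-sample predictions and summary metrics. When the archive
#' records its training ids, each row is flagged `seen` (was in the training
#' data) or `unseen`.
#'
#' @param model_path Path to a `model.rds` from [cmd_train()].
#' @param features Path to a descriptor TSV, or the tibble itself.
#' @param out_dir Optional directory for `predictions.tsv` and
#'   `metrics.yaml`.
#' @return A list with `predictions` (tibble) and `metrics` (tibble).
#' @export
cmd_evaluate <- function(model_path, features, out_dir = NULL) {
  archive <- readRDS(model_path)
  data <- if (is.character(features)) {
    readr::read_tsv(features, show_col_types = FALSE)
  } else features
  x <- feature_matrix(data)
  n_expected <- archive$model$arch$n_inputs %||%
    archive$model$n_features %||% archive$model$best$n_features
  if (!is.null(n_expected) && ncol(x) != n_expected) {
    abort(paste0("descriptor width ", ncol(x),
                 " incompatible with model (", n_expected, ")"))
  }
  pred <- predict(archive$model, data)
  predictions <- tibble::tibble(
    id = data$id,
    class = data$class,
    predicted = as.character(pred),
    correct = as.character(pred) == data$class
  )
  if (!is.null(archive$train_ids)) {
    predictions$exposure <- ifelse(predictions$id %in% archive$train_ids,
                                   "seen", "unseen")
  }
  cm <- confusion_matrix(predictions$class, predictions$predicted)
  metrics <- tibble::tibble(
    accuracy = accuracy(cm),
    mse = mse_metric(encode_targets(pred), encode_targets(data$class)),
    n = nrow(data)
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(predictions, file.path(out_dir, "predictions.tsv"))
    yaml::write_yaml(as.list(metrics), file.path(out_dir, "metrics.yaml"))
  }
  list(predictions = predictions, metrics = metrics, confusion = cm)
}

#' Summarise report files into the comparison grid
#'
#' Pipeline stage: collect `report.yaml` files written by [cmd_train()] and
#' assemble the classifier-x-feature summary grid.
#'
#' @param report_paths Character vector of `report.yaml` paths.
#' @param out Optional output TSV path.
#' @return The summary tibble.
#' @export
cmd_summarize <- function(report_paths, out = NULL) {
  rows <- purrr::map_dfr(report_paths, function(p) {
    r <- yaml::read_yaml(p)
    tibble::tibble(combo = r$combo, accuracy = r$accuracy, mse = r$mse,
                   n = r$n, evaluated_on = r$evaluated_on)
  })
  if (anyDuplicated(rows$combo)) abort("duplicate combo tags in reports")
  if (all(rows$combo %in% combo_levels())) {
    rows <- rows[order(match(rows$combo, combo_levels())), ]
  }
  if (!is.null(out)) readr::write_tsv(rows, out)
  rows
}
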