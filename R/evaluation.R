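#' Six-class confusion matrix
#'
#' Counts of (true class, predicted class) pairs on the canonical class
#' order: rows are true classes, columns predictions.
#'
#' @param truth,estimate Equal-length vectors of class names (character or
#'   factor on the six canonical levels).
#' @return A 6 x 6 integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    abort("truth and estimate must have equal length")
  }
  tr <- class_factor(truth)
  es <- class_factor(estimate)
  m <- unclass(table(tr, es))
  dimnames(m) <- list(true = CLASS_LEVELS, predicted = CLASS_LEVELS)
  structure(m, class = c("confusion_matrix", class(m)))
}

as_confusion_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  dimnames(m) <- list(true = CLASS_LEVELS[seq_len(nrow(m))],
                      predicted = CLASS_LEVELS[seq_len(ncol(m))])
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm A square count matrix (rows true, columns predicted).
#' @return Accuracy in percent: 100 x trace / total.
#' @export
#' @examples
#' accuracy(confusion_matrix(c("normal", "normal"), c("normal", "normal")))
accuracy <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    abort("cm must be a square count matrix")
  }
  total <- sum(cm)
  if (total == 0) abort("empty confusion matrix: no samples")
  100 * sum(diag(cm)) / total
}

#' Mean squared error between output and target vectors
#'
#' The single MSE definition shared by the network and SVM reports: the mean
#' over samples *and* over the six output units of the squared difference,
#' with SVM predictions one-hot coded before comparison. Zero exactly when
#' outputs equal targets.
#'
#' @param outputs,targets Numeric matrices of identical shape (n x 6).
#' @return A single number.
#' @export
mse_metric <- function(outputs, targets) {
  if (!is.matrix(outputs)) outputs <- as.matrix(outputs)
  if (!is.matrix(targets)) targets <- as.matrix(targets)
  if (!all(dim(outputs) == dim(targets))) {
    abort("outputs and targets must have identical dimensions")
  }
  mean((outputs - targets)^2)
}

#' Average the per-member metrics of an ensemble
#'
#' The arithmetic used for ensemble member tables: column totals and means
#' of the members' MSE and accuracy.
#'
#' @param members A tibble with numeric columns `mse` and `accuracy`.
#' @return A one-row tibble with `n`, `total_mse`, `total_accuracy`,
#'   `mean_mse`, `mean_accuracy`.
#' @export
member_average <- function(members) {
  stopifnot(all(c("mse", "accuracy") %in% names(members)))
  tibble::tibble(
    n = nrow(members),
    total_mse = sum(members$mse),
    total_accuracy = sum(members$accuracy),
    mean_mse = mean(members$mse),
    mean_accuracy = mean(members$accuracy)
  )
}

#' Bundle one classifier-x-feature experiment into a report
#'
#' @param combo Tag of the combination, e.g. `"single_ann_hog"`; one of the
#'   eight canonical tags in [combo_levels()].
#' @param truth,estimate Class labels of the evaluated samples.
#' @param outputs Optional n x 6 output matrix (defaults to one-hot coded
#'   `estimate`).
#' @param evaluated_on Which samples the metrics describe (e.g. `"test"`,
#'   `"holdout"`, `"all"`); reports always say which set was scored.
#' @param seeds Integer vector of seeds used by the experiment.
#' @param config A list snapshot of the configuration.
#' @return An `experiment_report` with accuracy (percent), MSE and the
#'   confusion matrix.
#' @export
experiment_report <- function(combo, truth, estimate, outputs = NULL,
                              evaluated_on = "test", seeds = integer(),
                              config = list()) {
  cm <- confusion_matrix(truth, estimate)
  if (is.null(outputs)) outputs <- encode_targets(estimate)
  structure(
    list(combo = combo,
         accuracy = accuracy(cm),
         mse = mse_metric(outputs, encode_targets(truth)),
         confusion = cm,
         n = length(truth),
         evaluated_on = evaluated_on,
         seeds = seeds,
         config = config),
    class = "experiment_report"
  )
}

#' Canonical order of the eight classifier-x-feature combinations
#'
#' Single and ensemble networks and SVMs, each on HOG and LBP features, in
#' the order used by the summary grid.
#'
#' @return A character vector of eight tags.
#' @export
combo_levels <- function() {
  c("single_ann_hog", "ensemble_ann_hog",
    "single_ann_lbp", "ensemble_ann_lbp",
    "single_svm_hog", "ensemble_svm_hog",
    "single_svm_lbp", "ensemble_svm_lbp")
}

#' Summary grid over experiment reports
#'
#' One row per report with accuracy and MSE, ordered canonically when the
#' combos are canonical tags; duplicate combo tags are an error.
#'
#' @param reports A list of [experiment_report()] objects.
#' @return A tibble with columns `combo`, `accuracy`, `mse`, `n`,
#'   `evaluated_on`.
#' @export
summarize_grid <- function(reports) {
  if (length(reports) == 0L) abort("summarize_grid needs at least one report")
  if (inherits(reports, "experiment_report")) reports <- list(reports)
  combos <- vapply(reports, `[[`, character(1), "combo")
  if (anyDuplicated(combos)) {
    abort(paste0("duplicate combo tags: ",
                 paste(unique(combos[duplicated(combos)]), collapse = ", ")))
  }
  out <- tibble::tibble(
    combo = combos,
    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
    mse = vapply(reports, `[[`, numeric(1), "mse"),
    n = vapply(reports, `[[`, numeric(1), "n"),
    evaluated_on = vapply(reports, `[[`, character(1), "evaluated_on")
  )
  if (all(combos %in% combo_levels())) {
    out <- out[order(match(out$combo, combo_levels())), ]
  }
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report:", x$combo, "\n")
  cat(sprintf("  accuracy: %.1f%%  MSE: %.4f  (n = %d, on %s)\n",
              x$accuracy, x$mse, x$n, x$evaluated_on))
  invisible(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  cat(sprintf("accuracy: %.1f%%\n", accuracy(x)))
  invisible(x)
}

#' @export
tidy.experiment_report <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(unclass(x$confusion),
                                        responseName = "n"))
}

#' @export
glance.experiment_report <- function(x, ...) {
  tibble::tibble(combo = x$combo, accuracy = x$accuracy, mse = x$mse,
                 n = x$n, evaluated_on = x$evaluated_on)
}
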