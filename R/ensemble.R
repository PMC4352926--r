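#' Plurality vote over member predictions
#'
#' The winning class is the one with the most votes; no majority is
#' required. Ties resolve to the lowest class index in the canonical order.
#'
#' @param votes Member predictions: a character/factor vector (one sample),
#'   or a members x samples matrix of class names.
#' @return A factor of winning classes (length 1 for a vector of votes).
#' @export
#' @examples
#' plurality_vote(c("normal", "normal", "EGFR_deletion"))
plurality_vote <- function(votes) {
  if (is.matrix(votes)) {
    idx <- apply(votes, 2L, function(v) vote_one(class_index(v)))
  } else {
    if (length(votes) == 0L) abort("plurality_vote needs at least one vote")
    idx <- vote_one(class_index(votes))
  }
  factor(CLASS_LEVELS[idx], levels = CLASS_LEVELS)
}

vote_one <- function(idx) {
  if (length(idx) == 0L) abort("plurality_vote needs at least one vote")
  counts <- tabulate(idx, nbins = length(CLASS_LEVELS))
  which.max(counts)  # first maximum = lowest class index
}

#' Bagged ensemble of six-class perceptrons
#'
#' Trains `n_base` networks on independent bootstrap resamples of the data.
#' Each member uses its entire bootstrap sample for training and its
#' out-of-bag rows for early stopping and for the selection accuracy.
#' Members with out-of-bag accuracy at or above `threshold` are retained;
#' the ensemble is then topped up (or trimmed) to exactly `n_selected`
#' members by out-of-bag accuracy rank. Prediction is by plurality vote.
#'
#' @param data A descriptor tibble with a `class` column (typically the
#'   training portion of a split).
#' @param n_base Number of base networks trained (default 50).
#' @param n_selected Number of members retained (default 12).
#' @param threshold Selection accuracy floor as a fraction (default 0.9475,
#'   i.e. approximately 95 percent and above).
#' @param hidden,max_epochs,patience Passed to the base-network trainer.
#' @param seed Integer seed; member seeds are derived from it.
#' @return An `mlp_ensemble` with the selected members and a `members`
#'   tibble of per-member out-of-bag metrics.
#' @export
fit_mlp_ensemble <- function(data, n_base = 50L, n_selected = 12L,
                             threshold = 0.9475, hidden = c(80L, 80L),
                             max_epochs = 500L, patience = 6L, seed = 1L) {
  if (n_selected > n_base) abort("n_selected must be <= n_base")
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  if (!"class" %in% names(data)) abort("data must contain a 'class' column")
  x <- feature_matrix(data)
  y <- class_factor(data$class)
  targets <- t(encode_targets(y))
  scaling <- fit_feature_scaling(x)
  x <- apply_feature_scaling(x, scaling)
  arch <- mlp_architecture(n_inputs = ncol(x), hidden = hidden)
  members <- vector("list", n_base)
  oob_acc <- oob_mse <- numeric(n_base)
  for (b in seq_len(n_base)) {
    member_seed <- derive_seed(seed, b)
    idx <- withr_seed(member_seed,
                      sample.int(nrow(x), nrow(x), replace = TRUE))
    oob <- setdiff(seq_len(nrow(x)), unique(idx))
    # degenerate draw with no out-of-bag rows: validate on the bag itself
    val <- if (length(oob) > 0L) oob else seq_len(nrow(x))
    res <- scg_train(arch,
                     t(x[idx, , drop = FALSE]), targets[, idx, drop = FALSE],
                     t(x[val, , drop = FALSE]), targets[, val, drop = FALSE],
                     max_epochs = max_epochs, patience = patience,
                     seed = derive_seed(member_seed, 1L))
    params <- unpack_params(res$theta, arch)
    out_val <- t(forward_pass(params, t(x[val, , drop = FALSE]))[[length(params) + 1L]])
    pred_val <- decode_outputs(out_val)
    members[[b]] <- params
    oob_acc[b] <- mean(pred_val == y[val])
    oob_mse[b] <- mse_metric(out_val, encode_targets(y[val]))
  }
  rank_order <- order(-oob_acc, oob_mse, seq_len(n_base))
  qualified <- which(oob_acc >= threshold)
  selected <- if (length(qualified) >= n_selected) {
    rank_order[rank_order %in% qualified][seq_len(n_selected)]
  } else {
    rank_order[seq_len(n_selected)]
  }
  structure(
    list(arch = arch,
         scaling = scaling,
         members = members[selected],
         member_metrics = tibble::tibble(
           member = seq_len(n_base),
           oob_accuracy = 100 * oob_acc,
           oob_mse = oob_mse,
           selected = seq_len(n_base) %in% selected
         ),
         n_selected = n_selected,
         threshold = threshold,
         seed = seed,
         config = list(n_base = n_base, hidden = hidden,
                       max_epochs = max_epochs, patience = patience)),
    class = "mlp_ensemble"
  )
}

#' @export
predict.mlp_ensemble <- function(object, newdata,
                                 type = c("class", "votes", "raw"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  x <- apply_feature_scaling(x, object$scaling)
  preds <- vapply(object$members, function(p) {
    as.character(decode_outputs(mlp_forward(p, x)))
  }, character(nrow(x)))
  votes <- t(matrix(preds, nrow = nrow(x)))  # members x samples
  if (type == "votes") return(votes)
  if (type == "raw") {
    # mean one-hot vote share per class, used for the ensemble MSE
    counts <- apply(votes, 2L, function(v)
      tabulate(class_index(v), nbins = length(CLASS_LEVELS)))
    out <- t(counts) / nrow(votes)
    colnames(out) <- CLASS_LEVELS
    return(out)
  }
  plurality_vote(votes)
}

#' @export
print.mlp_ensemble <- function(x, ...) {
  cat(sprintf(
    "Bagged perceptron ensemble: %d of %d members (threshold %.2f%%)\n",
    length(x$members), x$config$n_base, 100 * x$threshold))
  sel <- x$member_metrics[x$member_metrics$selected, ]
  cat(sprintf("  member out-of-bag accuracy: %.1f%% to %.1f%%\n",
              min(sel$oob_accuracy), max(sel$oob_accuracy)))
  invisible(x)
}

#' @export
tidy.mlp_ensemble <- function(x, ...) x$member_metrics

#' @export
glance.mlp_ensemble <- function(x, ...) {
  sel <- x$member_metrics[x$member_metrics$selected, ]
  tibble::tibble(
    n_base = x$config$n_base,
    n_selected = length(x$members),
    mean_member_accuracy = mean(sel$oob_accuracy),
    mean_member_mse = mean(sel$oob_mse)
  )
}
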