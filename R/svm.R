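#' Kernel specification for the one-against-all SVM
#'
#' The five supported kernels: `linear`; `quadratic` (polynomial of fixed
#' degree 2); `polynomial` (degree 3 by default); `rbf` (Gaussian); and
#' `mlp` (sigmoid kernel `tanh(scale * <x, x'> + offset)`). Unset `gamma`
#' resolves at fit time: 1 for the polynomial family, `1/d` for `rbf` and
#' `mlp` where `d` is the descriptor length.
#'
#' @param name One of `"linear"`, `"quadratic"`, `"polynomial"`, `"rbf"`,
#'   `"mlp"`.
#' @param degree Polynomial degree (>= 2; `quadratic` fixes 2).
#' @param gamma Kernel scale (must be > 0 for `rbf` when given).
#' @param coef0 Additive kernel constant; defaults to 1 for the polynomial
#'   family and -1 for the sigmoid (`mlp`) kernel.
#' @param cost Soft-margin regularisation constant C (default 1).
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(name = c("linear", "quadratic", "polynomial", "rbf",
                                 "mlp"),
                        degree = 3L, gamma = NULL, coef0 = NULL, cost = 1) {
  name <- match.arg(name)
  if (name == "quadratic") degree <- 2L
  if (name == "polynomial" && degree < 2L) {
    abort("polynomial kernel requires degree >= 2")
  }
  if (!is.null(gamma) && gamma <= 0 && name == "rbf") {
    abort("rbf kernel requires gamma > 0")
  }
  structure(list(name = name, degree = as.integer(degree), gamma = gamma,
                 coef0 = coef0, cost = cost),
            class = "kernel_spec")
}

resolve_kernel <- function(spec, d) {
  switch(spec$name,
    linear = list(kernel = "linear", degree = 3L, gamma = 1 / d, coef0 = 0),
    quadratic = list(kernel = "polynomial", degree = 2L,
                     gamma = spec$gamma %||% 1, coef0 = spec$coef0 %||% 1),
    polynomial = list(kernel = "polynomial", degree = spec$degree,
                      gamma = spec$gamma %||% 1, coef0 = spec$coef0 %||% 1),
    rbf = list(kernel = "radial", degree = 3L,
               gamma = spec$gamma %||% (1 / d), coef0 = 0),
    mlp = list(kernel = "sigmoid", degree = 3L,
               gamma = spec$gamma %||% (1 / d), coef0 = spec$coef0 %||% -1)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-against-all multiclass SVM
#'
#' Trains one binary soft-margin machine per class (that class versus the
#' rest) with a shared kernel; a sample is assigned to the class whose
#' machine returns the largest decision value, ties resolving to the lowest
#' class index.
#'
#' @param data A descriptor tibble with a `class` column.
#' @param kernel A [kernel_spec()].
#' @param seed Integer seed (the underlying quadratic-programming fit is
#'   deterministic; the seed is recorded for provenance).
#' @return An `ova_svm` with one machine per class.
#' @export
fit_ova_svm <- function(data, kernel = kernel_spec("polynomial"), seed = 1L) {
  if (!"class" %in% names(data)) abort("data must contain a 'class' column")
  if (!inherits(kernel, "kernel_spec")) {
    abort("kernel must be created with kernel_spec()")
  }
  x <- feature_matrix(data)
  y <- class_factor(data$class)
  present <- CLASS_LEVELS[CLASS_LEVELS %in% unique(as.character(y))]
  if (length(present) < 2L) abort("need at least 2 classes to train")
  # standardise by training statistics: kernel machines are scale-sensitive
  # and raw count descriptors (LBP) are badly conditioned otherwise
  centre <- colMeans(x)
  spread <- apply(x, 2L, stats::sd)
  spread[spread == 0] <- 1
  xs <- sweep(sweep(x, 2L, centre), 2L, spread, "/")
  pars <- resolve_kernel(kernel, ncol(xs))
  machines <- lapply(setNames(CLASS_LEVELS, CLASS_LEVELS), function(cls) {
    if (!cls %in% present) return(NULL)  # class absent: no machine
    yy <- factor(ifelse(y == cls, "pos", "neg"), levels = c("pos", "neg"))
    withr_seed(seed, e1071::svm(
      xs, yy, type = "C-classification", kernel = pars$kernel,
      degree = pars$degree, gamma = pars$gamma, coef0 = pars$coef0,
      cost = kernel$cost, scale = FALSE
    ))
  })
  structure(list(machines = machines, kernel = kernel, seed = seed,
                 centre = centre, spread = spread,
                 n_features = ncol(x), classes_present = present),
            class = "ova_svm")
}

ova_decision_values <- function(object, x) {
  dv <- matrix(-Inf, nrow = nrow(x), ncol = length(CLASS_LEVELS),
               dimnames = list(NULL, CLASS_LEVELS))
  for (cls in CLASS_LEVELS) {
    m <- object$machines[[cls]]
    if (is.null(m)) next
    pr <- predict(m, x, decision.values = TRUE)
    v <- attr(pr, "decision.values")
    # orient so that larger means more 'pos' (the target class)
    if (colnames(v)[1] == "pos/neg") dv[, cls] <- v[, 1] else dv[, cls] <- -v[, 1]
  }
  dv
}

#' @export
predict.ova_svm <- function(object, newdata,
                            type = c("class", "decision"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  if (ncol(x) != object$n_features) {
    abort(paste0("descriptor width ", ncol(x), " incompatible with model (",
                 object$n_features, ")"))
  }
  x <- sweep(sweep(x, 2L, object$centre), 2L, object$spread, "/")
  dv <- ova_decision_values(object, x)
  if (type == "decision") return(dv)
  decode_outputs(dv)  # argmax with lowest-index tie-break
}

#' @export
print.ova_svm <- function(x, ...) {
  cat(sprintf("One-against-all SVM (%s kernel, C = %g): %d machines\n",
              x$kernel$name, x$kernel$cost,
              sum(!vapply(x$machines, is.null, logical(1)))))
  invisible(x)
}

#' Repeated stratified holdout evaluation
#'
#' Performs `n_rounds` seeded stratified holdout splits (80/20 by default),
#' fits the classifier on each training portion, scores the held-out
#' portion, and reports per-round and mean accuracy (percent) and MSE
#' (one-hot predictions against one-hot targets).
#'
#' @param data A descriptor tibble with a `class` column.
#' @param kernel A [kernel_spec()] for the default SVM fitter.
#' @param n_rounds Number of holdout rounds (default 20).
#' @param train_frac Training fraction per round (default 0.8).
#' @param seed Integer seed; round seeds are derived from it.
#' @param fit_fun,predict_fun Optional overrides: `fit_fun(train_data, seed)`
#'   returning a model and `predict_fun(model, test_data)` returning class
#'   labels, so the same harness evaluates any classifier.
#' @return A `holdout_eval` list with `rounds` (tibble), `mean_accuracy` and
#'   `mean_mse`.
#' @export
repeated_holdout <- function(data, kernel = kernel_spec("polynomial"),
                             n_rounds = 20L, train_frac = 0.8, seed = 1L,
                             fit_fun = NULL, predict_fun = NULL) {
  if (n_rounds < 1L) abort("n_rounds must be >= 1")
  if (train_frac <= 0 || train_frac >= 1) {
    abort("train_frac must be in (0, 1)")
  }
  if (is.null(fit_fun)) {
    fit_fun <- function(d, s) fit_ova_svm(d, kernel = kernel, seed = s)
  }
  if (is.null(predict_fun)) {
    predict_fun <- function(m, d) predict(m, d)
  }
  rounds <- purrr::map_dfr(seq_len(n_rounds), function(r) {
    rs <- derive_seed(seed, r)
    parts <- split_dataset(data,
                           fractions = c(train = train_frac,
                                         test = 1 - train_frac),
                           seed = rs)
    if (nrow(parts$test) == 0L || nrow(parts$train) == 0L) {
      abort("degenerate holdout split: empty train or test portion")
    }
    model <- fit_fun(parts$train, rs)
    pred <- predict_fun(model, parts$test)
    truth <- class_factor(parts$test$class)
    tibble::tibble(
      round = r,
      accuracy = 100 * mean(pred == truth),
      mse = mse_metric(encode_targets(pred), encode_targets(truth))
    )
  })
  structure(list(rounds = rounds,
                 mean_accuracy = mean(rounds$accuracy),
                 mean_mse = mean(rounds$mse),
                 n_rounds = n_rounds, train_frac = train_frac, seed = seed),
            class = "holdout_eval")
}

#' @export
print.holdout_eval <- function(x, ...) {
  cat(sprintf(
    "%d-round %.0f/%.0f holdout: mean accuracy %.1f%%, mean MSE %.4f\n",
    x$n_rounds, 100 * x$train_frac, 100 * (1 - x$train_frac),
    x$mean_accuracy, x$mean_mse))
  invisible(x)
}

#' @export
tidy.holdout_eval <- function(x, ...) x$rounds

#' @export
glance.holdout_eval <- function(x, ...) {
  tibble::tibble(n_rounds = x$n_rounds, train_frac = x$train_frac,
                 mean_accuracy = x$mean_accuracy, mean_mse = x$mean_mse)
}

#' Kernel comparison harness
#'
#' Runs the repeated-holdout evaluation once per kernel and returns the
#' five-row comparison table (kernel, mean MSE, mean accuracy).
#'
#' @inheritParams repeated_holdout
#' @param kernels Character vector of kernel names (default all five).
#' @return A tibble with one row per kernel.
#' @export
kernel_comparison <- function(data,
                              kernels = c("linear", "quadratic", "polynomial",
                                          "rbf", "mlp"),
                              n_rounds = 20L, train_frac = 0.8, seed = 1L) {
  purrr::map_dfr(kernels, function(k) {
    ev <- repeated_holdout(data, kernel = kernel_spec(k),
                           n_rounds = n_rounds, train_frac = train_frac,
                           seed = seed)
    tibble::tibble(kernel = k, mse = ev$mean_mse, accuracy = ev$mean_accuracy)
  })
}

#' Bucket-of-models SVM ensemble
#'
#' Trains `n_models` one-against-all SVMs on independent seeded stratified
#' re-splits of the data and returns the member with the highest holdout
#' accuracy (ties to the earliest member). Deterministic given the seed.
#'
#' @inheritParams repeated_holdout
#' @param n_models Number of bucket members (default 50).
#' @return An `svm_bucket` whose `best` element is the winning `ova_svm`;
#'   `members` tabulates every member's holdout accuracy and MSE.
#' @export
fit_svm_bucket <- function(data, kernel = kernel_spec("polynomial"),
                           n_models = 50L, train_frac = 0.8, seed = 1L) {
  if (n_models < 1L) abort("n_models must be >= 1")
  fits <- vector("list", n_models)
  acc <- mse <- numeric(n_models)
  for (b in seq_len(n_models)) {
    rs <- derive_seed(seed, b)
    parts <- split_dataset(data,
                           fractions = c(train = train_frac,
                                         test = 1 - train_frac),
                           seed = rs)
    fits[[b]] <- fit_ova_svm(parts$train, kernel = kernel, seed = rs)
    pred <- predict(fits[[b]], parts$test)
    truth <- class_factor(parts$test$class)
    acc[b] <- 100 * mean(pred == truth)
    mse[b] <- mse_metric(encode_targets(pred), encode_targets(truth))
  }
  best <- which.max(acc)
  structure(
    list(best = fits[[best]], best_index = best,
         members = tibble::tibble(member = seq_len(n_models),
                                  accuracy = acc, mse = mse),
         kernel = kernel, seed = seed),
    class = "svm_bucket"
  )
}

#' @export
predict.svm_bucket <- function(object, newdata, ...) {
  predict(object$best, newdata, ...)
}

#' @export
print.svm_bucket <- function(x, ...) {
  cat(sprintf(
    "Bucket of %d SVMs (%s kernel); best member %d: %.1f%% holdout accuracy\n",
    nrow(x$members), x$kernel$name, x$best_index,
    x$members$accuracy[x$best_index]))
  invisible(x)
}

#' @export
tidy.svm_bucket <- function(x, ...) x$members

#' @export
glance.svm_bucket <- function(x, ...) {
  tibble::tibble(n_models = nrow(x$members), best_index = x$best_index,
                 best_accuracy = x$members$accuracy[x$best_index],
                 best_mse = x$members$mse[x$best_index])
}
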