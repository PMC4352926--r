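#' Single artificial neuron
#'
#' Applies an activation to the bias-plus-weighted-sum of the inputs:
#' `f(w0 + sum(w * x))`.
#'
#' @param x Numeric input vector.
#' @param weights Numeric weight vector, same length as `x`.
#' @param bias Bias term `w0`.
#' @param activation `"tanh"`, `"logistic"` or `"linear"`.
#' @param slope Slope constant `a` of the logistic activation
#'   `1 / (1 + exp(-a z))`.
#' @return A single number.
#' @export
#' @examples
#' neuron_forward(c(1, 1), c(0.5, 0.5), bias = -1, activation = "linear")
neuron_forward <- function(x, weights, bias = 0,
                           activation = c("tanh", "logistic", "linear"),
                           slope = 1) {
  activation <- match.arg(activation)
  if (length(x) != length(weights)) {
    abort("input and weight vectors must have equal length")
  }
  z <- bias + sum(weights * x)
  switch(activation,
         tanh = tanh(z),
         logistic = 1 / (1 + exp(-slope * z)),
         linear = z)
}

#' Network architecture of the six-class perceptron
#'
#' Two hidden layers of equal width with hyperbolic-tangent activations in
#' the hidden and output layers; 81 inputs (the HOG descriptor length) and 6
#' outputs (one per class) by default.
#'
#' @param n_inputs Number of input units.
#' @param hidden Integer vector of hidden-layer widths.
#' @param n_outputs Number of output units.
#' @return An `mlp_architecture` list.
#' @export
mlp_architecture <- function(n_inputs = 81L, hidden = c(80L, 80L),
                             n_outputs = 6L) {
  if (any(hidden < 1L)) abort("hidden-layer widths must be >= 1")
  structure(list(n_inputs = as.integer(n_inputs),
                 hidden = as.integer(hidden),
                 n_outputs = as.integer(n_outputs)),
            class = "mlp_architecture")
}

layer_sizes <- function(arch) c(arch$n_inputs, arch$hidden, arch$n_outputs)

init_params <- function(arch, seed) {
  sizes <- layer_sizes(arch)
  withr_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fan_in <- sizes[l]
      r <- 1 / sqrt(fan_in)
      list(W = matrix(runif(sizes[l + 1L] * fan_in, -r, r),
                      nrow = sizes[l + 1L]),
           b = runif(sizes[l + 1L], -r, r))
    })
  })
}

pack_params <- function(params) {
  unlist(lapply(params, function(p) c(as.vector(p$W), p$b)), use.names = FALSE)
}

unpack_params <- function(theta, arch) {
  sizes <- layer_sizes(arch)
  out <- vector("list", length(sizes) - 1L)
  pos <- 0L
  for (l in seq_along(out)) {
    nw <- sizes[l + 1L] * sizes[l]
    out[[l]] <- list(
      W = matrix(theta[pos + seq_len(nw)], nrow = sizes[l + 1L]),
      b = theta[pos + nw + seq_len(sizes[l + 1L])]
    )
    pos <- pos + nw + sizes[l + 1L]
  }
  out
}

# Forward pass; x is d x n (samples in columns). Returns activations per
# layer (tanh everywhere, including the output layer).
forward_pass <- function(params, x) {
  acts <- vector("list", length(params) + 1L)
  acts[[1L]] <- x
  for (l in seq_along(params)) {
    acts[[l + 1L]] <- tanh(params[[l]]$W %*% acts[[l]] + params[[l]]$b)
  }
  acts
}

# Mean squared error over samples and output units, plus its gradient packed
# as a single vector.
loss_and_grad <- function(theta, arch, x, targets) {
  params <- unpack_params(theta, arch)
  acts <- forward_pass(params, x)
  n_out <- length(acts)
  y <- acts[[n_out]]
  denom <- length(y)
  err <- y - targets
  loss <- sum(err^2) / denom
  delta <- (2 * err / denom) * (1 - y^2)
  grads <- vector("list", length(params))
  for (l in rev(seq_along(params))) {
    grads[[l]] <- list(W = delta %*% t(acts[[l]]), b = rowSums(delta))
    if (l > 1L) {
      delta <- (t(params[[l]]$W) %*% delta) * (1 - acts[[l]]^2)
    }
  }
  list(loss = loss, grad = pack_params(grads))
}

# Min-max input normalisation to [-1, 1], fitted on training data and
# stored with the model; tanh networks saturate on raw count descriptors.
fit_feature_scaling <- function(x) {
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  hi[hi == lo] <- lo[hi == lo] + 1  # constant columns map to -1
  list(lo = lo, hi = hi)
}

apply_feature_scaling <- function(x, scaling) {
  if (is.null(scaling)) return(x)
  2 * sweep(sweep(x, 2L, scaling$lo), 2L, scaling$hi - scaling$lo, "/") - 1
}

#' Forward pass of a trained network
#'
#' Applies the fit's stored input normalisation (when `fit` is an
#' `mlp_fit`) before propagating.
#'
#' @param fit An `mlp_fit` (or a raw parameter list, taken as-is).
#' @param x A numeric matrix with samples in rows (n x d), or a single
#'   length-d vector.
#' @return An n x 6 matrix of outputs in (-1, 1).
#' @export
mlp_forward <- function(fit, x) {
  scaling <- if (inherits(fit, "mlp_fit")) fit$scaling
  params <- if (inherits(fit, "mlp_fit")) fit$params else fit
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  x <- apply_feature_scaling(x, scaling)
  d_expected <- ncol(params[[1L]]$W)
  if (ncol(x) != d_expected) {
    abort(paste0("input has ", ncol(x), " features; network expects ",
                 d_expected))
  }
  acts <- forward_pass(params, t(x))
  t(acts[[length(acts)]])
}

# Scaled conjugate gradient descent (Moller's algorithm, sigma0 = 5e-5,
# initial lambda = 5e-7). One SCG step counts as one epoch. Training stops at
# max_epochs, on convergence (zero gradient), or when validation error has
# not improved for `patience` consecutive epochs; the returned weights are
# those of the epoch with minimum validation error.
scg_train <- function(arch, x_train, t_train, x_val, t_val,
                      max_epochs = 500L, patience = 6L, seed = 1L,
                      sigma0 = 5e-5, lambda0 = 5e-7) {
  theta <- pack_params(init_params(arch, seed))
  n_par <- length(theta)
  fg <- loss_and_grad(theta, arch, x_train, t_train)
  if (!is.finite(fg$loss)) abort("divergence: non-finite training loss")
  loss <- fg$loss
  r <- -fg$grad
  p <- r
  lambda <- lambda0
  lambda_bar <- 0
  success <- TRUE
  delta <- 0
  val_mse <- function(th) {
    params <- unpack_params(th, arch)
    acts <- forward_pass(params, x_val)
    mean((acts[[length(acts)]] - t_val)^2)
  }
  history <- matrix(NA_real_, nrow = max_epochs, ncol = 2L,
                    dimnames = list(NULL, c("train_mse", "validation_mse")))
  best <- list(theta = theta, val = val_mse(theta), epoch = 0L)
  bad_streak <- 0L
  epoch <- 0L
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    p2 <- sum(p * p)
    if (p2 == 0 || sum(r * r) == 0) { epoch <- epoch - 1L; break }
    if (success) {
      sigma <- sigma0 / sqrt(p2)
      g2 <- loss_and_grad(theta + sigma * p, arch, x_train, t_train)$grad
      s <- (g2 - (-r)) / sigma
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambda_bar) * p2
    if (delta <= 0) {
      lambda_bar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    cand <- theta + alpha * p
    fg_cand <- loss_and_grad(cand, arch, x_train, t_train)
    if (!is.finite(fg_cand$loss)) abort("divergence: non-finite training loss")
    comp <- 2 * delta * (loss - fg_cand$loss) / mu^2
    if (comp >= 0) {
      theta <- cand
      loss <- fg_cand$loss
      r_new <- -fg_cand$grad
      lambda_bar <- 0
      success <- TRUE
      if (epoch %% n_par == 0L) {
        p <- r_new
      } else {
        beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (comp >= 0.75) lambda <- lambda / 4
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (comp < 0.25) lambda <- lambda + delta * (1 - comp) / p2
    v <- val_mse(theta)
    history[epoch, ] <- c(loss, v)
    if (v < best$val) {
      best <- list(theta = theta, val = v, epoch = epoch)
      bad_streak <- 0L
    } else {
      bad_streak <- bad_streak + 1L
      if (bad_streak >= patience) break
    }
  }
  idx <- seq_len(epoch)
  hist_tbl <- tibble::tibble(
    epoch = idx,
    train_mse = history[idx, 1L],
    validation_mse = history[idx, 2L]
  )
  list(theta = best$theta, best_epoch = best$epoch, history = hist_tbl)
}

#' Fit a six-class perceptron on a descriptor table
#'
#' Splits the data 70/15/15 (stratified by class) with the given seed, trains
#' a two-hidden-layer tanh network against the one-hot class targets using
#' scaled-conjugate-gradient descent, and returns the weights at the epoch of
#' minimum validation error. Fully deterministic given the seed.
#'
#' @param data A descriptor tibble (from [hog_features()] or
#'   [lbp_features()]) with a `class` column.
#' @param hidden Hidden-layer widths (default `c(80, 80)`).
#' @param max_epochs Maximum training epochs (default 500).
#' @param patience Consecutive epochs of non-improving validation error
#'   before stopping (default 6).
#' @param split Named train/validation/test fractions.
#' @param seed Integer seed controlling the split and weight initialisation.
#' @return An `mlp_fit` with elements `params`, `arch`, `history`,
#'   `best_epoch`, `splits` (row assignment), and `metrics` (accuracy and MSE
#'   on the test split and on all data).
#' @export
fit_mlp <- function(data, hidden = c(80L, 80L), max_epochs = 500L,
                    patience = 6L,
                    split = c(train = 0.70, validation = 0.15, test = 0.15),
                    seed = 1L) {
  if (!"class" %in% names(data)) abort("data must contain a 'class' column")
  x <- feature_matrix(data)
  y <- class_factor(data$class)
  parts <- split_dataset(data, fractions = split,
                         seed = derive_seed(seed, 1L))
  grp <- attr(parts, "assignment")
  arch <- mlp_architecture(n_inputs = ncol(x), hidden = hidden)
  tr <- grp == "train"
  va <- grp == "validation"
  if (!any(tr) || !any(va)) abort("train and validation splits must be non-empty")
  if (length(unique(y[tr])) < length(unique(y))) {
    abort(paste0("empty class in training split: ",
                 paste(setdiff(unique(as.character(y)),
                               unique(as.character(y[tr]))), collapse = ", ")))
  }
  targets <- t(encode_targets(y))
  scaling <- fit_feature_scaling(x[tr, , drop = FALSE])
  xs <- apply_feature_scaling(x, scaling)
  res <- scg_train(arch, t(xs[tr, , drop = FALSE]), targets[, tr, drop = FALSE],
                   t(xs[va, , drop = FALSE]), targets[, va, drop = FALSE],
                   max_epochs = max_epochs, patience = patience,
                   seed = derive_seed(seed, 2L))
  fit <- structure(
    list(params = unpack_params(res$theta, arch), arch = arch,
         scaling = scaling,
         history = res$history, best_epoch = res$best_epoch,
         splits = grp, seed = seed,
         config = list(hidden = hidden, max_epochs = max_epochs,
                       patience = patience, split = split)),
    class = "mlp_fit"
  )
  out_all <- mlp_forward(fit, x)
  pred_all <- decode_outputs(out_all)
  te <- grp == "test"
  fit$metrics <- tibble::tibble(
    set = c("test", "all"),
    accuracy = c(
      if (any(te)) 100 * mean(pred_all[te] == y[te]) else NA_real_,
      100 * mean(pred_all == y)
    ),
    mse = c(
      if (any(te)) mse_metric(out_all[te, , drop = FALSE],
                              encode_targets(y[te])) else NA_real_,
      mse_metric(out_all, encode_targets(y))
    )
  )
  fit
}

#' @export
predict.mlp_fit <- function(object, newdata, type = c("class", "raw"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  out <- mlp_forward(object, x)
  if (type == "raw") out else decode_outputs(out)
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf("Six-class perceptron: %d-%s-%d (tanh), SCG-trained\n",
              x$arch$n_inputs, paste(x$arch$hidden, collapse = "-"),
              x$arch$n_outputs))
  cat(sprintf("  best epoch %d of %d; validation MSE %.4f\n",
              x$best_epoch, nrow(x$history),
              min(x$history$validation_mse)))
  invisible(x)
}

#' @export
tidy.mlp_fit <- function(x, ...) x$history

#' @export
glance.mlp_fit <- function(x, ...) {
  tibble::tibble(
    hidden = paste(x$arch$hidden, collapse = "x"),
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    validation_mse = min(x$history$validation_mse),
    test_accuracy = x$metrics$accuracy[x$metrics$set == "test"],
    test_mse = x$metrics$mse[x$metrics$set == "test"]
  )
}

#' Hidden-layer width sweep
#'
#' Trains one network per hidden width (default 10, 20, ..., 100 units in
#' each of the two hidden layers) and records its MSE and accuracy. Because
#' which dataset best matches a published sweep is ambiguous, both the
#' held-out test metrics and the all-data metrics are reported.
#'
#' @inheritParams fit_mlp
#' @param sizes Integer vector of hidden widths to try.
#' @param keep_fits Also return the fitted models (default FALSE).
#' @return A tibble with one row per width: `hidden`, `best_epoch`,
#'   `validation_mse`, `test_mse`, `test_accuracy`, `all_mse`,
#'   `all_accuracy`; with `keep_fits`, the fits are in attribute `"fits"`.
#' @export
hidden_size_sweep <- function(data, sizes = seq(10L, 100L, by = 10L),
                              max_epochs = 500L, patience = 6L, seed = 1L,
                              keep_fits = FALSE) {
  fits <- lapply(seq_along(sizes), function(i) {
    fit_mlp(data, hidden = rep(sizes[i], 2L), max_epochs = max_epochs,
            patience = patience, seed = derive_seed(seed, i))
  })
  out <- tibble::tibble(
    hidden = as.integer(sizes),
    best_epoch = vapply(fits, `[[`, integer(1), "best_epoch"),
    validation_mse = vapply(fits, function(f) min(f$history$validation_mse),
                            numeric(1)),
    test_mse = vapply(fits, function(f)
      f$metrics$mse[f$metrics$set == "test"], numeric(1)),
    test_accuracy = vapply(fits, function(f)
      f$metrics$accuracy[f$metrics$set == "test"], numeric(1)),
    all_mse = vapply(fits, function(f)
      f$metrics$mse[f$metrics$set == "all"], numeric(1)),
    all_accuracy = vapply(fits, function(f)
      f$metrics$accuracy[f$metrics$set == "all"], numeric(1))
  )
  if (keep_fits) attr(out, "fits") <- fits
  out
}
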