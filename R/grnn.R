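#' Fit a generalized regression neural network
#'
#' A GRNN stores every training row as a kernel center (input-to-hidden
#' weights) and its class label as the corresponding hidden-to-output weight.
#' The output for an input `x` is the Gaussian-kernel-weighted average of the
#' training labels,
#' `y = sum(t_i k_i) / sum(k_i)` with `k_i = exp(-d_i^2 / (2 sigma^2))`,
#' where `d_i` is the Euclidean distance from `x` to center `i` and `sigma`
#' the spreading factor. Because the kernels decay with distance, the kernel
#' sum itself signals whether `x` lies anywhere near the training data: a sum
#' below `reject_threshold` rejects the input, giving the GRNN a closed
#' (hyperspheric) decision boundary. Features are standardized per sensor on
#' the training split, so `sigma` is in standardized units.
#'
#' @param train a `labeled_dataset`.
#' @param sigma spreading factor (> 0).
#' @param reject_threshold minimum kernel sum for a confident output
#'   (default 1e-6; 0 disables rejection).
#' @param standardize z-score features on the training split (default TRUE).
#' @return an object of class `grnn_model`.
#' @export
grnn_model <- function(train, sigma, reject_threshold = 1e-6,
                       standardize = TRUE) {
  if (sigma <= 0) stop("sigma must be positive")
  if (reject_threshold < 0) stop("reject_threshold must be >= 0")
  scaler <- if (standardize) fit_scaler(train$features) else NULL
  X <- if (standardize) apply_scaler(scaler, train$features) else train$features
  structure(list(centers = X, targets = as.numeric(train$labels),
                 sigma = sigma, reject_threshold = reject_threshold,
                 scaler = scaler, n_classes = length(train$n_per_class)),
            class = "grnn_model")
}

# Raw continuous GRNN output and kernel sum for one (already scaled) input.
grnn_output <- function(model, xs) {
  d2 <- rowSums(sweep(model$centers, 2, xs)^2)
  k <- exp(-d2 / (2 * model$sigma^2))
  s <- sum(k)
  list(y = if (s > 0) sum(model$targets * k) / s else NA_real_, ksum = s)
}

#' Classify a measurement with a GRNN
#'
#' Rejects when the kernel sum falls below the model's threshold; otherwise
#' rounds the kernel-weighted label average to the nearest integer. A rounded
#' value outside `1..M` is an unknown-class label (possible only at the
#' rounding boundary, since the raw output is a convex combination of
#' training labels).
#'
#' @param model a `grnn_model`.
#' @param x numeric feature vector.
#' @return an `enose_prediction`.
#' @export
grnn_predict <- function(model, x) {
  x <- as_feature_vector(x, ncol(model$centers))
  xs <- if (!is.null(model$scaler)) as.numeric(apply_scaler(model$scaler, x))
        else x
  out <- grnn_output(model, xs)
  if (out$ksum < model$reject_threshold || !is.finite(out$y))
    return(prediction(NA, rejected = TRUE))
  prediction(round_label(out$y))
}

#' Select the GRNN spreading factor on a validation split
#'
#' For each candidate `sigma` the validation squared error
#' `E = sum((y(x_v) - t_v)^2)` is computed from the raw (unrounded,
#' unrejected) outputs; the first grid point attaining the minimum wins.
#'
#' @param train training `labeled_dataset`.
#' @param val validation `labeled_dataset`.
#' @param sigma_grid numeric vector of candidate spreading factors.
#' @param reject_threshold threshold for the returned model.
#' @return the selected `grnn_model`, with attribute `val_errors` (the `E`
#'   per grid point).
#' @export
grnn_tune_sigma <- function(train, val, sigma_grid = c(0.03, 0.1, 0.3, 1),
                            reject_threshold = 1e-6) {
  if (length(sigma_grid) == 0) stop("sigma_grid must be nonempty")
  errs <- vapply(sigma_grid, function(s) {
    m <- grnn_model(train, s, reject_threshold = 0)
    Xv <- if (!is.null(m$scaler)) apply_scaler(m$scaler, val$features)
          else val$features
    ys <- vapply(seq_len(nrow(Xv)),
                 function(i) grnn_output(m, Xv[i, ])$y, numeric(1))
    ys[!is.finite(ys)] <- 0  # fully out-of-reach validation point
    sum((ys - val$labels)^2)
  }, numeric(1))
  best <- which.min(errs)  # which.min returns the first minimizer
  structure(grnn_model(train, sigma_grid[best],
                       reject_threshold = reject_threshold),
            val_errors = errs)
}
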