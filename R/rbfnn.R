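#' Train a radial basis function network by exact interpolation
#'
#' Like the GRNN, the RBFNN centers one Gaussian unit on every training row,
#' but the hidden-to-output weights are solved for rather than set to the
#' labels: with the all-pairs kernel matrix
#' `Phi[i, j] = exp(-||x_i - x_j||^2 / (2 sigma^2))`
#' over the training rows, the weight vector is `w2 = Phi^{-1} t` (a
#' Moore-Penrose pseudo-inverse rescues ill-conditioned `Phi`), so the
#' network reproduces its training targets exactly whenever `Phi` is
#' full-rank. Each candidate `sigma` on the grid is scored by the validation
#' squared error and the best is returned. Features are standardized per
#' sensor on the training split.
#'
#' @param train training `labeled_dataset`.
#' @param val validation `labeled_dataset` (use `train` to skip tuning).
#' @param sigma_grid candidate kernel widths (standardized units).
#' @param reject enable kernel-sum rejection thresholding (default FALSE:
#'   far-field inputs then decay to an out-of-range output and are labeled
#'   as an unknown class rather than rejected).
#' @param reject_threshold minimum kernel sum when `reject = TRUE`.
#' @param standardize z-score features on the training split (default TRUE).
#' @return an object of class `rbfnn_model` with fields `centers`, `sigma`,
#'   `w2`, `reject`, `reject_threshold`, and attribute `val_errors`.
#' @export
rbfnn_train <- function(train, val, sigma_grid = c(0.1, 0.3, 0.5, 1),
                        reject = FALSE, reject_threshold = 1e-6,
                        standardize = TRUE) {
  if (length(sigma_grid) == 0) stop("sigma_grid must be nonempty")
  scaler <- if (standardize) fit_scaler(train$features) else NULL
  X <- if (standardize) apply_scaler(scaler, train$features) else train$features
  Xv <- if (standardize) apply_scaler(scaler, val$features) else val$features
  tgt <- as.numeric(train$labels)
  D2 <- cross_dist2(X, X)
  D2v <- cross_dist2(Xv, X)
  fits <- lapply(sigma_grid, function(s) {
    Phi <- exp(-D2 / (2 * s^2))
    w2 <- tryCatch(solve(Phi, tgt), error = function(e) NULL)
    if (is.null(w2) || any(!is.finite(w2)))
      w2 <- tryCatch(as.numeric(MASS::ginv(Phi) %*% tgt),
                     error = function(e) NULL)
    if (is.null(w2) || any(!is.finite(w2))) return(NULL)
    yv <- as.numeric(exp(-D2v / (2 * s^2)) %*% w2)
    list(w2 = w2, err = sum((yv - val$labels)^2))
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("training error: kernel matrix singular for every sigma on the grid")
  errs <- rep(Inf, length(sigma_grid))
  errs[ok] <- vapply(fits[ok], `[[`, numeric(1), "err")
  best <- which.min(errs)
  structure(list(centers = X, sigma = sigma_grid[best],
                 w2 = fits[[best]]$w2, reject = reject,
                 reject_threshold = reject_threshold, scaler = scaler,
                 n_classes = length(train$n_per_class)),
            class = "rbfnn_model", val_errors = errs)
}

#' Classify a measurement with a trained RBFNN
#'
#' The output is `y = sum(w2_i * exp(-||x - c_i||^2 / (2 sigma^2)))`, rounded
#' to an integer label: inside `1..M` a trained class, otherwise an
#' unknown-class label (far-field inputs decay to `y ~ 0`, i.e. unknown
#' class 0). With `reject = TRUE` a kernel sum below the threshold rejects
#' instead.
#'
#' @param model an `rbfnn_model`.
#' @param x numeric feature vector.
#' @return an `enose_prediction`.
#' @export
rbfnn_predict <- function(model, x) {
  x <- as_feature_vector(x, ncol(model$centers))
  xs <- if (!is.null(model$scaler)) as.numeric(apply_scaler(model$scaler, x))
        else x
  k <- exp(-rowSums(sweep(model$centers, 2, xs)^2) / (2 * model$sigma^2))
  if (model$reject && sum(k) < model$reject_threshold)
    return(prediction(NA, rejected = TRUE))
  prediction(round_label(sum(model$w2 * k)))
}
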