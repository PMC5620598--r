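#' Fit a minimum-maximum-mean (MMM) hyperbox model
#'
#' For each trained class the model stores the per-sensor maximum (matrix
#' `Q`), minimum (`V`), mean (`U`) and standard deviation (`S`) of that
#' class's training rows. The `[V, Q]` intervals define an axis-aligned
#' hyperbox per class: a closed decision region that supports rejecting
#' inputs falling inside no box, unlike open half-space boundaries. `S`
#' drives validation-driven boundary expansion (see [expand_boundaries()]).
#'
#' @param train a `labeled_dataset` with at least one row per class.
#' @return an object of class `hyperbox_model` with fields `Q`, `V`, `U`,
#'   `S` (class-by-sensor matrices), `expansion` (accumulated multiplier of
#'   `S`, starts at 0) and `class_labels`.
#' @export
fit_mmm <- function(train) {
  M <- length(train$n_per_class)
  present <- sort(unique(train$labels))
  if (any(train$n_per_class[present] < 1) || length(present) == 0)
    stop("fit error: every class needs at least one training row")
  N <- ncol(train$features)
  Q <- V <- U <- S <- matrix(NA_real_, length(present), N)
  for (i in seq_along(present)) {
    Xm <- train$features[train$labels == present[i], , drop = FALSE]
    if (nrow(Xm) == 0) stop("fit error: empty class ", present[i])
    Q[i, ] <- apply(Xm, 2, max)
    V[i, ] <- apply(Xm, 2, min)
    U[i, ] <- colMeans(Xm)
    s <- apply(Xm, 2, stats::sd)
    S[i, ] <- ifelse(is.finite(s), s, 0)
  }
  structure(list(Q = Q, V = V, U = U, S = S, expansion = 0,
                 class_labels = as.integer(present)),
            class = "hyperbox_model")
}

#' @export
print.hyperbox_model <- function(x, ...) {
  cat(sprintf("<hyperbox_model: %d classes x %d sensors, expansion %.4f>\n",
              nrow(x$Q), ncol(x$Q), x$expansion))
  invisible(x)
}

#' Classify a measurement with the MMM hyperbox rule
#'
#' Candidate classes are those whose (possibly expanded) box contains `x`
#' elementwise (`V_m <= x <= Q_m`, boundaries inclusive). No candidate means
#' the input is rejected ("unclassified"); one candidate wins outright;
#' among several the class whose mean row of `U` is Euclidean-nearest to `x`
#' wins, with residual exact-distance ties broken toward the lowest class
#' label. All tied candidates are reported in `tie_classes`.
#'
#' @param model a `hyperbox_model`.
#' @param x numeric feature vector of length N.
#' @return an `enose_prediction`.
#' @export
classify_mmm <- function(model, x) {
  x <- as_feature_vector(x, ncol(model$Q))
  inside <- vapply(seq_len(nrow(model$Q)), function(m) {
    all(model$V[m, ] <= x & x <= model$Q[m, ])
  }, logical(1))
  cand <- which(inside)
  if (length(cand) == 0) return(prediction(NA, rejected = TRUE))
  if (length(cand) == 1)
    return(prediction(model$class_labels[cand]))
  d2 <- rowSums((model$U[cand, , drop = FALSE] -
                   matrix(x, length(cand), length(x), byrow = TRUE))^2)
  best <- cand[which(d2 == min(d2))]
  prediction(min(model$class_labels[best]),
             tie_classes = model$class_labels[cand])
}

#' Classify every row of a matrix or dataset
#'
#' @param model a fitted classifier model.
#' @param X numeric matrix of feature rows, or a `labeled_dataset`.
#' @return list of `enose_prediction`s.
#' @export
predict_all <- function(model, X) {
  if (inherits(X, "labeled_dataset")) X <- X$features
  fn <- switch(class(model)[1],
               hyperbox_model = classify_mmm,
               knn_model = knn_predict,
               multiclass_svm = svm_predict_multiclass,
               mlp_model = mlp_predict,
               grnn_model = grnn_predict,
               rbfnn_model = rbfnn_predict,
               stop("unsupported model class: ", class(model)[1]))
  lapply(seq_len(nrow(X)), function(i) fn(model, X[i, ]))
}

#' Expand hyperbox boundaries by a multiple of the class dispersions
#'
#' Adds `eta * S_m` to class `m`'s maximum row and subtracts it from the
#' minimum row, for every class, enlarging the decision regions to admit
#' borderline validation samples. `U` and `S` are untouched; the accumulated
#' expansion multiplier is tracked, so two expansions of `eta/2` equal one of
#' `eta`.
#'
#' @param model a `hyperbox_model`.
#' @param eta positive expansion rate (dimensionless multiple of `S`).
#' @return the expanded `hyperbox_model`.
#' @export
expand_boundaries <- function(model, eta) {
  if (eta <= 0) stop("eta must be positive")
  model$Q <- model$Q + eta * model$S
  model$V <- model$V - eta * model$S
  model$expansion <- model$expansion + eta
  model
}

#' Validation misassignment error of an MMM model
#'
#' Fraction of validation rows whose [classify_mmm()] outcome differs from
#' the true label; a rejection of a trained-class row counts as an error.
#'
#' @param model a `hyperbox_model`.
#' @param val nonempty `labeled_dataset`.
#' @return scalar error fraction in `[0, 1]`.
#' @export
mmm_validation_error <- function(model, val) {
  preds <- predict_all(model, val)
  out <- outcomes(preds)
  mean(is.na(out) | out != val$labels)
}

#' Squared-label validation error (diagnostic)
#'
#' Sum over non-rejected validation rows of `(assigned label - true label)^2`.
#' Squared differences between arbitrary integer class labels depend on how
#' the labels were numbered, so this is a diagnostic only; model selection
#' uses [mmm_validation_error()].
#'
#' @param model a `hyperbox_model`.
#' @param val a `labeled_dataset`.
#' @return list with `sq_error` and `n_rejected`.
#' @export
mmm_squared_error <- function(model, val) {
  out <- outcomes(predict_all(model, val))
  keep <- !is.na(out)
  list(sq_error = sum((out[keep] - val$labels[keep])^2),
       n_rejected = sum(!keep))
}

#' Train an MMM model with validation-driven boundary expansion
#'
#' Fits the min/max/mean/sd matrices on the training split, then repeatedly
#' measures the validation error and expands all class boxes by `eta * S`
#' until the error drops to `error_threshold` or `max_rounds` expansions have
#' been applied. The model with the smallest validation error seen is
#' returned (earliest round on ties, i.e. the least-expanded such model).
#'
#' @param train training `labeled_dataset`.
#' @param val validation `labeled_dataset`.
#' @param eta expansion rate per round (default 0.1111, i.e. 11.11% of each
#'   class's per-sensor standard deviations).
#' @param error_threshold stop once validation error is at or below this
#'   (default 0.02).
#' @param max_rounds maximum number of expansions (default 10).
#' @return the best `hyperbox_model`, with attributes `rounds` (expansions
#'   actually applied to the returned model), `error_history` (validation
#'   error after 0, 1, ... expansions) and `converged`.
#' @export
train_mmm <- function(train, val, eta = 0.1111, error_threshold = 0.02,
                      max_rounds = 10L) {
  if (eta <= 0) stop("eta must be positive")
  if (max_rounds < 1) stop("max_rounds must be >= 1")
  model <- fit_mmm(train)
  errs <- mmm_validation_error(model, val)
  best <- model; best_err <- errs[1]; best_round <- 0L
  converged <- best_err <= error_threshold
  round <- 0L
  while (!converged && round < max_rounds) {
    model <- expand_boundaries(model, eta)
    round <- round + 1L
    e <- mmm_validation_error(model, val)
    errs <- c(errs, e)
    if (e < best_err) { best <- model; best_err <- e; best_round <- round }
    converged <- e <= error_threshold
  }
  if (!converged)
    message(sprintf("max_rounds (%d) reached; best validation error %.4f",
                    max_rounds, best_err))
  structure(best, rounds = best_round, error_history = errs,
            converged = converged)
}

#' Serialize / restore a hyperbox model as JSON
#'
#' Doubles are written at full precision (17 significant digits) so the
#' round trip is bit-exact.
#'
#' @param model a `hyperbox_model`.
#' @param path JSON file path.
#' @return `mmm_to_json` returns `path` invisibly; `mmm_from_json` returns a
#'   `hyperbox_model`.
#' @export
mmm_to_json <- function(model, path) {
  jsonlite::write_json(
    list(type = "mmm", classes = model$class_labels,
         Q = model$Q, V = model$V, U = model$U, S = model$S,
         expansion = model$expansion),
    path, auto_unbox = TRUE, digits = I(17), matrix = "rowmajor")
  invisible(path)
}

#' @rdname mmm_to_json
#' @export
mmm_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$type, "mmm")) stop("not an MMM model file")
  structure(list(Q = x$Q, V = x$V, U = x$U, S = x$S,
                 expansion = as.numeric(x$expansion),
                 class_labels = as.integer(x$classes)),
            class = "hyperbox_model")
}
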