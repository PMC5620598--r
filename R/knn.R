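#' Fit a k-nearest-neighbor model
#'
#' Stores the training rows (standardized per sensor with a z-score fitted on
#' the training split, since Euclidean distances are scale-sensitive) and
#' their labels. `k` must be odd, must not be a multiple of the number of
#' classes, and cannot exceed the number of training rows. k-NN has an open
#' decision boundary: it always returns some trained label, never a
#' rejection, which is the structural cause of its 100% false-alarm rate on
#' out-of-training odors.
#'
#' @param train a `labeled_dataset`.
#' @param k neighbor count (default 3).
#' @param standardize z-score features on the training split (default TRUE).
#' @return an object of class `knn_model`.
#' @export
knn_model <- function(train, k = 3L, standardize = TRUE) {
  k <- as.integer(k)
  M <- length(unique(train$labels))
  if (k %% 2L == 0L) stop("k must be an odd number")
  if (k %% M == 0L) stop("k must not be a multiple of the number of classes")
  if (k > nrow(train$features)) stop("k exceeds the number of training rows")
  scaler <- if (standardize) fit_scaler(train$features) else NULL
  X <- if (standardize) apply_scaler(scaler, train$features) else train$features
  structure(list(stored_features = X, stored_labels = train$labels,
                 k = k, scaler = scaler, n_classes = M),
            class = "knn_model")
}

#' Classify a measurement by majority vote among its k nearest neighbors
#'
#' Euclidean distances to all stored rows are ranked (distance ties at the
#' k-th rank broken by stored order); the plurality label among the k nearest
#' wins. A residual vote tie (possible when the neighborhood spans more than
#' two classes) goes to the tied class owning the single nearest neighbor.
#' Closed world: the outcome is always a trained label.
#'
#' @param model a `knn_model`.
#' @param x numeric feature vector.
#' @return an `enose_prediction` (never rejected).
#' @export
knn_predict <- function(model, x) {
  x <- as_feature_vector(x, ncol(model$stored_features))
  if (!is.null(model$scaler)) x <- as.numeric(apply_scaler(model$scaler, x))
  d2 <- rowSums(sweep(model$stored_features, 2, x)^2)
  nn <- order(d2)[seq_len(model$k)]  # stable: stored order breaks rank ties
  votes <- table(model$stored_labels[nn])
  top <- as.integer(names(votes)[votes == max(votes)])
  if (length(top) == 1L) return(prediction(top))
  for (i in nn) {  # nearest neighbor belonging to a tied class decides
    lab <- model$stored_labels[i]
    if (lab %in% top) return(prediction(lab, tie_classes = top))
  }
}
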