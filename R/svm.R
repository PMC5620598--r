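#' Train a binary maximum-margin (linear SVM) classifier
#'
#' Solves the dual problem: maximize
#' `sum(alpha) - 0.5 * sum_{i,j} alpha_i alpha_j t_i t_j <x_i, x_j>`
#' subject to `alpha >= 0` and `sum(alpha * t) = 0`, via a general-purpose
#' interior-point quadratic optimizer ([kernlab::ipop()]). The weight vector
#' is `w = sum(alpha_i t_i x_i)` and the bias comes from the
#' Karush-Kuhn-Tucker condition `t_s (w . x_s + b) = 1` averaged over support
#' vectors. The printed dual is hard-margin (`C = Inf`); a soft-margin box
#' `0 <= alpha <= C` is available for non-separable data.
#'
#' @param a numeric matrix: rows of the class mapped to target −1.
#' @param bclass numeric matrix: rows of the class mapped to target +1.
#' @param C soft-margin box constraint; `Inf` (default) is hard margin.
#' @param label_pair integer labels `(neg, pos)` the two classes carry in the
#'   multiclass setting.
#' @return an object of class `binary_svm` with fields `alphas`,
#'   `support_idx`, `w`, `b`, `label_pair`, `targets`.
#' @export
svm_train_binary <- function(a, bclass, C = Inf, label_pair = c(-1L, 1L)) {
  a <- as.matrix(a); bclass <- as.matrix(bclass)
  X <- rbind(a, bclass)
  t <- c(rep(-1, nrow(a)), rep(1, nrow(bclass)))
  n <- nrow(X)
  # center internally for conditioning; w is unaffected and b is shifted back
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  K <- Xc %*% t(Xc)
  H0 <- (t %o% t) * K
  scale_ridge <- max(mean(diag(K)), 1)
  upper <- rep(if (is.finite(C)) C else 1e6, n)
  sol <- NULL
  for (ridge in scale_ridge * c(1e-12, 1e-9, 1e-6)) {
    sol <- tryCatch(
      kernlab::ipop(c = matrix(rep(-1, n)), H = H0 + diag(ridge, n),
                    A = matrix(t, 1), b = 0, l = rep(0, n), u = upper,
                    r = 0, sigf = 12, maxiter = 400),
      error = function(e) NULL)
    if (!is.null(sol)) break
  }
  if (is.null(sol))
    stop("solver failure: dual optimization did not converge ",
         "(classes may not be linearly separable; try a finite C)")
  alpha <- as.numeric(kernlab::primal(sol))
  alpha[alpha < 1e-8 * max(alpha)] <- 0
  sv <- which(alpha > 0)
  if (length(sv) == 0) stop("solver failure: no support vectors found")
  w <- colSums(alpha * t * Xc)
  margin_sv <- sv[alpha[sv] < 0.999 * upper[sv]]  # on-margin SVs define b
  if (length(margin_sv) == 0) margin_sv <- sv
  b <- mean(t[margin_sv] - Xc[margin_sv, , drop = FALSE] %*% w) - sum(w * mu)
  structure(list(alphas = alpha, support_idx = sv, w = w, b = b,
                 label_pair = as.integer(label_pair), targets = t,
                 features = X),
            class = "binary_svm")
}

#' Binary SVM decision value and sign
#'
#' `f(u) = w . u + b`; the sign assigns `u` to `label_pair[1]` (negative) or
#' `label_pair[2]` (positive).
#'
#' @param model a `binary_svm`.
#' @param x numeric feature vector.
#' @return the winning label of `label_pair`, with the decision value as
#'   attribute `"decision"`.
#' @export
svm_decide_binary <- function(model, x) {
  f <- sum(model$w * x) + model$b
  lab <- if (f >= 0) model$label_pair[2] else model$label_pair[1]
  structure(lab, decision = f)
}

#' Train a one-vs-one multiclass SVM
#'
#' Trains one binary maximum-margin classifier per unordered pair of classes
#' on the (per-sensor standardized) training features, and stores the class
#' mean vectors for vote tie-breaking.
#'
#' @param train a `labeled_dataset`.
#' @param C soft-margin constraint passed to [svm_train_binary()]
#'   (default 10; use `Inf` for the hard-margin dual).
#' @param standardize z-score features on the training split (default TRUE).
#' @return an object of class `multiclass_svm`.
#' @export
svm_train_multiclass <- function(train, C = 10, standardize = TRUE) {
  scaler <- if (standardize) fit_scaler(train$features) else NULL
  X <- if (standardize) apply_scaler(scaler, train$features) else train$features
  labs <- sort(unique(train$labels))
  if (length(labs) < 2) stop("need at least two classes")
  models <- list()
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (j <= i) next
    key <- paste(labs[i], labs[j], sep = "_")
    models[[key]] <- svm_train_binary(X[train$labels == labs[i], , drop = FALSE],
                                      X[train$labels == labs[j], , drop = FALSE],
                                      C = C, label_pair = c(labs[i], labs[j]))
  }
  means <- t(vapply(labs, function(m) colMeans(X[train$labels == m, ,
                                                 drop = FALSE]),
                    numeric(ncol(X))))
  structure(list(models = models, class_means = means,
                 class_labels = as.integer(labs), scaler = scaler),
            class = "multiclass_svm")
}

#' Classify a measurement by pairwise SVM plurality voting
#'
#' Every pairwise binary model votes by the sign of its decision function;
#' the plurality label wins, with vote ties broken toward the tied class
#' whose mean vector is Euclidean-nearest to the input. Closed world: the
#' outcome is always a trained label, never a rejection.
#'
#' @param model a `multiclass_svm`.
#' @param x numeric feature vector.
#' @return an `enose_prediction` (never rejected).
#' @export
svm_predict_multiclass <- function(model, x) {
  x <- as_feature_vector(x, ncol(model$class_means))
  if (!is.null(model$scaler)) x <- as.numeric(apply_scaler(model$scaler, x))
  labs <- model$class_labels
  if (length(model$models) != choose(length(labs), 2))
    stop("configuration error: missing pairwise model")
  votes <- stats::setNames(rep(0L, length(labs)), labs)
  for (bm in model$models) {
    winner <- as.character(svm_decide_binary(bm, x))
    votes[winner] <- votes[winner] + 1L
  }
  top <- labs[votes == max(votes)]
  if (length(top) == 1L) return(prediction(top))
  d2 <- rowSums(sweep(model$class_means[match(top, labs), , drop = FALSE],
                      2, x)^2)
  prediction(top[which.min(d2)], tie_classes = top)
}
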