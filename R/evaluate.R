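#' Trained-class test report (misclassification / correct classification)
#'
#' Scores predictions on test rows drawn from the trained classes. A
#' prediction is correct iff its outcome equals the true label; rejections
#' and unknown-class outcomes both count as misclassifications (a
#' trained-class odor the system failed to assign to its class). Percentages
#' are on base `n_test`, printed to 4 decimal places with halves rounded
#' away from zero (so 1/54 reports as 1.8519).
#'
#' @param preds list of `enose_prediction`s.
#' @param labels integer true labels, same length.
#' @return an object of class `trained_class_report` with counts `n_test`,
#'   `n_misclassified`, `n_correct` and percentages `pct_misclassified`,
#'   `pct_correct`.
#' @export
evaluate_trained <- function(preds, labels) {
  if (length(preds) != length(labels))
    stop("input error: predictions and labels differ in length")
  if (length(preds) == 0) stop("input error: empty prediction list")
  out <- outcomes(preds)
  n_correct <- sum(!is.na(out) & out == labels)
  n <- length(preds)
  structure(list(n_test = n, n_misclassified = n - n_correct,
                 n_correct = n_correct,
                 pct_misclassified = round_half_away(100 * (n - n_correct) / n, 4),
                 pct_correct = round_half_away(100 * n_correct / n, 4)),
            class = "trained_class_report")
}

#' @export
print.trained_class_report <- function(x, ...) {
  cat(sprintf("<trained-class report: %d/%d misclassified (%.4f%%), %d/%d correct (%.4f%%)>\n",
              x$n_misclassified, x$n_test, x$pct_misclassified,
              x$n_correct, x$n_test, x$pct_correct))
  invisible(x)
}

#' Irrelevant-class (open-set) report
#'
#' Scores predictions on rows from odor classes excluded from training.
#' Outcomes partition three ways: a trained-class label is a false positive
#' (false alarm), an out-of-range label is an unknown-class assignment, and
#' a rejection is a true negative (correct rejection). Percentages are on
#' base `n_irrelevant`, 4 decimal places.
#'
#' @param preds list of `enose_prediction`s on irrelevant rows only.
#' @param n_trained_classes number of trained classes M (labels `1..M`
#'   count as false positives).
#' @return an object of class `irrelevant_report` with counts
#'   `n_irrelevant`, `n_false_positive`, `n_unknown`, `n_rejected` and the
#'   matching `pct_*` fields.
#' @export
evaluate_irrelevant <- function(preds, n_trained_classes) {
  if (length(preds) == 0) stop("input error: empty prediction list")
  out <- outcomes(preds)
  rej <- vapply(preds, is_rejected, logical(1))
  fp <- sum(!rej & out >= 1 & out <= n_trained_classes)
  unk <- sum(!rej & (out < 1 | out > n_trained_classes))
  n <- length(preds)
  pct <- function(k) round_half_away(100 * k / n, 4)
  structure(list(n_irrelevant = n, n_false_positive = fp, n_unknown = unk,
                 n_rejected = sum(rej), pct_false_positive = pct(fp),
                 pct_unknown = pct(unk), pct_rejected = pct(sum(rej))),
            class = "irrelevant_report")
}

#' @export
print.irrelevant_report <- function(x, ...) {
  cat(sprintf("<irrelevant report (n=%d): %d false positive (%.4f%%), %d unknown (%.4f%%), %d rejected (%.4f%%)>\n",
              x$n_irrelevant, x$n_false_positive, x$pct_false_positive,
              x$n_unknown, x$pct_unknown, x$n_rejected, x$pct_rejected))
  invisible(x)
}

#' Coefficient of determination of label-valued predictions
#'
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares about the
#' target mean. For classifiers whose outputs are class labels the numeric
#' outcome is used; rejected predictions carry no numeric outcome and must
#' be excluded pairwise by the caller.
#'
#' @param preds numeric predicted values.
#' @param targets numeric targets, same length.
#' @return scalar R-squared.
#' @export
r_squared <- function(preds, targets) {
  if (length(preds) != length(targets) || length(preds) == 0)
    stop("input error: need equal nonempty lengths")
  ss_tot <- sum((targets - mean(targets))^2)
  if (ss_tot == 0) stop("undefined value: targets have zero variance")
  1 - sum((preds - targets)^2) / ss_tot
}

# Train one model under its protocol and return predictions on test rows
# and on the irrelevant rows.
fit_and_score <- function(name, trained_ds, irrelevant_X, seed, hyper) {
  fractions <- if (name %in% c("knn", "svm")) c(0.7, 0, 0.3)
               else c(0.7, 0.15, 0.15)
  sp <- stratified_split(trained_ds, fractions, seed = derive_seed(seed, "split"))
  tr <- ds_subset(trained_ds, sp$train_idx)
  va <- if (length(sp$val_idx) > 0) ds_subset(trained_ds, sp$val_idx) else tr
  te <- ds_subset(trained_ds, sp$test_idx)
  model <- switch(name,
    mmm = train_mmm(tr, va, eta = hyper$eta, error_threshold = hyper$error_threshold,
                    max_rounds = hyper$max_rounds),
    knn = knn_model(tr, k = hyper$k),
    svm = svm_train_multiclass(tr, C = hyper$C),
    mlp = mlp_train(tr, va, eta = hyper$mlp_eta, max_epochs = hyper$max_epochs,
                    seed = derive_seed(seed, "init")),
    grnn = grnn_tune_sigma(tr, va, sigma_grid = hyper$grnn_sigma_grid,
                           reject_threshold = hyper$reject_threshold),
    rbfnn = rbfnn_train(tr, va, sigma_grid = hyper$rbf_sigma_grid),
    stop("unknown model name: ", name))
  list(model = model,
       test = evaluate_trained(predict_all(model, te), te$labels),
       irrelevant = evaluate_irrelevant(predict_all(model, irrelevant_X),
                                        length(trained_ds$n_per_class)))
}

#' Default hyperparameters for the model comparison
#'
#' @return named list of hyperparameters: MMM expansion rate 0.1111 (11.11%
#'   of the class standard deviations), error threshold 0.02, 10 rounds;
#'   k-NN k = 3; SVM soft-margin C = 10; MLP learning rate 0.01; GRNN
#'   spreading-factor grid starting at 0.03 with kernel-sum rejection
#'   threshold 1e-6; RBFNN width grid 0.1-1.
#' @export
default_hyperparameters <- function() {
  list(eta = 0.1111, error_threshold = 0.02, max_rounds = 10L,
       k = 3L, C = 10, mlp_eta = 0.01, max_epochs = 300L,
       grnn_sigma_grid = c(0.03, 0.1, 0.3, 1),
       rbf_sigma_grid = c(0.1, 0.3, 0.5, 1),
       reject_threshold = 1e-6)
}

#' Run the full open-set model comparison
#'
#' For each seed: generate the synthetic design, fit the trained-class
#' hyperboxes, push the irrelevant classes outside them at the configured
#' separation margin, train every selected model under its split protocol
#' (70/30 for k-NN and SVM, 70/15/15 for the rest), and evaluate both the
#' trained-class test report and the irrelevant-class report. Reports are
#' averaged over seeds (mean counts may be fractional).
#'
#' @param cfg a `generator_config` (e.g. [default_design()]).
#' @param models character vector of model names among
#'   `c("mmm", "knn", "svm", "mlp", "grnn", "rbfnn")`.
#' @param seeds integer vector of run seeds (one simulation per seed).
#' @param hyper hyperparameter list, see [default_hyperparameters()].
#' @return an object of class `comparison_report`: per-model list with
#'   `per_seed` reports and `mean` averaged reports; failed runs are
#'   recorded and excluded from means with a warning.
#' @export
run_comparison <- function(cfg, models = c("mmm", "knn", "svm", "grnn"),
                           seeds = 1:10, hyper = default_hyperparameters()) {
  if (length(seeds) < 1) stop("need at least one seed")
  res <- stats::setNames(vector("list", length(models)), models)
  for (nm in models) res[[nm]] <- list(per_seed = list(), failures = list())
  for (s in seeds) {
    cfg_s <- cfg
    cfg_s$seed <- derive_seed(s, "generate")
    ds0 <- generate_features(cfg_s)
    trained0 <- ds_subset(ds0, which(!ds0$irrelevant))
    sp <- stratified_split(trained0, c(0.7, 0.15, 0.15),
                           seed = derive_seed(s, "split"))
    boxes <- fit_mmm(ds_subset(trained0, sp$train_idx))
    cfg_sep <- if (cfg_s$separation_margin > 0)
      enforce_separation(cfg_s, boxes) else cfg_s
    ds <- generate_features(cfg_sep)
    trained_ds <- ds_subset(ds, which(!ds$irrelevant))
    irrelevant_X <- ds$features[ds$irrelevant, , drop = FALSE]
    for (nm in models) {
      r <- tryCatch(fit_and_score(nm, trained_ds, irrelevant_X, s, hyper),
                    error = function(e) e)
      if (inherits(r, "error")) {
        warning(sprintf("model %s failed for seed %d: %s", nm, s,
                        conditionMessage(r)))
        res[[nm]]$failures[[as.character(s)]] <- conditionMessage(r)
      } else {
        res[[nm]]$per_seed[[as.character(s)]] <-
          list(test = r$test, irrelevant = r$irrelevant)
      }
    }
  }
  avg <- function(reports, fields) {
    out <- lapply(fields, function(f)
      mean(vapply(reports, function(r) as.numeric(r[[f]]), numeric(1))))
    stats::setNames(out, fields)
  }
  for (nm in models) {
    ps <- res[[nm]]$per_seed
    if (length(ps) == 0) next
    res[[nm]]$mean <- list(
      test = avg(lapply(ps, `[[`, "test"),
                 c("n_test", "n_misclassified", "n_correct",
                   "pct_misclassified", "pct_correct")),
      irrelevant = avg(lapply(ps, `[[`, "irrelevant"),
                       c("n_irrelevant", "n_false_positive", "n_unknown",
                         "n_rejected", "pct_false_positive", "pct_unknown",
                         "pct_rejected")))
  }
  structure(list(models = res, seeds = seeds), class = "comparison_report")
}

#' Flatten a comparison report to a data frame
#'
#' One row per model with the averaged trained-class and irrelevant-class
#' metrics (the column structure of the misclassification and
#' correct-rejection tables).
#'
#' @param x a `comparison_report`.
#' @param ... unused.
#' @return a data.frame.
#' @export
as.data.frame.comparison_report <- function(x, ...) {
  rows <- lapply(names(x$models), function(nm) {
    m <- x$models[[nm]]$mean
    if (is.null(m)) return(NULL)
    data.frame(model = nm, n_test = m$test$n_test,
               n_misclassified = m$test$n_misclassified,
               pct_misclassified = m$test$pct_misclassified,
               pct_correct = m$test$pct_correct,
               n_irrelevant = m$irrelevant$n_irrelevant,
               n_false_positive = m$irrelevant$n_false_positive,
               pct_false_positive = m$irrelevant$pct_false_positive,
               n_unknown = m$irrelevant$n_unknown,
               pct_unknown = m$irrelevant$pct_unknown,
               n_rejected = m$irrelevant$n_rejected,
               pct_rejected = m$irrelevant$pct_rejected)
  })
  do.call(rbind, rows)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report: %d models x %d seeds>\n",
              length(x$models), length(x$seeds)))
  print(as.data.frame(x))
  invisible(x)
}
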