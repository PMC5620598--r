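#' Round half away from zero
#'
#' Percentages in evaluation reports are printed to a fixed number of decimal
#' places with ties rounded away from zero (so 1.85185... -> 1.8519), unlike
#' [base::round()]'s round-half-even rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Round a continuous classifier output to an integer class label
#'
#' Half-integer outputs round away from zero (2.5 -> 3).
#'
#' @param y numeric scalar or vector.
#' @return integer vector.
#' @export
round_label <- function(y) as.integer(round_half_away(y, 0))

#' Derive a stage seed from a global run seed
#'
#' One global seed fans out to per-stage seeds so that each pipeline stage
#' (generation, splitting, model initialization, ...) is independently
#' reproducible. The scheme is `(seed + 7919 * stage_index) mod (2^31 - 1)`,
#' with stage indices taken from a fixed registry of stage names.
#'
#' @param seed integer global seed.
#' @param stage character stage name, or an integer offset.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stages <- c(generate = 1L, split = 2L, init = 3L, shuffle = 4L,
              separation = 5L, comparison = 6L)
  idx <- if (is.character(stage)) {
    if (!stage %in% names(stages)) stop("unknown stage: ", stage)
    stages[[stage]]
  } else {
    as.integer(stage)
  }
  as.integer((as.numeric(seed) + 7919 * idx) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards (generation must be a pure function of its seed
# without clobbering the user's random stream).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a classifier prediction
#'
#' A prediction is either a class label (an integer: a trained-class label in
#' `1..M`, or an out-of-range "unknown class" label emitted by classifiers
#' with a numeric output), or a rejection ("unclassified": the input matched
#' no class region). Only classifiers with a closed decision boundary (MMM,
#' GRNN, RBFNN with thresholding) can reject.
#'
#' @param outcome integer class label, or `NA` when rejected.
#' @param rejected logical; `TRUE` for a rejection.
#' @param tie_classes integer labels tied before tie-breaking (empty if none).
#' @return an object of class `enose_prediction`.
#' @export
prediction <- function(outcome, rejected = FALSE, tie_classes = integer(0)) {
  if (rejected) outcome <- NA_integer_
  if (length(tie_classes) > 0 && !rejected && !(outcome %in% tie_classes))
    stop("outcome must be one of tie_classes when ties are reported")
  structure(list(outcome = as.integer(outcome), rejected = isTRUE(rejected),
                 tie_classes = as.integer(tie_classes)),
            class = "enose_prediction")
}

#' @export
print.enose_prediction <- function(x, ...) {
  if (x$rejected) cat("<prediction: REJECTED>\n")
  else if (length(x$tie_classes))
    cat(sprintf("<prediction: class %d (tie among %s)>\n", x$outcome,
                paste(x$tie_classes, collapse = ",")))
  else cat(sprintf("<prediction: class %d>\n", x$outcome))
  invisible(x)
}

#' Is a prediction a rejection?
#' @param p an `enose_prediction`.
#' @return logical.
#' @export
is_rejected <- function(p) isTRUE(p$rejected)

# Extract integer outcomes (NA for rejections) from a list of predictions.
outcomes <- function(preds) {
  vapply(preds, function(p) p$outcome, integer(1))
}

# Per-sensor z-score scaler fitted on training data. Constant sensors get
# scale 1 so they pass through centered but unscaled.
fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(scaler, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

# All-pairs / cross squared Euclidean distances (rows of A to rows of B).
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  d2
}

as_feature_vector <- function(x, n_sensors) {
  x <- as.numeric(x)
  if (length(x) != n_sensors)
    stop(sprintf("feature vector has length %d, expected %d sensors",
                 length(x), n_sensors))
  x
}
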