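#' Labeled e-nose feature dataset
#'
#' The canonical container for steady-state sensor features: a numeric matrix
#' whose rows are odor measurements and columns are sensor steady-state
#' voltages (volts), with an integer class label per row. Class labels are
#' 1-based and run `1..M`. An optional per-row `irrelevant` flag marks rows
#' drawn from odor classes excluded from training (the open-set test
#' material).
#'
#' @param features numeric matrix, rows = measurements, columns = sensors.
#' @param labels integer class labels (`1..M`), one per row.
#' @param class_names optional character vector of class names, length `M`.
#' @param irrelevant optional logical vector flagging out-of-training rows.
#' @return an object of class `labeled_dataset` with fields `features`,
#'   `labels`, `class_names`, `n_per_class`, `irrelevant`.
#' @export
labeled_dataset <- function(features, labels, class_names = NULL,
                            irrelevant = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) stop("features must be numeric")
  if (ncol(features) < 1) stop("need at least one sensor column")
  if (nrow(features) < 1) stop("empty dataset: no measurement rows")
  if (length(labels) != nrow(features))
    stop("labels length must equal the number of rows")
  if (any(labels != as.integer(labels)) || any(labels < 1))
    stop("labels must be positive integers (1..M)")
  labels <- as.integer(labels)
  M <- max(labels)
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(M))
  if (length(class_names) != M)
    stop("class_names must have one entry per class")
  if (is.null(irrelevant)) irrelevant <- rep(FALSE, nrow(features))
  if (length(irrelevant) != nrow(features))
    stop("irrelevant flag must have one entry per row")
  colnames(features) <- paste0("sensor_", seq_len(ncol(features)))
  structure(list(features = features, labels = labels,
                 class_names = class_names,
                 n_per_class = tabulate(labels, M),
                 irrelevant = as.logical(irrelevant)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d rows x %d sensors, %d classes%s>\n",
              nrow(x$features), ncol(x$features), length(x$n_per_class),
              if (any(x$irrelevant))
                sprintf(", %d irrelevant rows", sum(x$irrelevant)) else ""))
  invisible(x)
}

#' Number of rows / sensors / classes of a dataset
#' @param ds a `labeled_dataset`.
#' @return integer.
#' @export
n_measurements <- function(ds) nrow(ds$features)

#' @rdname n_measurements
#' @export
n_sensors <- function(ds) ncol(ds$features)

#' @rdname n_measurements
#' @export
n_classes <- function(ds) length(ds$n_per_class)

#' Row subset of a dataset
#'
#' Keeps the original class labelling (classes absent from the subset keep
#' their label numbers), so a validation subset of a 9-class set still refers
#' to classes `1..9`.
#'
#' @param ds a `labeled_dataset`.
#' @param idx integer row indices.
#' @return a `labeled_dataset`.
#' @export
ds_subset <- function(ds, idx) {
  if (length(idx) == 0) stop("empty dataset: no measurement rows selected")
  out <- labeled_dataset(ds$features[idx, , drop = FALSE], ds$labels[idx],
                         class_names = NULL, irrelevant = ds$irrelevant[idx])
  M <- length(out$n_per_class)  # max label present in the subset
  out$class_names <- ds$class_names[seq_len(M)]
  out
}

#' Read a feature table from CSV
#'
#' The canonical dialect is comma-separated with a header row
#' `sensor_1,...,sensor_N,label` and optionally a trailing logical
#' `irrelevant` column. Row order is preserved.
#'
#' @param path CSV file path.
#' @return a `labeled_dataset`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (!"label" %in% names(df)) stop("format error: missing 'label' column")
  sensor_cols <- setdiff(names(df), c("label", "irrelevant"))
  if (length(sensor_cols) < 1) stop("format error: no sensor columns")
  if (nrow(df) == 0) stop("empty dataset: file has a header but no rows")
  feat <- matrix(NA_real_, nrow(df), length(sensor_cols),
                 dimnames = list(NULL, sensor_cols))
  for (j in seq_along(sensor_cols)) {
    v <- suppressWarnings(as.numeric(df[[sensor_cols[j]]]))
    bad <- which(is.na(v) & !is.na(df[[sensor_cols[j]]]))
    if (length(bad) > 0)
      stop(sprintf("parse error: non-numeric cell at row %d, column '%s'",
                   bad[1], sensor_cols[j]))
    feat[, j] <- v
  }
  lab <- suppressWarnings(as.numeric(df$label))
  if (anyNA(lab)) stop(sprintf("parse error: non-numeric cell at row %d, column 'label'",
                               which(is.na(lab))[1]))
  irr <- if ("irrelevant" %in% names(df)) as.logical(df$irrelevant) else NULL
  labeled_dataset(feat, lab, irrelevant = irr)
}

#' Write a feature table to CSV
#'
#' Values are written with 17 significant digits so that a read-back
#' reproduces the doubles exactly.
#'
#' @param ds a `labeled_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ds, path) {
  df <- as.data.frame(apply(ds$features, 2, function(v) sprintf("%.17g", v)),
                      stringsAsFactors = FALSE)
  if (nrow(ds$features) == 1) df <- as.data.frame(t(df))
  names(df) <- colnames(ds$features)
  df$label <- ds$labels
  if (any(ds$irrelevant)) df$irrelevant <- ds$irrelevant
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified train/validation/test split
#'
#' Rows are shuffled within each class and partitioned per class according to
#' `fractions`; the split is deterministic for a fixed seed. Per-class sizes
#' are `floor(train frac * L)` for training, `floor(val frac * L)` for
#' validation, and the remainder for testing, which yields 14/3/3 per class
#' under the 70/15/15 protocol and 14/0/6 under 70/30 for classes of 20
#' replicates.
#'
#' @param ds a `labeled_dataset`.
#' @param fractions numeric triple `(train, val, test)` summing to 1; the
#'   validation fraction may be 0.
#' @param seed integer seed for the within-class shuffle.
#' @return an object of class `split_assignment` with fields `train_idx`,
#'   `val_idx`, `test_idx`, `fractions`, `seed`.
#' @export
stratified_split <- function(ds, fractions, seed = 1L) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three nonnegative numbers summing to 1")
  M <- length(ds$n_per_class)
  tr <- va <- te <- integer(0)
  with_seed(seed, {
    for (m in seq_len(M)) {
      rows <- which(ds$labels == m)
      L <- length(rows)
      if (L == 0) next
      n_tr <- floor(fractions[1] * L)
      n_va <- floor(fractions[2] * L)
      n_te <- L - n_tr - n_va
      sizes <- c(n_tr, n_va, n_te)
      if (any(fractions > 0 & sizes == 0))
        stop(sprintf("class %d has %d rows: too small for fractions (%s)",
                     m, L, paste(fractions, collapse = ", ")))
      rows <- rows[sample.int(L)]
      tr <- c(tr, rows[seq_len(n_tr)])
      if (n_va > 0) va <- c(va, rows[n_tr + seq_len(n_va)])
      if (n_te > 0) te <- c(te, rows[n_tr + n_va + seq_len(n_te)])
    }
  })
  structure(list(train_idx = tr, val_idx = va, test_idx = te,
                 fractions = fractions, seed = as.integer(seed)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment: %d train / %d val / %d test (%s)>\n",
              length(x$train_idx), length(x$val_idx), length(x$test_idx),
              paste(x$fractions, collapse = "/")))
  invisible(x)
}

#' Serialize / restore a split assignment as JSON
#'
#' @param split a `split_assignment`.
#' @param path JSON file path.
#' @return `split_to_json` returns `path` invisibly; `split_from_json`
#'   returns a `split_assignment`.
#' @export
split_to_json <- function(split, path) {
  jsonlite::write_json(
    list(train = split$train_idx, val = split$val_idx, test = split$test_idx,
         fractions = split$fractions, seed = split$seed),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname split_to_json
#' @export
split_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_idx = as.integer(x$train), val_idx = as.integer(x$val),
                 test_idx = as.integer(x$test),
                 fractions = as.numeric(x$fractions),
                 seed = as.integer(x$seed[1])),
            class = "split_assignment")
}
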