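#' Principal component analysis for sensor feature tables
#'
#' Centers the feature matrix on its column means, forms the sample
#' covariance matrix (denominator n − 1), and eigendecomposes it; components
#' are the eigenvectors sorted by descending eigenvalue. Each component's
#' sign is fixed so its largest-magnitude loading is positive, making score
#' plots reproducible.
#'
#' @param features numeric matrix, rows = measurements (at least 2).
#' @return an object of class `pca_model` with fields `mean_vector`,
#'   `components` (columns are orthonormal directions) and `eigenvalues`.
#' @export
fit_pca <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2)
    stop("degenerate input: PCA needs at least 2 rows")
  mu <- colMeans(features)
  Xc <- sweep(features, 2, mu)
  C <- crossprod(Xc) / (nrow(Xc) - 1)
  eig <- eigen(C, symmetric = TRUE)  # eigenvalues already descending
  comp <- eig$vectors
  for (j in seq_len(ncol(comp))) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  vals <- eig$values
  vals[vals < 0 & vals > -1e-10] <- 0  # clamp eigen() round-off
  structure(list(mean_vector = mu, components = comp, eigenvalues = vals),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model: %d components, leading variance %.4g>\n",
              length(x$eigenvalues), x$eigenvalues[1]))
  invisible(x)
}

#' Project features onto the leading principal components
#'
#' @param model a `pca_model`.
#' @param features numeric matrix to project.
#' @param n_components number of leading components to keep.
#' @return score matrix (rows = measurements, columns `pc1..pcK`).
#' @export
pca_transform <- function(model, features, n_components) {
  features <- as.matrix(features)
  if (n_components > ncol(model$components))
    stop("parameter error: n_components exceeds available components")
  sc <- sweep(features, 2, model$mean_vector) %*%
    model$components[, seq_len(n_components), drop = FALSE]
  colnames(sc) <- paste0("pc", seq_len(n_components))
  sc
}
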