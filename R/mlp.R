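#' Gradient of the per-sample squared error of the 3-layer perceptron
#'
#' The network is `y = w2 . h(W1' x + 1)` with tan-sigmoid hidden units
#' `h(a) = 2 / (1 + exp(-2a)) - 1` (i.e. `tanh(a)`), hidden biases fixed at
#' 1, and a single linear output neuron whose value is the class decision.
#' For the half squared error `0.5 * (y - t)^2` the backpropagated error
#' terms are `delta_out = y - t` for the output link and
#' `delta_j = (1 - h_j^2) * w2_j * delta_out` for each hidden node, giving
#' gradients `dE/dw2 = delta_out * h` and `dE/dW1[i,j] = delta_j * x_i`.
#'
#' @param W1 input-to-hidden weight matrix (N x J).
#' @param w2 hidden-to-output weight vector (length J).
#' @param x input feature vector (length N).
#' @param target numeric target (the integer class label).
#' @return list with `gW1`, `gw2`, `y` (network output), `h` (hidden output).
#' @export
mlp_gradient <- function(W1, w2, x, target) {
  a <- as.numeric(crossprod(W1, x)) + 1
  h <- tanh(a)
  y <- sum(w2 * h)
  d_out <- y - target
  d_hid <- (1 - h^2) * w2 * d_out
  list(gW1 = outer(x, d_hid), gw2 = d_out * h, y = y, h = h)
}

#' Train a multilayer perceptron by per-sample backpropagation
#'
#' A 3-layer network (N inputs, J tan-sigmoid hidden units with bias 1, one
#' linear output) regresses the integer class label directly. Weights start
#' uniform in (−0.5, 0.5); each epoch visits the training rows in a freshly
#' shuffled order, applying a stochastic gradient step of rate `eta` per
#' sample. After every epoch the validation mean squared error is recorded;
#' training stops at `max_epochs` or after 10 epochs without improvement,
#' and the weights with the best validation MSE are returned. Deterministic
#' for a fixed seed.
#'
#' @param train training `labeled_dataset`.
#' @param val validation `labeled_dataset`.
#' @param J hidden layer size (default 10).
#' @param eta learning rate (default 0.01).
#' @param max_epochs epoch limit (default 500).
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed for initialization and shuffling.
#' @return an object of class `mlp_model` with fields `W1`, `w2`, `J`,
#'   `eta`, `epochs_run`, `val_mse_history`, `n_classes`.
#' @export
mlp_train <- function(train, val, J = 10L, eta = 0.01, max_epochs = 500L,
                      patience = 10L, seed = 1L) {
  if (eta < 0) stop("eta must be nonnegative")
  X <- train$features; tgt <- train$labels
  Xv <- val$features; tv <- val$labels
  N <- ncol(X)
  val_mse <- function(W1, w2) {
    H <- tanh(Xv %*% W1 + 1)
    mean((as.numeric(H %*% w2) - tv)^2)
  }
  with_seed(seed, {
    W1 <- matrix(stats::runif(N * J, -0.5, 0.5), N, J)
    w2 <- stats::runif(J, -0.5, 0.5)
    hist <- numeric(0)
    best <- list(W1 = W1, w2 = w2, mse = Inf, epoch = 0L)
    stall <- 0L; epoch <- 0L
    while (epoch < max_epochs && stall < patience) {
      epoch <- epoch + 1L
      for (i in sample.int(nrow(X))) {
        g <- mlp_gradient(W1, w2, X[i, ], tgt[i])
        W1 <- W1 - eta * g$gW1
        w2 <- w2 - eta * g$gw2
      }
      mse <- val_mse(W1, w2)
      if (!is.finite(mse))
        stop("training error: MSE diverged; use a smaller eta")
      hist <- c(hist, mse)
      if (mse < best$mse - 1e-12) {
        best <- list(W1 = W1, w2 = w2, mse = mse, epoch = epoch)
        stall <- 0L
      } else stall <- stall + 1L
    }
    structure(list(W1 = best$W1, w2 = best$w2, J = as.integer(J), eta = eta,
                   epochs_run = epoch, val_mse_history = hist,
                   n_classes = length(train$n_per_class)),
              class = "mlp_model")
  })
}

#' Classify a measurement with a trained perceptron
#'
#' The continuous network output is rounded to the nearest integer (halves
#' away from zero). A rounded value inside `1..M` is that trained class; any
#' other value is an "unknown class" label — the network asserted a class
#' that was never trained, which counts as neither a trained assignment nor
#' a rejection in the open-set evaluation.
#'
#' @param model an `mlp_model`.
#' @param x numeric feature vector.
#' @return an `enose_prediction` (never rejected).
#' @export
mlp_predict <- function(model, x) {
  x <- as_feature_vector(x, nrow(model$W1))
  h <- tanh(as.numeric(crossprod(model$W1, x)) + 1)
  y <- sum(model$w2 * h)
  prediction(round_label(y))
}
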