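#' Serialize any trained model to JSON
#'
#' Every model type writes a JSON object with a `"type"` tag and its numeric
#' state at full double precision; [deserialize_model()] restores the
#' matching class.
#'
#' @param model a trained model object.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
serialize_model <- function(model, path) {
  ser_scaler <- function(s) if (is.null(s)) NULL
    else list(center = s$center, scale = s$scale)
  x <- switch(class(model)[1],
    hyperbox_model = list(type = "mmm", classes = model$class_labels,
                          Q = model$Q, V = model$V, U = model$U, S = model$S,
                          expansion = model$expansion),
    knn_model = list(type = "knn", k = model$k,
                     stored_features = model$stored_features,
                     stored_labels = model$stored_labels,
                     n_classes = model$n_classes,
                     scaler = ser_scaler(model$scaler)),
    multiclass_svm = list(type = "svm", class_labels = model$class_labels,
                          class_means = model$class_means,
                          scaler = ser_scaler(model$scaler),
                          models = lapply(model$models, function(b)
                            list(w = b$w, b = b$b, alphas = b$alphas,
                                 support_idx = b$support_idx,
                                 label_pair = b$label_pair))),
    mlp_model = list(type = "mlp", W1 = model$W1, w2 = model$w2, J = model$J,
                     eta = model$eta, epochs_run = model$epochs_run,
                     val_mse_history = model$val_mse_history,
                     n_classes = model$n_classes),
    grnn_model = list(type = "grnn", centers = model$centers,
                      targets = model$targets, sigma = model$sigma,
                      reject_threshold = model$reject_threshold,
                      n_classes = model$n_classes,
                      scaler = ser_scaler(model$scaler)),
    rbfnn_model = list(type = "rbfnn", centers = model$centers,
                       sigma = model$sigma, w2 = model$w2,
                       reject = model$reject,
                       reject_threshold = model$reject_threshold,
                       n_classes = model$n_classes,
                       scaler = ser_scaler(model$scaler)),
    stop("unsupported model class: ", class(model)[1]))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname serialize_model
#' @export
deserialize_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_scaler <- function(s) if (is.null(s)) NULL
    else list(center = as.numeric(s$center), scale = as.numeric(s$scale))
  switch(x$type,
    mmm = structure(list(Q = x$Q, V = x$V, U = x$U, S = x$S,
                         expansion = as.numeric(x$expansion),
                         class_labels = as.integer(x$classes)),
                    class = "hyperbox_model"),
    knn = structure(list(stored_features = x$stored_features,
                         stored_labels = as.integer(x$stored_labels),
                         k = as.integer(x$k),
                         n_classes = as.integer(x$n_classes),
                         scaler = de_scaler(x$scaler)),
                    class = "knn_model"),
    svm = structure(list(models = lapply(x$models, function(b)
                           structure(list(w = as.numeric(b$w),
                                          b = as.numeric(b$b),
                                          alphas = as.numeric(b$alphas),
                                          support_idx = as.integer(b$support_idx),
                                          label_pair = as.integer(b$label_pair)),
                                     class = "binary_svm")),
                         class_means = x$class_means,
                         class_labels = as.integer(x$class_labels),
                         scaler = de_scaler(x$scaler)),
                    class = "multiclass_svm"),
    mlp = structure(list(W1 = x$W1, w2 = as.numeric(x$w2),
                         J = as.integer(x$J), eta = as.numeric(x$eta),
                         epochs_run = as.integer(x$epochs_run),
                         val_mse_history = as.numeric(x$val_mse_history),
                         n_classes = as.integer(x$n_classes)),
                    class = "mlp_model"),
    grnn = structure(list(centers = x$centers,
                          targets = as.numeric(x$targets),
                          sigma = as.numeric(x$sigma),
                          reject_threshold = as.numeric(x$reject_threshold),
                          n_classes = as.integer(x$n_classes),
                          scaler = de_scaler(x$scaler)),
                     class = "grnn_model"),
    rbfnn = structure(list(centers = x$centers, sigma = as.numeric(x$sigma),
                           w2 = as.numeric(x$w2),
                           reject = isTRUE(x$reject),
                           reject_threshold = as.numeric(x$reject_threshold),
                           n_classes = as.integer(x$n_classes),
                           scaler = de_scaler(x$scaler)),
                      class = "rbfnn_model"),
    stop("unknown model type tag: ", x$type))
}
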