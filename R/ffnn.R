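# Single-hidden-layer feed-forward network trained without
# backpropagation: the flat weight vector is the crow search position, the
# training loss is the fitness function.

#' Network topology
#'
#' @param n_inputs Number of input features.
#' @param n_hidden Hidden units.
#' @param n_outputs Classes.
#' @param activation Hidden activation, `"tanh"` or `"logistic"`.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_inputs = 22, n_hidden = 10, n_outputs = 4,
                         activation = c("tanh", "logistic")) {
  activation <- match.arg(activation)
  stopifnot(n_inputs >= 1, n_hidden >= 1, n_outputs >= 1)
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden = as.integer(n_hidden),
                 n_outputs = as.integer(n_outputs),
                 activation = activation),
            class = "network_spec")
}

#' Number of free parameters of a network
#'
#' `(n_inputs + 1) * n_hidden + (n_hidden + 1) * n_outputs` (the +1 are
#' bias units). This is the dimension of the crow search space.
#'
#' @param spec A [network_spec()].
#' @return Integer parameter count.
#' @export
n_weights <- function(spec) {
  (spec$n_inputs + 1L) * spec$n_hidden + (spec$n_hidden + 1L) * spec$n_outputs
}

#' Decode a flat weight vector into the two layer matrices
#'
#' Encoding order (fixed): first the input-to-hidden matrix `W1`,
#' `(n_inputs + 1) x n_hidden`, column-major with the bias row first; then
#' hidden-to-output `W2`, `(n_hidden + 1) x n_outputs`, likewise. The
#' round-trip through [encode_weights()] is exact.
#'
#' @param spec A [network_spec()].
#' @param weights Numeric vector of length [n_weights()].
#' @return List with matrices `W1` and `W2`.
#' @export
decode_weights <- function(spec, weights) {
  np <- n_weights(spec)
  if (length(weights) != np) {
    stopf("weight vector has length %d; spec requires %d", length(weights), np)
  }
  n1 <- (spec$n_inputs + 1L) * spec$n_hidden
  list(W1 = matrix(weights[seq_len(n1)], spec$n_inputs + 1L, spec$n_hidden),
       W2 = matrix(weights[(n1 + 1L):np], spec$n_hidden + 1L, spec$n_outputs))
}

#' Flatten layer matrices into the search-space vector
#'
#' @param spec A [network_spec()].
#' @param layers List with `W1` and `W2` as from [decode_weights()].
#' @return Numeric vector of length [n_weights()].
#' @export
encode_weights <- function(spec, layers) {
  stopifnot(identical(dim(layers$W1), c(spec$n_inputs + 1L, spec$n_hidden)),
            identical(dim(layers$W2), c(spec$n_hidden + 1L, spec$n_outputs)))
  c(as.numeric(layers$W1), as.numeric(layers$W2))
}

#' Forward pass: class scores
#'
#' Input -> hidden (tanh or logistic) -> output, then a normalised
#' exponential over the output activations, so scores are non-negative and
#' each row sums to 1. With all-zero weights every class scores
#' `1 / n_outputs`.
#'
#' @param spec A [network_spec()].
#' @param weights Flat weight vector.
#' @param x Feature vector or matrix (rows = observations, columns must
#'   match `n_inputs`).
#' @return Score matrix, one row per observation, one column per class.
#' @export
ffnn_forward <- function(spec, weights, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != spec$n_inputs) {
    stopf("input has %d features; spec requires %d", ncol(x), spec$n_inputs)
  }
  ly <- decode_weights(spec, weights)
  act <- if (spec$activation == "tanh") tanh else stats::plogis
  h <- act(cbind(1, x) %*% ly$W1)
  s <- cbind(1, h) %*% ly$W2
  s <- exp(s - apply(s, 1, max))  # shift for numerical stability
  s / rowSums(s)
}

#' Classification loss of a weight vector
#'
#' `"cross_entropy"` (default): mean negative log-score of the true class;
#' `ln(n_outputs)` under uniform scores, 0 for a perfect scorer.
#' `"misclassification"`: fraction of argmax predictions differing from
#' the labels.
#'
#' @param spec A [network_spec()].
#' @param weights Flat weight vector.
#' @param x Feature matrix.
#' @param y Integer class labels in `1..n_outputs`.
#' @param type Loss type.
#' @return Non-negative scalar.
#' @export
ffnn_loss <- function(spec, weights, x, y,
                      type = c("cross_entropy", "misclassification")) {
  type <- match.arg(type)
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (nrow(x) == 0) stopf("ffnn_loss: empty dataset")
  y <- as.integer(y)
  stopifnot(all(y >= 1), all(y <= spec$n_outputs), length(y) == nrow(x))
  p <- ffnn_forward(spec, weights, x)
  if (type == "cross_entropy") {
    -mean(log(pmax(p[cbind(seq_len(nrow(p)), y)], 1e-300)))
  } else {
    mean(max.col(p, ties.method = "first") != y)
  }
}

#' Train the network with the crow search algorithm
#'
#' Features are z-scored per column with statistics from the training data
#' only (stored in the model and re-applied at prediction time); the flat
#' weight vector is then optimised by [csa_run()] over the box
#' `[-weight_bound, weight_bound]^d`, minimising the chosen loss on the
#' training set. No gradients are used.
#'
#' @param x Training feature matrix (or data frame of features).
#' @param y Class labels: factor or character/integer vector.
#' @param spec A [network_spec()]; `n_inputs`/`n_outputs` must match the
#'   data.
#' @param weight_bound Half-width `B` of the search box per weight.
#' @param loss `"cross_entropy"` or `"misclassification"`.
#' @param flock_size,flight_length,awareness_probability,max_iterations
#'   Crow search controls (see [csa_params()]).
#' @param standardize Z-score features before training (default `TRUE`).
#' @param seed RNG seed for the optimiser.
#' @return An object of class `eegcsa_model`: `spec`, `weights`, `center`,
#'   `scale`, `labels` (class-index order), `training` metadata (loss
#'   type, final loss, CSA params, fitness history, seed).
#' @export
ffnn_train <- function(x, y, spec = NULL, weight_bound = 5,
                       loss = c("cross_entropy", "misclassification"),
                       flock_size = 20, flight_length = 2,
                       awareness_probability = 0.1, max_iterations = 300,
                       standardize = TRUE, seed = 1) {
  loss <- match.arg(loss)
  x <- as.matrix(x)
  if (!is.factor(y)) y <- factor(y)
  labels <- levels(y)
  yi <- as.integer(y)
  if (is.null(spec)) {
    spec <- network_spec(n_inputs = ncol(x), n_outputs = length(labels))
  }
  if (ncol(x) != spec$n_inputs || length(labels) > spec$n_outputs) {
    stopf("data (%d features, %d classes) does not match network spec (%d inputs, %d outputs)",
          ncol(x), length(labels), spec$n_inputs, spec$n_outputs)
  }
  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale < 1e-12] <- 1
  } else {
    center <- rep(0, ncol(x))
    scale <- rep(1, ncol(x))
  }
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  params <- csa_params(dimension = n_weights(spec),
                       lower = -weight_bound, upper = weight_bound,
                       flock_size = flock_size, flight_length = flight_length,
                       awareness_probability = awareness_probability,
                       max_iterations = max_iterations, seed = seed)
  res <- csa_run(params, function(w) ffnn_loss(spec, w, z, yi, type = loss))
  structure(list(spec = spec, weights = res$best_position,
                 center = center, scale = scale, labels = labels,
                 training = list(loss = loss, final_loss = res$best_fitness,
                                 evaluations = res$evaluations,
                                 fitness_history = res$fitness_history,
                                 csa = params, seed = seed)),
            class = "eegcsa_model")
}

#' Predict task labels or class scores
#'
#' Applies the stored standardisation and forward pass; class = argmax of
#' the scores, ties broken deterministically toward the lowest class
#' index.
#'
#' @param object An `eegcsa_model`.
#' @param newdata Feature vector or matrix.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Character vector of labels, or the score matrix.
#' @export
predict.eegcsa_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else
    if (is.data.frame(newdata)) as.matrix(newdata) else matrix(newdata, nrow = 1)
  if (ncol(x) != object$spec$n_inputs) {
    stopf("newdata has %d features; model expects %d", ncol(x), object$spec$n_inputs)
  }
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  p <- ffnn_forward(object$spec, object$weights, z)
  if (type == "prob") {
    colnames(p) <- c(object$labels,
                     rep(NA, object$spec$n_outputs - length(object$labels)))
    return(p)
  }
  object$labels[pmin(max.col(p, ties.method = "first"), length(object$labels))]
}

#' @export
print.eegcsa_model <- function(x, ...) {
  cat(sprintf("FFNN (%d-%d-%d, %s) trained by crow search; final %s loss %.4g\n",
              x$spec$n_inputs, x$spec$n_hidden, x$spec$n_outputs,
              x$spec$activation, x$training$loss, x$training$final_loss))
  invisible(x)
}

#' Serialise a trained model to JSON
#'
#' @param model An `eegcsa_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(spec = unclass(model$spec), weights = model$weights,
              center = model$center, scale = model$scale,
              labels = model$labels,
              training = list(loss = model$training$loss,
                              final_loss = model$training$final_loss,
                              evaluations = model$training$evaluations,
                              seed = model$training$seed,
                              csa = unclass(model$training$csa)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialised model
#'
#' @param path JSON file written by [write_model()].
#' @return An `eegcsa_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- structure(obj$spec, class = "network_spec")
  spec$n_inputs <- as.integer(spec$n_inputs)
  spec$n_hidden <- as.integer(spec$n_hidden)
  spec$n_outputs <- as.integer(spec$n_outputs)
  structure(list(spec = spec, weights = as.numeric(obj$weights),
                 center = as.numeric(obj$center), scale = as.numeric(obj$scale),
                 labels = obj$labels, training = obj$training),
            class = "eegcsa_model")
}
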