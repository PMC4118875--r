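#' Fit a small neural-network classifier on PCA scores
#'
#' A single-hidden-layer feed-forward network with softmax output,
#' trained on global PCA scores (the usual dimensionality reduction
#' before a neural classifier on spectra), via [nnet::nnet()]. Training
#' is deterministic under `seed` (the seed fixes the random initial
#' weights). Prediction is the argmax of the softmax outputs; there is no
#' rejection option.
#'
#' @param train_scores Numeric matrix of input features (rows = spectra,
#'   columns = retained PC scores).
#' @param labels Class label per row.
#' @param width Hidden-layer width (default 8).
#' @param seed Seed for weight initialization (default 1).
#' @param maxit Optimizer iteration budget (default 300).
#' @param decay Weight decay (default 1e-4).
#' @return An object of class `ann_model`.
#' @export
fit_ann <- function(train_scores, labels, width = 8, seed = 1,
                    maxit = 300, decay = 1e-4) {
  train_scores <- as.matrix(train_scores)
  stopifnot(width >= 1, nrow(train_scores) == length(labels))
  classes <- unique(as.character(labels))
  y <- nnet::class.ind(factor(labels, levels = classes))
  net <- with_seed_local(seed, {
    nnet::nnet(train_scores, y, size = width, softmax = TRUE,
               maxit = maxit, decay = decay, trace = FALSE)
  })
  if (net$convergence != 0) {
    warning(sprintf("ANN optimizer stopped before convergence (final loss %.4g)",
                    net$value), call. = FALSE)
  }
  structure(list(net = net, classes = classes, width = as.integer(width),
                 input_dim = ncol(train_scores), seed = as.integer(seed)),
            class = "ann_model")
}

#' Predict classes with a fitted ANN model
#'
#' @param object An `ann_model`.
#' @param scores Feature matrix with `input_dim` columns.
#' @param ... Unused.
#' @return Character vector of assigned class labels.
#' @export
predict.ann_model <- function(object, scores, ...) {
  scores <- as.matrix(scores)
  if (ncol(scores) != object$input_dim) {
    stop(sprintf("expected %d input features, got %d", object$input_dim,
                 ncol(scores)), call. = FALSE)
  }
  prob <- stats::predict(object$net, scores, type = "raw")
  prob <- matrix(prob, nrow = nrow(scores))
  object$classes[max.col(prob, ties.method = "first")]
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("<ann_model> %d -> %d -> %d (softmax), seed %d\n",
              x$input_dim, x$width, length(x$classes), x$seed))
  invisible(x)
}
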