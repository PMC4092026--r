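#' Linear readout trained by Least Mean Squares
#'
#' One linear unit per class over the reservoir state vector plus a fixed
#' bias input of 1. Targets are one-hot coded (1 for the sample's class, 0
#' otherwise) and weights follow the LMS stochastic-gradient update
#' `w_i <- w_i + eta * (d - y) * x_i` per unit and sample. Classification is
#' by arg-max over unit outputs, ties broken by the lowest class index.
#'
#' @param n_classes Number of classes.
#' @param n_features State-vector length (reservoir size L).
#' @param learning_rate LMS step size eta (default 0.001).
#' @return A `linear_readout` with a zero-initialised
#'   `n_classes x (n_features + 1)` weight matrix (last column is the bias).
#' @export
linear_readout <- function(n_classes, n_features, learning_rate = 0.001) {
  stopifnot(n_classes >= 2, n_features >= 1, learning_rate > 0)
  structure(
    list(weights = matrix(0, n_classes, n_features + 1L),
         learning_rate = learning_rate,
         n_classes = as.integer(n_classes)),
    class = "linear_readout"
  )
}

#' @export
print.linear_readout <- function(x, ...) {
  cat(sprintf("<linear_readout> %d classes, %d state inputs + bias, eta=%g\n",
              x$n_classes, ncol(x$weights) - 1L, x$learning_rate))
  invisible(x)
}

readout_outputs <- function(readout, x) {
  drop(readout$weights %*% c(x, 1))
}

#' One LMS update on a single labelled state vector
#'
#' @param readout A [linear_readout()].
#' @param x State vector (finite, length `n_features`).
#' @param target_class Integer class label in `[1, n_classes]`.
#' @return The updated readout.
#' @export
lms_step <- function(readout, x, target_class) {
  stopifnot(all(is.finite(x)),
            target_class >= 1, target_class <= readout$n_classes)
  xb <- c(x, 1)
  y <- drop(readout$weights %*% xb)
  d <- as.numeric(seq_len(readout$n_classes) == target_class)
  readout$weights <- readout$weights +
    readout$learning_rate * tcrossprod(d - y, xb)
  readout
}

#' Train a readout with shuffled LMS passes
#'
#' @param states `L x N` matrix of state vectors (one column per sample).
#' @param labels Integer labels, one per column; every class in
#'   `[1, n_classes]` must occur.
#' @param n_classes Number of classes (default `max(labels)`).
#' @param epochs Shuffled passes over the data (default 20; 0 returns the
#'   zero-initialised readout).
#' @param learning_rate LMS step size (default 0.001).
#' @param seed Seed for the per-epoch shuffles.
#' @return A trained `linear_readout`.
#' @export
train_readout <- function(states, labels, n_classes = max(labels),
                          epochs = 20L, learning_rate = 0.001, seed = 1L) {
  states <- as.matrix(states)
  stopifnot(ncol(states) == length(labels))
  if (!all(seq_len(n_classes) %in% labels))
    stop("every class must appear in the training set", call. = FALSE)
  local_rng(seed)
  readout <- linear_readout(n_classes, nrow(states), learning_rate)
  W <- readout$weights
  eta <- learning_rate
  for (e in seq_len(epochs)) {
    for (i in sample.int(ncol(states))) {
      xb <- c(states[, i], 1)
      y <- drop(W %*% xb)
      d <- as.numeric(seq_len(n_classes) == labels[i])
      W <- W + eta * tcrossprod(d - y, xb)
    }
  }
  readout$weights <- W
  readout
}

#' Classify state vectors with a trained readout
#'
#' @param readout A trained `linear_readout`.
#' @param states A state vector, or an `L x N` matrix of them.
#' @return Integer predicted label(s); exact ties resolve to the lowest
#'   class index.
#' @export
classify <- function(readout, states) {
  states <- as.matrix(states)
  if (nrow(states) == ncol(readout$weights) - 1L) {
    scores <- readout$weights %*% rbind(states, 1)
  } else {
    stop("state dimension does not match the readout", call. = FALSE)
  }
  apply(scores, 2, which.max)
}

#' Classification accuracy on a labelled state set
#'
#' @param readout A trained `linear_readout`.
#' @param states `L x N` state matrix.
#' @param labels True labels (length N >= 1).
#' @return Fraction correct, in `[0, 1]`.
#' @export
readout_accuracy <- function(readout, states, labels) {
  if (length(labels) == 0L) stop("empty test set", call. = FALSE)
  mean(classify(readout, states) == labels)
}
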