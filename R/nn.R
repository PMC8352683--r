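#' Initialise a single-hidden-layer classification network
#'
#' The network has `n_in` input units (one per symptom), a single hidden layer
#' of `Y = 10 + n_in + n_out` sigmoid units, and `n_out` softmax output units,
#' trained with cross-entropy loss. Thresholds are carried as ordinary
#' connection weights: an extra input unit and an extra hidden unit are
#' clamped to the constant value -1, so `W_in` is `(n_in + 1) x Y` with the
#' last row holding the hidden thresholds `b_p`, and `W_out` is
#' `(Y + 1) x n_out` with the last row holding the output thresholds
#' `theta_q`. Weights are drawn i.i.d. uniform(-0.5, 0.5).
#'
#' @param n_in Number of input units (symptoms), at least 1.
#' @param n_out Number of output classes, at least 2.
#' @param eta Positive learning rate.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   parameter matrices.
#' @param classes Optional vector of class labels of length `n_out` (defaults
#'   to `1:n_out`); output unit `q` corresponds to `classes[q]`.
#' @return An object of class `symptom_nn`.
#' @export
nn_init <- function(n_in, n_out, eta = 0.1, seed = NULL, classes = NULL) {
  if (!is.numeric(n_in) || n_in < 1) stop("`n_in` must be >= 1", call. = FALSE)
  if (!is.numeric(n_out) || n_out < 2) stop("`n_out` must be >= 2", call. = FALSE)
  if (!is.numeric(eta) || eta <= 0) stop("`eta` must be > 0", call. = FALSE)
  n_in <- as.integer(n_in); n_out <- as.integer(n_out)
  n_hidden <- 10L + n_in + n_out
  if (is.null(classes)) classes <- seq_len(n_out)
  if (length(classes) != n_out) stop("`classes` must have length `n_out`", call. = FALSE)
  draw <- function() {
    list(W_in = matrix(stats::runif((n_in + 1L) * n_hidden, -0.5, 0.5),
                       n_in + 1L, n_hidden),
         W_out = matrix(stats::runif((n_hidden + 1L) * n_out, -0.5, 0.5),
                        n_hidden + 1L, n_out))
  }
  w <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(
    list(n_in = n_in, n_hidden = n_hidden, n_out = n_out, eta = eta,
         classes = classes, W_in = w$W_in, W_out = w$W_out, seed = seed,
         loss_history = numeric(0), epochs_run = 0L),
    class = "symptom_nn")
}

#' @export
print.symptom_nn <- function(x, ...) {
  cat(sprintf("<symptom_nn> %d-%d-%d (eta=%g, %d epochs trained)\n",
              x$n_in, x$n_hidden, x$n_out, x$eta, x$epochs_run))
  invisible(x)
}

#' Forward pass through the network
#'
#' Computes, for one symptom vector `x`: hidden inputs
#' `hn_p = sum_n w_np x_n - b_p` (via the constant -1 bias unit), sigmoid
#' hidden outputs `ho_p = 1 / (1 + exp(-hn_p))`, output inputs
#' `yn_q = sum_p w_pq ho_p - theta_q`, and the softmax outputs `yo`
#' (computed with max-subtraction for overflow safety).
#'
#' @param net A `symptom_nn`.
#' @param x Numeric 0/1 vector of length `net$n_in`.
#' @return A list with `hn`, `ho`, `yn`, `yo`.
#' @export
nn_forward <- function(net, x) {
  stopifnot(inherits(net, "symptom_nn"))
  if (length(x) != net$n_in) {
    stop(sprintf("input has length %d; network expects %d", length(x), net$n_in),
         call. = FALSE)
  }
  hn <- drop(crossprod(net$W_in, c(x, -1)))
  ho <- 1 / (1 + exp(-hn))
  yn <- drop(crossprod(net$W_out, c(ho, -1)))
  z <- yn - max(yn)
  yo <- exp(z) / sum(exp(z))
  list(hn = hn, ho = ho, yn = yn, yo = yo)
}

# Batched forward pass: X is n x n_in; returns the n x n_out softmax matrix.
nn_forward_mat <- function(net, X) {
  X <- as.matrix(X)
  if (ncol(X) != net$n_in) {
    stop(sprintf("input has %d columns; network expects %d", ncol(X), net$n_in),
         call. = FALSE)
  }
  HN <- cbind(X, -1) %*% net$W_in
  HO <- 1 / (1 + exp(-HN))
  YN <- cbind(HO, -1) %*% net$W_out
  Z <- YN - apply(YN, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Weighted cross-entropy loss
#'
#' `weight * (-sum_q d_q log(yo_q))`. The logarithm argument is clipped below
#' at 1e-12 to guard against underflow; genuinely non-positive probabilities
#' are a domain error.
#'
#' @param yo Softmax output vector (strictly positive, sums to 1).
#' @param d One-hot target vector.
#' @param weight Positive per-sample weight (default 1).
#' @return Non-negative scalar loss.
#' @export
nn_loss <- function(yo, d, weight = 1) {
  if (any(yo <= 0)) stop("output probabilities must be strictly positive", call. = FALSE)
  if (sum(d == 1) != 1 || sum(d) != 1) stop("`d` must be one-hot", call. = FALSE)
  if (weight <= 0) stop("`weight` must be > 0", call. = FALSE)
  weight * -sum(d * log(pmax(yo, 1e-12)))
}

#' Analytic loss gradients for one sample
#'
#' Backpropagation for the cross-entropy / softmax head: the output-layer
#' error term is `delta_q = yo_q - d_q`, giving
#' `d e / d w_pq = delta_q * ho_p` (with `ho_{Y+1} = -1` for the threshold
#' row); the hidden-layer term multiplies the back-propagated error by the
#' sigmoid derivative `exp(-hn) (1 + exp(-hn))^-2`. Both gradients scale
#' linearly with `weight`.
#'
#' @inheritParams nn_forward
#' @param d One-hot target of length `net$n_out`.
#' @param weight Positive per-sample weight.
#' @return A list with `dW_out` (`(Y+1) x n_out`) and `dW_in`
#'   (`(n_in+1) x Y`), the gradients of the weighted loss.
#' @export
nn_gradients <- function(net, x, d, weight = 1) {
  fw <- nn_forward(net, x)
  delta <- weight * (fw$yo - d)
  dW_out <- outer(c(fw$ho, -1), delta)
  sig_deriv <- exp(-fw$hn) * (1 + exp(-fw$hn))^-2
  sig <- drop(net$W_out[seq_len(net$n_hidden), , drop = FALSE] %*% delta) * sig_deriv
  dW_in <- outer(c(x, -1), sig)
  list(dW_out = dW_out, dW_in = dW_in)
}

#' Train the network by per-sample stochastic gradient descent
#'
#' Visits the samples in a freshly shuffled order each epoch and applies
#' `W <- W - eta * gradient` after every sample, per the update rules of the
#' backpropagation derivation. Training stops early when the mean epoch loss
#' improves by less than `tol` for `patience` consecutive epochs. Per-sample
#' weights are normalised to mean 1 before training so that a uniform weight
#' vector is exactly equivalent to unweighted training.
#'
#' @param net A `symptom_nn` (its `eta` is used).
#' @param X Numeric matrix/data frame of samples, `n x n_in`.
#' @param targets Either an `n x n_out` one-hot matrix, or a vector of class
#'   labels matching `net$classes`.
#' @param weights Optional positive per-sample weights (recycled scalar ok).
#' @param epochs Maximum number of epochs.
#' @param shuffle_seed Optional seed controlling the per-epoch visiting order
#'   (when `NULL` the current RNG stream is used).
#' @param tol,patience Early-stopping rule on mean epoch loss.
#' @return The trained `symptom_nn`, with `loss_history` (mean loss per epoch
#'   run) and `epochs_run` filled in.
#' @export
nn_train <- function(net, X, targets, weights = NULL, epochs = 200,
                     shuffle_seed = NULL, tol = 1e-6, patience = 10) {
  stopifnot(inherits(net, "symptom_nn"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 1) stop("training set is empty", call. = FALSE)
  if (ncol(X) != net$n_in) stop("X has wrong number of columns", call. = FALSE)
  D <- as_one_hot(targets, net)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- rep_len(weights, n)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  weights <- weights / mean(weights)
  draw_orders <- function() {
    vapply(seq_len(epochs), function(e) sample.int(n), integer(n))
  }
  orders <- if (is.null(shuffle_seed)) draw_orders() else
    withr::with_seed(shuffle_seed, draw_orders())
  orders <- matrix(orders, nrow = n)  # n x epochs, 1-based
  res <- nn_sgd_cpp(net$W_in, net$W_out, X, D, weights, net$eta, orders,
                    tol, as.integer(patience))
  if (res$diverged > 0) {
    stop(sprintf("training diverged (non-finite loss) at epoch %d", res$diverged),
         call. = FALSE)
  }
  net$W_in <- res$W_in
  net$W_out <- res$W_out
  net$loss_history <- c(net$loss_history, res$loss_history)
  net$epochs_run <- net$epochs_run + length(res$loss_history)
  net
}

as_one_hot <- function(targets, net) {
  if (is.matrix(targets)) {
    if (ncol(targets) != net$n_out) stop("target matrix has wrong width", call. = FALSE)
    if (any(rowSums(targets) != 1) || !all(targets %in% c(0, 1))) {
      stop("target rows must be one-hot", call. = FALSE)
    }
    return(targets)
  }
  idx <- match(targets, net$classes)
  if (anyNA(idx)) {
    stop(sprintf("unknown class label(s): %s",
                 paste(unique(targets[is.na(idx)]), collapse = ", ")), call. = FALSE)
  }
  D <- matrix(0, length(idx), net$n_out)
  D[cbind(seq_along(idx), idx)] <- 1
  D
}

#' Fit a network classifier to labelled symptom data
#'
#' Convenience wrapper: builds the one-hot targets from the labels, draws the
#' initial weights and the shuffling orders from a single seeded RNG stream,
#' and trains.
#'
#' @param X Samples, `n x N`.
#' @param labels Class label per sample.
#' @param classes Optional full class set (taxonomy order); defaults to
#'   `sort(unique(labels))`.
#' @param eta,epochs,weights,tol,patience Passed to [nn_init()]/[nn_train()].
#' @param seed Optional seed governing initialisation and shuffling.
#' @return A trained `symptom_nn`.
#' @export
fit_symptom_nn <- function(X, labels, classes = NULL, eta = 0.1, epochs = 200,
                           weights = NULL, seed = NULL, tol = 1e-6, patience = 10) {
  if (is.null(classes)) classes <- sort(unique(labels))
  if (length(classes) < 2) stop("at least two classes are required", call. = FALSE)
  run <- function() {
    net <- nn_init(ncol(as.matrix(X)), length(classes), eta = eta, classes = classes)
    nn_train(net, X, labels, weights = weights, epochs = epochs,
             tol = tol, patience = patience)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Predict classes or class probabilities
#'
#' Class prediction is `argmax_q yo_q`, with ties broken toward the lowest
#' output index (hence the lowest class in `net$classes` order).
#'
#' @param object A `symptom_nn`.
#' @param newdata Matrix or data frame of symptom vectors (or a single
#'   numeric vector).
#' @param type `"class"` for labels, `"prob"` for the softmax matrix.
#' @param ... Unused.
#' @export
predict.symptom_nn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  P <- nn_forward_mat(object, newdata)
  colnames(P) <- as.character(object$classes)
  if (type == "prob") return(P)
  object$classes[max.col(P, ties.method = "first")]
}

#' @export
tidy.symptom_nn <- function(x, ...) {
  w_in <- tibble::tibble(
    layer = "input_hidden",
    from = rep(seq_len(nrow(x$W_in)), ncol(x$W_in)),
    to = rep(seq_len(ncol(x$W_in)), each = nrow(x$W_in)),
    weight = as.vector(x$W_in))
  w_out <- tibble::tibble(
    layer = "hidden_output",
    from = rep(seq_len(nrow(x$W_out)), ncol(x$W_out)),
    to = rep(seq_len(ncol(x$W_out)), each = nrow(x$W_out)),
    weight = as.vector(x$W_out))
  dplyr::bind_rows(w_in, w_out)
}

#' @export
glance.symptom_nn <- function(x, ...) {
  tibble::tibble(
    n_in = x$n_in, n_hidden = x$n_hidden, n_out = x$n_out, eta = x$eta,
    epochs_run = x$epochs_run,
    final_loss = if (length(x$loss_history)) x$loss_history[length(x$loss_history)]
                 else NA_real_)
}

#' Plot the training loss curve of a network
#'
#' @param object A trained `symptom_nn`.
#' @param ... Unused.
#' @return A ggplot object (mean cross-entropy loss per epoch).
#' @export
autoplot.symptom_nn <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$loss_history),
                       loss = object$loss_history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean cross-entropy loss")
}
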