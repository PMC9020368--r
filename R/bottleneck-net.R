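#' Fit a bottleneck network to a behavioral matrix
#'
#' Trains a fully connected feed-forward network with a single hidden layer of
#' `R` units (the "descending neurons") to map the `N` one-hot behavioral
#' commands onto the rows of the target behavioral matrix.  The network
#' computes
#' \deqn{a^{(1)} = W^{(1)\top} x - B^{(1)}, \qquad
#'       y = a^{(2)} = W^{(2)\top} \rho(a^{(1)}) - B^{(2)}}
#' with logistic activation \eqn{\rho(x) = 1/(1+e^{-x})}.  By default the
#' logistic function is applied to the output layer as well
#' (`y = \rho(a^{(2)})`); `sigmoid_output = FALSE` gives the linear-output
#' variant.  Training minimizes the mean-squared error
#' between `y` and the target rows by gradient descent with momentum over a
#' fixed number of epochs (no early stopping); an epoch is one pass over all
#' `N` commands, full-batch by default or shuffled mini-batches when
#' `batch_size` is given.  Outputs are binarized downstream by thresholding
#' at 0.5 (see [binarize()]), and a behavior counts as learned only when its
#' entire binarized output row matches the target row.
#'
#' Weights are initialized uniformly in
#' \eqn{[-1, 1]/\sqrt{\mathrm{fan\,in}}} and biases at zero, reproducibly
#' from `seed`.
#'
#' @param target a `behavior_matrix` (or plain binary matrix) of dimension
#'   `N x M`.
#' @param R hidden-layer (bottleneck) size, `R >= 1`.
#' @param epochs number of training epochs (default `1e5`, by which point
#'   the loss curve has flattened at the study's standard scale).
#' @param learning_rate gradient-descent step size.
#' @param momentum momentum coefficient in `[0, 1)`.
#' @param batch_size mini-batch size; `NULL` (default) trains full-batch.
#' @param seed integer seed controlling initialization (and the mini-batch
#'   shuffle, when used).
#' @param sigmoid_output apply the logistic function to the output layer as
#'   well (default).  `FALSE` leaves the output layer linear; that variant
#'   optimizes poorly near the bottleneck because the squared error then
#'   penalizes confident (overshooting) outputs that binarize correctly.
#' @param trace_every record the full-batch loss every this many epochs.
#' @return An object of class `bottleneck_net` with components
#'   \describe{
#'     \item{W1, B1, W2, B2}{trained weights (`N x R`, length `R`,
#'       `R x M`, length `M`).}
#'     \item{loss_trace}{data frame of `(epoch, loss)` samples.}
#'     \item{fitted}{raw (pre-binarization) `N x M` network outputs.}
#'     \item{binary}{binarized outputs.}
#'     \item{fraction_learned}{fraction of behaviors reproduced exactly.}
#'   }
#' @seealso [fraction_learned()], [perturb()], [capacity_sweep()]
#' @examples
#' b <- random_behaviors(10, 10, k = 3, seed = 1)
#' fit <- bottleneck_net(b, R = 10, epochs = 2000, seed = 1)
#' fit$fraction_learned
#' @export
bottleneck_net <- function(target, R, epochs = 1e5,
                           learning_rate = 1, momentum = 0.9,
                           batch_size = NULL, seed = NULL,
                           sigmoid_output = TRUE,
                           trace_every = max(1L, epochs %/% 1000L)) {
  tmat <- unclass(target)
  if (!is.matrix(tmat) || !all(tmat %in% c(0, 1)))
    stop("target must be a binary matrix", call. = FALSE)
  storage.mode(tmat) <- "double"
  N <- nrow(tmat); M <- ncol(tmat)
  if (length(R) != 1L || R < 1 || R != round(R))
    stop("R must be a positive integer", call. = FALSE)
  if (epochs < 1 || learning_rate <= 0 || momentum < 0 || momentum >= 1)
    stop("invalid training configuration", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  W1 <- matrix(stats::runif(N * R, -1, 1) / sqrt(N), N, R)
  W2 <- matrix(stats::runif(R * M, -1, 1) / sqrt(R), R, M)
  B1 <- numeric(R)
  B2 <- numeric(M)
  shuffle_seed <- if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed

  res <- cpp_train_bottleneck(tmat, W1, B1, W2, B2,
                              as.integer(epochs), learning_rate, momentum,
                              as.integer(if (is.null(batch_size)) 0L else batch_size),
                              as.integer(shuffle_seed),
                              as.integer(trace_every), sigmoid_output)
  if (res$diverged_at > 0)
    stop(sprintf("training diverged (non-finite loss) at epoch %d",
                 res$diverged_at), call. = FALSE)

  params <- list(W1 = res$W1, B1 = drop(res$B1),
                 W2 = res$W2, B2 = drop(res$B2))
  raw <- net_forward(params, sigmoid_output = sigmoid_output)
  bin <- binarize(raw)
  object <- list(
    W1 = params$W1, B1 = params$B1, W2 = params$W2, B2 = params$B2,
    N = N, R = as.integer(R), M = M,
    target = target,
    config = list(epochs = epochs, learning_rate = learning_rate,
                  momentum = momentum, batch_size = batch_size,
                  seed = seed, sigmoid_output = sigmoid_output),
    loss_trace = data.frame(epoch = res$trace_epoch, loss = res$trace_loss),
    fitted = raw,
    binary = bin,
    fraction_learned = mean(rowSums(bin != tmat) == 0L)
  )
  class(object) <- "bottleneck_net"
  object
}

#' Forward pass of a bottleneck network
#'
#' Evaluates the network on one-hot inputs.  `clamp_units`/`clamp_value`
#' force the listed hidden activations to a constant (1 for forced
#' activation, 0 for inhibition) while leaving every parameter untouched;
#' this is the exact limit of injecting an arbitrarily large weight into the
#' first weight matrix.
#'
#' @param params a `bottleneck_net` or a list with `W1`, `B1`, `W2`, `B2`.
#' @param inputs indices of the input commands to evaluate (default: all
#'   `N`), or an `n x N` matrix of one-hot rows.
#' @param clamp_units hidden units whose activation is overridden.
#' @param clamp_value the forced activation value (0 or 1).
#' @param sigmoid_output apply the logistic function to the output layer.
#' @return An `n x M` matrix of raw network outputs (not binarized).
#' @export
net_forward <- function(params, inputs = NULL, clamp_units = NULL,
                        clamp_value = 1,
                        sigmoid_output = isTRUE(params$config$sigmoid_output)) {
  N <- nrow(params$W1); R <- ncol(params$W1)
  if (is.null(inputs)) {
    A1 <- sweep(params$W1, 2L, params$B1)
  } else if (is.matrix(inputs)) {
    if (ncol(inputs) != N || !all(rowSums(inputs == 1) == 1L & rowSums(inputs) == 1))
      stop("inputs must be one-hot rows of length N", call. = FALSE)
    A1 <- sweep(inputs %*% params$W1, 2L, params$B1)
  } else {
    if (any(inputs < 1 | inputs > N))
      stop("input indices out of range", call. = FALSE)
    A1 <- sweep(params$W1[inputs, , drop = FALSE], 2L, params$B1)
  }
  H <- 1 / (1 + exp(-A1))
  if (!is.null(clamp_units)) {
    if (any(clamp_units < 1 | clamp_units > R))
      stop("hidden-unit index out of range", call. = FALSE)
    H[, clamp_units] <- clamp_value
  }
  Y <- sweep(H %*% params$W2, 2L, params$B2)
  if (sigmoid_output) Y <- 1 / (1 + exp(-Y))
  Y
}

#' Binarize network outputs
#'
#' Thresholds each entry with a Heaviside step centered at 0.5; an entry
#' exactly equal to 0.5 maps to 1.
#'
#' @param y numeric vector or matrix of network outputs.
#' @return Integer 0/1 object of the same shape.
#' @export
binarize <- function(y) {
  if (!all(is.finite(y))) stop("outputs must be finite", call. = FALSE)
  b <- (y >= 0.5) + 0L
  b
}

#' Fraction of behaviors learned
#'
#' A behavior is learned when the entire binarized output row for its one-hot
#' command equals the target row; per-entry accuracy is never substituted.
#'
#' @param object a `bottleneck_net`.
#' @param target target matrix to score against (defaults to the training
#'   target).
#' @return Fraction in `[0, 1]`.
#' @export
fraction_learned <- function(object, target = object$target) {
  tmat <- unclass(target)
  bin <- binarize(net_forward(object))
  if (!all(dim(bin) == dim(tmat)))
    stop("target dimensions do not match the network", call. = FALSE)
  mean(rowSums(bin != tmat) == 0L)
}

#' @export
print.bottleneck_net <- function(x, ...) {
  cat(sprintf("Bottleneck network: %d -> %d -> %d\n", x$N, x$R, x$M))
  cat(sprintf("  trained %s epochs (lr = %g, momentum = %g%s)\n",
              format(x$config$epochs, big.mark = ","),
              x$config$learning_rate, x$config$momentum,
              if (is.null(x$config$batch_size)) ", full batch"
              else sprintf(", batch size %d", x$config$batch_size)))
  cat(sprintf("  final MSE loss: %.3g\n", utils::tail(x$loss_trace$loss, 1)))
  cat(sprintf("  fraction of behaviors learned: %.3f\n", x$fraction_learned))
  invisible(x)
}

#' @export
summary.bottleneck_net <- function(object, ...) {
  res <- list(
    dims = c(N = object$N, R = object$R, M = object$M),
    config = object$config,
    final_loss = utils::tail(object$loss_trace$loss, 1),
    fraction_learned = object$fraction_learned,
    per_unit_accuracy = mean(object$binary == unclass(object$target)),
    hidden_saturation = {
      H <- 1 / (1 + exp(-sweep(object$W1, 2L, object$B1)))
      mean(pmin(H, 1 - H))
    })
  class(res) <- "summary.bottleneck_net"
  res
}

#' @export
print.summary.bottleneck_net <- function(x, ...) {
  cat(sprintf("Bottleneck network %d -> %d -> %d\n",
              x$dims["N"], x$dims["R"], x$dims["M"]))
  cat(sprintf("  final MSE loss:        %.3g\n", x$final_loss))
  cat(sprintf("  behaviors learned:     %.1f%%\n", 100 * x$fraction_learned))
  cat(sprintf("  per-entry accuracy:    %.1f%%\n", 100 * x$per_unit_accuracy))
  cat(sprintf("  hidden-layer distance from {0,1}: %.3f\n", x$hidden_saturation))
  invisible(x)
}

#' @export
coef.bottleneck_net <- function(object, ...) {
  list(W1 = object$W1, B1 = object$B1, W2 = object$W2, B2 = object$B2)
}

#' Predict motor output for behavioral commands
#'
#' @param object a `bottleneck_net`.
#' @param newdata command indices or a matrix of one-hot rows; default all.
#' @param type `"binary"` for thresholded motor patterns, `"response"` for
#'   raw outputs.
#' @param ... unused.
#' @return An `n x M` matrix.
#' @export
predict.bottleneck_net <- function(object, newdata = NULL,
                                   type = c("binary", "response"), ...) {
  type <- match.arg(type)
  y <- net_forward(object, inputs = newdata)
  if (type == "binary") binarize(y) else y
}

#' @export
fitted.bottleneck_net <- function(object, ...) object$fitted

#' @export
residuals.bottleneck_net <- function(object, ...) {
  object$fitted - unclass(object$target)
}

#' @export
plot.bottleneck_net <- function(x, ...) {
  graphics::plot(x$loss_trace$epoch, x$loss_trace$loss, type = "l",
                 log = "y", xlab = "epoch", ylab = "MSE loss",
                 main = sprintf("Training loss (%d -> %d -> %d)",
                                x$N, x$R, x$M), ...)
  invisible(x)
}

#' Persist and restore a trained network
#'
#' Saves the trained parameters, shapes, training configuration, loss trace
#' and final metrics as a single JSON archive, and restores a functional
#' `bottleneck_net` from it.  The training target travels with the archive
#' so scoring and perturbation analyses work on the restored object.
#'
#' @param object a fitted [bottleneck_net()].
#' @param file path of the JSON archive.
#' @return `write_network` returns `file` invisibly; `read_network` the
#'   restored `bottleneck_net`.
#' @export
write_network <- function(object, file) {
  stopifnot(inherits(object, "bottleneck_net"))
  payload <- list(
    dims = list(N = object$N, R = object$R, M = object$M),
    W1 = object$W1, B1 = object$B1, W2 = object$W2, B2 = object$B2,
    target = unclass(object$target), target_k = attr(object$target, "k"),
    config = object$config,
    loss_trace = object$loss_trace,
    fraction_learned = object$fraction_learned)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(file)
}

#' @rdname write_network
#' @export
read_network <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  target <- p$target
  storage.mode(target) <- "integer"
  object <- list(
    W1 = p$W1, B1 = p$B1, W2 = p$W2, B2 = p$B2,
    N = p$dims$N, R = as.integer(p$dims$R), M = p$dims$M,
    target = target,
    config = p$config,
    loss_trace = as.data.frame(p$loss_trace))
  class(object) <- "bottleneck_net"
  object$fitted <- net_forward(object)
  object$binary <- binarize(object$fitted)
  object$fraction_learned <- mean(rowSums(object$binary != target) == 0L)
  object
}
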