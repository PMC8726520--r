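# Stacked autoencoder for attribute compression.
#
# Greedy layer-wise pretraining of symmetric sigmoid autoencoders: each
# layer is trained to reconstruct its own input under mean-squared error
# by minibatch stochastic gradient descent, then its code feeds the next
# layer.  The final code width is the package's uniform 64-dim attribute
# width.

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -35), 35)))

#' Stacked-autoencoder settings
#'
#' @param widths Layer widths from input to code, strictly decreasing and
#'   ending in the code width.  `NULL` lets the caller derive widths from
#'   the data (see [node_attributes()]).
#' @param epochs Pretraining epochs per layer.
#' @param lr SGD learning rate.
#' @param batch_size Minibatch size.
#' @return A list of settings of class `sae_config`.
#' @export
sae_config <- function(widths = NULL, epochs = 50L, lr = 0.01,
                       batch_size = 16L) {
  structure(list(widths = widths, epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size)), class = "sae_config")
}

#' Train a stacked autoencoder
#'
#' @param x Input matrix (rows = samples).
#' @param widths Integer vector of widths, `widths[1] == ncol(x)`,
#'   strictly decreasing, last element 64.  A single width equal to
#'   `ncol(x)` yields an identity pass-through model (no training).
#' @param epochs,lr,batch_size SGD settings (see [sae_config()]).
#' @param seed Integer seed; fixes initialization and minibatch order.
#' @return Object of class `sae_model`: `layers` (list of `W1`, `b1` per
#'   encoder stage), `widths`, and `loss` (per-layer epoch-mean
#'   reconstruction loss traces).
#' @export
train_sae <- function(x, widths, epochs = 50L, lr = 0.01, batch_size = 16L,
                      seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 input rows to train")
  widths <- as.integer(widths)
  if (widths[1] != ncol(x))
    stop(sprintf("widths[1] (%d) must equal input width (%d)", widths[1], ncol(x)))
  if (length(widths) == 1L) {
    return(structure(list(layers = list(), widths = widths, loss = list()),
                     class = "sae_model"))
  }
  if (any(diff(widths) >= 0))
    stop("widths must be strictly decreasing to the code width")

  layers <- list()
  losses <- list()
  cur <- x
  with_local_seed(seed, {
    for (l in seq_len(length(widths) - 1L)) {
      n_in <- widths[l]; n_out <- widths[l + 1L]
      lim <- sqrt(6 / (n_in + n_out))
      W1 <- matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
      b1 <- numeric(n_out)
      W2 <- matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
      b2 <- numeric(n_in)
      n <- nrow(cur)
      trace <- numeric(epochs)
      for (ep in seq_len(epochs)) {
        ord <- sample.int(n)
        ep_loss <- 0
        for (start in seq(1L, n, by = batch_size)) {
          b_idx <- ord[start:min(start + batch_size - 1L, n)]
          xb <- cur[b_idx, , drop = FALSE]
          m <- nrow(xb)
          h <- sigmoid(sweep(xb %*% W1, 2, b1, "+"))
          xr <- sigmoid(sweep(h %*% W2, 2, b2, "+"))
          err <- xr - xb
          ep_loss <- ep_loss + sum(err^2)
          d_out <- 2 * err * xr * (1 - xr) / (m * n_in)
          d_hid <- (d_out %*% t(W2)) * h * (1 - h)
          W2 <- W2 - lr * t(h) %*% d_out
          b2 <- b2 - lr * colSums(d_out)
          W1 <- W1 - lr * t(xb) %*% d_hid
          b1 <- b1 - lr * colSums(d_hid)
          if (!all(is.finite(W1)) || !all(is.finite(W2)))
            stop(sprintf("non-finite autoencoder weights (lr = %g)", lr))
        }
        trace[ep] <- ep_loss / (n * n_in)
      }
      layers[[l]] <- list(W1 = W1, b1 = b1)
      losses[[l]] <- trace
      cur <- sigmoid(sweep(cur %*% W1, 2, b1, "+"))
    }
  })
  structure(list(layers = layers, widths = widths, loss = losses),
            class = "sae_model")
}

#' Encode rows through a trained stacked autoencoder
#'
#' @param object A `sae_model`.
#' @param x Matrix whose width matches the model input width.
#' @param ... Unused.
#' @return Matrix with the same rows and the code width (identity for a
#'   pass-through model).
#' @export
predict.sae_model <- function(object, x, ...) {
  x <- as.matrix(x)
  if (nrow(x) == 0L)
    return(matrix(numeric(0), 0L, object$widths[length(object$widths)]))
  if (ncol(x) != object$widths[1])
    stop(sprintf("input width %d does not match model width %d",
                 ncol(x), object$widths[1]))
  for (lay in object$layers)
    x <- sigmoid(sweep(x %*% lay$W1, 2, lay$b1, "+"))
  unname(x)
}

#' @export
print.sae_model <- function(x, ...) {
  cat(sprintf("stacked autoencoder: %s\n", paste(x$widths, collapse = " -> ")))
  if (length(x$loss))
    cat(sprintf("  final reconstruction loss per layer: %s\n",
                paste(signif(vapply(x$loss, function(t) t[length(t)],
                                    numeric(1)), 3), collapse = ", ")))
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}
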