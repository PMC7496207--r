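# Dense feed-forward network used by the voting ensemble:
#   input D -> 128 relu -> dropout 0.25 -> 64 relu -> dropout 0.5
#           -> 32 relu -> C softmax
# trained with categorical cross-entropy and Adam. Implemented with base-R
# matrix ops; the networks are small enough that BLAS-backed %*% keeps a
# full ensemble fit in seconds on one core.

relu <- function(z) z * (z > 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_init <- function(widths) {
  # He-normal initialization for relu layers, zero biases
  L <- length(widths) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- widths[l]
    W[[l]] <- matrix(rnorm(fan_in * widths[l + 1L], sd = sqrt(2 / fan_in)),
                     fan_in, widths[l + 1L])
    b[[l]] <- rep(0, widths[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X, dropout = NULL) {
  # dropout: list of keep-probability masks per hidden layer (train time,
  # inverted dropout) or NULL at prediction time
  L <- length(par$W)
  Z <- A <- vector("list", L)
  inp <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(inp %*% par$W[[l]], 2L, par$b[[l]], `+`)
    if (l < L) {
      A[[l]] <- relu(Z[[l]])
      if (!is.null(dropout) && !is.null(dropout[[l]])) {
        A[[l]] <- A[[l]] * dropout[[l]]
      }
    } else {
      A[[l]] <- softmax_rows(Z[[l]])
    }
    inp <- A[[l]]
  }
  list(Z = Z, A = A)
}

mlp_backward <- function(par, X, Y, fwd, dropout) {
  L <- length(par$W)
  n <- nrow(X)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- (fwd$A[[L]] - Y) / n           # softmax + cross-entropy
  for (l in rev(seq_len(L))) {
    inp <- if (l == 1L) X else fwd$A[[l - 1L]]
    gW[[l]] <- crossprod(inp, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(par$W[[l]])
      if (!is.null(dropout[[l - 1L]])) delta <- delta * dropout[[l - 1L]]
      delta <- delta * (fwd$Z[[l - 1L]] > 0)
    }
  }
  list(W = gW, b = gb)
}

adam_state <- function(par) {
  zero_like <- function(x) {
    lapply(x, function(w) if (is.matrix(w)) matrix(0, nrow(w), ncol(w))
           else rep(0, length(w)))
  }
  list(mW = zero_like(par$W), vW = zero_like(par$W),
       mb = zero_like(par$b), vb = zero_like(par$b), t = 0L)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(par$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grad$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grad$W[[l]]^2
    par$W[[l]] <- par$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grad$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grad$b[[l]]^2
    par$b[[l]] <- par$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(par = par, state = state)
}

#' Train one multilayer perceptron classifier
#'
#' Architecture: input D, hidden relu layers of 128, 64 and 32 units with
#' dropout 0.25 after the first and 0.5 after the second, softmax output
#' over the classes. Trained by minibatch Adam on the categorical
#' cross-entropy, fully reproducible from `seed`.
#'
#' @param X numeric matrix, cells x features (already preprocessed).
#' @param labels character vector of class labels, one per row of `X`.
#' @param class_order character vector fixing the output-unit order; must
#'   contain every label in `labels`.
#' @param epochs passes over the data, default 50.
#' @param batch_size minibatch size, default 64.
#' @param learning_rate Adam step size, default 1e-3.
#' @param hidden hidden-layer widths, default `c(128, 64, 32)`.
#' @param dropout_rates dropout probability after each hidden layer,
#'   default `c(0.25, 0.5, 0)`.
#' @param seed RNG seed (weight init, dropout masks, shuffling).
#' @return An object of class `"cellvote_mlp"`.
#' @export
mlp_train <- function(X, labels, class_order = sort(unique(labels)),
                      epochs = 50, batch_size = 64, learning_rate = 1e-3,
                      hidden = c(128, 64, 32),
                      dropout_rates = c(0.25, 0.5, 0), seed = 1L) {
  stopifnot(nrow(X) == length(labels), all(labels %in% class_order))
  stopifnot(length(dropout_rates) == length(hidden))
  n <- nrow(X)
  C <- length(class_order)
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), match(labels, class_order))] <- 1
  widths <- c(ncol(X), hidden, C)

  par <- NULL
  with_seed(seed, {
    par <- mlp_init(widths)
    state <- adam_state(par)
    keep <- 1 - dropout_rates
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        masks <- lapply(seq_along(hidden), function(l) {
          if (keep[l] >= 1) NULL else
            matrix(stats::rbinom(length(idx) * hidden[l], 1L, keep[l]),
                   length(idx), hidden[l]) / keep[l]
        })
        fwd <- mlp_forward(par, Xb, masks)
        grad <- mlp_backward(par, Xb, Yb, fwd, masks)
        upd <- adam_step(par, grad, state, learning_rate)
        par <- upd$par
        state <- upd$state
      }
    }
  })
  structure(list(par = par, class_order = class_order, widths = widths),
            class = "cellvote_mlp")
}

#' Class probabilities from a trained perceptron
#'
#' @param object a `"cellvote_mlp"`.
#' @param X cells x features matrix with the training feature order.
#' @param ... unused.
#' @return Cells x classes matrix of softmax probabilities (rows sum to 1).
#' @export
predict.cellvote_mlp <- function(object, X, ...) {
  stopifnot(ncol(X) == object$widths[1L])
  fwd <- mlp_forward(object$par, X, dropout = NULL)
  P <- fwd$A[[length(fwd$A)]]
  colnames(P) <- object$class_order
  rownames(P) <- rownames(X)
  P
}
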