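# Multilayer perceptron for binary classification on tabular data.
#
# Plain-R implementation (BLAS matrix products): fully-connected layers, ReLU
# or tanh activations, inverted dropout, sigmoid output trained by Adam on the
# binary cross-entropy with decoupled L2 weight decay. Dimensions here are
# small (tens of subjects, hundreds to thousands of features), so full-batch
# or small-minibatch training in R is fast and bit-reproducible under a seed.

mlp_init <- function(p, hidden) {
  dims <- c(p, hidden, 1L)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    # He initialisation, suited to ReLU
    W <- matrix(stats::rnorm(fan_in * dims[l + 1L], sd = sqrt(2 / fan_in)),
                fan_in, dims[l + 1L])
    layers[[l]] <- list(W = W, b = rep(0, dims[l + 1L]))
  }
  layers
}

mlp_act <- function(z, activation) {
  if (activation == "relu") pmax(z, 0) else tanh(z)
}

mlp_act_grad <- function(a, z, activation) {
  if (activation == "relu") (z > 0) * 1 else 1 - a^2
}

mlp_forward <- function(layers, x, activation, dropout = 0, training = FALSE) {
  a <- x
  cache <- list()
  L <- length(layers)
  for (l in seq_len(L)) {
    z <- sweep(a %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    if (l < L) {
      h <- mlp_act(z, activation)
      mask <- NULL
      if (training && dropout > 0) {
        mask <- matrix(stats::runif(length(h)) >= dropout, nrow(h), ncol(h)) / (1 - dropout)
        h <- h * mask
      }
      cache[[l]] <- list(a_in = a, z = z, mask = mask)
      a <- h
    } else {
      cache[[l]] <- list(a_in = a, z = z)
      a <- stats::plogis(z)
    }
  }
  list(out = as.numeric(a), cache = cache)
}

mlp_backward <- function(layers, cache, y, activation, dropout = 0) {
  L <- length(layers)
  n <- length(y)
  grads <- vector("list", L)
  # sigmoid + BCE: delta at the output is (p - y) / n
  p_hat <- stats::plogis(cache[[L]]$z)
  delta <- matrix((p_hat - y) / n, n, 1)
  for (l in rev(seq_len(L))) {
    a_in <- cache[[l]]$a_in
    grads[[l]] <- list(W = crossprod(a_in, delta), b = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(layers[[l]]$W)
      if (!is.null(cache[[l - 1]]$mask)) delta <- delta * cache[[l - 1]]$mask
      h <- mlp_act(cache[[l - 1]]$z, activation)
      delta <- delta * mlp_act_grad(h, cache[[l - 1]]$z, activation)
    }
  }
  grads
}

mlp_train <- function(x, y, hidden = c(64L, 32L), activation = "relu",
                      learning_rate = 0.01, weight_decay = 1e-4,
                      epochs = 200L, batch_size = Inf, dropout = 0.2,
                      seed = 1L) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  with_seed(seed, {
    layers <- mlp_init(ncol(x), as.integer(hidden))
    # Adam state
    m <- purrr::map(layers, ~ list(W = .x$W * 0, b = .x$b * 0))
    v <- m
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t <- 0L
    n <- nrow(x)
    bs <- if (!is.finite(batch_size)) n else min(as.integer(batch_size), n)
    for (epoch in seq_len(epochs)) {
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        fwd <- mlp_forward(layers, x[idx, , drop = FALSE], activation,
                           dropout = dropout, training = TRUE)
        grads <- mlp_backward(layers, fwd$cache, y[idx], activation, dropout)
        t <- t + 1L
        for (l in seq_along(layers)) {
          for (par in c("W", "b")) {
            g <- grads[[l]][[par]]
            if (par == "W" && weight_decay > 0) g <- g + weight_decay * layers[[l]][[par]]
            m[[l]][[par]] <- beta1 * m[[l]][[par]] + (1 - beta1) * g
            v[[l]][[par]] <- beta2 * v[[l]][[par]] + (1 - beta2) * g^2
            mhat <- m[[l]][[par]] / (1 - beta1^t)
            vhat <- v[[l]][[par]] / (1 - beta2^t)
            layers[[l]][[par]] <- layers[[l]][[par]] - learning_rate * mhat / (sqrt(vhat) + eps)
          }
        }
      }
    }
    structure(list(layers = layers, activation = activation, p = ncol(x)),
              class = "mzclass_mlp")
  })
}

mlp_predict <- function(model, x) {
  mlp_forward(model$layers, x, model$activation, training = FALSE)$out
}
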