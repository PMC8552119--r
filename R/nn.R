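# Minimal feed-forward engine backing the DeepLSE model: dense layers,
# batch normalization, inverted dropout, ReLU/sigmoid activations, and Adam.
# Layers are plain lists; forward passes cache what backward needs; all
# randomness (init, shuffling, dropout masks) comes from R's RNG so seeded
# runs are bit-reproducible.

nn_dense <- function(d_in, d_out) {
  limit <- sqrt(6 / (d_in + d_out))  # Glorot uniform
  list(kind = "dense",
       W = matrix(stats::runif(d_in * d_out, -limit, limit), d_in, d_out),
       b = numeric(d_out))
}

nn_bnorm <- function(d, momentum = 0.9, eps = 1e-5) {
  list(kind = "bnorm", gamma = rep(1, d), beta = numeric(d),
       rmean = numeric(d), rvar = rep(1, d), momentum = momentum, eps = eps)
}

nn_relu <- function() list(kind = "relu")
nn_sigmoid <- function() list(kind = "sigmoid")
nn_dropout <- function(rate) list(kind = "dropout", rate = rate)

# Forward through a layer list. In training mode batch-norm uses batch
# statistics (and updates running ones) and dropout draws fresh masks; in
# inference mode batch-norm uses running statistics and dropout is identity.
# Returns list(out, caches, layers) — layers returned because batch-norm
# running statistics mutate during training.
nn_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    lay <- layers[[i]]
    if (lay$kind == "dense") {
      caches[[i]] <- list(X = X)
      X <- X %*% lay$W
      X <- sweep(X, 2L, lay$b, "+")
    } else if (lay$kind == "bnorm") {
      if (training) {
        mu <- colMeans(X)
        Xc <- sweep(X, 2L, mu)
        v <- colMeans(Xc^2)
        inv_std <- 1 / sqrt(v + lay$eps)
        xhat <- sweep(Xc, 2L, inv_std, "*")
        lay$rmean <- lay$momentum * lay$rmean + (1 - lay$momentum) * mu
        lay$rvar <- lay$momentum * lay$rvar + (1 - lay$momentum) * v
        layers[[i]] <- lay
        caches[[i]] <- list(xhat = xhat, inv_std = inv_std)
      } else {
        inv_std <- 1 / sqrt(lay$rvar + lay$eps)
        xhat <- sweep(sweep(X, 2L, lay$rmean), 2L, inv_std, "*")
      }
      X <- sweep(sweep(xhat, 2L, lay$gamma, "*"), 2L, lay$beta, "+")
    } else if (lay$kind == "relu") {
      caches[[i]] <- list(mask = X > 0)
      X <- pmax(X, 0)
    } else if (lay$kind == "sigmoid") {
      X <- 1 / (1 + exp(-X))
      caches[[i]] <- list(out = X)
    } else if (lay$kind == "dropout") {
      if (training && lay$rate > 0) {
        mask <- matrix(stats::runif(length(X)) >= lay$rate,
                       nrow(X), ncol(X)) / (1 - lay$rate)
        caches[[i]] <- list(mask = mask)
        X <- X * mask
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    } else {
      stop("unknown layer kind: ", lay$kind)
    }
  }
  list(out = X, caches = caches, layers = layers)
}

# Backward through a layer list given the gradient of the loss w.r.t. the
# output. Returns list(dX, grads) with grads parallel to layers.
nn_backward <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    lay <- layers[[i]]
    cache <- caches[[i]]
    if (lay$kind == "dense") {
      grads[[i]] <- list(W = crossprod(cache$X, dY), b = colSums(dY))
      dY <- tcrossprod(dY, lay$W)
    } else if (lay$kind == "bnorm") {
      m <- nrow(dY)
      xhat <- cache$xhat
      grads[[i]] <- list(gamma = colSums(dY * xhat), beta = colSums(dY))
      dxhat <- sweep(dY, 2L, lay$gamma, "*")
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dY <- sweep(dxhat, 2L, s1 / m) - sweep(xhat, 2L, s2 / m, "*")
      dY <- sweep(dY, 2L, cache$inv_std, "*")
    } else if (lay$kind == "relu") {
      dY <- dY * cache$mask
    } else if (lay$kind == "sigmoid") {
      dY <- dY * cache$out * (1 - cache$out)
    } else if (lay$kind == "dropout") {
      if (!is.null(cache$mask)) dY <- dY * cache$mask
    }
  }
  list(dX = dY, grads = grads)
}

nn_adam_init <- function(layers) {
  lapply(layers, function(lay) {
    if (lay$kind == "dense") {
      list(W = list(m = lay$W * 0, v = lay$W * 0),
           b = list(m = lay$b * 0, v = lay$b * 0))
    } else if (lay$kind == "bnorm") {
      list(gamma = list(m = lay$gamma * 0, v = lay$gamma * 0),
           beta = list(m = lay$beta * 0, v = lay$beta * 0))
    } else NULL
  })
}

nn_adam_step <- function(layers, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      layers[[i]][[p]] <- layers[[i]][[p]] -
        lr * (st$m / corr1) / (sqrt(st$v / corr2) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

nn_softmax <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

nn_count_params <- function(layers) {
  sum(vapply(layers, function(lay) {
    switch(lay$kind,
           dense = length(lay$W) + length(lay$b),
           bnorm = length(lay$gamma) + length(lay$beta),
           0L)
  }, numeric(1)))
}
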