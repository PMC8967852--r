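# Minimal feed-forward / 1-D convolutional network engine.
#
# Models are plain R lists of layer lists, so checkpoints are deep copies
# and everything serializes naturally. Activations are cached on the layer
# during a training-mode forward pass; nn_backward consumes the caches and
# returns per-layer parameter gradients for the Adam step.
#
# Tensor conventions: dense activations are (batch x features) matrices;
# convolutional activations are (batch, channels, length) arrays.

new_layer <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "nn_layer")
}

# PyTorch-style uniform fan-in initialization
init_uniform <- function(dims, fan_in) {
  b <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -b, b), dim = dims)
}

layer_dense <- function(n_in, n_out) {
  new_layer("dense",
            W = init_uniform(c(n_in, n_out), n_in),
            b = init_uniform(c(n_out), n_in))
}

layer_conv1d <- function(in_ch, out_ch, k, p) {
  new_layer("conv1d", k = k, p = p,
            W = init_uniform(c(out_ch, in_ch, k), in_ch * k),
            b = init_uniform(c(out_ch), in_ch * k))
}

layer_bn <- function(n_features, momentum = 0.1, eps = 1e-5) {
  new_layer("batchnorm",
            gamma = rep(1, n_features), beta = rep(0, n_features),
            run_mean = rep(0, n_features), run_var = rep(1, n_features),
            momentum = momentum, eps = eps)
}

layer_act <- function(fun) new_layer("activation", fun = fun)
layer_dropout <- function(p) new_layer("dropout", p = p)
layer_maxpool <- function(k = 6, s = 2) new_layer("maxpool", k = k, s = s)
layer_flatten <- function() new_layer("flatten")

nn_trainable <- c("W", "b", "gamma", "beta")

# ---- forward -------------------------------------------------------------

pad_time <- function(A, p) {
  if (p == 0) return(A)
  d <- dim(A)
  out <- array(0, c(d[1], d[2], d[3] + 2 * p))
  out[, , (p + 1):(p + d[3])] <- A
  out
}

im2col <- function(Apad, k, L_out) {
  d <- dim(Apad)
  B <- array(0, c(d[1], d[2], k, L_out))
  for (j in seq_len(k)) B[, , j, ] <- Apad[, , j:(j + L_out - 1)]
  B <- aperm(B, c(1, 4, 2, 3))          # (batch, L_out, C, k)
  dim(B) <- c(d[1] * L_out, d[2] * k)
  B
}

forward_layer <- function(ly, X, training) {
  switch(ly$type,
    dense = {
      if (training) ly$cache_x <- X
      list(ly = ly, out = sweep(X %*% ly$W, 2, ly$b, "+"))
    },
    conv1d = {
      d <- dim(X)
      L_out <- d[3] + 2 * ly$p - ly$k + 1
      Apad <- pad_time(X, ly$p)
      Xcol <- im2col(Apad, ly$k, L_out)
      Wmat <- aperm(ly$W, c(2, 3, 1))
      dim(Wmat) <- c(d[2] * ly$k, dim(ly$W)[1])
      Y <- sweep(Xcol %*% Wmat, 2, ly$b, "+")
      dim(Y) <- c(d[1], L_out, dim(ly$W)[1])
      if (training) { ly$cache_xcol <- Xcol; ly$cache_dim <- d }
      list(ly = ly, out = aperm(Y, c(1, 3, 2)))
    },
    batchnorm = {
      nd <- length(dim(X))
      if (nd == 2) { ax <- 2; n_eff <- nrow(X) } else { ax <- 2; n_eff <- dim(X)[1] * dim(X)[3] }
      if (training) {
        mu <- apply(X, ax, mean)
        v <- apply(X, ax, function(z) mean((z - mean(z))^2))
        ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * mu
        ly$run_var <- (1 - ly$momentum) * ly$run_var + ly$momentum * v
      } else {
        mu <- ly$run_mean; v <- ly$run_var
      }
      sd_ <- sqrt(v + ly$eps)
      xhat <- bn_broadcast(X, mu, "-")
      xhat <- bn_broadcast(xhat, sd_, "/")
      out <- bn_broadcast(bn_broadcast(xhat, ly$gamma, "*"), ly$beta, "+")
      if (training) { ly$cache_xhat <- xhat; ly$cache_sd <- sd_; ly$cache_n <- n_eff }
      list(ly = ly, out = out)
    },
    activation = {
      out <- switch(ly$fun,
        relu = pmax(X, 0),
        leaky_relu = ifelse(X > 0, X, 0.01 * X),
        sigmoid = 1 / (1 + exp(-X)))
      if (training) { ly$cache_x <- X; ly$cache_out <- out }
      list(ly = ly, out = out)
    },
    dropout = {
      if (training && ly$p > 0) {
        mask <- array(stats::runif(length(X)) >= ly$p, dim = dim(X) %||% length(X))
        ly$cache_mask <- mask
        list(ly = ly, out = X * mask / (1 - ly$p))
      } else list(ly = ly, out = X)
    },
    maxpool = {
      d <- dim(X)
      L_out <- (d[3] - ly$k) %/% ly$s + 1
      pos1 <- seq(1L, by = ly$s, length.out = L_out)
      M <- X[, , pos1, drop = FALSE]
      idx <- array(1L, dim(M))
      for (j in 2:ly$k) {
        S <- X[, , pos1 + j - 1L, drop = FALSE]
        upd <- S > M
        M[upd] <- S[upd]
        idx[upd] <- j
      }
      if (training) { ly$cache_idx <- idx; ly$cache_dim <- d }
      list(ly = ly, out = M)
    },
    flatten = {
      d <- dim(X)
      if (training) ly$cache_dim <- d
      out <- X
      dim(out) <- c(d[1], prod(d[-1]))
      list(ly = ly, out = out)
    },
    stop("unknown layer type: ", ly$type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# elementwise op between a tensor and a per-channel vector
bn_broadcast <- function(X, v, op) {
  f <- match.fun(op)
  if (length(dim(X)) == 2 || is.null(dim(X))) {
    sweep(rbind(X), 2, v, op)
  } else {
    d <- dim(X)
    f(X, aperm(array(v, c(d[2], d[1], d[3])), c(2, 1, 3)))
  }
}

nn_forward <- function(model, X, training = FALSE) {
  for (i in seq_along(model$layers)) {
    r <- forward_layer(model$layers[[i]], X, training)
    model$layers[[i]] <- r$ly
    X <- r$out
  }
  list(model = model, out = X)
}

# ---- backward ------------------------------------------------------------

backward_layer <- function(ly, dY) {
  switch(ly$type,
    dense = {
      list(dX = dY %*% t(ly$W),
           grads = list(W = t(ly$cache_x) %*% dY, b = colSums(rbind(dY))))
    },
    conv1d = {
      d <- ly$cache_dim
      out_ch <- dim(ly$W)[1]
      dYp <- aperm(dY, c(1, 3, 2))
      L_out <- dim(dY)[3]
      dim(dYp) <- c(d[1] * L_out, out_ch)
      dWmat <- t(ly$cache_xcol) %*% dYp
      dim(dWmat) <- c(d[2], ly$k, out_ch)
      Wmat <- aperm(ly$W, c(2, 3, 1))
      dim(Wmat) <- c(d[2] * ly$k, out_ch)
      dXcol <- dYp %*% t(Wmat)
      dim(dXcol) <- c(d[1], L_out, d[2], ly$k)
      dXcol <- aperm(dXcol, c(1, 3, 4, 2))  # (batch, C, k, L_out)
      dApad <- array(0, c(d[1], d[2], d[3] + 2 * ly$p))
      for (j in seq_len(ly$k)) {
        rng <- j:(j + L_out - 1)
        dApad[, , rng] <- dApad[, , rng] + dXcol[, , j, ]
      }
      dX <- if (ly$p > 0) dApad[, , (ly$p + 1):(ly$p + d[3]), drop = FALSE] else dApad
      list(dX = dX, grads = list(W = aperm(dWmat, c(3, 1, 2)), b = colSums(dYp)))
    },
    batchnorm = {
      xhat <- ly$cache_xhat; sd_ <- ly$cache_sd; n <- ly$cache_n
      dxhat <- bn_broadcast(dY, ly$gamma, "*")
      sum_c <- function(A) apply(A, 2, sum)
      dgamma <- sum_c(dY * xhat)
      dbeta <- sum_c(dY)
      t1 <- bn_broadcast(dxhat, sd_, "/")
      t2 <- bn_broadcast(xhat, sum_c(dxhat * xhat) / (n * sd_), "*")
      t3 <- bn_broadcast(array(1, dim(dY) %||% length(dY)), sum_c(dxhat) / (n * sd_), "*")
      dX <- t1 - t2 - t3
      if (length(dim(dY)) == 2) dX <- as.matrix(dX)
      list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
    },
    activation = {
      dX <- switch(ly$fun,
        relu = dY * (ly$cache_x > 0),
        leaky_relu = dY * ifelse(ly$cache_x > 0, 1, 0.01),
        sigmoid = dY * ly$cache_out * (1 - ly$cache_out))
      list(dX = dX, grads = NULL)
    },
    dropout = {
      if (!is.null(ly$cache_mask)) {
        list(dX = dY * ly$cache_mask / (1 - ly$p), grads = NULL)
      } else list(dX = dY, grads = NULL)
    },
    maxpool = {
      d <- ly$cache_dim
      L_out <- dim(dY)[3]
      pos1 <- seq(1L, by = ly$s, length.out = L_out)
      dX <- array(0, d)
      for (j in seq_len(ly$k)) {
        contrib <- dY * (ly$cache_idx == j)
        rng <- pos1 + j - 1L
        dX[, , rng] <- dX[, , rng, drop = FALSE] + contrib
      }
      list(dX = dX, grads = NULL)
    },
    flatten = {
      dim(dY) <- ly$cache_dim
      list(dX = dY, grads = NULL)
    })
}

nn_backward <- function(model, dY) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    r <- backward_layer(model$layers[[i]], dY)
    grads[i] <- list(r$grads)   # [[<- would drop NULL entries and shift
    dY <- r$dX
  }
  grads
}

# drop forward caches (before storing a checkpoint)
nn_strip_cache <- function(model) {
  model$layers <- lapply(model$layers, function(ly) {
    ly[grep("^cache_", names(ly))] <- NULL
    ly
  })
  model
}

# ---- optimizer -----------------------------------------------------------

adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    ps <- intersect(names(ly), nn_trainable)
    if (!length(ps)) return(NULL)
    stats_ <- lapply(ly[ps], function(p) list(m = array(0, dim(p) %||% length(p)),
                                              v = array(0, dim(p) %||% length(p))))
    stats_
  })
}

adam_step <- function(model, grads, opt, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, t = 1) {
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (pn in names(g)) {
      gi <- g[[pn]]
      st <- opt[[i]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * gi
      st$v <- beta2 * st$v + (1 - beta2) * gi^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      model$layers[[i]][[pn]] <- model$layers[[i]][[pn]] - lr * mhat / (sqrt(vhat) + eps)
      opt[[i]][[pn]] <- st
    }
  }
  list(model = model, opt = opt)
}

# binary cross entropy and its gradient w.r.t. the sigmoid output
bce_loss <- function(p, y, clamp = 1e-7) {
  p <- pmin(pmax(p, clamp), 1 - clamp)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

bce_grad <- function(p, y, clamp = 1e-7) {
  p <- pmin(pmax(p, clamp), 1 - clamp)
  (-(y / p) + (1 - y) / (1 - p)) / length(y)
}
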