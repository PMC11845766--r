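# A small layer framework with hand-written backpropagation. Layers are
# environments holding parameters `p`, gradients `g`, optimizer state and
# a per-batch cache; networks are lists of layers. All tensors are native
# R arrays in [H, W, C, B] layout (images) or [B, F] matrices (features);
# the dense kernels live in src/conv_ops.cpp.

new_layer <- function(type, p = list(), hyper = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$p <- p
  e$g <- list()
  e$hyper <- hyper
  e$state <- list()
  e$cache <- NULL
  class(e) <- "nn_layer"
  e
}

layer_conv3x3 <- function(c_in, c_out, seed) {
  w <- with_seed(seed, {
    array(stats::rnorm(9 * c_in * c_out, sd = sqrt(2 / (9 * c_in))),
          dim = c(3L, 3L, c_in, c_out))
  })
  new_layer("conv3x3", p = list(w = w))
}

layer_bn2d <- function(c_ch, momentum = 0.9, eps = 1e-5) {
  l <- new_layer("bn2d", p = list(gamma = rep(1, c_ch),
                                  beta = rep(0, c_ch)),
                 hyper = list(momentum = momentum, eps = eps))
  l$state <- list(mean = rep(0, c_ch), var = rep(1, c_ch))
  l
}

layer_relu <- function() new_layer("relu")

layer_maxpool2 <- function() new_layer("maxpool2")

layer_gap <- function() new_layer("gap")

layer_bn1d <- function(n_f, momentum = 0.9, eps = 1e-5) {
  l <- new_layer("bn1d", p = list(gamma = rep(1, n_f), beta = rep(0, n_f)),
                 hyper = list(momentum = momentum, eps = eps))
  l$state <- list(mean = rep(0, n_f), var = rep(1, n_f))
  l
}

layer_dense <- function(n_in, n_out, seed) {
  lim <- sqrt(6 / (n_in + n_out))
  w <- with_seed(seed, matrix(stats::runif(n_in * n_out, -lim, lim),
                              n_in, n_out))
  new_layer("dense", p = list(w = w, b = rep(0, n_out)))
}

layer_dropout <- function(rate) {
  new_layer("dropout", hyper = list(rate = rate))
}

# One fused convolutional head (3 conv blocks + GAP) backed by the
# single-precision kernels in src/head_ops.cpp. Parameters and running
# statistics live on the R side; activations stay in a reusable C++
# workspace.
layer_cnn_head <- function(seed, momentum = 0.9, eps = 1e-5) {
  filters <- c(32L, 64L, 256L)
  c_in <- c(1L, filters[1], filters[2])
  p <- list()
  st <- list()
  for (i in 1:3) {
    p[[paste0("w", i)]] <- with_seed(derive_seed(seed, i), {
      array(stats::rnorm(9 * c_in[i] * filters[i],
                         sd = sqrt(2 / (9 * c_in[i]))),
            dim = c(3L, 3L, c_in[i], filters[i]))
    })
    p[[paste0("g", i)]] <- rep(1, filters[i])
    p[[paste0("b", i)]] <- rep(0, filters[i])
    st[[paste0("rm", i)]] <- rep(0, filters[i])
    st[[paste0("rv", i)]] <- rep(1, filters[i])
  }
  l <- new_layer("cnn_head", p = p,
                 hyper = list(momentum = momentum, eps = eps))
  l$state <- st
  l
}

layer_kan <- function(n_in, n_out, spec, seed) {
  par <- kan_layer_init(n_in, n_out, spec, seed)
  new_layer("kan",
            p = list(base_weights = par$base_weights,
                     spline_coeffs = par$spline_coeffs,
                     spline_scalers = par$spline_scalers),
            hyper = list(n_in = par$n_in, n_out = par$n_out, spec = spec))
}

head_param_list <- function(l) {
  c(l$p, l$state[c("rm1", "rv1", "rm2", "rv2", "rm3", "rv3")],
    list(eps = l$hyper$eps))
}

forward_layer <- function(l, X, training = FALSE) {
  switch(
    l$type,
    cnn_head = {
      res <- .head_forward(X, head_param_list(l), training,
                           l$state$workspace)
      l$state$workspace <- res$cache
      if (training) {
        l$cache <- res$cache
        mom <- l$hyper$momentum
        bs <- res$batch_stats
        for (i in 1:3) {
          rm <- paste0("rm", i); rv <- paste0("rv", i)
          l$state[[rm]] <- mom * l$state[[rm]] +
            (1 - mom) * bs[[paste0("m", i)]]
          l$state[[rv]] <- mom * l$state[[rv]] +
            (1 - mom) * bs[[paste0("v", i)]]
        }
      }
      res$emb
    },
    conv3x3 = {
      if (training) l$cache <- list(X = X)
      .conv3x3_forward(X, l$p$w)
    },
    bn2d = {
      if (training) {
        st <- .bn2d_stats(X)
        inv_std <- 1 / sqrt(st$var + l$hyper$eps)
        mom <- l$hyper$momentum
        l$state$mean <- mom * l$state$mean + (1 - mom) * st$mean
        l$state$var <- mom * l$state$var + (1 - mom) * st$var
        ap <- .bn2d_apply(X, st$mean, inv_std, l$p$gamma, l$p$beta, TRUE)
        l$cache <- list(xhat = ap$xhat, inv_std = inv_std)
        ap$y
      } else {
        inv_std <- 1 / sqrt(l$state$var + l$hyper$eps)
        .bn2d_apply(X, l$state$mean, inv_std, l$p$gamma, l$p$beta, FALSE)$y
      }
    },
    relu = {
      Y <- pmax(X, 0)
      if (!is.null(dim(X))) dim(Y) <- dim(X)
      if (training) l$cache <- list(mask = Y > 0)
      Y
    },
    maxpool2 = {
      mp <- .maxpool2_forward(X)
      if (training) l$cache <- list(idx = mp$idx, in_dim = dim(X))
      mp$y
    },
    gap = {
      d <- dim(X)
      if (training) l$cache <- list(in_dim = d)
      M <- X
      dim(M) <- c(d[1] * d[2], d[3] * d[4])
      t(matrix(colMeans(M), d[3], d[4]))
    },
    bn1d = {
      if (training) {
        mu <- colMeans(X)
        v <- colMeans(X^2) - mu^2
        v[v < 0] <- 0
        inv_std <- 1 / sqrt(v + l$hyper$eps)
        mom <- l$hyper$momentum
        l$state$mean <- mom * l$state$mean + (1 - mom) * mu
        l$state$var <- mom * l$state$var + (1 - mom) * v
        xhat <- sweep(X, 2L, mu) * rep(inv_std, each = nrow(X))
        l$cache <- list(xhat = xhat, inv_std = inv_std)
        sweep(xhat * rep(l$p$gamma, each = nrow(X)), 2L, l$p$beta, `+`)
      } else {
        inv_std <- 1 / sqrt(l$state$var + l$hyper$eps)
        xhat <- sweep(X, 2L, l$state$mean) * rep(inv_std, each = nrow(X))
        sweep(xhat * rep(l$p$gamma, each = nrow(X)), 2L, l$p$beta, `+`)
      }
    },
    dense = {
      if (training) l$cache <- list(X = X)
      sweep(X %*% l$p$w, 2L, l$p$b, `+`)
    },
    dropout = {
      if (training && l$hyper$rate > 0) {
        mask <- (stats::runif(length(X)) >= l$hyper$rate) /
          (1 - l$hyper$rate)
        dim(mask) <- dim(X)
        l$cache <- list(mask = mask)
        X * mask
      } else {
        X
      }
    },
    kan = {
      par <- c(l$p, list(n_in = l$hyper$n_in, n_out = l$hyper$n_out,
                         spec = l$hyper$spec))
      Y <- kan_layer_forward(X, par, cache = training)
      if (training) {
        l$cache <- attr(Y, "cache")
        attr(Y, "cache") <- NULL
      }
      Y
    },
    abort(paste0("unknown layer type ", l$type))
  )
}

backward_layer <- function(l, dY) {
  switch(
    l$type,
    cnn_head = {
      gr <- .head_backward(l$cache, dY, head_param_list(l))
      for (i in 1:3) {
        l$g[[paste0("w", i)]] <- gr[[paste0("dw", i)]]
        l$g[[paste0("g", i)]] <- gr[[paste0("dg", i)]]
        l$g[[paste0("b", i)]] <- gr[[paste0("db", i)]]
      }
      NULL  # input gradient not needed: heads sit on the data
    },
    conv3x3 = {
      bk <- .conv3x3_backward(l$cache$X, l$p$w, dY)
      l$g$w <- bk$dw
      bk$dx
    },
    bn2d = {
      bk <- .bn2d_backward(dY, l$cache$xhat, l$p$gamma, l$cache$inv_std)
      l$g$gamma <- bk$dgamma
      l$g$beta <- bk$dbeta
      bk$dx
    },
    relu = dY * l$cache$mask,
    maxpool2 = .maxpool2_backward(l$cache$idx, dY, l$cache$in_dim),
    gap = {
      d <- l$cache$in_dim
      M <- t(dY) / (d[1] * d[2])            # [C, B]
      array(rep(as.vector(M), each = d[1] * d[2]), dim = d)
    },
    bn1d = {
      n <- nrow(dY)
      xhat <- l$cache$xhat
      l$g$gamma <- colSums(dY * xhat)
      l$g$beta <- colSums(dY)
      g_is <- l$p$gamma * l$cache$inv_std
      centered <- sweep(dY, 2L, l$g$beta / n) -
        xhat * rep(l$g$gamma / n, each = n)
      centered * rep(g_is, each = n)
    },
    dense = {
      l$g$w <- crossprod(l$cache$X, dY)
      l$g$b <- colSums(dY)
      dY %*% t(l$p$w)
    },
    dropout = {
      if (is.null(l$cache)) dY else dY * l$cache$mask
    },
    kan = {
      par <- c(l$p, list(n_in = l$hyper$n_in, n_out = l$hyper$n_out,
                         spec = l$hyper$spec))
      bk <- kan_layer_backward(dY, par, l$cache)
      l$g$base_weights <- bk$d_base_weights
      l$g$spline_coeffs <- bk$d_spline_coeffs
      l$g$spline_scalers <- bk$d_spline_scalers
      bk$dX
    },
    abort(paste0("unknown layer type ", l$type))
  )
}

forward_stack <- function(layers, X, training = FALSE) {
  for (l in layers) X <- forward_layer(l, X, training)
  X
}

backward_stack <- function(layers, dY) {
  for (l in rev(layers)) dY <- backward_layer(l, dY)
  dY
}

clear_caches <- function(layers) {
  for (l in layers) {
    l$cache <- NULL
    if (l$type == "cnn_head") l$state$workspace <- NULL
  }
  invisible(NULL)
}

layer_param_count <- function(l) {
  sum(vapply(l$p, length, integer(1)))
}

# Nadam step over every parameter of every layer (in place).
nadam_step <- function(layers, step, lr) {
  for (l in layers) {
    for (nm in names(l$p)) {
      g <- l$g[[nm]]
      if (is.null(g)) next
      if (is.null(l$state$opt[[nm]])) {
        l$state$opt[[nm]] <- list(m = l$p[[nm]] * 0, v = l$p[[nm]] * 0)
      }
      upd <- nadam_update(l$state$opt[[nm]], g, step, lr)
      l$state$opt[[nm]] <- upd$state
      l$p[[nm]] <- l$p[[nm]] - upd$delta
    }
  }
  invisible(NULL)
}
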