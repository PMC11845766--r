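# Kolmogorov-Arnold network layers from first principles.
#
# Every edge (i, j) of a KAN layer carries a learnable univariate function
#   phi_ij(x) = w_base[i,j] * silu(x) + w_spl[i,j] * sum_m c[i,j,m] B_m(x)
# where the B_m are the G+k degree-k B-splines supported on a uniform grid
# of G intervals over [a, b], extended by k knots on each side. Outputs are
# sums of edge activations over incoming edges; a network is the
# composition of L such layers.

#' B-spline specification for KAN edges
#'
#' @param order_k Polynomial degree of the splines (>= 1); default 3
#'   (cubic).
#' @param grid_size Number of grid intervals G (>= 1); default 5.
#' @param grid_range Closed interval the grid spans; default \[-1, 1\].
#' @return A list of class `spline_spec`.
#' @export
spline_spec <- function(order_k = 3L, grid_size = 5L,
                        grid_range = c(-1, 1)) {
  stopifnot(is_count(order_k), is_count(grid_size),
            length(grid_range) == 2L, grid_range[1] < grid_range[2])
  structure(list(order_k = as.integer(order_k),
                 grid_size = as.integer(grid_size),
                 grid_range = as.numeric(grid_range)),
            class = "spline_spec")
}

n_spline_basis <- function(spec) spec$grid_size + spec$order_k

#' Extended knot sequence of a spline grid
#'
#' Uniform knots over the grid range with `order_k` extra knots appended on
#' each side at the same spacing, giving `G + 2k + 1` knots in total --
#' enough to support all `G + k` B-splines whose support intersects the
#' grid range.
#'
#' @param spec A [spline_spec()].
#' @return Strictly increasing numeric vector of knots.
#' @export
extend_grid <- function(spec) {
  stopifnot(inherits(spec, "spline_spec"))
  a <- spec$grid_range[1]; b <- spec$grid_range[2]
  h <- (b - a) / spec$grid_size
  seq(a - spec$order_k * h, b + spec$order_k * h, by = h)[
    seq_len(spec$grid_size + 2L * spec$order_k + 1L)]
}

# Cox-de Boor recursion, vectorized over x. Returns the degree-`degree`
# basis matrix [length(x), n_knots - degree - 1].
cox_de_boor <- function(x, knots, degree) {
  nx <- length(x)
  m <- length(knots) - 1L
  B <- matrix(0, nx, m)
  for (j in seq_len(m)) {
    B[, j] <- as.numeric(x >= knots[j] & x < knots[j + 1L])
  }
  if (degree == 0L) return(B)
  for (d in seq_len(degree)) {
    nb <- m - d
    Bn <- matrix(0, nx, nb)
    for (j in seq_len(nb)) {
      left <- (x - knots[j]) / (knots[j + d] - knots[j])
      right <- (knots[j + d + 1L] - x) / (knots[j + d + 1L] - knots[j + 1L])
      Bn[, j] <- left * B[, j] + right * B[, j + 1L]
    }
    B <- Bn
  }
  B
}

#' Evaluate the B-spline basis at points
#'
#' Degree-k Cox-de Boor basis values of the `G + k` splines supported on
#' the extended grid. Inside the grid range the values are a partition of
#' unity; outside the extended support they are all zero.
#'
#' @param x Numeric vector of evaluation points.
#' @param spec A [spline_spec()].
#' @return `length(x)` x `(G + k)` matrix of basis values.
#' @export
bspline_basis <- function(x, spec) {
  if (any(!is.finite(x))) abort("non-finite evaluation point")
  knots <- extend_grid(spec)
  cox_de_boor(x, knots, spec$order_k)
}

# basis values and first derivatives in one pass (shared degree k-1 stage)
bspline_basis_with_deriv <- function(x, spec) {
  knots <- extend_grid(spec)
  k <- spec$order_k
  Blow <- cox_de_boor(x, knots, k - 1L)
  nb <- n_spline_basis(spec)
  B <- matrix(0, length(x), nb)
  D <- matrix(0, length(x), nb)
  for (j in seq_len(nb)) {
    left <- (x - knots[j]) / (knots[j + k] - knots[j])
    right <- (knots[j + k + 1L] - x) / (knots[j + k + 1L] - knots[j + 1L])
    B[, j] <- left * Blow[, j] + right * Blow[, j + 1L]
    D[, j] <- k * (Blow[, j] / (knots[j + k] - knots[j]) -
                     Blow[, j + 1L] / (knots[j + k + 1L] - knots[j + 1L]))
  }
  list(value = B, deriv = D)
}

#' Number of learnable parameters of one KAN layer
#'
#' Each of the `n_in * n_out` edges carries `G + k` spline coefficients,
#' one base weight and one spline scaler; there are no biases, so the count
#' is `n_in * n_out * (G + k + 2)`.
#'
#' @param n_in,n_out Layer widths.
#' @param spec A [spline_spec()].
#' @return Integer parameter count.
#' @export
kan_param_count <- function(n_in, n_out, spec = spline_spec()) {
  if (!is_count(n_in) || !is_count(n_out)) {
    abort("layer widths must be positive integers")
  }
  as.integer(n_in) * as.integer(n_out) *
    (n_spline_basis(spec) + 2L)
}

#' Initialize the parameters of one KAN layer
#'
#' Base weights are fan-in-scaled uniform, spline coefficients small
#' Gaussian noise, scalers 1.
#'
#' @param n_in,n_out Layer widths.
#' @param spec A [spline_spec()].
#' @param seed Integer seed for the initialization.
#' @return A list of class `kan_layer_params` with `base_weights`
#'   (`n_in` x `n_out`), `spline_coeffs` (`n_in*(G+k)` x `n_out`, rows
#'   grouped by input then basis index), `spline_scalers`
#'   (`n_in` x `n_out`), plus the widths and spec.
#' @export
kan_layer_init <- function(n_in, n_out, spec = spline_spec(), seed = 0L) {
  stopifnot(is_count(n_in), is_count(n_out))
  nb <- n_spline_basis(spec)
  with_seed(seed, {
    lim <- sqrt(6 / n_in)
    structure(list(
      n_in = as.integer(n_in), n_out = as.integer(n_out), spec = spec,
      base_weights = matrix(stats::runif(n_in * n_out, -lim, lim),
                            n_in, n_out),
      spline_coeffs = matrix(stats::rnorm(n_in * nb * n_out, sd = 0.1),
                             n_in * nb, n_out),
      spline_scalers = matrix(1, n_in, n_out)),
      class = "kan_layer_params")
  })
}

# rearrange basis values of a [B, n_in] input into the flat [B, n_in*(G+k)]
# layout whose column (i-1)*(G+k)+m matches the spline_coeffs row order
flatten_basis <- function(Bas, n_batch, n_in, nb) {
  A <- array(Bas, c(n_batch, n_in, nb))
  matrix(aperm(A, c(1L, 3L, 2L)), n_batch, nb * n_in)
}

#' Forward pass of one KAN layer
#'
#' Computes `y_j = sum_i [ w_base[i,j] silu(x_i) +
#' w_spl[i,j] sum_m c[i,j,m] B_m(x_i) ]` for a batch of inputs. With
#' `cache = TRUE` the quantities needed for backpropagation are attached.
#'
#' @param X Batch matrix (`n_batch` x `n_in`) or a single `n_in` vector.
#' @param params A `kan_layer_params`.
#' @param cache Keep intermediates for [kan_layer_backward()].
#' @return `n_batch` x `n_out` matrix (with attribute `cache` when
#'   requested).
#' @export
kan_layer_forward <- function(X, params, cache = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != params$n_in) {
    abort(paste0("input width ", ncol(X), " != layer n_in ", params$n_in))
  }
  nb <- n_spline_basis(params$spec)
  n_batch <- nrow(X)
  S <- silu(X)
  bd <- bspline_basis_with_deriv(as.vector(X), params$spec)
  Bflat <- flatten_basis(bd$value, n_batch, params$n_in, nb)
  scaler_exp <- params$spline_scalers[rep(seq_len(params$n_in), each = nb), ,
                                      drop = FALSE]
  Ceff <- params$spline_coeffs * scaler_exp
  Y <- S %*% params$base_weights + Bflat %*% Ceff
  if (cache) {
    attr(Y, "cache") <- list(
      X = X, S = S, Bflat = Bflat,
      Dflat = flatten_basis(bd$deriv, n_batch, params$n_in, nb),
      Ceff = Ceff, scaler_exp = scaler_exp)
  }
  Y
}

#' Backward pass of one KAN layer
#'
#' Given the upstream gradient and the cache attached by
#' [kan_layer_forward()], returns the gradient with respect to the inputs
#' and all learnable parameters.
#'
#' @param dY Upstream gradient (`n_batch` x `n_out`).
#' @param params A `kan_layer_params`.
#' @param cache The cache from `kan_layer_forward(..., cache = TRUE)`.
#' @return List with `dX`, `d_base_weights`, `d_spline_coeffs`,
#'   `d_spline_scalers`.
#' @export
kan_layer_backward <- function(dY, params, cache) {
  nb <- n_spline_basis(params$spec)
  n_in <- params$n_in
  n_batch <- nrow(cache$X)
  d_base <- crossprod(cache$S, dY)
  dCeff <- crossprod(cache$Bflat, dY)
  d_coeffs <- dCeff * cache$scaler_exp
  grp <- rep(seq_len(n_in), each = nb)
  d_scalers <- rowsum(params$spline_coeffs * dCeff, grp, reorder = FALSE)
  dimnames(d_scalers) <- NULL
  # input gradient: base path + spline path through the basis derivative
  dX_base <- (dY %*% t(params$base_weights)) * silu_grad(cache$X)
  M <- (dY %*% t(cache$Ceff)) * cache$Dflat
  arr <- array(M, c(n_batch, nb, n_in))
  dX_spline <- colSums(aperm(arr, c(2L, 1L, 3L)))
  list(dX = dX_base + dX_spline, d_base_weights = d_base,
       d_spline_coeffs = d_coeffs, d_spline_scalers = d_scalers)
}

#' Construct a KAN network
#'
#' A sequence of KAN layers chaining the widths in `shape`.
#'
#' @param shape Integer vector of widths `[n_1, ..., n_{L+1}]`.
#' @param spec A [spline_spec()] shared by all layers.
#' @param seed Integer seed for initialization.
#' @return A list of class `kan_network` with elements `shape`, `spec`,
#'   `layers`.
#' @export
kan_network <- function(shape, spec = spline_spec(), seed = 0L) {
  stopifnot(length(shape) >= 2L, all(vapply(shape, is_count, TRUE)))
  layers <- lapply(seq_len(length(shape) - 1L), function(l) {
    kan_layer_init(shape[l], shape[l + 1L], spec,
                   seed = derive_seed(seed, l))
  })
  structure(list(shape = as.integer(shape), spec = spec, layers = layers),
            class = "kan_network")
}

#' Forward pass of a KAN network
#'
#' Sequential composition of the layers.
#'
#' @param X Batch matrix (`n_batch` x `n_1`) or single vector.
#' @param net A [kan_network()].
#' @return `n_batch` x `n_{L+1}` matrix of outputs.
#' @export
kan_forward <- function(X, net) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != net$shape[1]) abort("input width does not match network")
  for (layer in net$layers) X <- kan_layer_forward(X, layer)
  X
}

#' Total learnable parameters of a KAN network
#'
#' @param net A [kan_network()].
#' @return Integer count, equal to the sum of [kan_param_count()] over the
#'   layers.
#' @export
kan_network_param_count <- function(net) {
  sum(vapply(net$layers, function(l) {
    kan_param_count(l$n_in, l$n_out, l$spec)
  }, integer(1)))
}

#' Fit a KAN network to a regression target
#'
#' Full-batch gradient descent on mean squared error with the Nadam update
#' rule; used for expressivity checks and as a reference training loop for
#' small KANs.
#'
#' @param net A [kan_network()].
#' @param X Input matrix (`n` x `n_1`).
#' @param y Target vector or matrix (`n` x `n_{L+1}`).
#' @param steps Number of full-batch updates.
#' @param learning_rate Step size.
#' @return The trained network, with a numeric `loss` attribute tracing
#'   the per-step MSE.
#' @export
kan_fit_regression <- function(net, X, y, steps = 2000L,
                               learning_rate = 0.01) {
  if (is.null(dim(X))) X <- matrix(X, ncol = net$shape[1])
  y <- matrix(y, nrow = nrow(X))
  opt <- lapply(net$layers, function(l) {
    lapply(list(base_weights = l$base_weights,
                spline_coeffs = l$spline_coeffs,
                spline_scalers = l$spline_scalers),
           function(p) list(m = p * 0, v = p * 0))
  })
  loss_trace <- numeric(steps)
  n <- nrow(X)
  for (step in seq_len(steps)) {
    acts <- vector("list", length(net$layers) + 1L)
    acts[[1]] <- X
    caches <- vector("list", length(net$layers))
    for (l in seq_along(net$layers)) {
      out <- kan_layer_forward(acts[[l]], net$layers[[l]], cache = TRUE)
      caches[[l]] <- attr(out, "cache")
      attr(out, "cache") <- NULL
      acts[[l + 1L]] <- out
    }
    err <- acts[[length(acts)]] - y
    loss_trace[step] <- mean(err^2)
    dY <- 2 * err / (n * ncol(err))
    for (l in rev(seq_along(net$layers))) {
      gr <- kan_layer_backward(dY, net$layers[[l]], caches[[l]])
      for (nm in c("base_weights", "spline_coeffs", "spline_scalers")) {
        g <- gr[[paste0("d_", nm)]]
        upd <- nadam_update(opt[[l]][[nm]], g, step, learning_rate)
        opt[[l]][[nm]] <- upd$state
        net$layers[[l]][[nm]] <- net$layers[[l]][[nm]] - upd$delta
      }
      dY <- gr$dX
    }
  }
  attr(net, "loss") <- loss_trace
  net
}

# One Nadam update (Adam with Nesterov momentum, Keras convention).
# Returns the updated optimizer state and the parameter delta.
nadam_update <- function(state, g, step, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  m <- beta1 * state$m + (1 - beta1) * g
  v <- beta2 * state$v + (1 - beta2) * g^2
  m_hat <- m / (1 - beta1^(step + 1)) +
    (1 - beta1) * g / (1 - beta1^step)
  v_hat <- v / (1 - beta2^step)
  list(state = list(m = m, v = v),
       delta = lr * m_hat / (sqrt(v_hat) + eps))
}
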