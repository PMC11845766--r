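# KAN machinery: extended grids, Cox-de Boor basis properties, layer
# forward/backward against finite differences, composition, parameter
# counting, and expressivity.

test_that("extended grids have G + 2k + 1 uniformly spaced knots", {
  k1 <- extend_grid(spline_spec(3, 5, c(-1, 1)))
  expect_equal(k1, seq(-2.2, 2.2, by = 0.4))
  expect_equal(extend_grid(spline_spec(1, 1, c(0, 1))), c(-1, 0, 1, 2))
  for (G in c(1, 4, 8)) {
    for (k in c(1, 3, 5)) {
      kn <- extend_grid(spline_spec(k, G))
      expect_equal(length(kn), G + 2 * k + 1)
      expect_true(all(diff(kn) > 0))
    }
  }
})

test_that("the basis is a partition of unity on the grid range", {
  for (G in 1:8) {
    for (k in 1:5) {
      spec <- spline_spec(k, G, c(-1, 1))
      x <- seq(-1, 1, length.out = 41)
      B <- bspline_basis(x, spec)
      expect_equal(ncol(B), G + k)
      expect_lt(max(abs(rowSums(B) - 1)), 1e-12)
      expect_true(all(B >= 0 & B <= 1))
    }
  }
})

test_that("basis functions have compact support of k+1 intervals", {
  spec <- spline_spec(3, 6, c(-1, 1))
  knots <- extend_grid(spec)
  B <- bspline_basis(seq(-2.5, 2.5, by = 0.01), spec)
  for (j in seq_len(ncol(B))) {
    active <- which(B[, j] > 1e-14)
    if (length(active)) {
      x_active <- seq(-2.5, 2.5, by = 0.01)[active]
      # support is [t_j, t_{j+k+1}]: width (k+1) * spacing
      expect_lte(max(x_active) - min(x_active),
                 (spec$order_k + 1) * diff(knots)[1] + 0.02)
    }
  }
  # far outside the extended support everything is zero
  expect_true(all(bspline_basis(c(-50, 50), spec) == 0))
})

test_that("the cardinal cubic basis takes 2/3 at its central knot", {
  # uniform unit-spaced knots: B-spline of degree 3 evaluated at the
  # middle of its support
  spec <- spline_spec(3, 4, c(0, 4))
  expect_equal(max(bspline_basis(2, spec)), 2 / 3, tolerance = 1e-12)
})

test_that("zeroing the spline path reduces the layer to silu features", {
  spec <- spline_spec()
  par <- kan_layer_init(4, 3, spec, seed = 1)
  par$spline_coeffs[] <- 0
  par$spline_scalers[] <- 0
  par$base_weights <- diag(1, 4, 3)
  X <- matrix(seq(-0.9, 0.9, length.out = 12), 3, 4)
  Y <- kan_layer_forward(X, par)
  S <- X / (1 + exp(-X))
  expect_equal(Y, S %*% par$base_weights)
})

test_that("spline coefficients can interpolate the identity on the grid", {
  spec <- spline_spec(3, 5, c(-1, 1))
  par <- kan_layer_init(1, 1, spec, seed = 2)
  par$base_weights[] <- 0
  par$spline_scalers[] <- 1
  # least-squares fit of coefficients to g(x) = x on a dense grid
  xs <- seq(-1, 1, length.out = 201)
  B <- bspline_basis(xs, spec)
  par$spline_coeffs <- matrix(qr.solve(B, xs), ncol = 1)
  y <- kan_layer_forward(matrix(xs, ncol = 1), par)
  expect_lt(max(abs(y - xs)), 0.05)
})

test_that("analytic gradients match central finite differences", {
  spec <- spline_spec()
  par <- kan_layer_init(3, 2, spec, seed = 42)
  X <- withr::with_seed(1, matrix(runif(12, -0.9, 0.9), 4, 3))
  dY <- withr::with_seed(2, matrix(rnorm(8), 4, 2))
  out <- kan_layer_forward(X, par, cache = TRUE)
  gr <- kan_layer_backward(dY, par, attr(out, "cache"))
  h <- 1e-5
  fd <- function(get, set) {
    v <- get(par)
    g <- v * 0
    for (i in seq_along(v)) {
      pp <- set(par, replace(v, i, v[i] + h))
      pm <- set(par, replace(v, i, v[i] - h))
      g[i] <- sum((kan_layer_forward(X, pp) -
                     kan_layer_forward(X, pm)) * dY) / (2 * h)
    }
    g
  }
  rel <- function(a, b) max(abs(a - b)) / max(abs(b))
  g_bw <- fd(function(p) p$base_weights,
             function(p, v) { p$base_weights <- v; p })
  expect_lt(rel(gr$d_base_weights, g_bw), 1e-4)
  g_sc <- fd(function(p) p$spline_coeffs,
             function(p, v) {
               p$spline_coeffs <- matrix(v, nrow(p$spline_coeffs)); p
             })
  expect_lt(rel(as.vector(gr$d_spline_coeffs), g_sc), 1e-4)
  g_ss <- fd(function(p) p$spline_scalers,
             function(p, v) {
               p$spline_scalers <- matrix(v, nrow(p$spline_scalers)); p
             })
  expect_lt(rel(as.vector(gr$d_spline_scalers), g_ss), 1e-4)
  # input gradient
  gX <- X * 0
  for (i in seq_along(X)) {
    Xp <- replace(X, i, X[i] + h)
    Xm <- replace(X, i, X[i] - h)
    gX[i] <- sum((kan_layer_forward(Xp, par) -
                    kan_layer_forward(Xm, par)) * dY) / (2 * h)
  }
  expect_lt(rel(gr$dX, gX), 1e-4)
})

test_that("networks chain widths and compose layers sequentially", {
  net <- kan_network(c(3, 7, 1), seed = 3)
  expect_equal(net$shape, c(3L, 7L, 1L))   # 2n+1 middle width for n = 3
  X <- withr::with_seed(4, matrix(runif(9, -1, 1), 3, 3))
  # L = 1 equals a single layer forward
  net1 <- kan_network(c(3, 2), seed = 5)
  expect_equal(kan_forward(X, net1),
               kan_layer_forward(X, net1$layers[[1]]))
  # manual composition equals kan_forward
  manual <- kan_layer_forward(kan_layer_forward(X, net$layers[[1]]),
                              net$layers[[2]])
  expect_equal(kan_forward(X, net), manual)
  expect_error(kan_forward(matrix(0, 2, 4), net), "width")
})

test_that("parameter counts follow n_in * n_out * (G + k + 2)", {
  spec <- spline_spec(3, 5)
  expect_identical(kan_param_count(769, 6, spec), 46140L)
  expect_identical(kan_param_count(1, 1, spec), 10L)
  expect_identical(kan_param_count(2, 3, spec), 60L)
  expect_error(kan_param_count(0, 5, spec), "positive")
  # count oracle: enumerate the learnable scalars in the containers
  for (dims in list(c(2, 5), c(7, 3))) {
    for (spec2 in list(spline_spec(2, 4), spline_spec(4, 7))) {
      par <- kan_layer_init(dims[1], dims[2], spec2, seed = 1)
      walked <- length(par$base_weights) + length(par$spline_coeffs) +
        length(par$spline_scalers)
      expect_identical(kan_param_count(dims[1], dims[2], spec2),
                       as.integer(walked))
    }
  }
  net <- kan_network(c(768, 769, 6))
  expect_identical(kan_network_param_count(net), 5905920L + 46140L)
})

test_that("a [1,5,1] KAN fits sin(pi x) where a linear model cannot", {
  x <- matrix(seq(-1, 1, length.out = 256), ncol = 1)
  y <- sin(pi * x)
  net <- kan_network(c(1, 5, 1), seed = 0)
  net <- kan_fit_regression(net, x, y, steps = 2000, learning_rate = 0.01)
  rmse <- sqrt(mean((kan_forward(x, net) - y)^2))
  expect_lt(rmse, 0.05)
  lin_rmse <- sqrt(mean(stats::resid(stats::lm(y ~ x))^2))
  expect_gt(lin_rmse, 0.3)
})

test_that("out-of-range inputs evaluate through the extended knots", {
  spec <- spline_spec(3, 5, c(-1, 1))
  B <- bspline_basis(c(-1.5, 1.5), spec)
  expect_true(all(is.finite(B)))
  expect_true(any(B > 0))            # extended support still active
  expect_lt(max(rowSums(B)), 1)      # partition of unity only inside
})
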