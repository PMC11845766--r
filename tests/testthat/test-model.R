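# Architecture contracts: head embeddings, fusion, parameter counts,
# softmax prediction, determinism, and agreement of the fused
# single-precision head with the double-precision layer-by-layer path.

test_that("each head maps its input height to a 256-dim embedding", {
  model <- build_trispectrakan(seed = 1)
  for (nm in c("mfcc", "chroma", "mspec")) {
    h <- c(mfcc = 20L, chroma = 12L, mspec = 128L)[[nm]]
    X <- withr::with_seed(2, array(rnorm(h * 259 * 2), c(h, 259, 1, 2)))
    E <- trispectrakan:::forward_stack(model$heads[[nm]], X)
    expect_equal(dim(E), c(2L, 256L))
    expect_true(all(is.finite(E)))
  }
  # all-zero input in eval mode stays finite
  Z <- array(0, c(128, 259, 1, 1))
  expect_true(all(is.finite(
    trispectrakan:::forward_stack(model$heads$mspec, Z))))
})

test_that("fusion concatenates in (mfcc, chroma, mspec) order", {
  e1 <- matrix(1, 2, 256)
  e2 <- matrix(2, 2, 256)
  e3 <- matrix(3, 2, 256)
  E <- fuse_embeddings(e1, e2, e3)
  expect_equal(dim(E), c(2L, 768L))
  expect_true(all(E[, 1:256] == 1))
  expect_true(all(E[, 257:512] == 2))
  expect_true(all(E[, 513:768] == 3))
  expect_true(all(fuse_embeddings(e1 * 0, e2 * 0, e3 * 0) == 0))
  expect_error(fuse_embeddings(e1[, 1:10], e2, e3), "256")
})

test_that("the KAN classifier has the printed layer parameter counts", {
  model <- build_trispectrakan(seed = 0)
  s <- summary(model)
  expect_equal(s$params[s$layer == "Output layer"], 46140L)
  expect_equal(s$params[s$layer == "Hidden layer"], 5905920L)
  # head weight sharing is NOT used: three independent parameter sets
  w_m <- model$heads$mfcc[[1]]$p$w3
  w_c <- model$heads$chroma[[1]]$p$w3
  expect_false(identical(w_m, w_c))
})

test_that("baseline dense layers match n_in * n_out + n_out", {
  expect_identical(dense_param_count(768, 750), 576750L)
  expect_identical(dense_param_count(750, 250), 187750L)
  expect_identical(dense_param_count(250, 75), 18825L)
  expect_identical(dense_param_count(75, 25), 1900L)
  expect_identical(dense_param_count(25, 6), 156L)
  expect_identical(dense_param_count(1, 1), 2L)
  expect_error(dense_param_count(0, 1), "positive")

  base <- build_hybrid_cnn_baseline(seed = 0)
  dense <- Filter(function(l) l$type == "dense",
                  base$trunk)
  counts <- vapply(dense, trispectrakan:::layer_param_count, integer(1))
  expect_equal(counts, c(576750L, 187750L, 18825L, 1900L, 156L))
})

test_that("forward yields finite (B, 6) logits for both variants", {
  triples <- random_triples(2, seed = 3)
  for (build in list(build_trispectrakan, build_hybrid_cnn_baseline)) {
    model <- build(seed = 4)
    logits <- trispectrakan:::model_forward(
      model, trispectrakan:::stack_triples(triples))
    expect_equal(dim(logits), c(2L, 6L))
    expect_true(all(is.finite(logits)))
  }
})

test_that("same seed gives identical initial parameters; builds differ", {
  a <- build_trispectrakan(seed = 9)
  b <- build_trispectrakan(seed = 9)
  c <- build_trispectrakan(seed = 10)
  get_w <- function(m) m$heads$mspec[[1]]$p$w1
  expect_identical(get_w(a), get_w(b))
  expect_false(identical(get_w(a), get_w(c)))
  kan_a <- a$trunk[[2]]$p$spline_coeffs
  expect_identical(kan_a, b$trunk[[2]]$p$spline_coeffs)
})

test_that("predictions live on the probability simplex", {
  model <- build_trispectrakan(seed = 5)
  preds <- predict(model, random_triples(3, seed = 6))
  p <- as.matrix(preds[, paste0("p_", model$class_labels)])
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(preds$label %in% 0:5))
  # softmax closed forms
  sm <- trispectrakan:::softmax_rows(matrix(0, 1, 6))
  expect_equal(as.vector(sm), rep(1 / 6, 6))
  sm1 <- trispectrakan:::softmax_rows(matrix(c(1, 0, 0, 0, 0, 0), 1))
  expect_equal(sm1[1, 1], exp(1) / (exp(1) + 5), tolerance = 1e-12)
  # argmax ties break to the lowest class index
  expect_equal(max.col(matrix(c(0.3, 0.3, 0.2, 0.1, 0.05, 0.05), 1),
                       ties.method = "first"), 1L)
})

test_that("the fused head equals the double-precision reference path", {
  model <- build_trispectrakan(seed = 7)
  for (nm in c("mfcc", "mspec")) {
    h <- c(mfcc = 20L, mspec = 128L)[[nm]]
    X <- withr::with_seed(8, array(rnorm(h * 259 * 3), c(h, 259, 1, 3)))
    fused <- trispectrakan:::forward_stack(model$heads[[nm]], X,
                                           training = TRUE)
    ref <- trispectrakan:::reference_head_forward(model$heads[[nm]], X,
                                                  training = TRUE)
    expect_lt(max(abs(fused - ref)), 1e-3)
  }
})

test_that("fused head gradients match finite differences", {
  # small input so the check runs in seconds; float32 arithmetic bounds
  # the attainable agreement
  hl <- trispectrakan:::layer_cnn_head(seed = 11)
  X <- withr::with_seed(12, array(rnorm(8 * 10 * 2), c(8, 10, 1, 2)))
  E <- trispectrakan:::forward_layer(hl, X, training = TRUE)
  dE <- withr::with_seed(13, matrix(rnorm(length(E)), nrow(E)))
  trispectrakan:::backward_layer(hl, dE)
  g_w2 <- hl$g$w2
  h <- 1e-2
  idx <- withr::with_seed(14, sample(length(hl$p$w2), 20))
  for (i in idx) {
    hp <- trispectrakan:::layer_cnn_head(seed = 11)
    hp$p$w2[i] <- hp$p$w2[i] + h
    hm <- trispectrakan:::layer_cnn_head(seed = 11)
    hm$p$w2[i] <- hm$p$w2[i] - h
    num <- sum((trispectrakan:::forward_layer(hp, X, TRUE) -
                  trispectrakan:::forward_layer(hm, X, TRUE)) * dE) / (2 * h)
    expect_lt(abs(num - g_w2[i]), 2e-2 * max(1, abs(num)))
  }
})

test_that("dropout is disabled at eval time: deterministic outputs", {
  model <- build_hybrid_cnn_baseline(seed = 15)
  inp <- trispectrakan:::stack_triples(random_triples(2, seed = 16))
  l1 <- trispectrakan:::model_forward(model, inp, training = FALSE)
  l2 <- trispectrakan:::model_forward(model, inp, training = FALSE)
  expect_identical(l1, l2)
})

test_that("a full forward/backward pass on batch 32 runs and is finite", {
  model <- build_trispectrakan(seed = 17)
  inp <- trispectrakan:::stack_triples(random_triples(32, seed = 18))
  logits <- trispectrakan:::model_forward(model, inp, training = TRUE)
  expect_true(all(is.finite(logits)))
  trispectrakan:::model_backward(model, logits * 0 + 1e-2)
  for (l in trispectrakan:::model_layers(model)) {
    for (g in l$g) expect_true(all(is.finite(g)))
  }
})

test_that("checkpoints round-trip parameters and running statistics", {
  model <- build_trispectrakan(seed = 19)
  # perturb a running stat so the save captures non-initial state
  model$heads$mfcc[[1]]$state$rm1 <- runif(32)
  inp <- trispectrakan:::stack_triples(random_triples(2, seed = 20))
  before <- trispectrakan:::model_forward(model, inp)
  path <- withr::local_tempfile()
  save_model(model, path)
  restored <- load_model(path)
  after <- trispectrakan:::model_forward(restored, inp)
  expect_equal(after, before, tolerance = 1e-12)
})
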