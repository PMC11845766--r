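# The two classifier architectures. Both share the same three-branch front
# end: one convolutional head per spectral representation (MFCC 20x259,
# chroma 12x259, mel spectrogram 128x259), each ending in a 256-dim
# embedding; the embeddings are concatenated into a 768-dim fusion vector.
# TriSpectraKAN classifies the fusion through a [768, 769, 6] KAN; the
# hybrid-CNN baseline through a 750-250-75-25-6 dense stack.

#' Head configuration
#'
#' @param input_height Number of feature rows (20, 12 or 128).
#' @param input_width Number of time frames (259 for 6-s segments).
#' @param embedding_dim Output embedding width (256).
#' @return A list of class `head_config`.
#' @export
head_config <- function(input_height, input_width = 259L,
                        embedding_dim = 256L) {
  structure(list(input_height = as.integer(input_height),
                 input_width = as.integer(input_width),
                 conv_blocks = list(c(filters = 32L, kernel = 3L, pool = 2L),
                                    c(filters = 64L, kernel = 3L, pool = 2L),
                                    c(filters = 256L, kernel = 3L,
                                      pool = 1L)),
                 embedding_dim = as.integer(embedding_dim)),
            class = "head_config")
}

#' Model configuration
#'
#' Defaults are the selected training-time values: 6 classes, KAN hidden
#' width 769, cubic splines on a 5-interval grid, baseline dense widths
#' 750-250-75-25.
#'
#' @param variant `"trispectrakan"` or `"hybrid_cnn"`.
#' @param n_classes Number of diagnosis classes.
#' @param kan_hidden Width of the KAN hidden layer.
#' @param spline A [spline_spec()].
#' @param mlp_widths Hidden widths of the baseline dense stack.
#' @param dropout_rate Dropout between baseline dense layers.
#' @return A list of class `model_config`.
#' @export
model_config <- function(variant = c("trispectrakan", "hybrid_cnn"),
                         n_classes = 6L, kan_hidden = 769L,
                         spline = spline_spec(),
                         mlp_widths = c(750L, 250L, 75L, 25L),
                         dropout_rate = 0.3) {
  variant <- match.arg(variant)
  stopifnot(n_classes >= 2L, is_count(kan_hidden),
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(variant = variant, n_classes = as.integer(n_classes),
                 kan_hidden = as.integer(kan_hidden), spline = spline,
                 mlp_widths = as.integer(mlp_widths),
                 dropout_rate = dropout_rate),
            class = "model_config")
}

#' Build one convolutional feature head
#'
#' Three 3x3 convolution blocks (32, 64, 256 filters), each with batch
#' normalization and ReLU, 2x2 max pooling after the first two blocks,
#' global average pooling over the surviving time-frequency grid, and a
#' final batch normalization of the 256-dim embedding. The same layout
#' serves input heights 12, 20 and 128 unchanged.
#'
#' @param cfg A [head_config()].
#' @param seed Integer seed for weight initialization.
#' @return List of `nn_layer` objects.
#' @export
build_feature_head <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "head_config"),
            cfg$conv_blocks[[3]][["filters"]] == cfg$embedding_dim)
  list(layer_cnn_head(seed), layer_bn1d(cfg$embedding_dim))
}

# Reference head forward in double precision, composing the generic
# layer-by-layer kernels with the same parameters as a fused cnn_head.
# Used as the correctness oracle for the fused single-precision path.
reference_head_forward <- function(head_layers, X, training = FALSE) {
  hl <- head_layers[[1]]
  stopifnot(hl$type == "cnn_head")
  layers <- list()
  for (i in 1:3) {
    conv <- new_layer("conv3x3", p = list(w = hl$p[[paste0("w", i)]]))
    bn <- layer_bn2d(length(hl$p[[paste0("g", i)]]), hl$hyper$momentum,
                     hl$hyper$eps)
    bn$p$gamma <- hl$p[[paste0("g", i)]]
    bn$p$beta <- hl$p[[paste0("b", i)]]
    bn$state$mean <- hl$state[[paste0("rm", i)]]
    bn$state$var <- hl$state[[paste0("rv", i)]]
    layers <- c(layers, list(conv, bn, layer_relu()))
    if (i < 3) layers <- c(layers, list(layer_maxpool2()))
  }
  layers <- c(layers, list(layer_gap()))
  E <- forward_stack(layers, X, training)
  forward_layer(head_layers[[2]], E, training)
}

#' Fuse the three head embeddings
#'
#' Concatenation in the fixed order (mfcc, chroma, mspec).
#'
#' @param e_mfcc,e_chroma,e_mspec Batch matrices (`B` x 256) or single
#'   256-vectors.
#' @return `B` x 768 matrix.
#' @export
fuse_embeddings <- function(e_mfcc, e_chroma, e_mspec) {
  as_mat <- function(e) if (is.null(dim(e))) matrix(e, nrow = 1L) else e
  e_mfcc <- as_mat(e_mfcc); e_chroma <- as_mat(e_chroma)
  e_mspec <- as_mat(e_mspec)
  if (ncol(e_mfcc) != 256L || ncol(e_chroma) != 256L ||
      ncol(e_mspec) != 256L) {
    abort("each embedding must be 256-dimensional")
  }
  cbind(e_mfcc, e_chroma, e_mspec)
}

build_model <- function(cfg, seed = 0L) {
  heads <- list(
    mfcc = build_feature_head(head_config(20L), derive_seed(seed, 101)),
    chroma = build_feature_head(head_config(12L), derive_seed(seed, 102)),
    mspec = build_feature_head(head_config(128L), derive_seed(seed, 103)))
  fusion_dim <- 3L * 256L
  if (cfg$variant == "trispectrakan") {
    trunk <- list(
      layer_bn1d(fusion_dim),
      layer_kan(fusion_dim, cfg$kan_hidden, cfg$spline,
                derive_seed(seed, 201)),
      layer_kan(cfg$kan_hidden, cfg$n_classes, cfg$spline,
                derive_seed(seed, 202)))
  } else {
    widths <- c(fusion_dim, cfg$mlp_widths, cfg$n_classes)
    trunk <- list()
    for (i in seq_len(length(widths) - 1L)) {
      trunk <- c(trunk, list(layer_dense(widths[i], widths[i + 1L],
                                         derive_seed(seed, 300 + i))))
      if (i < length(widths) - 1L) {
        trunk <- c(trunk, list(layer_relu(),
                               layer_dropout(cfg$dropout_rate)))
      }
    }
  }
  structure(list(variant = cfg$variant, config = cfg, heads = heads,
                 trunk = trunk, class_labels = DIAGNOSIS_LEVELS, seed = seed),
            class = "lung_sound_model")
}

#' Build the TriSpectraKAN classifier
#'
#' Three convolutional heads, 768-dim fusion, and a \[768, 769, 6\] KAN
#' classifier with a batch-normalized input so activations sit inside the
#' spline grid range.
#'
#' @param cfg A [model_config()] with `variant = "trispectrakan"`.
#' @param seed Integer seed for all weight initialization.
#' @return A `lung_sound_model`.
#' @export
build_trispectrakan <- function(cfg = model_config("trispectrakan"),
                                seed = 0L) {
  if (cfg$variant != "trispectrakan") abort("cfg$variant must be trispectrakan")
  build_model(cfg, seed)
}

#' Build the hybrid-CNN baseline
#'
#' Same heads and fusion as TriSpectraKAN, followed by a
#' 768-750-250-75-25-6 dense stack with ReLU and dropout between layers and
#' a bias on every dense layer.
#'
#' @param cfg A [model_config()] with `variant = "hybrid_cnn"`.
#' @param seed Integer seed.
#' @return A `lung_sound_model`.
#' @export
build_hybrid_cnn_baseline <- function(cfg = model_config("hybrid_cnn"),
                                      seed = 0L) {
  if (cfg$variant != "hybrid_cnn") abort("cfg$variant must be hybrid_cnn")
  build_model(cfg, seed)
}

#' Parameter count of a dense layer
#'
#' Weights plus biases: `n_in * n_out + n_out`.
#'
#' @param n_in,n_out Layer widths.
#' @return Integer count.
#' @export
dense_param_count <- function(n_in, n_out) {
  if (!is_count(n_in) || !is_count(n_out)) {
    abort("layer widths must be positive integers")
  }
  as.integer(n_in) * as.integer(n_out) + as.integer(n_out)
}

# Stack a list of feature triples into the three [H, W, 1, B] input arrays.
stack_triples <- function(triples) {
  if (inherits(triples, "feature_triple")) triples <- list(triples)
  B <- length(triples)
  mk <- function(field, H) {
    arr <- array(0, dim = c(H, triples[[1]]$n_frames, 1L, B))
    for (b in seq_len(B)) arr[, , 1L, b] <- triples[[b]][[field]]
    arr
  }
  list(mfcc = mk("mfcc", 20L), chroma = mk("chroma", 12L),
       mspec = mk("mspec", 128L))
}

model_forward <- function(model, inputs, training = FALSE) {
  e <- lapply(c("mfcc", "chroma", "mspec"), function(nm) {
    forward_stack(model$heads[[nm]], inputs[[nm]], training)
  })
  E <- fuse_embeddings(e[[1]], e[[2]], e[[3]])
  forward_stack(model$trunk, E, training)
}

model_backward <- function(model, d_logits) {
  dE <- backward_stack(model$trunk, d_logits)
  backward_stack(model$heads$mfcc, dE[, 1:256, drop = FALSE])
  backward_stack(model$heads$chroma, dE[, 257:512, drop = FALSE])
  backward_stack(model$heads$mspec, dE[, 513:768, drop = FALSE])
  invisible(NULL)
}

model_layers <- function(model) {
  c(model$heads$mfcc, model$heads$chroma, model$heads$mspec, model$trunk)
}

#' Total learnable parameters of a model
#'
#' @param model A `lung_sound_model`.
#' @return Integer count over every weight container.
#' @export
model_param_count <- function(model) {
  sum(vapply(model_layers(model), layer_param_count, integer(1)))
}

#' Predict class probabilities for segments
#'
#' Runs the model in evaluation mode and applies a softmax over the six
#' logits. The predicted label is the argmax, ties broken by the lowest
#' class index.
#'
#' @param object A `lung_sound_model`.
#' @param triples A `feature_triple` or list of them.
#' @param ... Unused.
#' @return A tibble with `label` (class code), `diagnosis` and `p_<class>`
#'   probability columns, one row per segment.
#' @export
predict.lung_sound_model <- function(object, triples, ...) {
  inputs <- stack_triples(triples)
  logits <- model_forward(object, inputs, training = FALSE)
  probs <- softmax_rows(logits)
  colnames(probs) <- paste0("p_", object$class_labels)
  label <- apply(probs, 1L, which.max) - 1L
  dplyr::bind_cols(
    tibble(label = as.integer(label),
           diagnosis = object$class_labels[label + 1L]),
    as_tibble(probs))
}

#' Layer/parameter summary of a model
#'
#' A layer listing in the conventional layer / output shape / parameter
#' format, including the per-head embeddings, the fusion width and the
#' classifier stack.
#'
#' @param object A `lung_sound_model`.
#' @param ... Unused.
#' @return A tibble with columns `layer`, `output_shape`, `params`
#'   (invisibly also printed).
#' @export
summary.lung_sound_model <- function(object, ...) {
  head_count <- function(h) sum(vapply(h, layer_param_count, integer(1)))
  rows <- list(
    c("mfcc input", "(20, 259, 1)", 0),
    c("chroma input", "(12, 259, 1)", 0),
    c("mspec input", "(128, 259, 1)", 0),
    c("mfccModel", "(None, 256)", head_count(object$heads$mfcc)),
    c("chromaModel", "(None, 256)", head_count(object$heads$chroma)),
    c("mspecModel", "(None, 256)", head_count(object$heads$mspec)),
    c("Concatenate", "(None, 768)", 0))
  if (object$variant == "trispectrakan") {
    kan_layers <- object$trunk[vapply(object$trunk, function(l) l$type,
                                      "") == "kan"]
    rows <- c(rows, list(
      c("KAN input (batch norm)", "(None, 768)",
        layer_param_count(object$trunk[[1]])),
      c("Hidden layer", paste0("(None, ", kan_layers[[1]]$hyper$n_out, ")"),
        layer_param_count(kan_layers[[1]])),
      c("Output layer", paste0("(None, ", kan_layers[[2]]$hyper$n_out, ")"),
        layer_param_count(kan_layers[[2]]))))
  } else {
    dense_layers <- object$trunk[vapply(object$trunk, function(l) l$type,
                                        "") == "dense"]
    for (dl in dense_layers) {
      rows <- c(rows, list(
        c("Dense", paste0("(None, ", ncol(dl$p$w), ")"),
          layer_param_count(dl))))
    }
  }
  out <- tibble(
    layer = vapply(rows, `[[`, "", 1L),
    output_shape = vapply(rows, `[[`, "", 2L),
    params = as.integer(vapply(rows, function(r) as.numeric(r[[3]]), 0)))
  out <- dplyr::bind_rows(out, tibble(layer = "Total", output_shape = "",
                                      params = model_param_count(object)))
  out
}

#' Save model parameters to a checkpoint
#'
#' One flat binary file of doubles plus a JSON header describing the
#' variant, seed, spline spec, class labels and per-tensor shapes.
#'
#' @param model A `lung_sound_model`.
#' @param path Checkpoint path (the header is written to `<path>.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  layers <- model_layers(model)
  tensors <- list()
  shapes <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in names(l$p)) {
      key <- paste0("L", i, ".", nm)
      tensors[[key]] <- as.numeric(l$p[[nm]])
      shapes[[key]] <- dim(l$p[[nm]]) %||% length(l$p[[nm]])
    }
    if (l$type %in% c("bn1d", "bn2d")) {
      for (nm in c("mean", "var")) {
        key <- paste0("L", i, ".running_", nm)
        tensors[[key]] <- as.numeric(l$state[[nm]])
        shapes[[key]] <- length(l$state[[nm]])
      }
    }
    if (l$type == "cnn_head") {
      for (nm in c("rm1", "rv1", "rm2", "rv2", "rm3", "rv3")) {
        key <- paste0("L", i, ".running_", nm)
        tensors[[key]] <- as.numeric(l$state[[nm]])
        shapes[[key]] <- length(l$state[[nm]])
      }
    }
  }
  header <- list(variant = model$variant, seed = model$seed,
                 spline = unclass(model$config$spline),
                 class_labels = model$class_labels,
                 n_classes = model$config$n_classes,
                 kan_hidden = model$config$kan_hidden,
                 mlp_widths = model$config$mlp_widths,
                 dropout_rate = model$config$dropout_rate,
                 tensors = shapes)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  for (key in names(tensors)) writeBin(tensors[[key]], con)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint path written by [save_model()].
#' @return A `lung_sound_model` with restored parameters and batch-norm
#'   running statistics.
#' @export
load_model <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- model_config(header$variant, n_classes = header$n_classes,
                      kan_hidden = header$kan_hidden,
                      spline = spline_spec(header$spline$order_k,
                                           header$spline$grid_size,
                                           header$spline$grid_range),
                      mlp_widths = header$mlp_widths,
                      dropout_rate = header$dropout_rate)
  model <- build_model(cfg, seed = header$seed)
  layers <- model_layers(model)
  con <- file(path, "rb")
  on.exit(close(con))
  for (key in names(header$tensors)) {
    shape <- header$tensors[[key]]
    vals <- readBin(con, "double", prod(shape))
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    i <- as.integer(sub("^L", "", parts[1]))
    nm <- parts[2]
    if (startsWith(nm, "running_")) {
      layers[[i]]$state[[sub("^running_", "", nm)]] <- vals
    } else {
      if (length(shape) > 1L) dim(vals) <- shape
      layers[[i]]$p[[nm]] <- vals
    }
  }
  model
}
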