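#' Rectified linear unit
#'
#' Elementwise `max(0, x)`, the activation used by every convolutional and
#' hidden dense layer of the network.
#'
#' @param x A numeric vector, matrix, or array.
#' @return An object of the same shape with negative entries clipped to zero.
#' @examples
#' relu(c(-2, 0, 3.5))
#' @export
relu <- function(x) {
  stopifnot(is.numeric(x))
  pmax(x, 0)
}

#' Softmax transform
#'
#' Maps a real vector of length `k` to a probability vector
#' \eqn{\sigma(z)_i = e^{z_i} / \sum_j e^{z_j}}. The maximum is subtracted
#' before exponentiation so the transform is overflow-safe and
#' shift-invariant.
#'
#' @param z A numeric vector.
#' @return A probability vector of the same length summing to 1.
#' @examples
#' softmax(c(0, log(3)))
#' @export
softmax <- function(z) {
  stopifnot(is.numeric(z), length(z) >= 1)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Binary cross-entropy loss
#'
#' \eqn{-(y \log p + (1-y)\log(1-p))} with `p` clipped to
#' `[eps, 1 - eps]` for numerical safety. Vectorized over its arguments.
#'
#' @param y Binary labels (0/1).
#' @param p Predicted probabilities of the positive class.
#' @param eps Clipping constant, default `1e-7`.
#' @return Nonnegative loss values, one per element.
#' @examples
#' bce_loss(1, 0.5) # log(2)
#' @export
bce_loss <- function(y, p, eps = 1e-7) {
  stopifnot(all(y %in% c(0, 1)))
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Architecture specification for the block-structured network
#'
#' Describes a network of `n_blocks` convolutional blocks (two convolution
#' layers with batch normalization and ReLU — the first with valid padding,
#' the second padded to conserve length — then max pooling and dropout),
#' followed by a flatten layer and a stack of dense layers ending in the
#' classifier. Filters start at `base_filters` and double with each block.
#'
#' For `output_activation = "sigmoid"` the last entry of `dense_sizes` must
#' be 1 (the classifier unit). For `"softmax"` the classifier layer size is
#' resolved to the number of classes by [build_network()] and appended to
#' `dense_sizes` at that point.
#'
#' @param n_blocks Number of convolutional blocks (>= 1).
#' @param kernel_size Convolution kernel width (3 for time-series/genomic
#'   recipes, 5 for text).
#' @param pool_size Max-pooling width (2 or 3 depending on modality).
#' @param dense_sizes Integer vector of dense layer widths after flatten.
#' @param output_activation `"sigmoid"` (binary) or `"softmax"`.
#' @param optimizer `"adam"` or `"rmsprop"`.
#' @param base_filters Filters in the first block, default 64.
#' @param dropout_rate Dropout rate at the end of every block, default 0.4.
#' @param embedding Optional `list(vocab_size =, embed_dim =)`; required for
#'   the text modality, disallowed otherwise.
#' @param input_shape Optional input dims `(length, channels)` or
#'   `(max_len)` for text; usually inferred from data at build time.
#' @return An object of class `architecture_spec`.
#' @seealso [recipe_genomic()], [recipe_activity()], [recipe_text()]
#' @export
architecture_spec <- function(n_blocks,
                              kernel_size,
                              pool_size,
                              dense_sizes,
                              output_activation = c("sigmoid", "softmax"),
                              optimizer = c("adam", "rmsprop"),
                              base_filters = 64,
                              dropout_rate = 0.4,
                              embedding = NULL,
                              input_shape = NULL) {
  output_activation <- match.arg(output_activation)
  optimizer <- match.arg(optimizer)
  stopifnot(is_count(n_blocks), is_count(kernel_size), is_count(pool_size),
            is_count(base_filters), length(dense_sizes) >= 1,
            all(vapply(dense_sizes, is_count, logical(1))),
            dropout_rate >= 0, dropout_rate < 1)
  if (output_activation == "sigmoid" && tail(dense_sizes, 1) != 1) {
    abort("sigmoid output requires the last dense layer to have 1 unit")
  }
  if (!is.null(embedding)) {
    stopifnot(is_count(embedding$vocab_size), is_count(embedding$embed_dim))
  }
  structure(
    list(n_blocks = as.integer(n_blocks),
         base_filters = as.integer(base_filters),
         kernel_size = as.integer(kernel_size),
         pool_size = as.integer(pool_size),
         dropout_rate = dropout_rate,
         dense_sizes = as.integer(dense_sizes),
         output_activation = output_activation,
         optimizer = optimizer,
         embedding = embedding,
         input_shape = input_shape),
    class = "architecture_spec"
  )
}

#' @export
print.architecture_spec <- function(x, ...) {
  emb <- if (is.null(x$embedding)) "none" else
    sprintf("%d x %d", x$embedding$vocab_size, x$embedding$embed_dim)
  cat(sprintf(
    paste0("<architecture_spec> %d block(s), base filters %d, kernel %d, ",
           "pool %d,\n  dropout %.2f, dense [%s], %s output, %s optimizer, ",
           "embedding %s\n"),
    x$n_blocks, x$base_filters, x$kernel_size, x$pool_size, x$dropout_rate,
    paste(x$dense_sizes, collapse = ", "), x$output_activation, x$optimizer,
    emb))
  invisible(x)
}

#' Per-modality architecture recipes
#'
#' The three architecture variants used across the benchmark tasks:
#' * `recipe_genomic()`: kernel 3, pool 2, dense 64 then a single sigmoid
#'   classifier unit, Adam. (For binary labels under cross-entropy a 1-unit
#'   sigmoid head is equivalent to a 2-unit softmax head.)
#' * `recipe_activity()`: kernel 3, pool 2, dense 256 and 128 then a softmax
#'   classifier sized to the number of classes at build time, Adam.
#' * `recipe_text()`: token embedding (vocabulary 10000, dimension 64),
#'   kernel 5, pool 3, dense 64 then a sigmoid unit, RMSprop.
#'
#' @param n_blocks Number of convolutional blocks.
#' @param vocab_size,embed_dim Embedding table dimensions (text only).
#' @return An [architecture_spec()].
#' @export
recipe_genomic <- function(n_blocks = 3) {
  architecture_spec(n_blocks, kernel_size = 3, pool_size = 2,
                    dense_sizes = c(64, 1),
                    output_activation = "sigmoid", optimizer = "adam")
}

#' @rdname recipe_genomic
#' @export
recipe_activity <- function(n_blocks = 1) {
  architecture_spec(n_blocks, kernel_size = 3, pool_size = 2,
                    dense_sizes = c(256, 128),
                    output_activation = "softmax", optimizer = "adam")
}

#' @rdname recipe_genomic
#' @export
recipe_text <- function(n_blocks = 3, vocab_size = 10000, embed_dim = 64) {
  architecture_spec(n_blocks, kernel_size = 5, pool_size = 3,
                    dense_sizes = c(64, 1),
                    output_activation = "sigmoid", optimizer = "rmsprop",
                    embedding = list(vocab_size = as.integer(vocab_size),
                                     embed_dim = as.integer(embed_dim)))
}

# Resolve input dims from a labeled_dataset or raw array for a given spec.
resolve_input_shape <- function(spec, X) {
  d <- dim(X)
  if (!is.null(spec$embedding)) {
    stopifnot(length(d) == 2)
    return(c(d[2]))
  }
  if (length(d) == 2) return(c(d[2], 1L))  # flat features as length x 1
  stopifnot(length(d) == 3)
  c(d[2], d[3])
}

#' Build an untrained network from an architecture specification
#'
#' Assembles the layer stack, initializes the weights, and derives the
#' catalog of extraction-eligible layers. Each block contributes three
#' catalog entries (`conv1`, `conv2`, `pool`); the head contributes the
#' flatten layer and every dense layer, so the catalog has
#' `3 * n_blocks + 1 + length(dense_sizes)` entries (dense sizes as resolved,
#' i.e. including the classifier layer).
#'
#' @param spec An [architecture_spec()].
#' @param n_classes Number of classes (>= 2).
#' @param input_shape Input dims `(length, channels)`, or `max_len` for text;
#'   may be omitted if `spec$input_shape` is set.
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `conv_network` with elements `spec`, `layers`,
#'   `catalog` (a tibble), `n_classes`, and `n_params`.
#' @examples
#' net <- build_network(recipe_genomic(3), n_classes = 2,
#'                      input_shape = c(57, 4), seed = 1)
#' layer_catalog(net)
#' @export
build_network <- function(spec, n_classes, input_shape = NULL, seed = NULL) {
  stopifnot(inherits(spec, "architecture_spec"), is_count(n_classes),
            n_classes >= 2)
  input_shape <- input_shape %||% spec$input_shape
  if (is.null(input_shape)) abort("input_shape must be given")

  dense_sizes <- spec$dense_sizes
  if (spec$output_activation == "softmax" &&
      tail(dense_sizes, 1) != n_classes) {
    dense_sizes <- c(dense_sizes, as.integer(n_classes))
  }
  if (spec$output_activation == "sigmoid" && n_classes != 2) {
    abort("sigmoid output supports exactly 2 classes")
  }
  spec$dense_sizes <- dense_sizes
  spec$input_shape <- input_shape

  with_seed_(seed, {
    layers <- list()
    catalog <- list()
    add_cat <- function(name, kind, shape, layer_id) {
      catalog[[length(catalog) + 1]] <<- tibble::tibble(
        index = length(catalog) + 1L, name = name, kind = kind,
        output_shape = paste(shape, collapse = "x"),
        n_features = prod(shape), layer_id = layer_id)
    }

    if (!is.null(spec$embedding)) {
      stopifnot(length(input_shape) == 1)
      layers <- c(layers, list(new_embedding_layer(spec$embedding$vocab_size,
                                                   spec$embedding$embed_dim)))
      len <- input_shape[1]; ch <- spec$embedding$embed_dim
    } else {
      stopifnot(length(input_shape) == 2)
      len <- input_shape[1]; ch <- input_shape[2]
    }

    for (b in seq_len(spec$n_blocks)) {
      filters <- spec$base_filters * 2L^(b - 1L)
      if (len < spec$kernel_size) {
        abort(sprintf(
          "block %d: spatial length %d is smaller than kernel %d; use fewer blocks",
          b, len, spec$kernel_size))
      }
      layers <- c(layers, list(new_conv_layer(spec$kernel_size, ch, filters,
                                              "valid")))
      len <- len - spec$kernel_size + 1L
      add_cat(sprintf("block%d_conv1", b), "conv", c(len, filters),
              length(layers))
      layers <- c(layers, list(new_conv_layer(spec$kernel_size, filters,
                                              filters, "same")))
      add_cat(sprintf("block%d_conv2", b), "conv", c(len, filters),
              length(layers))
      if (len < spec$pool_size) {
        abort(sprintf(
          "block %d: spatial length %d is smaller than pool size %d; use fewer blocks",
          b, len, spec$pool_size))
      }
      layers <- c(layers, list(new_pool_layer(spec$pool_size)))
      len <- len %/% spec$pool_size
      add_cat(sprintf("block%d_pool", b), "pool", c(len, filters),
              length(layers))
      layers <- c(layers, list(new_dropout_layer(spec$dropout_rate)))
      ch <- filters
    }

    layers <- c(layers, list(new_flatten_layer()))
    add_cat("flatten", "flatten", c(len * ch), length(layers))

    d_in <- len * ch
    n_dense <- length(dense_sizes)
    for (i in seq_len(n_dense)) {
      act <- if (i < n_dense) "relu" else spec$output_activation
      layers <- c(layers, list(new_dense_layer(d_in, dense_sizes[i], act)))
      add_cat(sprintf("dense%d", i), "dense", c(dense_sizes[i]),
              length(layers))
      d_in <- dense_sizes[i]
    }

    catalog <- dplyr::bind_rows(catalog)
    n_params <- sum(vapply(layers, function(ly) {
      if (is.null(ly$par)) 0 else sum(vapply(ly$par, length, numeric(1)))
    }, numeric(1)))
    log_msg(sprintf("built %d-block network: %d extractable layers, %d trainable parameters",
                    spec$n_blocks, nrow(catalog), n_params))
    structure(list(spec = spec, layers = layers, catalog = catalog,
                   n_classes = as.integer(n_classes), n_params = n_params),
              class = "conv_network")
  })
}

#' Layer catalog of a network
#'
#' The ordered table of extraction-eligible layers: three per convolutional
#' block (`conv1`, `conv2`, `pool`), then `flatten` and each dense layer.
#' Convolution and dense entries refer to post-activation outputs.
#'
#' @param net A `conv_network` or `trained_network`.
#' @return A tibble with columns `index`, `name`, `kind`, `output_shape`,
#'   `n_features`.
#' @export
layer_catalog <- function(net) {
  stopifnot(inherits(net, c("conv_network", "trained_network")))
  dplyr::select(net$catalog, -"layer_id")
}

#' @export
print.conv_network <- function(x, ...) {
  cat(sprintf("<conv_network> %d block(s), %d classes, %g trainable parameters\n",
              x$spec$n_blocks, x$n_classes, x$n_params))
  print(layer_catalog(x), n = Inf)
  invisible(x)
}

# Full forward pass. Returns probabilities, per-layer caches (training only),
# the possibly-updated layers (batch-norm running stats), and the activation
# captured at `capture_layer_id` (position in the layers list), if any.
net_forward <- function(layers, X, training = FALSE, capture_layer_id = NULL,
                        keep_caches = training) {
  caches <- vector("list", length(layers))
  captured <- NULL
  out <- X
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    r <- switch(ly$type,
      embedding = embedding_forward(ly, out),
      conv = conv_forward(ly, out, training),
      pool = pool_forward(ly, out),
      dropout = dropout_forward(ly, out, training),
      flatten = flatten_forward(ly, out),
      dense = dense_forward(ly, out, training)
    )
    out <- r$out
    if (keep_caches) caches[[i]] <- r$cache
    if (!is.null(r$layer)) layers[[i]] <- r$layer
    if (!is.null(capture_layer_id) && i == capture_layer_id) {
      captured <- out
      if (!keep_caches) break  # extraction never needs the deeper layers
    }
  }
  list(out = out, caches = caches, layers = layers, captured = captured)
}
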