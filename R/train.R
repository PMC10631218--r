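# Mini-batch training of the convolutional network with early stopping on
# validation loss (patience in epochs, best weights restored at stop).

# Early stopping on a monitored loss: a new strict minimum resets the
# patience counter; `patience` consecutive non-improving epochs stop.
es_init <- function(patience) {
  list(best = Inf, best_epoch = 0L, wait = 0L, patience = patience,
       stop = FALSE)
}

es_update <- function(es, loss, epoch) {
  if (loss < es$best) {
    es$best <- loss; es$best_epoch <- as.integer(epoch); es$wait <- 0L
  } else {
    es$wait <- es$wait + 1L
    if (es$wait >= es$patience) es$stop <- TRUE
  }
  es
}

labels_to_targets <- function(y, n_classes, output_activation) {
  if (output_activation == "sigmoid") {
    matrix(as.numeric(y), ncol = 1)
  } else {
    Y <- matrix(0, length(y), n_classes)
    Y[cbind(seq_along(y), y + 1L)] <- 1
    Y
  }
}

# Mean cross-entropy of probability matrix P against target matrix Y.
ce_loss <- function(P, Y, eps = 1e-7) {
  P <- pmin(pmax(P, eps), 1 - eps)
  if (ncol(P) == 1) {
    mean(-(Y * log(P) + (1 - Y) * log(1 - P)))
  } else {
    mean(-rowSums(Y * log(P)))
  }
}

prob_to_class <- function(P) {
  if (ncol(P) == 1) as.integer(P[, 1] > 0.5) else max.col(P, "first") - 1L
}

model_input <- function(X) {
  if (length(dim(X)) == 2 && is.double(X)) array(X, c(dim(X), 1L)) else X
}

# Datasets reach the network as (n, length, channels) arrays; flat feature
# tables are treated as length x 1 signals, token matrices stay integer.
dataset_input <- function(ds) {
  X <- if (inherits(ds, "labeled_dataset")) ds$X else ds
  if (is.integer(X) && length(dim(X)) == 2) return(X)          # tokens
  if (length(dim(X)) == 2) return(array(X, c(dim(X), 1L)))     # flat
  X
}

dataset_labels <- function(ds) {
  if (inherits(ds, "labeled_dataset")) ds$y else abort("labels required")
}

#' Train a network with early stopping on validation loss
#'
#' Runs mini-batch gradient descent (Adam or RMSprop as fixed by the
#' architecture spec) under cross-entropy loss, monitoring validation loss
#' after every epoch. Training stops when the validation loss has not
#' reached a new strict minimum for `patience` consecutive epochs, or at
#' `max_epochs`; the weights from the best-validation-loss epoch are
#' restored.
#'
#' @param net An untrained `conv_network` from [build_network()].
#' @param train,val `labeled_dataset` objects (see [labeled_dataset()]).
#' @param max_epochs Maximum number of epochs (default 100).
#' @param batch_size Mini-batch size (default 32).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param seed Optional integer seed driving shuffling and dropout.
#' @param verbose Log one line per epoch.
#' @return A `trained_network`: the fitted layers plus `history` (per-epoch
#'   tibble of train/val loss and accuracy) and `stopped_epoch`.
#' @export
train_network <- function(net, train, val, max_epochs = 100, batch_size = 32,
                          patience = 10, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "conv_network"), is_count(max_epochs),
            is_count(batch_size), is_count(patience))
  Xtr <- dataset_input(train); ytr <- dataset_labels(train)
  Xva <- dataset_input(val); yva <- dataset_labels(val)
  n <- dim(Xtr)[1]
  if (n < 1 || dim(Xva)[1] < 1) abort("train and validation sets must be nonempty")
  act <- net$spec$output_activation
  Ytr <- labels_to_targets(ytr, net$n_classes, act)
  Yva <- labels_to_targets(yva, net$n_classes, act)

  layers <- net$layers
  opts <- lapply(layers, function(ly) {
    if (is.null(ly$par)) NULL else opt_init(net$spec$optimizer, ly$par)
  })
  dense_ids <- which(vapply(layers, function(l) l$type == "dense", logical(1)))
  out_id <- max(dense_ids)

  history <- vector("list", max_epochs)
  es <- es_init(patience)
  best_layers <- layers
  stopped <- max_epochs

  with_seed_(seed, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      ep_loss <- 0; ep_correct <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1, n)]
        B <- length(idx)
        Xb <- index_first(Xtr, idx)
        Yb <- Ytr[idx, , drop = FALSE]
        fw <- net_forward(layers, Xb, training = TRUE)
        layers <- fw$layers
        P <- fw$out
        loss <- ce_loss(P, Yb)
        if (!is.finite(loss)) {
          abort(sprintf("non-finite loss at epoch %d; try a smaller learning rate or check inputs", epoch))
        }
        ep_loss <- ep_loss + loss * B
        ep_correct <- ep_correct + sum(prob_to_class(P) == prob_to_class(Yb * 1))
        # fused activation+loss gradient at the classifier layer
        grad <- (P - Yb) / B
        for (i in rev(seq_along(layers))) {
          ly <- layers[[i]]
          bk <- switch(ly$type,
            dense = dense_backward(ly, fw$caches[[i]], grad,
                                   wrt = if (i == out_id) "z" else "act"),
            flatten = flatten_backward(ly, fw$caches[[i]], grad),
            dropout = dropout_backward(ly, fw$caches[[i]], grad),
            pool = pool_backward(ly, fw$caches[[i]], grad),
            conv = conv_backward(ly, fw$caches[[i]], grad),
            embedding = embedding_backward(ly, fw$caches[[i]], grad)
          )
          if (!is.null(bk$grads)) {
            st <- opt_step(opts[[i]], layers[[i]]$par, bk$grads)
            opts[[i]] <- st$opt
            layers[[i]]$par <- st$par
          }
          grad <- bk$dX
          if (is.null(grad)) break  # embedding reached, nothing upstream
        }
      }
      # validation metrics in inference mode
      va <- net_forward(layers, Xva, training = FALSE, keep_caches = FALSE)
      val_loss <- ce_loss(va$out, Yva)
      val_acc <- mean(prob_to_class(va$out) == yva)
      tr_loss <- ep_loss / n
      tr_acc <- ep_correct / n
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = tr_loss, train_acc = tr_acc,
        val_loss = val_loss, val_acc = val_acc)
      if (verbose) {
        log_msg(sprintf("epoch %3d: loss %.4f acc %.3f | val loss %.4f acc %.3f",
                        epoch, tr_loss, tr_acc, val_loss, val_acc))
      }
      improved <- val_loss < es$best
      es <- es_update(es, val_loss, epoch)
      if (improved) best_layers <- layers
      if (es$stop) { stopped <- epoch; break }
    }
  })

  structure(
    list(spec = net$spec, layers = best_layers, catalog = net$catalog,
         n_classes = net$n_classes, n_params = net$n_params,
         history = dplyr::bind_rows(history),
         stopped_epoch = as.integer(stopped), best_epoch = es$best_epoch,
         seed = seed),
    class = c("trained_network", "conv_network"))
}

# Subset the first axis of a 2- or 3-d array.
index_first <- function(X, idx) {
  if (length(dim(X)) == 3) X[idx, , , drop = FALSE] else X[idx, , drop = FALSE]
}

#' @export
print.trained_network <- function(x, ...) {
  cat(sprintf(
    "<trained_network> %d block(s), stopped at epoch %d (best epoch %d, val loss %.4f)\n",
    x$spec$n_blocks, x$stopped_epoch, x$best_epoch,
    x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' Predict with a trained network (deep-only baseline)
#'
#' Runs the forward pass in inference mode (dropout off, batch-norm using
#' learned statistics).
#'
#' @param object A `trained_network`.
#' @param newdata A `labeled_dataset` or raw input array.
#' @param type `"prob"` for class probabilities, `"class"` for hard labels.
#' @param ... Unused.
#' @return For `"prob"` an `n x k` probability matrix (binary sigmoid heads
#'   are expanded to two columns summing to 1); for `"class"` integer labels
#'   in `[0, k)`.
#' @export
predict.trained_network <- function(object, newdata,
                                    type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- dataset_input(newdata)
  check_input_shape(object, X)
  P <- net_forward(object$layers, X, training = FALSE, keep_caches = FALSE)$out
  if (ncol(P) == 1) P <- cbind(1 - P[, 1], P[, 1])
  if (type == "class") max.col(P, "first") - 1L else P
}

check_input_shape <- function(net, X) {
  want <- net$spec$input_shape
  d <- dim(X)
  ok <- if (length(want) == 1) length(d) == 2 && d[2] == want
        else length(d) == 3 && all(d[2:3] == want)
  if (!ok) {
    abort(sprintf("input shape (%s) does not match network input (%s)",
                  paste(d[-1], collapse = "x"), paste(want, collapse = "x")))
  }
  invisible(TRUE)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a fitted network
#'
#' @param x A `trained_network`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `train_loss`, `train_acc`,
#'   `val_loss`, `val_acc`).
#' @exportS3Method generics::tidy
tidy.trained_network <- function(x, ...) x$history

#' @rdname tidy.trained_network
#' @return For `glance()`: a one-row tibble with `n_blocks`, `n_params`,
#'   `stopped_epoch`, `best_epoch`, and the best-epoch validation metrics.
#' @exportS3Method generics::glance
glance.trained_network <- function(x, ...) {
  b <- x$history[x$best_epoch, ]
  tibble::tibble(n_blocks = x$spec$n_blocks, n_params = x$n_params,
                 stopped_epoch = x$stopped_epoch, best_epoch = x$best_epoch,
                 val_loss = b$val_loss, val_acc = b$val_acc)
}

#' Plot training curves
#'
#' @param object A `trained_network`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss and accuracy by epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.trained_network <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = c("split", "metric"), names_sep = "_")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
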