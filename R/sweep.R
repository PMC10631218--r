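# Experimental protocol: grow convolutional blocks, sweep every extraction
# layer, compare hybrid accuracy against the deep-only and trees-on-raw
# baselines, and trace accuracy against training-set size.

#' Flatten a dataset's raw tensor into a plain feature table
#'
#' The representation the trees-on-raw baseline consumes: time-series and
#' one-hot tensors are flattened position-major/channel-minor, flat tables
#' pass through, token matrices are cast to numeric.
#'
#' @param ds A `labeled_dataset`.
#' @return A numeric matrix with one row per example.
#' @export
raw_feature_table <- function(ds) {
  X <- ds$X
  d <- dim(X)
  if (length(d) == 3) {
    out <- matrix(aperm(X, c(1, 3, 2)), d[1], d[2] * d[3])
    colnames(out) <- sprintf("p%d_c%d", rep(seq_len(d[2]), each = d[3]),
                             rep(seq_len(d[3]), d[2]))
  } else {
    out <- matrix(as.numeric(X), d[1], d[2])
    colnames(out) <- colnames(X) %||% sprintf("f%d", seq_len(d[2]))
  }
  out
}

#' Sweep every extraction layer of a trained network
#'
#' For each layer in the catalog: extract train and evaluation features,
#' fit the boosted-tree classifier on the training features, and record
#' accuracy on the evaluation set.
#'
#' @param net A `trained_network`.
#' @param train,eval `labeled_dataset` partitions.
#' @param seed Seed passed to each tree fit.
#' @return A tibble with `layer_index`, `layer_name`, `n_features`,
#'   `accuracy` — one row per catalog layer.
#' @export
run_layer_sweep <- function(net, train, eval, seed = 0) {
  sw <- layer_sweep_multi(net, train, list(accuracy = eval), seed)
  sw
}

# Fit once per layer, evaluate on several partitions.
layer_sweep_multi <- function(net, train, eval_sets, seed = 0) {
  cat_tbl <- net$catalog
  rows <- lapply(seq_len(nrow(cat_tbl)), function(i) {
    fm_tr <- extract_features(net, i, train)
    model <- fit_trees(fm_tr, train$y, seed = seed)
    accs <- lapply(eval_sets, function(ev) {
      evaluate_accuracy(model, extract_features(net, i, ev), ev$y)
    })
    dplyr::bind_cols(
      tibble::tibble(layer_index = cat_tbl$index[i],
                     layer_name = cat_tbl$name[i],
                     n_features = cat_tbl$n_features[i]),
      tibble::as_tibble(accs))
  })
  dplyr::bind_rows(rows)
}

net_accuracy <- function(net, ds) {
  mean(predict(net, ds, type = "class") == ds$y)
}

#' Grow convolutional blocks and sweep extraction layers
#'
#' The full model-selection protocol: for b = 1, 2, ... train a b-block
#' network from scratch, sweep every extraction layer with the boosted-tree
#' classifier, and stop when the best-over-layers accuracy no longer
#' improves on the previous block count (strict comparison), when
#' `max_blocks` is reached, or when the input is too short for another
#' block. The best configuration is reported with ties broken toward fewer
#' blocks, then the shallower layer.
#'
#' Layer selection uses the validation split by default; `select_on =
#' "test"` reproduces protocols that select directly on the test set.
#' Reported `best` accuracy is always the held-out test accuracy of the
#' selected configuration.
#'
#' @param data A list with `train`, `val`, `test` `labeled_dataset`s (as
#'   returned by [split_dataset()]).
#' @param base_spec An [architecture_spec()]; its `n_blocks` is overridden
#'   by the sweep.
#' @param max_blocks Maximum number of blocks to try (default 4).
#' @param seed Master seed; per-block training seeds are derived from it.
#' @param select_on `"validation"` (default) or `"test"`.
#' @param max_epochs,batch_size,patience Training settings per block
#'   (defaults 30 / 32 / 10).
#' @return A `sweep_result` with elements `grid` (per (block, layer)
#'   accuracies), `dl_alone` (network-only accuracy per block count),
#'   `best`, `networks`, `select_on`, `seed`.
#' @export
run_block_sweep <- function(data, base_spec, max_blocks = 4, seed = NULL,
                            select_on = c("validation", "test"),
                            max_epochs = 30, batch_size = 32, patience = 10) {
  select_on <- match.arg(select_on)
  stopifnot(is_count(max_blocks))
  check_split(data)
  seeds <- derive_seeds(seed %||% 0L, max_blocks + 1L)
  sel_col <- if (select_on == "validation") "val_accuracy" else "test_accuracy"

  grid <- list(); dl <- list(); nets <- list()
  best_prev <- -Inf
  for (b in seq_len(max_blocks)) {
    spec_b <- base_spec
    spec_b$n_blocks <- b
    net0 <- tryCatch(
      build_network(spec_b, n_classes = length(data$train$class_names),
                    input_shape = resolve_input_shape(spec_b, dataset_input(data$train)),
                    seed = seeds[b]),
      error = function(e) {
        log_msg(sprintf("stopping block growth at b=%d: %s", b,
                        conditionMessage(e)))
        NULL
      })
    if (is.null(net0)) break
    net <- train_network(net0, data$train, data$val, max_epochs = max_epochs,
                         batch_size = batch_size, patience = patience,
                         seed = seeds[b])
    nets[[b]] <- net
    sw <- layer_sweep_multi(net, data$train,
                            list(val_accuracy = data$val,
                                 test_accuracy = data$test),
                            seed = seeds[max_blocks + 1L])
    grid[[b]] <- dplyr::mutate(sw, n_blocks = b, .before = 1)
    dl[[b]] <- tibble::tibble(n_blocks = b,
                              val_accuracy = net_accuracy(net, data$val),
                              test_accuracy = net_accuracy(net, data$test))
    best_b <- max(sw[[sel_col]])
    log_msg(sprintf("block sweep b=%d: best %s over layers = %.4f", b,
                    select_on, best_b))
    if (best_b <= best_prev) break
    best_prev <- best_b
  }

  grid <- dplyr::bind_rows(grid)
  best <- best_from_grid(grid, sel_col)
  structure(list(grid = grid, dl_alone = dplyr::bind_rows(dl), best = best,
                 networks = nets, select_on = select_on, seed = seed),
            class = "sweep_result")
}

# Best (blocks, layer) configuration under the selection metric; ties go
# to fewer blocks, then the shallower layer.
best_from_grid <- function(grid, sel_col) {
  ord <- order(-grid[[sel_col]], grid$n_blocks, grid$layer_index)
  top <- grid[ord[1], ]
  list(n_blocks = top$n_blocks, layer_index = top$layer_index,
       layer_name = top$layer_name, accuracy = top$test_accuracy,
       selection_accuracy = top[[sel_col]])
}

check_split <- function(data) {
  if (!is.list(data) || !all(c("train", "val", "test") %in% names(data)) ||
      !all(vapply(data[c("train", "val", "test")], inherits, logical(1),
                  "labeled_dataset"))) {
    abort("data must be a list with labeled_dataset elements train, val, test (see split_dataset())")
  }
  invisible(TRUE)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "<sweep_result> %d block level(s) x layers; best: %d block(s), layer %d (%s), test accuracy %.4f\n",
    max(x$grid$n_blocks), x$best$n_blocks, x$best$layer_index,
    x$best$layer_name, x$best$accuracy))
  invisible(x)
}

#' Tidy and summarize sweep results
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return `tidy()`: the (block, layer) accuracy grid. `glance()`: one row
#'   with the selected configuration and the baseline accuracies.
#' @exportS3Method generics::tidy
tidy.sweep_result <- function(x, ...) x$grid

#' @rdname tidy.sweep_result
#' @exportS3Method generics::glance
glance.sweep_result <- function(x, ...) {
  tibble::tibble(best_n_blocks = x$best$n_blocks,
                 best_layer_index = x$best$layer_index,
                 best_layer_name = x$best$layer_name,
                 best_accuracy = x$best$accuracy,
                 dl_alone_best = max(x$dl_alone$test_accuracy),
                 select_on = x$select_on)
}

#' Plot a sweep result
#'
#' Test accuracy per extraction layer, one line per block count, with the
#' deep-only baseline as dashed horizontal lines.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.sweep_result <- function(object, ...) {
  g <- dplyr::mutate(object$grid, n_blocks = factor(.data$n_blocks))
  d <- dplyr::mutate(object$dl_alone, n_blocks = factor(.data$n_blocks))
  ggplot2::ggplot(g, ggplot2::aes(.data$layer_index, .data$test_accuracy,
                                  colour = .data$n_blocks)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(data = d,
                        ggplot2::aes(yintercept = .data$test_accuracy,
                                     colour = .data$n_blocks),
                        linetype = "dashed") +
    ggplot2::labs(x = "extraction layer", y = "test accuracy",
                  colour = "blocks",
                  caption = "dashed: network-only baseline") +
    ggplot2::theme_minimal()
}

#' Deep-only and trees-on-raw baseline accuracies
#'
#' Trains the network end-to-end and reports its own test accuracy
#' (deep-only baseline), and fits the boosted-tree classifier directly on
#' the raw (or supplied handcrafted) feature table (trees-on-raw baseline).
#'
#' @param data A `train`/`val`/`test` split list.
#' @param spec An [architecture_spec()].
#' @param seed Master seed.
#' @param handcrafted Optional function `ds -> matrix` supplying the raw
#'   table (default [raw_feature_table()]).
#' @param max_epochs,batch_size,patience Training settings.
#' @return A tibble with columns `method` (`dl_alone`, `ml_raw`) and
#'   `accuracy`.
#' @export
run_baselines <- function(data, spec, seed = NULL, handcrafted = NULL,
                          max_epochs = 30, batch_size = 32, patience = 10) {
  check_split(data)
  seeds <- derive_seeds(seed %||% 0L, 2L)
  featurize <- handcrafted %||% raw_feature_table
  net0 <- build_network(spec, n_classes = length(data$train$class_names),
                        input_shape = resolve_input_shape(spec, dataset_input(data$train)),
                        seed = seeds[1])
  net <- train_network(net0, data$train, data$val, max_epochs = max_epochs,
                       batch_size = batch_size, patience = patience,
                       seed = seeds[1])
  model <- fit_trees(featurize(data$train), data$train$y, seed = seeds[2])
  tibble::tibble(
    method = c("dl_alone", "ml_raw"),
    accuracy = c(net_accuracy(net, data$test),
                 evaluate_accuracy(model, featurize(data$test), data$test$y)))
}

# Stratified subsample of a training set: every class keeps its share and
# tiny sizes still contain all classes.
stratified_subsample <- function(ds, size) {
  n <- ds_n(ds)
  if (size > n) abort(sprintf("requested size %d exceeds available n %d", size, n))
  by_class <- split(seq_len(n), ds$y)
  want <- pmax(round(size * lengths(by_class) / n), 1L)
  # absorb rounding drift where there is most (or least) headroom
  while (sum(want) > size) {
    j <- which.max(want)
    if (want[j] <= 1L) break
    want[j] <- want[j] - 1L
  }
  while (sum(want) < size) {
    j <- which.max(lengths(by_class) - want)
    want[j] <- want[j] + 1L
  }
  idx <- unlist(mapply(function(ix, w) sample(ix, w), by_class, want,
                       SIMPLIFY = FALSE), use.names = FALSE)
  ds_subset(ds, sort(idx))
}

#' Accuracy versus training-set size for hybrid and deep-only models
#'
#' For each requested size and replicate: stratified-subsample the training
#' set, train the network from scratch, record its own test accuracy
#' (deep-only), then sweep every extraction layer, choose the best layer on
#' the validation split, and record the hybrid test accuracy at that layer.
#'
#' @param data A `train`/`val`/`test` split list.
#' @param spec An [architecture_spec()].
#' @param sizes Increasing vector of training-set sizes.
#' @param replicates Replicates per size (default 5).
#' @param seed Master seed; replicate seeds are derived from it.
#' @param select_on `"validation"` (default) or `"test"` layer selection.
#' @param max_epochs,batch_size,patience Training settings.
#' @return A `learning_curve_result`: tibble `results` with `size`,
#'   `replicate`, `method` (`hybrid`, `dl_alone`), `accuracy`.
#' @export
run_learning_curve <- function(data, spec, sizes, replicates = 5,
                               seed = NULL,
                               select_on = c("validation", "test"),
                               max_epochs = 30, batch_size = 32,
                               patience = 10) {
  select_on <- match.arg(select_on)
  check_split(data)
  stopifnot(length(sizes) >= 1, all(diff(sizes) > 0))
  if (max(sizes) > ds_n(data$train)) {
    abort(sprintf("largest size %d exceeds training set size %d",
                  max(sizes), ds_n(data$train)))
  }
  sel_col <- if (select_on == "validation") "val_accuracy" else "test_accuracy"
  seeds <- derive_seeds(seed %||% 0L, replicates)
  rows <- list()
  for (r in seq_len(replicates)) {
    sub_seeds <- derive_seeds(seeds[r], length(sizes))
    for (si in seq_along(sizes)) {
      s <- sizes[si]
      sd_ <- sub_seeds[si]
      tr <- with_seed_(sd_, stratified_subsample(data$train, s))
      net0 <- build_network(spec, n_classes = length(tr$class_names),
                            input_shape = resolve_input_shape(spec, dataset_input(tr)),
                            seed = sd_)
      net <- train_network(net0, tr, data$val, max_epochs = max_epochs,
                           batch_size = batch_size, patience = patience,
                           seed = sd_)
      sw <- layer_sweep_multi(net, tr, list(val_accuracy = data$val,
                                            test_accuracy = data$test),
                              seed = sd_)
      hybrid_acc <- sw$test_accuracy[which.max(sw[[sel_col]])]
      rows[[length(rows) + 1]] <- tibble::tibble(
        size = s, replicate = r,
        method = c("hybrid", "dl_alone"),
        accuracy = c(hybrid_acc, net_accuracy(net, data$test)))
      log_msg(sprintf("learning curve rep %d size %d: hybrid %.4f, dl %.4f",
                      r, s, hybrid_acc, tail(rows[[length(rows)]]$accuracy, 1)))
    }
  }
  structure(list(results = dplyr::bind_rows(rows),
                 sizes = sizes, replicates = replicates, seed = seed,
                 select_on = select_on),
            class = "learning_curve_result")
}

#' @export
print.learning_curve_result <- function(x, ...) {
  cat(sprintf("<learning_curve_result> sizes [%s], %d replicate(s)\n",
              paste(x$sizes, collapse = ", "), x$replicates))
  print(glance(x))
  invisible(x)
}

#' Tidy and summarize a learning curve
#'
#' @param x A `learning_curve_result`.
#' @param ... Unused.
#' @return `tidy()`: per-replicate accuracies. `glance()`: mean accuracy
#'   per size and method, wide, with the hybrid-minus-deep gap.
#' @exportS3Method generics::tidy
tidy.learning_curve_result <- function(x, ...) x$results

#' @rdname tidy.learning_curve_result
#' @exportS3Method generics::glance
glance.learning_curve_result <- function(x, ...) {
  x$results |>
    dplyr::group_by(.data$size, .data$method) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "method", values_from = "accuracy") |>
    dplyr::mutate(gap = .data$hybrid - .data$dl_alone)
}

#' Plot a learning curve
#'
#' @param object A `learning_curve_result`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.learning_curve_result <- function(object, ...) {
  m <- object$results |>
    dplyr::group_by(.data$size, .data$method) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  ggplot2::ggplot(m, ggplot2::aes(.data$size, .data$accuracy,
                                  colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "training examples", y = "mean test accuracy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write sweep and learning-curve results to disk
#'
#' Tidy TSVs plus a JSON summary of the selected configuration.
#'
#' @param x A `sweep_result` or `learning_curve_result`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_results <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(x, "sweep_result")) {
    utils::write.table(x$grid, file.path(dir, "sweep_grid.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(x$dl_alone, file.path(dir, "dl_alone.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(x$best, file.path(dir, "best_config.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (inherits(x, "learning_curve_result")) {
    utils::write.table(x$results, file.path(dir, "learning_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    abort("unsupported result type")
  }
  invisible(dir)
}
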