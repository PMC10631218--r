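#' Re-express data as the activations of an internal network layer
#'
#' Runs the trained network forward in inference mode (dropout disabled,
#' batch normalization using learned statistics) and captures the output of
#' the chosen catalog layer — post-activation for convolution and dense
#' layers. Multi-axis outputs are flattened position-major, channel-minor
#' (feature `j` corresponds to position `(j - 1) %/% C + 1`, channel
#' `(j - 1) %% C + 1`), so boosted-tree feature indices are reproducible
#' and traceable back to layer coordinates.
#'
#' @param net A `trained_network`.
#' @param layer 1-based index into the layer catalog (see
#'   [layer_catalog()]).
#' @param X A `labeled_dataset` or raw input array.
#' @return A `feature_matrix`: list with `values` (n x d numeric matrix with
#'   coordinate column names), `layer_index`, `layer_name`, `coords`
#'   (tibble mapping feature index to position/channel), and
#'   `flatten_order`.
#' @export
extract_features <- function(net, layer, X) {
  stopifnot(inherits(net, "trained_network"))
  if (!is_count(layer) || layer > nrow(net$catalog)) {
    abort(paste0(
      sprintf("layer must be an integer in [1, %d]; catalog:\n", nrow(net$catalog)),
      paste(sprintf("  %2d %s (%s)", net$catalog$index, net$catalog$name,
                    net$catalog$output_shape), collapse = "\n")))
  }
  Xin <- dataset_input(X)
  check_input_shape(net, Xin)
  entry <- net$catalog[layer, ]
  cap <- net_forward(net$layers, Xin, training = FALSE, keep_caches = FALSE,
                     capture_layer_id = entry$layer_id)$captured
  d <- dim(cap)
  if (length(d) == 3) {
    values <- matrix(aperm(cap, c(1, 3, 2)), d[1], d[2] * d[3])
    coords <- tibble::tibble(
      feature = seq_len(d[2] * d[3]),
      position = rep(seq_len(d[2]), each = d[3]),
      channel = rep(seq_len(d[3]), d[2]))
    colnames(values) <- sprintf("p%d_c%d", coords$position, coords$channel)
  } else {
    values <- cap
    coords <- tibble::tibble(feature = seq_len(ncol(values)),
                             position = NA_integer_,
                             channel = seq_len(ncol(values)))
    colnames(values) <- sprintf("u%d", seq_len(ncol(values)))
  }
  structure(list(values = values,
                 layer_index = as.integer(layer),
                 layer_name = entry$name,
                 coords = coords,
                 flatten_order = "position-major, channel-minor",
                 n_blocks = net$spec$n_blocks),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d from layer %d (%s), flattened %s\n",
              nrow(x$values), ncol(x$values), x$layer_index, x$layer_name,
              x$flatten_order))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

as_feature_values <- function(fm) {
  if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
}

#' Concatenate handcrafted features to an extracted feature matrix
#'
#' Column-binds a table of user-engineered features (e.g. frequency-domain
#' summaries) after the network-extracted columns; provenance of both
#' sources is kept.
#'
#' @param fm A `feature_matrix`.
#' @param handcrafted A numeric matrix with the same number of rows.
#' @return A `feature_matrix` with `d_extracted + d_handcrafted` columns.
#' @export
concat_handcrafted <- function(fm, handcrafted) {
  stopifnot(inherits(fm, "feature_matrix"))
  handcrafted <- as.matrix(handcrafted)
  if (nrow(handcrafted) != nrow(fm$values)) {
    abort(sprintf("row mismatch: %d extracted vs %d handcrafted rows",
                  nrow(fm$values), nrow(handcrafted)))
  }
  if (ncol(handcrafted) == 0) return(fm)
  hc_names <- colnames(handcrafted) %||% sprintf("hc%d", seq_len(ncol(handcrafted)))
  colnames(handcrafted) <- hc_names
  fm$values <- cbind(fm$values, handcrafted)
  fm$coords <- dplyr::bind_rows(
    fm$coords,
    tibble::tibble(feature = nrow(fm$coords) + seq_len(ncol(handcrafted)),
                   position = NA_integer_, channel = NA_integer_))
  fm$handcrafted_cols <- hc_names
  fm
}

#' Overfitting-risk diagnostic for feature dimensionality
#'
#' A commonly used rule of thumb holds that overfitting is avoided when the
#' number of features `d` stays below the square root of the sample size
#' `n`. This diagnostic reports `d`, `sqrt(n)`, and flags risk when
#' `d >= sqrt(n)`.
#'
#' @param n Sample size (>= 1).
#' @param d Feature count (>= 1).
#' @return A one-row tibble with `n`, `d`, `sqrt_n`, `at_risk`.
#' @examples
#' overfit_diagnostic(106, 228) # flagged: 228 >= sqrt(106)
#' @export
overfit_diagnostic <- function(n, d) {
  stopifnot(is_count(n), is_count(d))
  tibble::tibble(n = as.integer(n), d = as.integer(d), sqrt_n = sqrt(n),
                 at_risk = d >= sqrt(n))
}

#' Export / import a feature matrix as compressed TSV
#'
#' The header row records the source layer; columns keep the coordinate
#' names assigned by [extract_features()].
#'
#' @param fm A `feature_matrix`.
#' @param path Output path (a `.tsv.gz` is written).
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns the `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# layer_index=%d layer_name=%s flatten_order=%s",
                     fm$layer_index, fm$layer_name, fm$flatten_order), con)
  utils::write.table(fm$values, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  hdr <- readLines(con, n = 1)
  meta <- regmatches(hdr, regexec(
    "layer_index=(\\d+) layer_name=(\\S+) flatten_order=(.+)$", hdr))[[1]]
  if (length(meta) != 4) abort("not a feature-matrix file: header missing")
  values <- as.matrix(utils::read.table(con, sep = "\t", header = TRUE,
                                        check.names = FALSE))
  structure(list(values = values, layer_index = as.integer(meta[2]),
                 layer_name = meta[3], coords = NULL,
                 flatten_order = meta[4]),
            class = "feature_matrix")
}
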