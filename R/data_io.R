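#' Labeled dataset container
#'
#' The common container all adapters produce: a dense numeric tensor `X`
#' whose trailing dimensions depend on the modality (window length x
#' channels for time series, sequence length x 4 for one-hot DNA, token
#' count for text, feature count for flat tables), integer class labels `y`
#' in `[0, k)`, and the ordered class names.
#'
#' @param X A numeric matrix or 3-d array; first dimension indexes examples.
#' @param y Integer labels in `[0, k)`, or a character/factor vector which is
#'   encoded against sorted unique values.
#' @param modality One of `"timeseries"`, `"sequence"`, `"text"`, `"flat"`.
#' @param class_names Ordered class names; inferred when `y` is
#'   character/factor.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(X, y,
                            modality = c("timeseries", "sequence", "text", "flat"),
                            class_names = NULL) {
  modality <- match.arg(modality)
  if (is.character(y) || is.factor(y)) {
    class_names <- class_names %||% sort(unique(as.character(y)))
    y <- match(as.character(y), class_names) - 1L
    if (anyNA(y)) abort("labels outside class_names")
  }
  y <- as.integer(y)
  k <- length(class_names %||% unique(y))
  class_names <- class_names %||% as.character(sort(unique(y)))
  n <- dim(X)[1]
  if (is.null(n) || n < 1) abort("dataset must contain at least one example")
  if (length(y) != n) abort("X and y disagree on the number of examples")
  if (any(y < 0 | y >= length(class_names))) abort("label out of range")
  if (modality == "sequence") {
    sums <- apply(X, c(1, 2), sum)
    if (any(abs(sums - 1) > 1e-12)) abort("one-hot rows must sum to exactly 1")
  }
  if (modality == "text" && !is.integer(X)) abort("text tensors must be integer token matrices")
  structure(list(X = X, y = y, modality = modality,
                 class_names = class_names),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %s, n = %d, shape (%s), %d classes [%s]\n",
              x$modality, dim(x$X)[1],
              paste(dim(x$X)[-1], collapse = " x "),
              length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  print(table(labels = x$class_names[x$y + 1L]))
  invisible(x)
}

ds_subset <- function(ds, idx) {
  labeled_dataset(index_first(ds$X, idx), ds$y[idx], ds$modality,
                  ds$class_names)
}

ds_n <- function(ds) dim(ds$X)[1]

# ---- time-series windowing --------------------------------------------------

#' Segment multichannel time series into fixed-length labeled windows
#'
#' Slides a window of `time_period` steps, advancing `time_step` steps at a
#' time, over each subject's series (windows never span two subjects). Each
#' window becomes one example of shape `time_period x channels`; its label
#' is the majority per-step label, ties broken by the earliest-occurring
#' class within the window. A series of `T` steps yields
#' `floor((T - time_period) / time_step) + 1` windows (0 when
#' `T < time_period`). With the benchmark settings — window 80 and 4
#' channels — each example carries 80 * 4 = 320 values.
#'
#' @param series A tibble with columns `subject_id`, `timestamp`, `label`,
#'   and one numeric column per channel.
#' @param time_period Window length in steps (default 80).
#' @param time_step Step between window starts (default 40; equal to
#'   `time_period` means no overlap).
#' @return A `labeled_dataset` with modality `"timeseries"`.
#' @export
window_time_series <- function(series, time_period = 80, time_step = 40) {
  stopifnot(is.data.frame(series), is_count(time_period), is_count(time_step),
            time_step <= time_period)
  if (nrow(series) == 0) abort("empty series: nothing to window")
  need <- c("subject_id", "timestamp", "label")
  if (!all(need %in% names(series))) {
    abort(paste("series must have columns", paste(need, collapse = ", ")))
  }
  ch_cols <- setdiff(names(series), need)
  if (length(ch_cols) == 0) abort("no channel columns found")
  for (cc in ch_cols) {
    v <- series[[cc]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      abort(sprintf("non-numeric channel value in column '%s' at row %d", cc, bad))
    }
  }
  C <- length(ch_cols)
  class_names <- sort(unique(as.character(series$label)))

  per_subject <- split(seq_len(nrow(series)), series$subject_id)
  xs <- list(); ys <- integer()
  for (rows in per_subject) {
    rows <- rows[order(series$timestamp[rows])]
    if (any(diff(series$timestamp[rows]) <= 0)) {
      abort("timestamps must be strictly increasing within a subject")
    }
    T_ <- length(rows)
    if (T_ < time_period) next
    ch <- as.matrix(series[rows, ch_cols, drop = FALSE])
    labs <- as.character(series$label[rows])
    for (s in seq(1L, T_ - time_period + 1L, by = time_step)) {
      w <- s:(s + time_period - 1L)
      xs[[length(xs) + 1L]] <- ch[w, , drop = FALSE]
      ys <- c(ys, majority_label(labs[w]))
    }
  }
  if (length(xs) == 0) abort("no window fits: all series shorter than time_period")
  X <- array(0, c(length(xs), time_period, C))
  for (i in seq_along(xs)) X[i, , ] <- xs[[i]]
  y <- match(ys, class_names) - 1L
  log_msg(sprintf("windowed %d subjects into %d examples of %d x %d = %d values",
                  length(per_subject), length(xs), time_period, C,
                  time_period * C))
  labeled_dataset(X, y, "timeseries", class_names)
}

interleave <- function(groups) {
  mx <- max(lengths(groups))
  out <- unlist(lapply(seq_len(mx), function(i) {
    vapply(groups, function(g) if (i <= length(g)) g[i] else NA_integer_,
           integer(1))
  }), use.names = FALSE)
  out[!is.na(out)]
}

# Majority label; ties go to the class occurring earliest in the window.
majority_label <- function(labs) {
  counts <- table(labs)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1) {
    first_pos <- vapply(top, function(l) match(l, labs), integer(1))
    top <- top[which.min(first_pos)]
  }
  top
}

# ---- DNA one-hot ------------------------------------------------------------

#' One-hot encode DNA sequences
#'
#' Encodes equal-length sequences over the alphabet `a, c, g, t`
#' (case-insensitive) as an `n x L x 4` tensor with fixed channel order
#' `(a, c, g, t)`; each position row contains exactly one 1. Ambiguous or
#' unknown characters are an error (no silent N handling).
#'
#' @param sequences Character vector of equal-length DNA strings.
#' @return A numeric array of dim `(n, L, 4)` with channel dimnames.
#' @examples
#' one_hot_encode("acgt")[1, , ]  # 4 x 4 identity
#' @export
one_hot_encode <- function(sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 1)
  sequences <- tolower(sequences)
  L <- unique(nchar(sequences))
  if (length(L) != 1) abort("ragged sequence lengths; all sequences must have equal length")
  alphabet <- c("a", "c", "g", "t")
  chars <- matrix(unlist(strsplit(sequences, "")), nrow = length(sequences),
                  byrow = TRUE)
  idx <- match(chars, alphabet)
  dim(idx) <- dim(chars)
  if (anyNA(idx)) {
    bad <- which(is.na(idx), arr.ind = TRUE)[1, ]
    abort(sprintf("unknown character '%s' in sequence %d at position %d",
                  chars[bad[1], bad[2]], bad[1], bad[2]))
  }
  X <- array(0, c(length(sequences), L, 4),
             dimnames = list(NULL, NULL, alphabet))
  X[cbind(rep(seq_along(sequences), L),
          rep(seq_len(L), each = length(sequences)),
          as.vector(idx))] <- 1
  X
}

#' @rdname one_hot_encode
#' @param X A one-hot tensor as produced by `one_hot_encode()`.
#' @return For `decode_one_hot()`: the character vector of sequences.
#' @export
decode_one_hot <- function(X) {
  alphabet <- c("a", "c", "g", "t")
  apply(X, 1, function(m) paste(alphabet[max.col(m, "first")], collapse = ""))
}

#' Build a sequence dataset from DNA strings and labels
#'
#' @param sequences Equal-length DNA strings over `a, c, g, t`.
#' @param labels Class labels (character, factor, or integers in `[0, k)`).
#' @param class_names Optional ordered class names.
#' @return A `labeled_dataset` with modality `"sequence"`.
#' @export
sequence_dataset <- function(sequences, labels, class_names = NULL) {
  labeled_dataset(one_hot_encode(sequences), labels, "sequence", class_names)
}

# ---- text tokenization ------------------------------------------------------

#' Fit a word tokenizer on a training corpus
#'
#' Builds a frequency-ranked vocabulary. Index 0 is padding, index 1 the
#' out-of-vocabulary token, and words occupy `2 ... vocab_size - 1` in
#' decreasing frequency order, so every emitted index lies in
#' `[0, vocab_size)`. Fit on the training split only, then apply to all
#' splits.
#'
#' @param texts Character vector of documents.
#' @param vocab_size Maximum vocabulary size including the two reserved
#'   indices (default 10000).
#' @return A `text_tokenizer`.
#' @export
fit_tokenizer <- function(texts, vocab_size = 10000) {
  stopifnot(is.character(texts), is_count(vocab_size), vocab_size > 2)
  if (length(texts) == 0 || all(!nzchar(trimws(texts)))) {
    abort("empty corpus: cannot fit a tokenizer")
  }
  words <- unlist(lapply(texts, split_words))
  freq <- sort(table(words), decreasing = TRUE)
  keep <- head(names(freq), vocab_size - 2L)
  structure(list(index = stats::setNames(seq_along(keep) + 1L, keep),
                 vocab_size = as.integer(vocab_size),
                 pad_index = 0L, oov_index = 1L),
            class = "text_tokenizer")
}

split_words <- function(text) {
  w <- strsplit(gsub("[^a-z0-9']+", " ", tolower(text)), "\\s+")[[1]]
  w[nzchar(w)]
}

#' Tokenize texts into padded integer sequences
#'
#' Converts each document to its word-index sequence under a fitted
#' tokenizer, truncated to the first `max_len` tokens and post-padded with
#' the pad index 0. Out-of-vocabulary words map to the reserved index 1.
#'
#' @param texts Character vector of documents.
#' @param tokenizer A `text_tokenizer` from [fit_tokenizer()]. If `NULL`, a
#'   tokenizer is fit on `texts` themselves (use only when `texts` is the
#'   training split).
#' @param max_len Maximum tokens per document (default 100).
#' @param vocab_size Passed to [fit_tokenizer()] when `tokenizer` is `NULL`.
#' @return An integer matrix `(n, max_len)` with the tokenizer attached as
#'   attribute `"tokenizer"`.
#' @export
tokenize_texts <- function(texts, tokenizer = NULL, max_len = 100,
                           vocab_size = 10000) {
  stopifnot(is.character(texts), is_count(max_len))
  if (length(texts) == 0) abort("empty corpus")
  tokenizer <- tokenizer %||% fit_tokenizer(texts, vocab_size)
  out <- matrix(tokenizer$pad_index, length(texts), max_len)
  for (i in seq_along(texts)) {
    w <- head(split_words(texts[i]), max_len)
    if (length(w) == 0) next
    idx <- unname(tokenizer$index[w])
    idx[is.na(idx)] <- tokenizer$oov_index
    out[i, seq_along(idx)] <- idx
  }
  storage.mode(out) <- "integer"
  attr(out, "tokenizer") <- tokenizer
  out
}

#' Build a text dataset from raw documents and binary labels
#'
#' @inheritParams tokenize_texts
#' @param labels Class labels.
#' @param class_names Optional ordered class names.
#' @return A `labeled_dataset` with modality `"text"`.
#' @export
text_dataset <- function(texts, labels, tokenizer = NULL, max_len = 100,
                         vocab_size = 10000, class_names = NULL) {
  X <- tokenize_texts(texts, tokenizer, max_len, vocab_size)
  tok <- attr(X, "tokenizer")
  attr(X, "tokenizer") <- NULL
  ds <- labeled_dataset(X, labels, "text", class_names)
  ds$tokenizer <- tok
  ds
}

# ---- ratings ----------------------------------------------------------------

#' Binarize star ratings
#'
#' A rating becomes the positive class (1) exactly when it is strictly
#' greater than the threshold — 2 for the Amazon task, 2.5 for IMDb and
#' Yelp.
#'
#' @param ratings Numeric ratings on the 1–5 scale.
#' @param threshold Positivity threshold (strict `>`).
#' @return Integer labels in `{0, 1}`.
#' @export
binarize_ratings <- function(ratings, threshold) {
  stopifnot(is.numeric(ratings), is.numeric(threshold), length(threshold) == 1)
  if (any(ratings < 1 | ratings > 5)) {
    abort(sprintf("rating outside [1, 5] at position %d",
                  which(ratings < 1 | ratings > 5)[1]))
  }
  as.integer(ratings > threshold)
}

# ---- normalization ----------------------------------------------------------

#' Per-feature min-max normalization fitted on the training split
#'
#' Fits column minima and ranges on `X` and rescales to `[0, 1]`; constant
#' columns map to 0. The returned transform is applied to validation/test
#' data with the training statistics via `predict()`.
#'
#' @param X Numeric matrix (rows are examples).
#' @param transform An existing `feature_transform` to apply instead of
#'   fitting a new one.
#' @return A list with `values` (the rescaled matrix) and `transform`.
#' @export
normalize_features <- function(X, transform = NULL) {
  X <- as.matrix(X)
  if (is.null(transform)) {
    mins <- apply(X, 2, min)
    rng <- apply(X, 2, max) - mins
    transform <- structure(list(min = mins, range = rng),
                           class = "feature_transform")
  }
  list(values = predict(transform, X), transform = transform)
}

#' @export
predict.feature_transform <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  out <- sweep(X, 2, object$min, "-")
  nonconst <- object$range > 0
  out[, nonconst] <- sweep(out[, nonconst, drop = FALSE], 2,
                           object$range[nonconst], "/")
  out[, !nonconst] <- 0
  out
}

# ---- splitting --------------------------------------------------------------

#' Train/validation/test split specification
#'
#' The benchmark protocol: 80% of the data randomly chosen for training,
#' 20% of that training portion held out for validation, and the remaining
#' 20% of the data for testing.
#'
#' @param train_frac Fraction of data for training+validation (default 0.8).
#' @param val_frac_of_train Fraction of the training portion used for
#'   validation (default 0.2).
#' @param seed Integer seed for the random shuffle.
#' @param stratified Stratify the shuffle by class (off by default; the
#'   protocol is a plain random split).
#' @return A `split_spec`.
#' @export
split_spec <- function(train_frac = 0.8, val_frac_of_train = 0.2, seed = NULL,
                       stratified = FALSE) {
  stopifnot(train_frac > 0, train_frac < 1,
            val_frac_of_train >= 0, val_frac_of_train < 1)
  structure(list(train_frac = train_frac,
                 val_frac_of_train = val_frac_of_train,
                 seed = seed, stratified = stratified),
            class = "split_spec")
}

#' Split a dataset into train, validation, and test partitions
#'
#' Deterministic under `spec$seed`; the three index sets are disjoint and
#' their union covers every example. Sizes are
#' `round(n * train_frac * (1 - val_frac))` / `round(n * train_frac * val_frac)`
#' / remainder (so for n = 1000 under the defaults: 640 / 160 / 200).
#'
#' @param ds A `labeled_dataset`.
#' @param spec A [split_spec()].
#' @return A list with elements `train`, `val`, `test` (each a
#'   `labeled_dataset`) and `indices` (the integer index sets).
#' @export
split_dataset <- function(ds, spec = split_spec()) {
  stopifnot(inherits(ds, "labeled_dataset"), inherits(spec, "split_spec"))
  n <- ds_n(ds)
  ord <- with_seed_(spec$seed, {
    if (spec$stratified) {
      # shuffle within class, then round-robin so contiguous cuts are
      # near-stratified
      by_class <- lapply(split(seq_len(n), ds$y), sample)
      interleave(by_class)
    } else {
      sample.int(n)
    }
  })
  n_pool <- round(n * spec$train_frac)
  n_val <- round(n_pool * spec$val_frac_of_train)
  n_train <- n_pool - n_val
  idx <- list(train = ord[seq_len(n_train)],
              val = if (n_val > 0) ord[n_train + seq_len(n_val)] else integer(),
              test = ord[setdiff(seq_len(n), seq_len(n_pool))])
  missing_classes <- setdiff(seq_along(ds$class_names) - 1L, ds$y[idx$train])
  if (length(missing_classes) > 0) {
    warn(sprintf("class(es) absent from training split: %s",
                 paste(ds$class_names[missing_classes + 1L], collapse = ", ")))
  }
  log_msg(sprintf("split n=%d into train/val/test = %d/%d/%d",
                  n, length(idx$train), length(idx$val), length(idx$test)))
  list(train = ds_subset(ds, idx$train),
       val = if (n_val > 0) ds_subset(ds, idx$val) else NULL,
       test = ds_subset(ds, idx$test),
       indices = idx)
}

# ---- file readers -----------------------------------------------------------

read_nonempty_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  attr(lines, "dropped") <- sum(!keep)
  structure(lines[keep], dropped = sum(!keep), lineno = which(keep))
}

#' Read a promoter flat file
#'
#' Parses the comma-separated `class,name,sequence` dialect of the UCI
#' molecular-biology promoter collection: class is `+` or `-`, and
#' whitespace/tab characters inside fields are discarded (sequences are
#' lowercase `acgt`).
#'
#' @param path Path to the flat file.
#' @return A tibble with columns `class`, `name`, `sequence`.
#' @export
read_promoter_file <- function(path) {
  lines <- read_nonempty_lines(path)
  if (length(lines) == 0) abort(sprintf("empty file: %s", path))
  lineno <- attr(lines, "lineno")
  recs <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 3) {
      abort(sprintf("malformed line %d: expected class,name,sequence", lineno[i]))
    }
    cls <- gsub("\\s", "", parts[1])
    if (!cls %in% c("+", "-")) {
      abort(sprintf("malformed line %d: class must be + or -", lineno[i]))
    }
    tibble::tibble(class = cls,
                   name = trimws(parts[2]),
                   sequence = tolower(gsub("\\s", "",
                                           paste(parts[-(1:2)], collapse = ""))))
  })
  out <- dplyr::bind_rows(recs)
  log_msg(sprintf("read %d promoter records (%d '+', %d '-'), %d blank lines dropped",
                  nrow(out), sum(out$class == "+"), sum(out$class == "-"),
                  attr(lines, "dropped")))
  out
}

#' @rdname read_promoter_file
#' @return For `promoter_dataset()`: a `labeled_dataset` with modality
#'   `"sequence"` and classes `non-promoter` (label 0, class `-`) and
#'   `promoter` (label 1, class `+`).
#' @export
promoter_dataset <- function(path) {
  rec <- read_promoter_file(path)
  sequence_dataset(rec$sequence,
                   ifelse(rec$class == "+", "promoter", "non-promoter"),
                   class_names = c("non-promoter", "promoter"))
}

#' Read an accelerometer CSV in the WISDM dialect
#'
#' Rows are `user,activity,timestamp,x,y,z;` with a tolerated trailing
#' semicolon. Use [add_magnitude()] to append the resultant-acceleration
#' channel so the canonical four-channel, 80-step windowing yields
#' 320 values per example.
#'
#' @param path Path to the CSV.
#' @return A tibble with columns `subject_id`, `label`, `timestamp`, `x`,
#'   `y`, `z`, ready for [window_time_series()].
#' @export
read_wisdm_csv <- function(path) {
  lines <- read_nonempty_lines(path)
  if (length(lines) == 0) abort(sprintf("empty file: %s", path))
  lineno <- attr(lines, "lineno")
  lines_clean <- sub(";\\s*$", "", lines)
  parts <- strsplit(lines_clean, ",")
  bad <- which(lengths(parts) != 6)
  if (length(bad) > 0) {
    abort(sprintf("malformed line %d: expected user,activity,timestamp,x,y,z",
                  lineno[bad[1]]))
  }
  m <- do.call(rbind, parts)
  num <- suppressWarnings(apply(m[, 3:6, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 4)
  if (anyNA(num)) {
    abort(sprintf("malformed line %d: non-numeric value",
                  lineno[which(rowSums(is.na(num)) > 0)[1]]))
  }
  out <- tibble::tibble(subject_id = m[, 1], label = m[, 2],
                        timestamp = num[, 1], x = num[, 2], y = num[, 3],
                        z = num[, 4])
  hist <- table(out$label)
  log_msg(sprintf("read %d sensor rows, %d subjects, classes: %s; %d blank lines dropped",
                  nrow(out), length(unique(out$subject_id)),
                  paste(sprintf("%s=%d", names(hist), hist), collapse = ", "),
                  attr(lines, "dropped")))
  out
}

#' @rdname read_wisdm_csv
#' @param series A series tibble with `x`, `y`, `z` channels.
#' @return For `add_magnitude()`: the tibble with an extra `m` channel
#'   `sqrt(x^2 + y^2 + z^2)`.
#' @export
add_magnitude <- function(series) {
  dplyr::mutate(series, m = sqrt(.data$x^2 + .data$y^2 + .data$z^2))
}

#' Read a sentiment file of tab-separated text and label
#'
#' One `sentence<TAB>label` record per line with label 0 or 1.
#'
#' @param path Path to the file.
#' @return A tibble with columns `text` and `label` (integer).
#' @export
read_sentiment_file <- function(path) {
  lines <- read_nonempty_lines(path)
  if (length(lines) == 0) abort(sprintf("empty file: %s", path))
  lineno <- attr(lines, "lineno")
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) != 2 |
                 !vapply(parts, function(p) tail(p, 1) %in% c("0", "1"),
                         logical(1)))
  if (length(bad) > 0) {
    abort(sprintf("malformed line %d: expected text<TAB>label with label 0/1",
                  lineno[bad[1]]))
  }
  out <- tibble::tibble(text = vapply(parts, `[`, character(1), 1),
                        label = as.integer(vapply(parts, `[`, character(1), 2)))
  log_msg(sprintf("read %d sentiment records (%d positive, %d negative), %d blank lines dropped",
                  nrow(out), sum(out$label == 1), sum(out$label == 0),
                  attr(lines, "dropped")))
  out
}
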