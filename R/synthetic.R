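# Synthetic data generators for the three modalities. Each is a pure
# function of its configuration and seed, and can emit files in the exact
# dialects the readers parse, so every pipeline stage is testable without
# external downloads.

#' Generate planted-motif DNA sequences
#'
#' Emulates a small two-class promoter-style task: balanced classes
#' (`ceiling(n/2)` positives, `floor(n/2)` negatives) of `length`-base
#' sequences. Positives carry one copy of the motif, each base of which is
#' mutated independently with probability `mutation_prob` (to a uniformly
#' chosen different base); negatives are pure background. With
#' `placement = "random"` the motif lands uniformly at random — the regime
#' where position-invariant convolutional features pay off and axis-aligned
#' tree splits on raw one-hot columns do not; `"fixed"` centers it at a
#' constant offset, the regime where trees on raw features succeed.
#'
#' @param n Number of sequences (default 300).
#' @param length Sequence length (default 57).
#' @param motif Motif string over `a, c, g, t` (default an 8-mer).
#' @param mutation_prob Per-base mutation probability in `[0, 1)`
#'   (default 0.15).
#' @param placement `"random"` (default) or `"fixed"`.
#' @param background Base frequencies for `(a, c, g, t)`; must sum to 1.
#' @param seed Integer seed; same seed, same dataset.
#' @return A tibble with columns `sequence` and `label` (1 = motif
#'   present).
#' @export
gen_motif_sequences <- function(n = 300, length = 57, motif = "tataatgc",
                                mutation_prob = 0.15,
                                placement = c("random", "fixed"),
                                background = c(0.25, 0.25, 0.25, 0.25),
                                seed = NULL) {
  placement <- match.arg(placement)
  alphabet <- c("a", "c", "g", "t")
  motif_chars <- strsplit(tolower(motif), "")[[1]]
  stopifnot(is_count(n), is_count(length), length(motif_chars) <= length,
            all(motif_chars %in% alphabet),
            mutation_prob >= 0, mutation_prob < 1)
  if (length(background) != 4 || any(background < 0) ||
      abs(sum(background) - 1) > 1e-8) {
    abort("background must be 4 nonnegative frequencies summing to 1")
  }
  m <- base::length(motif_chars)
  n_pos <- ceiling(n / 2); n_neg <- floor(n / 2)
  with_seed_(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(alphabet, length, replace = TRUE, prob = background),
            collapse = "")
    }, character(1))
    labels <- c(rep(1L, n_pos), rep(0L, n_neg))
    for (i in seq_len(n_pos)) {
      planted <- motif_chars
      mut <- runif(m) < mutation_prob
      for (j in which(mut)) {
        planted[j] <- sample(setdiff(alphabet, planted[j]), 1)
      }
      start <- if (placement == "fixed") {
        (length - m) %/% 2L + 1L
      } else {
        sample.int(length - m + 1L, 1)
      }
      s <- strsplit(seqs[i], "")[[1]]
      s[start:(start + m - 1L)] <- planted
      seqs[i] <- paste(s, collapse = "")
    }
    ord <- sample.int(n)
    tibble::tibble(sequence = seqs[ord], label = labels[ord])
  })
}

#' @rdname gen_motif_sequences
#' @param ... Passed to `gen_motif_sequences()`.
#' @return For `motif_dataset()`: the one-hot `labeled_dataset` (classes
#'   `background`, `motif`).
#' @export
motif_dataset <- function(...) {
  d <- gen_motif_sequences(...)
  labeled_dataset(one_hot_encode(d$sequence), d$label, "sequence",
                  class_names = c("background", "motif"))
}

#' Generate class-conditioned multichannel sensor series
#'
#' Emulates windowed activity-recognition data: each subject performs every
#' activity class once, in random order, for an equal share of
#' `timesteps`. Class `k` produces a sinusoid of class-specific frequency
#' on every channel (channel-specific amplitude, random phase per run) plus
#' Gaussian noise. Sampling rate is 20 Hz.
#'
#' @param n_subjects Number of subjects (default 6).
#' @param classes Number of activity classes (default 6).
#' @param channels Number of channels (default 4); the first three are
#'   named `x`, `y`, `z` so the series round-trips through the sensor-CSV
#'   dialect.
#' @param timesteps Timesteps per subject (default 1200).
#' @param noise_sd Gaussian noise standard deviation (default 0.3).
#' @param seed Integer seed.
#' @return A tidy tibble (`subject_id`, `label`, `timestamp`, one column per
#'   channel) ready for [window_time_series()].
#' @export
gen_activity_series <- function(n_subjects = 6, classes = 6, channels = 4,
                                timesteps = 1200, noise_sd = 0.3,
                                seed = NULL) {
  stopifnot(is_count(n_subjects), is_count(classes), classes >= 2,
            is_count(channels), is_count(timesteps), noise_sd >= 0)
  rate <- 20 # Hz
  run_len <- timesteps %/% classes
  freqs <- 0.4 + 0.35 * seq_len(classes)          # distinct per class
  amps <- 1 + 0.3 * (seq_len(channels) - 1)       # distinct per channel
  ch_names <- c("x", "y", "z", sprintf("c%d", seq_len(max(0, channels - 3)) + 3))
  ch_names <- ch_names[seq_len(channels)]
  with_seed_(seed, {
    rows <- lapply(seq_len(n_subjects), function(s) {
      order_k <- sample.int(classes)
      per_run <- lapply(seq_along(order_k), function(r) {
        k <- order_k[r]
        t0 <- (r - 1L) * run_len
        t <- (t0:(t0 + run_len - 1L)) / rate
        sig <- vapply(seq_len(channels), function(cc) {
          phase <- runif(1, 0, 2 * pi)
          amps[cc] * sin(2 * pi * freqs[k] * t + phase) +
            rnorm(run_len, sd = noise_sd)
        }, numeric(run_len))
        colnames(sig) <- ch_names
        dplyr::bind_cols(
          tibble::tibble(subject_id = sprintf("subj%02d", s),
                         label = sprintf("activity%d", k),
                         timestamp = t),
          tibble::as_tibble(sig))
      })
      dplyr::bind_rows(per_run)
    })
    dplyr::bind_rows(rows)
  })
}

#' Frequency-domain handcrafted features for windowed sensor data
#'
#' The classic engineered representation for activity windows: per channel,
#' the magnitudes of the first `n_bins` non-constant Fourier coefficients.
#' Useful as the `handcrafted` argument of [concat_handcrafted()] and as
#' the raw table for the trees-on-raw baseline.
#'
#' @param ds A `labeled_dataset` with modality `"timeseries"`.
#' @param n_bins Number of Fourier magnitude bins per channel (default 10).
#' @return A numeric matrix `n x (channels * n_bins)`.
#' @export
fft_magnitude_features <- function(ds, n_bins = 10) {
  stopifnot(inherits(ds, "labeled_dataset"), ds$modality == "timeseries")
  d <- dim(ds$X)
  out <- matrix(0, d[1], d[3] * n_bins)
  for (i in seq_len(d[1])) {
    for (cc in seq_len(d[3])) {
      sp <- Mod(stats::fft(ds$X[i, , cc]))[2:(n_bins + 1)]
      out[i, ((cc - 1) * n_bins + 1):(cc * n_bins)] <- sp
    }
  }
  colnames(out) <- sprintf("fft_ch%d_bin%d", rep(seq_len(d[3]), each = n_bins),
                           rep(seq_len(n_bins), d[3]))
  out
}

#' Generate biased token sequences
#'
#' Emulates tokenized sentiment data: a marked subset of the vocabulary is
#' over-sampled by the positive class by factor `class_token_bias`. At
#' bias 1 the class-conditional token distributions coincide (no signal);
#' as the bias grows the positive class concentrates on the marked tokens.
#'
#' @param n Number of documents.
#' @param vocab_size Vocabulary size (indices `0` pad / `1` reserved as in
#'   [fit_tokenizer()]).
#' @param max_len Tokens per document (documents are full length here).
#' @param class_token_bias Over-sampling factor for marked tokens in the
#'   positive class (> 0; capped so the marked probability is at most 1).
#' @param marked_frac Fraction of the vocabulary that is marked
#'   (default 0.05).
#' @param seed Integer seed.
#' @return A `labeled_dataset` with modality `"text"` (classes `neg`,
#'   `pos`), with the marked token ids attached as attribute
#'   `"marked_tokens"`.
#' @export
gen_token_sequences <- function(n, vocab_size = 2000, max_len = 100,
                                class_token_bias = 8, marked_frac = 0.05,
                                seed = NULL) {
  stopifnot(is_count(n), is_count(vocab_size), vocab_size > 10,
            is_count(max_len), class_token_bias > 0,
            marked_frac > 0, marked_frac < 1)
  tokens <- 2:(vocab_size - 1L)
  with_seed_(seed, {
    marked <- sort(sample(tokens, max(1L, round(marked_frac * length(tokens)))))
    unmarked <- setdiff(tokens, marked)
    q0 <- length(marked) / length(tokens)
    q1 <- min(1, class_token_bias * q0)
    n_pos <- ceiling(n / 2)
    labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
    X <- matrix(0L, n, max_len)
    for (i in seq_len(n)) {
      q <- if (labels[i] == 1L) q1 else q0
      from_marked <- runif(max_len) < q
      row <- integer(max_len)
      row[from_marked] <- sample(marked, sum(from_marked), replace = TRUE)
      row[!from_marked] <- sample(unmarked, sum(!from_marked), replace = TRUE)
      X[i, ] <- row
    }
    ord <- sample.int(n)
    ds <- labeled_dataset(X[ord, , drop = FALSE], labels[ord], "text",
                          class_names = c("neg", "pos"))
    attr(ds, "marked_tokens") <- marked
    ds
  })
}

# ---- dialect writers (round-trip with the readers) -------------------------

#' Write generator output in the reader dialects
#'
#' `write_promoter_file()` emits `class,name,sequence` lines (`+` for label
#' 1), `write_wisdm_csv()` emits `user,activity,timestamp,x,y,z;` rows, and
#' `write_sentiment_file()` emits `text<TAB>label` lines — the exact
#' dialects [read_promoter_file()], [read_wisdm_csv()] and
#' [read_sentiment_file()] parse, so the readers are integration-tested
#' end-to-end against generated data.
#'
#' @param sequences,labels,texts Generator output columns.
#' @param series A series tibble with channels `x`, `y`, `z`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoter_file <- function(sequences, labels, path) {
  writeLines(sprintf("%s,S%d,%s", ifelse(labels == 1, "+", "-"),
                     seq_along(sequences), sequences), path)
  invisible(path)
}

#' @rdname write_promoter_file
#' @export
write_wisdm_csv <- function(series, path) {
  stopifnot(all(c("subject_id", "label", "timestamp", "x", "y", "z") %in%
                  names(series)))
  writeLines(sprintf("%s,%s,%.6g,%.6g,%.6g,%.6g;", series$subject_id,
                     series$label, series$timestamp, series$x, series$y,
                     series$z), path)
  invisible(path)
}

#' @rdname write_promoter_file
#' @export
write_sentiment_file <- function(texts, labels, path) {
  writeLines(sprintf("%s\t%d", texts, as.integer(labels)), path)
  invisible(path)
}
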