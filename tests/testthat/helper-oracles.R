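# Shared fixtures and independent oracles. The naive forward pass below
# re-implements inference with plain R loops (direct convolution sums), so
# extraction can be checked against an implementation that shares no code
# with the im2col engine.

tiny_spec <- function(n_blocks = 1, dense = c(8, 1), filters = 4,
                      kernel = 3, pool = 2, dropout = 0) {
  architecture_spec(n_blocks, kernel_size = kernel, pool_size = pool,
                    dense_sizes = dense, base_filters = filters,
                    dropout_rate = dropout, output_activation = "sigmoid",
                    optimizer = "adam")
}

tiny_motif_split <- function(n = 60, length = 16, motif = "acgt", seed = 1,
                             ...) {
  ds <- motif_dataset(n = n, length = length, motif = motif, seed = seed, ...)
  suppressMessages(split_dataset(ds, split_spec(seed = seed)))
}

# Direct (non-im2col) convolution of one example: X (L, C), W (kC, F) with
# row index (offset-1)*C + channel, valid padding.
naive_conv1d <- function(X, W, b) {
  L <- nrow(X); C <- ncol(X); k <- nrow(W) / C; F_ <- ncol(W)
  Lo <- L - k + 1
  out <- matrix(0, Lo, F_)
  for (f in seq_len(F_)) {
    for (l in seq_len(Lo)) {
      acc <- b[f]
      for (j in seq_len(k)) {
        for (c in seq_len(C)) {
          acc <- acc + X[l + j - 1, c] * W[(j - 1) * C + c, f]
        }
      }
      out[l, f] <- acc
    }
  }
  out
}

# Inference-mode forward of a trained network for ONE example, with loops.
# Returns the per-catalog-layer activations, flattened position-major.
naive_forward_all <- function(net, x) {
  spec <- net$spec
  acts <- list()
  cur <- x # (L, C) matrix
  ci <- 0
  for (ly in net$layers) {
    if (ly$type == "conv") {
      if (ly$padding == "same") {
        k <- ly$kernel; pl <- (k - 1) %/% 2; pr <- k - 1 - pl
        cur <- rbind(matrix(0, pl, ncol(cur)), cur, matrix(0, pr, ncol(cur)))
      }
      Z <- naive_conv1d(cur, ly$par$W, ly$par$b)
      for (f in seq_len(ncol(Z))) {
        Z[, f] <- ly$par$gamma[f] * (Z[, f] - ly$run_mean[f]) /
          sqrt(ly$run_var[f] + ly$eps) + ly$par$beta[f]
      }
      cur <- pmax(Z, 0)
      ci <- ci + 1
      acts[[ci]] <- as.vector(t(cur)) # position-major, channel-minor
    } else if (ly$type == "pool") {
      p <- ly$pool; Lo <- nrow(cur) %/% p
      out <- matrix(0, Lo, ncol(cur))
      for (l in seq_len(Lo)) {
        out[l, ] <- apply(cur[((l - 1) * p + 1):(l * p), , drop = FALSE], 2, max)
      }
      cur <- out
      ci <- ci + 1
      acts[[ci]] <- as.vector(t(cur))
    } else if (ly$type == "dropout") {
      # identity at inference
    } else if (ly$type == "flatten") {
      cur <- as.vector(t(cur))
      ci <- ci + 1
      acts[[ci]] <- cur
    } else if (ly$type == "dense") {
      z <- drop(cur %*% ly$par$W) + ly$par$b
      cur <- switch(ly$activation,
                    relu = pmax(z, 0),
                    sigmoid = 1 / (1 + exp(-z)),
                    softmax = softmax(z))
      ci <- ci + 1
      acts[[ci]] <- cur
    }
  }
  acts
}

# Brute-force window count: enumerate valid start offsets.
brute_force_windows <- function(T_, period, step) {
  if (T_ < period) return(0L)
  length(seq(1L, T_ - period + 1L, by = step))
}

# Minimal single-label series tibble for windowing tests.
make_series <- function(T_, subject = "s1", label = "walk", channels = 3,
                        seed = 1) {
  withr::with_seed(seed, {
    ch <- matrix(rnorm(T_ * channels), T_, channels)
    colnames(ch) <- c("x", "y", "z", letters[seq_len(max(0, channels - 3))])[
      seq_len(channels)]
    dplyr::bind_cols(
      tibble::tibble(subject_id = subject, timestamp = seq_len(T_),
                     label = label),
      tibble::as_tibble(ch))
  })
}
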