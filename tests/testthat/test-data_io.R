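test_that("windowing arithmetic matches the segmentation rules", {
  # 80-step windows over 4 channels carry 80 * 4 = 320 values per example
  s <- make_series(200, channels = 4)
  ds <- suppressMessages(window_time_series(s, time_period = 80, time_step = 40))
  expect_equal(dim(ds$X)[2] * dim(ds$X)[3], 320)
  # starts 1, 41, 81, 121 for T = 200
  expect_equal(dim(ds$X)[1], 4)

  # no overlap when step equals period
  s2 <- make_series(160)
  ds2 <- suppressMessages(window_time_series(s2, 80, 80))
  expect_equal(dim(ds2$X)[1], 2)
})

test_that("window counts match brute-force start-offset enumeration", {
  withr::with_seed(42, {
    for (i in 1:25) {
      period <- sample(5:40, 1)
      step <- sample.int(period, 1)
      T_ <- sample(1:120, 1)
      expected <- brute_force_windows(T_, period, step)
      s <- make_series(T_, seed = i)
      if (expected == 0) {
        expect_error(
          suppressMessages(window_time_series(s, period, step)),
          "no window fits")
      } else {
        ds <- suppressMessages(window_time_series(s, period, step))
        expect_equal(dim(ds$X)[1], expected,
                     info = sprintf("T=%d period=%d step=%d", T_, period, step))
      }
    }
  })
})

test_that("windows never span subjects and labels use majority with earliest tie-break", {
  s1 <- make_series(10, subject = "a", label = "walk")
  s2 <- make_series(10, subject = "b", label = "jog", seed = 2)
  both <- dplyr::bind_rows(s1, s2)
  ds <- suppressMessages(window_time_series(both, 10, 5))
  # each subject admits exactly one 10-step window; a pooled series of 20
  # steps would admit 3
  expect_equal(dim(ds$X)[1], 2)
  expect_setequal(ds$class_names[ds$y + 1], c("walk", "jog"))

  # majority label; tie broken by earliest occurrence within the window
  s3 <- make_series(8, label = "walk")
  s3$label <- c("sit", "sit", "sit", "walk", "walk", "walk", "sit", "walk")
  ds3 <- suppressMessages(window_time_series(s3, 8, 8))
  expect_equal(ds3$class_names[ds3$y + 1], "sit") # 4-4 tie, sit occurs first

  # non-numeric channel is rejected with the row named
  s4 <- make_series(12)
  s4$x[5] <- NA_real_
  expect_error(suppressMessages(window_time_series(s4, 4, 4)), "row 5")
  expect_error(suppressMessages(window_time_series(s4[0, ], 4, 4)), "empty")
})

test_that("one-hot encoding follows the (a,c,g,t) channel convention", {
  expect_equal(one_hot_encode("a")[1, 1, ], c(a = 1, c = 0, g = 0, t = 0))
  expect_equal(unname(one_hot_encode("acgt")[1, , ]), diag(4))

  seqs <- gen_motif_sequences(n = 6, length = 57, seed = 3)$sequence
  X <- one_hot_encode(seqs)
  expect_equal(dim(X), c(6, 57, 4))
  expect_true(all(apply(X, c(1, 2), sum) == 1))
  expect_equal(decode_one_hot(X), seqs)

  expect_error(one_hot_encode(c("acg", "ac")), "ragged")
  expect_error(one_hot_encode("acgn"), "position 4")
})

test_that("tokenizer is deterministic, caps indices, and pads/truncates", {
  texts <- c("the cat sat", "the dog sat down", "cat dog cat")
  tok <- fit_tokenizer(texts, vocab_size = 10000)
  X1 <- tokenize_texts(texts, tok, max_len = 5)
  X2 <- tokenize_texts(texts, tok, max_len = 5)
  expect_identical(X1[, ], X2[, ])
  # 6 distinct words + pad + oov: indices stay inside [0, 8)
  expect_true(all(X1 >= 0 & X1 < 8))

  long <- paste(rep("word", 150), collapse = " ")
  Xl <- tokenize_texts(long, tok, max_len = 100)
  expect_equal(ncol(Xl), 100)

  # out-of-vocabulary words map to the reserved index, never >= vocab_size
  small <- fit_tokenizer(texts, vocab_size = 4)
  Xs <- tokenize_texts(c("unseen words only"), small, max_len = 5)
  expect_true(all(Xs < 4))
  expect_true(any(Xs == 1))

  expect_error(fit_tokenizer(character(0)), "empty corpus")
})

test_that("rating binarization is a strict greater-than rule", {
  expect_equal(binarize_ratings(3, 2.5), 1L)
  expect_equal(binarize_ratings(2, 2), 0L)
  expect_equal(binarize_ratings(2.5, 2.5), 0L)
  expect_equal(binarize_ratings(c(1, 2, 3, 4, 5), 2), c(0L, 0L, 1L, 1L, 1L))
  expect_error(binarize_ratings(6, 2), "outside")
})

test_that("min-max normalization is fit on train and re-applied exactly", {
  X <- cbind(a = c(0, 5, 10), b = c(3, 3, 3))
  r <- normalize_features(X)
  expect_equal(unname(r$values[, 1]), c(0, 0.5, 1))
  expect_equal(unname(r$values[, 2]), c(0, 0, 0))
  # stored transform reproduces identical output, and maps new data with
  # the training statistics
  again <- normalize_features(X, r$transform)
  expect_identical(r$values, again$values)
  expect_equal(unname(predict(r$transform, cbind(20, 3))[1, 1]), 2)
})

test_that("splits are exact partitions, sized by the 80/20 rule, and seeded", {
  ds <- motif_dataset(n = 1000, seed = 5)
  p <- suppressMessages(split_dataset(ds, split_spec(seed = 9)))
  expect_equal(lengths(p$indices[c("train", "val", "test")]),
               c(train = 640L, val = 160L, test = 200L))

  ds2 <- motif_dataset(n = 106, seed = 5)
  p2 <- suppressMessages(split_dataset(ds2, split_spec(seed = 9)))
  idx <- unname(unlist(p2$indices))
  expect_equal(sort(idx), 1:106)           # exact partition
  expect_equal(anyDuplicated(idx), 0)

  p3 <- suppressMessages(split_dataset(ds2, split_spec(seed = 9)))
  expect_identical(p2$indices, p3$indices) # seeded determinism

  p4 <- suppressMessages(split_dataset(ds2, split_spec(seed = 10)))
  expect_false(identical(p2$indices, p4$indices))
})

test_that("a class missing from the training split raises a warning", {
  ds <- labeled_dataset(matrix(rnorm(40), 20, 2), rep(c(0L, 1L), c(19, 1)),
                        "flat", class_names = c("a", "b"))
  # with 1 positive in 20, some seeds put it outside train
  found <- FALSE
  for (s in 1:50) {
    w <- tryCatch({
      suppressMessages(split_dataset(ds, split_spec(seed = s)))
      NULL
    }, warning = function(w) w)
    if (!is.null(w)) { found <- TRUE; break }
  }
  expect_true(found)
  expect_match(conditionMessage(w), "absent from training")
})

test_that("promoter flat files round-trip and parse strictly", {
  d <- gen_motif_sequences(n = 10, length = 57, seed = 21)
  f <- withr::local_tempfile(fileext = ".txt")
  write_promoter_file(d$sequence, d$label, f)
  rec <- suppressMessages(read_promoter_file(f))
  expect_equal(nrow(rec), 10)
  expect_equal(rec$sequence, d$sequence)
  expect_equal(rec$class == "+", d$label == 1)

  ds <- suppressMessages(promoter_dataset(f))
  expect_s3_class(ds, "labeled_dataset")
  expect_equal(ds$class_names, c("non-promoter", "promoter"))
  expect_equal(ds$y, d$label)

  # tabs and spaces inside fields are discarded (UCI formatting)
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("+,name1,\tac  gt\na-,", f2)
  expect_error(suppressMessages(read_promoter_file(f2)), "line 2")
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), f3)
  expect_error(suppressMessages(read_promoter_file(f3)), "empty")
})

test_that("sensor CSV dialect round-trips with magnitude channel", {
  series <- gen_activity_series(n_subjects = 2, classes = 2, channels = 3,
                                timesteps = 40, seed = 31)
  f <- withr::local_tempfile(fileext = ".csv")
  write_wisdm_csv(series, f)
  back <- suppressMessages(read_wisdm_csv(f))
  expect_equal(nrow(back), nrow(series))
  expect_equal(back$x, series$x, tolerance = 1e-5)
  expect_equal(back$label, series$label)
  withmag <- add_magnitude(back)
  expect_equal(withmag$m, sqrt(back$x^2 + back$y^2 + back$z^2))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("u1,walk,1,0.1,0.2,0.3;", "u1,walk,2,0.1,0.2;"), f2)
  expect_error(suppressMessages(read_wisdm_csv(f2)), "line 2")
})

test_that("sentiment files round-trip and malformed lines are located", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_sentiment_file(c("great product", "bad service"), c(1, 0), f)
  rec <- suppressMessages(read_sentiment_file(f))
  expect_equal(rec$text, c("great product", "bad service"))
  expect_equal(rec$label, c(1L, 0L))

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("fine\t1", "broken line"), f2)
  expect_error(suppressMessages(read_sentiment_file(f2)), "line 2")
})

test_that("labeled_dataset enforces its invariants", {
  expect_error(labeled_dataset(matrix(1, 2, 2), c(0L, 2L), "flat",
                               class_names = c("a", "b")), "out of range")
  X <- one_hot_encode(c("acgt", "ggcc"))
  X[1, 1, ] <- c(0.5, 0.5, 0, 0) * 2 # still sums to 1? no: force violation
  X[1, 1, ] <- c(0.5, 0.4, 0, 0)
  expect_error(labeled_dataset(X, c(0L, 1L), "sequence"), "sum to exactly 1")
})
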