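test_that("a 1-filter convolution with hand-set weights matches hand arithmetic", {
  spec <- architecture_spec(1, kernel_size = 2, pool_size = 2,
                            dense_sizes = c(2, 1), base_filters = 1,
                            dropout_rate = 0, output_activation = "sigmoid",
                            optimizer = "adam")
  net <- suppressMessages(build_network(spec, 2, input_shape = c(4, 1),
                                        seed = 1))
  # identity batch norm, weights (1, -1), bias 0.5
  net$layers[[1]]$par$W <- matrix(c(1, -1), 2, 1)
  net$layers[[1]]$par$b <- 0.5
  net$layers[[1]]$par$gamma <- 1; net$layers[[1]]$par$beta <- 0
  net$layers[[1]]$run_mean <- 0; net$layers[[1]]$run_var <- 1 - net$layers[[1]]$eps
  tn <- structure(net, class = c("trained_network", "conv_network"))

  x <- array(c(3, 1, 4, 1), c(1, 4, 1))
  fm <- extract_features(tn, 1, x)
  # valid conv: (3*1 + 1*-1) + .5, (1-4)+.5, (4-1)+.5 -> relu(2.5,-2.5,3.5)
  expect_equal(unname(fm$values[1, ]), c(2.5, 0, 3.5))
})

test_that("extraction equals an independent loop-based forward pass", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      L <- sample(10:18, 1)
      spec <- tiny_spec(n_blocks = sample(1:2, 1),
                        dense = c(sample(3:6, 1), 1),
                        filters = sample(2:5, 1),
                        kernel = sample(2:3, 1),
                        pool = 2, dropout = 0.3)
      ds <- motif_dataset(n = 30, length = L, motif = "acg",
                          seed = 1000 + rep)
      parts <- suppressMessages(split_dataset(ds, split_spec(seed = rep)))
      net0 <- tryCatch(
        suppressMessages(build_network(spec, 2, input_shape = c(L, 4),
                                       seed = rep)),
        error = function(e) NULL)
      if (is.null(net0)) next
      net <- suppressMessages(train_network(net0, parts$train, parts$val,
                                            max_epochs = 2, seed = rep))
      x <- parts$test$X[1, , , drop = FALSE]
      oracle <- naive_forward_all(net, parts$test$X[1, , ])
      for (li in seq_len(nrow(net$catalog))) {
        fm <- extract_features(net, li, x)
        expect_lt(max(abs(fm$values[1, ] - oracle[[li]])), 1e-5)
      }
    }
  })
})

test_that("post-ReLU extractions are nonnegative and repeated calls identical", {
  parts <- tiny_motif_split(n = 40, seed = 15)
  net0 <- suppressMessages(build_network(tiny_spec(dropout = 0.4), 2,
                                         input_shape = c(16, 4), seed = 15))
  net <- suppressMessages(train_network(net0, parts$train, parts$val,
                                        max_epochs = 3, seed = 15))
  conv_dense <- which(net$catalog$kind %in% c("conv", "dense"))
  for (li in conv_dense[-length(conv_dense)]) { # all but the sigmoid head
    fm <- extract_features(net, li, parts$test)
    expect_true(all(fm$values >= 0))
  }
  f1 <- extract_features(net, 3, parts$test)
  f2 <- extract_features(net, 3, parts$test)
  expect_identical(f1$values, f2$values)
})

test_that("extraction dimensions track the catalog and flatten order is stable", {
  net <- suppressMessages(build_network(recipe_genomic(3), 2, c(57, 4),
                                        seed = 3))
  tn <- structure(net, class = c("trained_network", "conv_network"))
  X <- motif_dataset(n = 4, seed = 3)$X
  # 3 pools: 57 -> 27 -> 12 -> 5 spatial steps at 256 filters
  fm <- extract_features(tn, 10, X) # flatten layer
  expect_equal(ncol(fm$values), 5 * 256)
  expect_equal(fm$layer_name, "flatten")
  # position-major, channel-minor coordinates
  fm1 <- extract_features(tn, 1, X)
  expect_equal(colnames(fm1$values)[1:3], c("p1_c1", "p1_c2", "p1_c3"))
  expect_equal(fm1$coords$position[1:65], rep(1:2, c(64, 1)))
})

test_that("extracting the final layer reproduces the network's probabilities", {
  parts <- tiny_motif_split(n = 40, seed = 16)
  net0 <- suppressMessages(build_network(tiny_spec(), 2,
                                         input_shape = c(16, 4), seed = 16))
  net <- suppressMessages(train_network(net0, parts$train, parts$val,
                                        max_epochs = 3, seed = 16))
  fm <- extract_features(net, nrow(net$catalog), parts$test)
  expect_equal(unname(fm$values[, 1]), predict(net, parts$test)[, 2],
               tolerance = 1e-12)
})

test_that("layer argument is validated against the catalog", {
  parts <- tiny_motif_split(n = 40, seed = 17)
  net0 <- suppressMessages(build_network(tiny_spec(), 2,
                                         input_shape = c(16, 4), seed = 17))
  net <- suppressMessages(train_network(net0, parts$train, parts$val,
                                        max_epochs = 2, seed = 17))
  expect_error(extract_features(net, 99, parts$test), "block1_conv1")
})

test_that("handcrafted features concatenate after extracted columns", {
  parts <- tiny_motif_split(n = 40, seed = 18)
  net0 <- suppressMessages(build_network(tiny_spec(), 2,
                                         input_shape = c(16, 4), seed = 18))
  net <- suppressMessages(train_network(net0, parts$train, parts$val,
                                        max_epochs = 2, seed = 18))
  fm <- extract_features(net, 5, parts$test)
  n <- nrow(fm$values); d <- ncol(fm$values)
  hc <- matrix(rnorm(n * 3), n, 3)
  cc <- concat_handcrafted(fm, hc)
  expect_equal(dim(cc$values), c(n, d + 3))
  expect_identical(cc$values[, seq_len(d)], fm$values)
  # zero-column concat is the identity; row mismatch is an error
  expect_identical(concat_handcrafted(fm, matrix(0, n, 0))$values, fm$values)
  expect_error(concat_handcrafted(fm, hc[-1, , drop = FALSE]), "row mismatch")
})

test_that("overfit diagnostic applies the d < sqrt(n) rule of thumb", {
  expect_false(overfit_diagnostic(10000, 50)$at_risk)
  expect_true(overfit_diagnostic(106, 228)$at_risk)
  expect_true(overfit_diagnostic(1, 1)$at_risk) # boundary: d >= sqrt(n)
})

test_that("feature matrices round-trip through compressed TSV", {
  parts <- tiny_motif_split(n = 20, seed = 19)
  net0 <- suppressMessages(build_network(tiny_spec(), 2,
                                         input_shape = c(16, 4), seed = 19))
  net <- suppressMessages(train_network(net0, parts$train, parts$val,
                                        max_epochs = 2, seed = 19))
  fm <- extract_features(net, 3, parts$test)
  f <- withr::local_tempfile(fileext = ".tsv.gz")
  write_feature_matrix(fm, f)
  back <- read_feature_matrix(f)
  expect_equal(back$layer_index, fm$layer_index)
  expect_equal(back$layer_name, fm$layer_name)
  expect_equal(unname(back$values), unname(fm$values), tolerance = 1e-12)
})
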