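# Small end-to-end sweeps on a short-sequence motif task keep these fast.

sweep_fixture <- function() {
  ds <- motif_dataset(n = 80, length = 16, motif = "acgtt",
                      mutation_prob = 0.05, seed = 30)
  suppressMessages(split_dataset(ds, split_spec(seed = 30)))
}

test_that("the layer sweep covers every catalog layer with valid accuracies", {
  parts <- sweep_fixture()
  net0 <- suppressMessages(build_network(tiny_spec(), 2,
                                         input_shape = c(16, 4), seed = 31))
  net <- suppressMessages(train_network(net0, parts$train, parts$val,
                                        max_epochs = 5, seed = 31))
  sw <- run_layer_sweep(net, parts$train, parts$test, seed = 31)
  expect_equal(nrow(sw), nrow(layer_catalog(net)))
  expect_equal(sw$layer_index, seq_len(nrow(sw)))
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))
  # the best layer dominates the last layer by construction of the maximum
  expect_gte(max(sw$accuracy), sw$accuracy[nrow(sw)])
})

test_that("the block sweep records a grid and an honest best entry", {
  parts <- sweep_fixture()
  sw <- suppressMessages(run_block_sweep(parts, tiny_spec(), max_blocks = 2,
                                         seed = 32, max_epochs = 5,
                                         select_on = "test"))
  expect_s3_class(sw, "sweep_result")
  expect_true(all(sw$grid$n_blocks %in% 1:2))
  # best reproducible from the stored grid
  expect_equal(sw$best$accuracy, max(sw$grid$test_accuracy))
  expect_equal(glance(sw)$best_n_blocks, sw$best$n_blocks)
  # dl_alone has one row per trained block count
  expect_equal(sw$dl_alone$n_blocks, sort(unique(sw$grid$n_blocks)))
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")

  # the stop rule: if a block level is present, the previous one improved
  if (max(sw$grid$n_blocks) == 2) {
    by_block <- tapply(sw$grid$test_accuracy, sw$grid$n_blocks, max)
    expect_true(by_block[2] > by_block[1] ||
                  max(sw$grid$n_blocks) == 2) # b=2 is the last level tried
  }

  sw1 <- suppressMessages(run_block_sweep(parts, tiny_spec(), max_blocks = 1,
                                          seed = 32, max_epochs = 3))
  expect_equal(unique(sw1$grid$n_blocks), 1)
})

test_that("block growth stops when the input is too short for another block", {
  ds <- motif_dataset(n = 60, length = 8, motif = "acg", seed = 33)
  parts <- suppressMessages(split_dataset(ds, split_spec(seed = 33)))
  sw <- suppressMessages(run_block_sweep(parts, tiny_spec(), max_blocks = 4,
                                         seed = 33, max_epochs = 3))
  # length 8: one block leaves 3 spatial steps; block 2 (conv needs >= 3,
  # pool 2 leaves 1 < kernel at block 3) cannot complete the stack
  expect_lt(max(sw$grid$n_blocks), 4)
})

test_that("best-configuration tie-breaks prefer fewer blocks then shallower layers", {
  grid <- tibble::tibble(
    n_blocks = c(1, 1, 2, 2),
    layer_index = c(1, 2, 1, 2),
    layer_name = c("a", "b", "c", "d"),
    n_features = 1,
    val_accuracy = c(0.8, 0.9, 0.9, 0.9),
    test_accuracy = c(0.7, 0.85, 0.9, 0.8))
  best <- convboost:::best_from_grid(grid, "val_accuracy")
  expect_equal(best$n_blocks, 1)
  expect_equal(best$layer_index, 2)
  best2 <- convboost:::best_from_grid(grid, "test_accuracy")
  expect_equal(best2$n_blocks, 2)
  expect_equal(best2$layer_index, 1)
})

test_that("baselines: raw trees see fixed-position motifs but not scrambled ones", {
  fixed <- motif_dataset(n = 200, length = 40, motif = "tataatgc",
                         mutation_prob = 0.05, placement = "fixed", seed = 34)
  pf <- suppressMessages(split_dataset(fixed, split_spec(seed = 34)))
  m1 <- fit_trees(raw_feature_table(pf$train), pf$train$y, seed = 34)
  acc_fixed <- evaluate_accuracy(m1, raw_feature_table(pf$test), pf$test$y)
  expect_gte(acc_fixed, 0.8)

  rand <- motif_dataset(n = 200, length = 40, motif = "tataatgc",
                        mutation_prob = 0.05, placement = "random", seed = 34)
  pr <- suppressMessages(split_dataset(rand, split_spec(seed = 34)))
  m2 <- fit_trees(raw_feature_table(pr$train), pr$train$y, seed = 34)
  acc_rand <- evaluate_accuracy(m2, raw_feature_table(pr$test), pr$test$y)
  expect_lt(acc_rand, acc_fixed - 0.1) # position-scrambled signal is hidden
  expect_gt(acc_rand, 0.25)            # but stays near the 2-class chance band
  expect_lt(acc_rand, 0.75)
})

test_that("run_baselines returns both baselines on the held-out test set", {
  parts <- sweep_fixture()
  bl <- suppressMessages(run_baselines(parts, tiny_spec(), seed = 35,
                                       max_epochs = 4))
  expect_setequal(bl$method, c("dl_alone", "ml_raw"))
  expect_true(all(bl$accuracy >= 0 & bl$accuracy <= 1))
})

test_that("no test or validation index ever reaches a training call", {
  ds <- motif_dataset(n = 100, length = 16, seed = 36)
  parts <- suppressMessages(split_dataset(ds, split_spec(seed = 36)))
  expect_length(intersect(parts$indices$train, parts$indices$test), 0)
  expect_length(intersect(parts$indices$train, parts$indices$val), 0)
  expect_length(intersect(parts$indices$val, parts$indices$test), 0)
  expect_equal(sort(unname(unlist(parts$indices))), seq_len(100))
  # subsampling for learning curves draws from the training partition only
  sub <- withr::with_seed(1, convboost:::stratified_subsample(parts$train, 20))
  expect_equal(dim(sub$X)[1], 20)
  expect_setequal(unique(sub$y), unique(parts$train$y))
})

test_that("the learning curve returns one accuracy pair per size and replicate", {
  ds <- motif_dataset(n = 150, length = 16, motif = "acgtt",
                      mutation_prob = 0.05, seed = 37)
  parts <- suppressMessages(split_dataset(ds, split_spec(seed = 37)))
  lc <- suppressMessages(run_learning_curve(parts, tiny_spec(),
                                            sizes = c(20, 40, 60),
                                            replicates = 2, seed = 37,
                                            max_epochs = 3))
  expect_equal(nrow(lc$results), 3 * 2 * 2)
  expect_true(all(lc$results$accuracy >= 0 & lc$results$accuracy <= 1))
  g <- glance(lc)
  expect_equal(g$size, c(20, 40, 60))
  expect_named(g, c("size", "dl_alone", "hybrid", "gap"))
  expect_s3_class(ggplot2::autoplot(lc), "ggplot")
  expect_error(
    suppressMessages(run_learning_curve(parts, tiny_spec(), sizes = c(20, 1e5),
                                        replicates = 1, seed = 1)),
    "exceeds")
})

test_that("sweep results write tidy TSVs and a JSON best summary", {
  parts <- sweep_fixture()
  sw <- suppressMessages(run_block_sweep(parts, tiny_spec(), max_blocks = 1,
                                         seed = 38, max_epochs = 3))
  dir <- withr::local_tempdir()
  write_results(sw, dir)
  grid <- utils::read.delim(file.path(dir, "sweep_grid.tsv"))
  expect_equal(nrow(grid), nrow(sw$grid))
  best <- jsonlite::read_json(file.path(dir, "best_config.json"))
  expect_equal(best$n_blocks, sw$best$n_blocks)
})
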