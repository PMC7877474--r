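shapes <- enumerate_free_hexominoes()
tiny_cfg <- network_config(n_conv_layers = 2L, fc_units = c(32L, 32L),
                           epochs = 3L, learning_rate = 1e-3)

make_tiny <- function(task, n, seed, siamese = FALSE) {
  split <- split_dictionary(shapes, 5L, seed = 1L)
  trials <- generate_dataset(task, n, shapes, split$train_ids, seed = seed)
  dataset_arrays(trials, shapes, siamese = siamese)
}

test_that("model builds are seeded and report parameter counts", {
  m1 <- build_cnn(tiny_cfg, seed = 7L)
  m2 <- build_cnn(tiny_cfg, seed = 7L)
  expect_identical(m1$weights$fc_W1, m2$weights$fc_W1)
  expect_identical(m1$weights$conv_W1, m2$weights$conv_W1)
  m3 <- build_cnn(tiny_cfg, seed = 8L)
  expect_false(identical(m1$weights$fc_W1, m3$weights$fc_W1))
  expect_gt(m1$param_count, 0)
  ## default architecture: the Siamese trunk+head has the same parameter
  ## count as the plain CNN (shared trunk, same classifier)
  full <- network_config()
  expect_equal(build_siamese(full, 1L)$param_count,
               build_cnn(full, 1L)$param_count, tolerance = 0.01)
  ## spatial collapse is rejected
  expect_error(build_cnn(network_config(n_conv_layers = 10L, input_h = 8L,
                                        input_w = 8L, padding = "valid",
                                        pool_stride = 2L)), "collapsed")
})

test_that("a conv-free configuration trains on raw pixels (smoke)", {
  cfg0 <- network_config(n_conv_layers = 0L, fc_units = c(16L, 16L),
                         epochs = 8L, learning_rate = 1e-3,
                         batch_size = 20L, stop_at_val = 0.99)
  d <- make_tiny("SR", 120, seed = 2L)
  val <- make_tiny("SR", 80, seed = 3L)
  m <- train_model(build_cnn(cfg0, 1L), d, val)
  expect_s3_class(m$history, "data.frame")
  expect_lte(nrow(m$history), 8)
  expect_true(all(m$history$val_acc >= 0 & m$history$val_acc <= 1))
})

test_that("training histories are reproducible and early stopping stops", {
  d <- make_tiny("SR", 100, seed = 5L)
  val <- make_tiny("SR", 100, seed = 6L)
  m1 <- train_model(build_cnn(tiny_cfg, 3L), d, val)
  m2 <- train_model(build_cnn(tiny_cfg, 3L), d, val)
  expect_identical(m1$history, m2$history)
  ## stop_at_val = 0 must stop after the first epoch
  m0 <- train_model(build_cnn(tiny_cfg, 3L), d, val, stop_at_val = 0)
  expect_equal(nrow(m0$history), 1L)
  ## no history continues past the first epoch at/above the threshold
  thr <- 0.5
  mt <- train_model(build_cnn(tiny_cfg, 3L), d, val, stop_at_val = thr)
  hits <- which(mt$history$val_acc >= thr)
  if (length(hits)) expect_equal(nrow(mt$history), min(hits))
})

test_that("siamese branches share the trunk and differ only by sign", {
  cfg <- tiny_cfg
  m <- build_siamese(cfg, seed = 2L)
  d <- make_tiny("SD", 30, seed = 9L, siamese = TRUE)
  Xa <- visreason:::flatten_images(d$xa)
  Xb <- visreason:::flatten_images(d$xb)
  cfg_l <- unclass(m$config); cfg_l$siamese <- TRUE
  ## identical inputs in both branches: zero feature difference, so every
  ## sample gets the same output
  p_same <- visreason:::cpp_nn_predict(m$weights, cfg_l, Xa, Xa)
  expect_lt(max(abs(p_same - p_same[, 1])), 1e-6)
  ## prediction works with distinct branches and stays in (0, 1)
  p <- visreason:::cpp_nn_predict(m$weights, cfg_l, Xa, Xb)
  expect_true(all(p > 0 & p < 1))
  expect_equal(dim(p), c(2L, 30L))
})

test_that("evaluate_model scores a trained model sensibly", {
  d <- make_tiny("SR", 150, seed = 11L)
  val <- make_tiny("SR", 100, seed = 12L)
  cfg <- network_config(n_conv_layers = 1L, fc_units = c(32L, 32L),
                        epochs = 10L, learning_rate = 1e-3,
                        stop_at_val = 0.95)
  m <- train_model(build_cnn(cfg, 4L), d, val)
  acc <- evaluate_model(m, val)$accuracy
  expect_equal(acc, tail(m$history$val_acc, 1))
  expect_gt(acc, 0.6)   # SR is learnable even by this reduced network
})

test_that("the dichotomy harness plumbs one smoke repetition end to end", {
  res <- run_dichotomy_experiment(
    runs = data.frame(task = "SR", arch = "cnn"), n_reps = 1L,
    shapes = shapes,
    config = network_config(n_conv_layers = 1L, fc_units = c(16L, 16L),
                            epochs = 2L, learning_rate = 1e-3),
    n_train = 60L, n_val = 40L, n_test = 40L, seed = 3L)
  expect_s3_class(res, "dichotomy_result")
  expect_equal(nrow(res), 1L)
  expect_true(all(c("train_acc", "best_val_acc", "test_acc", "epochs_run")
                  %in% names(res)))
  expect_true(all(res$test_acc >= 0 & res$test_acc <= 1))
  s <- summary(res)
  expect_equal(s$n_reps, 1)
})
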