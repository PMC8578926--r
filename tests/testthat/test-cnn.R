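test_that("convolution arithmetic sizes the network as published", {
  expect_equal(layer_output_length(200, 5, 2, 2), 100L)
  expect_equal(layer_output_length(7, 1, 1, 0), 7L)   # identity convolution
  # the full chain 200 -> 100 -> 50 -> 25 -> 13, then pool (3, 2, 0) -> 6
  L <- 200
  for (i in 1:4) L <- layer_output_length(L, 5, 2, 2)
  expect_equal(L, 13L)
  expect_equal(layer_output_length(L, 3, 2, 0), 6L)
  expect_error(layer_output_length(1, 5, 2, 0), "short")
})

test_that("architectures have the published channels, widths and slice totals", {
  a1 <- cnn_architecture("cnn1")
  a2 <- cnn_architecture("cnn2")
  expect_equal(a1$out_channels, c(2L, 4L, 8L, 16L))
  expect_equal(a2$out_channels, c(8L, 16L, 18L, 24L))
  expect_equal(a1$layer_lengths, c(100L, 50L, 25L, 13L))
  expect_equal(a1$flat_width, 96L)    # 16 channels x pooled length 6
  expect_equal(a2$flat_width, 144L)   # 24 channels x pooled length 6
  expect_equal(kernel_slice_totals(a1), c(2L, 8L, 32L, 128L))
  expect_equal(kernel_slice_totals(a2), c(16L, 128L, 288L, 432L))
})

test_that("prediction is deterministic, order-preserving and shape-checked", {
  net <- build_cnn(cnn_architecture("cnn1"), seed = 2)
  set.seed(3)
  X <- array(runif(200 * 1 * 7), dim = c(200, 1, 7))
  p1 <- predict(net, X)
  expect_length(p1, 7)
  expect_identical(predict(net, X), p1)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  expect_equal(predict(net, X[, , perm, drop = FALSE]), p1[perm])
  expect_error(predict(net, array(0, dim = c(200, 2, 3))), "channels")
})

test_that("identical seeds give identical weights, different seeds differ", {
  a <- build_cnn(cnn_architecture("cnn2"), seed = 10)
  b <- build_cnn(cnn_architecture("cnn2"), seed = 10)
  c <- build_cnn(cnn_architecture("cnn2"), seed = 11)
  expect_identical(a$params$conv_w, b$params$conv_w)
  expect_false(identical(a$params$conv_w, c$params$conv_w))
})

test_that("training descends, checkpoints the argmin epoch, and is seeded", {
  toyc <- toy_600()$cohort
  ds <- prepare_dataset(toyc, "one_channel", seed = 4)
  cfg <- training_config(max_epochs = 15, batch_sizes = 64L, seed = 5)
  net <- train_cnn(build_cnn(cnn_architecture("cnn1"), seed = 1), ds, cfg)
  h <- net$history
  expect_lt(h$train_mse[nrow(h)], h$train_mse[1])       # descent sanity
  expect_equal(net$chosen_epochs, which.min(h$val_mse)) # argmin selection
  expect_lte(net$val_mse, h$val_mse[nrow(h)])           # no-overfit property
  expect_equal(net$val_mse, min(h$val_mse))
  # bit-for-bit reproducibility of the training curve
  net2 <- train_cnn(build_cnn(cnn_architecture("cnn1"), seed = 1), ds, cfg)
  expect_identical(net$history$val_mse, net2$history$val_mse)
  expect_identical(net$params$head_w, net2$params$head_w)
})

test_that("constant targets are recovered by the regression head", {
  toyc <- toy_600()$cohort
  ds <- prepare_dataset(toyc, "one_channel", seed = 4)
  ds$y <- rep(2.5, length(ds$y))
  net <- train_cnn(build_cnn(cnn_architecture("cnn1"), seed = 1), ds,
                   training_config(max_epochs = 40, batch_sizes = 64L, seed = 5))
  preds <- predict(net, ds, "test")
  expect_lt(max(abs(preds - 2.5)), 0.05)
})

test_that("the two-channel model learns the toy waveform-to-label mapping", {
  fix <- toy_600()
  ds2 <- prepare_dataset(fix$cohort, "two_channel", seed = 4)
  net <- train_cnn(build_cnn(cnn_architecture("cnn2"), seed = 3), ds2,
                   training_config(max_epochs = 60, batch_sizes = 32L, seed = 5))
  preds <- predict(net, ds2, "test")
  r <- pearson_r(preds, ds2$y[ds2$split$test])$r
  expect_gt(r, 0.9)
})
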