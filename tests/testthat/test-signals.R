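test_that("resampling to 200 is exact at knots and accurate on smooth waves", {
  x <- sin(2 * pi * seq(0, 199) / 200) + 100
  expect_equal(resample_to_200(x), x)                      # identity at knots
  expect_equal(resample_to_200(rep(100, 37)), rep(100, 200))
  # sine sampled at 50 points, compared with the analytic cycle at 200
  coarse <- sin(2 * pi * seq(0, 49) / 50)
  fine <- resample_to_200(coarse)
  truth <- sin(2 * pi * seq(0, 199) / 200)
  expect_lt(max(abs(fine - truth)), 0.01)
  expect_equal(fine[1], coarse[1])
  expect_error(resample_to_200(5), "at least 2")
})

test_that("the central-difference derivative is exact on linear signals", {
  expect_equal(time_derivative(rep(7, 200), 0.8), rep(0, 200))
  a <- 0.35
  lin <- a * (0:199)
  tau <- 0.8 / 200
  d <- time_derivative(lin, 0.8)
  expect_equal(d[2:199], rep(a / tau, 198))   # interior points exact
  expect_error(time_derivative(lin, -1), "positive")
  expect_error(time_derivative(1:100, 1), "200")
})

test_that("the derivative is second-order accurate on a sinusoid", {
  T_cyc <- 0.9
  t <- T_cyc * (0:199) / 200
  f <- sin(2 * pi * t / T_cyc)
  truth <- (2 * pi / T_cyc) * cos(2 * pi * t / T_cyc)
  d <- time_derivative(f, T_cyc)
  expect_lt(max(abs(d - truth)), 1e-2 * (2 * pi / T_cyc))
})

test_that("the derivative operator is linear", {
  set.seed(5)
  f <- rnorm(200); g <- rnorm(200)
  expect_equal(time_derivative(2.5 * f - 1.3 * g, 0.7),
               2.5 * time_derivative(f, 0.7) - 1.3 * time_derivative(g, 0.7))
})

test_that("min-max scaling is fit on training rows and never clips", {
  X <- rbind(rep(0, 5), rep(1, 5))
  sc <- minmax_fit(X)
  expect_equal(unname(sc$min), rep(0, 5))
  expect_equal(unname(sc$max), rep(1, 5))
  expect_identical(minmax_fit(X)$min, sc$min)   # refit is identical

  set.seed(9)
  Xtr <- matrix(rnorm(300), 15, 20)
  sc <- minmax_fit(Xtr)
  N <- minmax_apply(Xtr, sc)
  expect_true(all(N >= 0 & N <= 1))
  expect_equal(minmax_invert(N, sc), Xtr, tolerance = 1e-12)  # round trip
  # out-of-range test values are retained, not clipped
  hot <- matrix(sc$max + 1, 1, 20)
  expect_true(all(minmax_apply(hot, sc) > 1))
  # constant columns map to zero
  Xc <- cbind(Xtr, 3)
  scc <- minmax_fit(Xc)
  expect_true(all(minmax_apply(Xc, scc)[, 21] == 0))
  expect_error(minmax_apply(Xtr[, 1:3], sc), "mismatch")
})

test_that("the 60/20/20 split has the published sizes and is seeded", {
  s <- split_60_20_20(3748, seed = 1)
  expect_length(s$train, 2248)
  expect_length(s$validation, 750)
  expect_length(s$test, 750)
  expect_setequal(c(s$train, s$validation, s$test), 1:3748)

  s10 <- split_60_20_20(10, seed = 2)
  expect_equal(lengths(s10[c("train", "validation", "test")]),
               c(train = 6, validation = 2, test = 2))
  expect_identical(split_60_20_20(500, seed = 3), split_60_20_20(500, seed = 3))
})

test_that("white-noise corruption respects the measured-power SNR contract", {
  set.seed(11)
  x <- rnorm(200)                       # ~unit power
  expect_identical(add_awgn(x, 250), x) # effectively noise-free
  # empirical SNR within +/- 0.2 dB on a large pooled draw
  X <- matrix(rnorm(200 * 1000, mean = 2), 1000, 200)
  Y <- add_awgn(X, 40, seed = 21)
  snr_emp <- 10 * log10(mean(X^2) / mean((Y - X)^2))
  expect_lt(abs(snr_emp - 40), 0.2)
  expect_identical(add_awgn(X, 40, seed = 21), Y)  # reproducible
  expect_error(add_awgn(rep(0, 10), 30), "zero-power")
})

test_that("noise severity orders corruption RMSE from 70 to 30 dB", {
  set.seed(13)
  x <- matrix(80 + 40 * abs(sin(seq(0, pi, length.out = 200))), 1, 200)[rep(1, 50), ]
  rmse_at <- vapply(c(70, 60, 50, 40, 30), function(s) {
    y <- add_awgn(x, s, seed = 31)
    sqrt(mean((y - x)^2))
  }, numeric(1))
  expect_true(all(diff(rmse_at) > 0))
})

test_that("channel tensors have the documented shapes", {
  toyc <- toy_600()$cohort
  ds1 <- prepare_dataset(toyc, "one_channel", seed = 4)
  ds2 <- prepare_dataset(toyc, "two_channel", seed = 4)
  expect_equal(dim(ds1$X), c(200, 1, 600))
  expect_equal(dim(ds2$X), c(200, 2, 600))
  # empty input is allowed
  sc <- ds1$scaler_p
  empty <- make_channels(matrix(0, 0, 200), numeric(0), "one_channel", sc)
  expect_equal(dim(empty), c(200, 1, 0))
  # training rows of the pressure channel are inside [0, 1]
  tr <- ds1$X[, 1, ds1$split$train]
  expect_true(all(tr >= 0 & tr <= 1))
})

test_that("test-set corruption propagates into the derivative channel", {
  toyc <- toy_600()$cohort
  ds2 <- prepare_dataset(toyc, "two_channel", seed = 4)
  corr <- corrupt_test_set(ds2, snr_db = 40, seed = 8)
  clean <- ds2$X[, , ds2$split$test, drop = FALSE]
  expect_equal(dim(corr$X_test), dim(clean))
  # both channels must differ from the clean tensor
  expect_gt(mean(abs(corr$X_test[, 1, ] - clean[, 1, ])), 0)
  expect_gt(mean(abs(corr$X_test[, 2, ] - clean[, 2, ])), 0)
})
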