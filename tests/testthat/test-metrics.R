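# Brute-force oracles: every statistic recomputed from its textbook formula.

oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

test_that("pearson_r matches the sample formula and cor.test", {
  expect_equal(pearson_r(1:10, 1:10)$r, 1)
  expect_equal(pearson_r(-(1:10) + 3, 1:10)$r, -1)
  expect_equal(pearson_r(c(1, 2, 3, 5), c(1, 2, 3, 4))$r, 0.9827, tolerance = 1e-4)
  set.seed(41)
  for (n in c(10, 100, 5000)) {
    x <- rnorm(n); y <- x + rnorm(n)
    got <- pearson_r(x, y)
    ora <- oracle_pearson(x, y)
    expect_equal(got$r, ora$r, tolerance = 1e-10)
    expect_equal(got$p_value, ora$p, tolerance = 1e-10)
    ct <- stats::cor.test(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-10)
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-8)
  }
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
})

test_that("nRMSE follows the range-normalized definition", {
  expect_equal(nrmse(1:5, 1:5), 0)
  # hand oracle: RMSE = sqrt(1/3), range 3
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 4)), 100 * sqrt(1 / 3) / 3)
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 4)), 19.245, tolerance = 1e-3)
  expect_equal(nrmse(c(1, 2, 3) + 7, c(1, 2, 4) + 7),
               nrmse(c(1, 2, 3), c(1, 2, 4)))   # translation invariant
  expect_error(nrmse(1:3, rep(2, 3)), "range")
})

test_that("Bland-Altman uses estimated-minus-reference and 1.96 SD limits", {
  ba0 <- bland_altman(1:5, 1:5)
  expect_equal(ba0$bias, 0); expect_equal(ba0$loa_low, 0)
  ba <- bland_altman(c(0.1, -0.1), c(0, 0))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sd(c(0.1, -0.1)))
  expect_equal(ba$loa_high, 0.2772, tolerance = 1e-3)
  shift <- bland_altman(1:5 + 0.5, 1:5)
  expect_equal(shift$bias, 0.5)
  expect_equal(shift$loa_low, 0.5)   # zero-variance differences
  # sign convention: overprediction gives positive bias
  expect_gt(bland_altman(c(2, 3), c(1, 2))$bias, 0)
})

test_that("error fractions count strictly and are monotone in the threshold", {
  expect_equal(unname(error_fractions(1:4, 1:4, 0.1)), 1)
  ef <- error_fractions(c(1.01, 1.1, 1.6), c(1, 1, 1), c(0.05, 0.5, 1))
  expect_equal(unname(ef), c(1 / 3, 2 / 3, 1))
  set.seed(17)
  p <- rnorm(200); r <- rnorm(200)
  fr <- error_fractions(p, r, c(0.1, 0.5, 1, 2, 5))
  expect_true(all(diff(fr) >= 0))
  # boundary: an error exactly at the threshold is not counted
  expect_equal(unname(error_fractions(1.5, 1, 0.5)), 0)
})

test_that("agreement reports match brute-force statistics on random data", {
  set.seed(53)
  for (n in c(10, 500)) {
    ref <- runif(n, 1, 5)
    est <- ref + rnorm(n, sd = 0.3)
    rep <- agreement_report(tibble::tibble(ref = ref, est = est), ref, est)
    # normal-equation oracle for the regression line
    sl <- sum((ref - mean(ref)) * (est - mean(est))) / sum((ref - mean(ref))^2)
    ic <- mean(est) - sl * mean(ref)
    expect_equal(rep$slope, sl, tolerance = 1e-10)
    expect_equal(rep$intercept, ic, tolerance = 1e-10)
    # residual orthogonality of the fitted line
    resid <- est - (ic + sl * ref)
    expect_lt(abs(sum(resid * ref)), 1e-8 * n)
    expect_equal(rep$RMSE, sqrt(mean((est - ref)^2)), tolerance = 1e-12)
    expect_equal(rep$bias, mean(est - ref), tolerance = 1e-12)
    expect_true(rep$loa_low <= rep$bias && rep$bias <= rep$loa_high)
    expect_equal(rep$pred_mean, mean(est), tolerance = 1e-12)
  }
})

test_that("agreement reports round-trip losslessly through JSON", {
  set.seed(59)
  ref <- runif(50, 1, 5); est <- ref + rnorm(50, sd = 0.2)
  rep <- agreement_report(tibble::tibble(ref = ref, est = est), ref, est)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(as.list(rep), path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in names(rep)) expect_equal(back[[f]], rep[[f]], tolerance = 1e-14)
})
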