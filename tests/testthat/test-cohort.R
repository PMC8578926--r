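test_that("parameter sampling reproduces the prescribed Gaussians", {
  dist <- parameter_distributions()
  p <- sample_parameters(10000, dist, seed = 99)
  # Monte-Carlo check of the E_es marginal (truncation barely bites here)
  expect_lt(abs(mean(p$E_es) - 2.3), 3 * 1 / sqrt(10000) + 0.03)
  # truncation to [0.3, 6] narrows the SD slightly below the nominal 1
  expect_lt(abs(sd(p$E_es) - 1), 0.08)
  expect_lt(abs(mean(p$HR) - 63.7), 0.4)
  # all draws respect the truncation bounds
  for (i in seq_len(nrow(dist))) {
    x <- p[[dist$parameter[i]]]
    expect_true(all(x >= dist$lower[i] & x <= dist$upper[i]))
  }
})

test_that("sampling is deterministic and degenerates to the means", {
  expect_identical(sample_parameters(50, seed = 7), sample_parameters(50, seed = 7))
  tight <- parameter_distributions()
  tight$sd <- rep(1e-12, nrow(tight))
  p <- sample_parameters(20, tight, seed = 1)
  for (i in seq_len(nrow(tight))) {
    expect_equal(unname(unlist(p[, tight$parameter[i]])),
                 rep(tight$mean[i], 20), tolerance = 1e-9)
  }
})

test_that("scale factors derive from height, diameter and distensibility", {
  s <- derive_scales(list(height = 180, diameter = 33.2, distensibility = 5.86))
  expect_equal(s$height_scale, 1)
  expect_equal(s$diameter_scale, 1)
  expect_equal(s$Ct_scale, 1)
  s2 <- derive_scales(list(height = 90, diameter = 33.2, distensibility = 11.72))
  expect_equal(s2$height_scale, 0.5)
  expect_equal(s2$Ct_scale, 2)
})

test_that("the plausibility filter applies an inclusive 2.807 SD band", {
  ref <- reference_bp_table()
  at_mean <- stats::setNames(ref$mean, ref$quantity)
  expect_true(plausibility_filter(at_mean, ref)$accepted)

  high <- at_mean
  high["brachial_SBP"] <- ref$mean[ref$quantity == "brachial_SBP"] +
    3 * ref$sd[ref$quantity == "brachial_SBP"]
  flt <- plausibility_filter(high, ref)
  expect_false(flt$accepted)
  expect_equal(flt$reason, "brachial_SBP")

  boundary <- at_mean
  boundary["brachial_SBP"] <- ref$mean[ref$quantity == "brachial_SBP"] +
    2.807 * ref$sd[ref$quantity == "brachial_SBP"]
  expect_true(plausibility_filter(boundary, ref)$accepted)
})

test_that("cohort bookkeeping is consistent and reproducible", {
  coh <- small_cohort()
  s <- coh$subjects
  expect_equal(nrow(s), 40)
  expect_equal(coh$n_accepted, sum(s$accepted))
  expect_equal(s$E_es_true, s$E_es)           # stored truth is the sampled E_es
  expect_equal(nrow(coh$brachial), 40)
  expect_equal(ncol(coh$brachial), 200)
  # accepted subjects have finite waves and valid BP orderings
  acc <- which(s$accepted)
  expect_true(all(is.finite(coh$brachial[acc, ])))
  expect_true(all(s$brachial_SBP[acc] > s$brachial_DBP[acc]))
  expect_true(all(s$brachial_DBP[acc] <= s$brachial_MAP[acc] &
                    s$brachial_MAP[acc] <= s$brachial_SBP[acc]))
  # reproducibility, including acceptance flags
  coh2 <- generate_cohort(n = 40, seed = 123)
  expect_identical(coh$subjects, coh2$subjects)
  expect_identical(coh$brachial, coh2$brachial)
})

test_that("a vacuous filter accepts every converged subject", {
  wide <- reference_bp_table()
  wide$sd <- rep(1e6, nrow(wide))
  coh <- generate_cohort(n = 25, ref = wide, seed = 55)
  s <- coh$subjects
  expect_equal(coh$n_accepted,
               sum(s$reject_reason %in% ""))
  expect_true(all(s$accepted | s$reject_reason %in%
                    c("non_converged", "diverged", "systole_exceeds_cycle",
                      "ees_not_above_eed")))
})
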