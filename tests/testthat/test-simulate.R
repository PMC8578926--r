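test_that("the reference subject converges with pulse-pressure amplification", {
  sim <- reference_sim()
  expect_true(sim$converged)
  brach <- sim$pressure[, "left_brachial"]
  aort <- sim$pressure[, "ascending_aorta"]
  expect_gt(max(brach), max(aort))               # brachial SBP > aortic SBP
  expect_gt(diff(range(brach)) / diff(range(aort)), 1)  # PPA > 1
  expect_true(all(is.finite(sim$pressure)))
})

test_that("cycle-to-cycle convergence decreases monotonically after cycle 3", {
  sim <- reference_sim()
  h <- sim$conv_history
  expect_true(all(diff(h[3:length(h)]) < 0))
})

test_that("mean flows conserve mass and obey the configured TPR", {
  sim <- reference_sim()
  inflow <- mean(sim$valve_flow)
  outflow <- sum(colMeans(sim$terminal_flow))
  expect_lt(abs(inflow - outflow) / inflow, 0.02)
  map_root <- mean(sim$pressure[, "ascending_aorta"])
  p_out <- build_default_tree()$terminals$P_out[1]
  expect_lt(abs((map_root - p_out) / inflow - 1.28) / 1.28, 0.05)
})

test_that("SBP and max dP/dt increase strictly with end-systolic elastance", {
  tree <- build_default_tree()
  sbp <- dpdt <- numeric(0)
  for (e in c(1.5, 2.0, 2.5, 3.0)) {
    sim <- simulate_subject(ventricle_params(E_es = e), tree)
    p <- sim$pressure[, "ascending_aorta"]
    sbp <- c(sbp, max(p))
    dpdt <- c(dpdt, max(diff(p)) / (sim$period / length(p)))
  }
  expect_true(all(diff(sbp) > 0))
  expect_true(all(diff(dpdt) > 0))
})

test_that("a heart with almost no elastance variation ejects almost nothing", {
  sim <- simulate_subject(
    ventricle_params(E_es = 0.2001, E_ed = 0.2, P_fill = 15),
    build_default_tree()
  )
  sv <- diff(range(sim$lv_volume))
  expect_lt(sv, 2)  # ml; essentially no stroke volume
  pp <- diff(range(sim$pressure[, "ascending_aorta"]))
  expect_lt(pp, 5)  # mmHg; essentially no pulse
})

test_that("aortic transit time is consistent with the distensibility wave speed", {
  sim <- reference_sim()
  tree <- build_default_tree()
  seg <- tree$segments
  path <- c("ascending_aorta", "aortic_arch_a", "aortic_arch_b",
            "thoracic_aorta", "abdominal_aorta", "iliac")
  rows <- match(path, seg$id)
  # expected transit: sum of length / local wave speed along the aortic path
  expected <- sum(seg$length_cm[rows] / 100 /
                    wave_speed(seg$distensibility[rows]))
  # measured: lag of the steepest upstroke between root and iliac outlet
  foot <- function(w) which.max(diff(w))
  lag <- (foot(sim$pressure[, "iliac"]) - foot(sim$pressure[, "ascending_aorta"]))
  lag <- (lag %% length(sim$time)) * sim$period / length(sim$time)
  expect_lt(abs(lag - expected) / expected, 0.20)
})

test_that("bp_summary computes SBP/DBP/MAP/PP with translation invariance", {
  const <- bp_summary(rep(90, 50))
  expect_equal(const$SBP, 90); expect_equal(const$DBP, 90)
  expect_equal(const$MAP, 90); expect_equal(const$PP, 0)

  s <- bp_summary(c(80, 120, 100, 80))
  expect_equal(s$SBP, 120); expect_equal(s$DBP, 80)
  expect_equal(s$PP, 40); expect_equal(s$MAP, 95)  # arithmetic-mean oracle

  shifted <- bp_summary(c(80, 120, 100, 80) + 10)
  expect_equal(shifted$SBP, s$SBP + 10)
  expect_equal(shifted$DBP, s$DBP + 10)
  expect_equal(shifted$MAP, s$MAP + 10)
  expect_equal(shifted$PP, s$PP)
  expect_error(bp_summary(c(1, NA, 3)), "finite")
})
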