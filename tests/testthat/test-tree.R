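test_that("default tree at reference scales reproduces the packaged geometry", {
  cfg <- read_tree_config()
  tree <- build_default_tree(height = 180, aortic_diameter_scale = 1,
                             distensibility = 5.86, TPR = 1.28, Ct_scale = 1)
  expect_equal(tree$segments$length_cm, cfg$segments$length_cm)
  expect_equal(tree$segments$d_in_cm, cfg$segments$d_in_cm)
  expect_equal(tree$segments$distensibility,
               5.86 * cfg$segments$stiffness_ratio)
  expect_equal(nrow(tree$terminals), sum(cfg$segments$is_terminal))
})

test_that("lengths scale linearly with height and diameters with the scale", {
  ref <- build_default_tree()
  half <- build_default_tree(height = 90)
  expect_equal(half$segments$length_cm, ref$segments$length_cm / 2)
  wide <- build_default_tree(aortic_diameter_scale = 1.2)
  expect_equal(wide$segments$d_in_cm, ref$segments$d_in_cm * 1.2)
})

test_that("terminal resistances are rescaled so the parallel total equals TPR", {
  for (tpr in c(0.7, 1.28, 2.1)) {
    tree <- build_default_tree(TPR = tpr)
    # oracle: sum the conductances of the series R_c + R_p branches
    g_total <- sum(1 / (tree$terminals$R_c + tree$terminals$R_p))
    expect_equal(1 / g_total, tpr, tolerance = 1e-6)
  }
})

test_that("terminal compliance scales with Ct_scale and keeps its split", {
  ref <- build_default_tree()
  doubled <- build_default_tree(Ct_scale = 2)
  expect_equal(doubled$terminals$C_t, 2 * ref$terminals$C_t)
})

test_that("nonpositive scale factors are rejected", {
  expect_error(build_default_tree(height = 0), "positive")
  expect_error(build_default_tree(TPR = -1), "positive")
})

test_that("the assembled network is a connected tree with Windkessel leaves", {
  tree <- build_default_tree()
  net <- pulsees:::.assemble_network(tree)
  n_nodes <- length(net$Cnode)
  # a tree: branches = nodes - 1
  expect_equal(length(net$u), n_nodes - 1)
  # every leaf (node that is no branch's upstream) has a terminal attached
  leaves <- setdiff(net$v, net$u)
  expect_setequal(leaves, net$term_node)
  expect_true(all(net$Cnode > 0))
  expect_true(all(net$R > 0) && all(net$L > 0))
})
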