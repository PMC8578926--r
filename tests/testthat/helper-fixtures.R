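# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

toy_600 <- function() {
  fixture("toy_600", function() {
    toy <- generate_toy_fixtures(600, seed = 7)
    list(toy = toy, cohort = toy_cohort(toy))
  })
}

# one reference-subject simulation, reused across cardiosim tests
reference_sim <- function() {
  fixture("reference_sim", function() {
    simulate_subject(ventricle_params(), build_default_tree())
  })
}

# small simulated cohort for cohort-bookkeeping tests
small_cohort <- function() {
  fixture("small_cohort", function() {
    generate_cohort(n = 40, seed = 123)
  })
}
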