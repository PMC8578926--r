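#' Analytic toy pulse fixture generator
#'
#' Solver-free substrate for testing the preprocessing / learning / metrics
#' stack. Each toy waveform is a parametric single-cycle pressure shape —
#' a squared-sine systolic bump on a diastolic baseline plus a small decaying
#' dicrotic bump — whose minimum is exactly DBP and whose amplitude is
#' exactly PP. The label is a fixed smooth function of the pulse pressure
#' and the maximum upstroke slope (plus optional Gaussian noise), so the
#' mapping from waveform to label is known and learnable.
#'
#' @param n Number of fixtures.
#' @param seed Integer seed.
#' @param noise_sd SD of the Gaussian label noise (mmHg/ml).
#' @param n_samples Samples per waveform.
#' @return A list with `pressure` (n x n_samples matrix, mmHg), `periods`
#'   (s), `labels` (mmHg/ml-like), and the parameter tibble `params`.
#' @export
generate_toy_fixtures <- function(n, seed = 1, noise_sd = 0.05,
                                  n_samples = 200) {
  stopifnot(n >= 1)
  set.seed(seed)
  params <- tibble(
    DBP = runif(n, 60, 90),
    PP = runif(n, 25, 70),
    period = runif(n, 0.7, 1.1),
    t_sys_frac = runif(n, 0.3, 0.45),
    dicrotic = runif(n, 0.05, 0.2),
    decay = runif(n, 0.15, 0.35)
  )
  tgrid <- seq(0, 1 - 1 / n_samples, length.out = n_samples)
  pressure <- matrix(0, n, n_samples)
  for (i in seq_len(n)) {
    p <- params[i, ]
    ts <- p$t_sys_frac
    wave <- numeric(n_samples)
    sys <- tgrid <= ts
    wave[sys] <- sin(pi * tgrid[sys] / ts)^2
    dia <- !sys
    td <- tgrid[dia] - ts
    wave[dia] <- p$dicrotic * exp(-td / p$decay) * sin(pi * td / (1 - ts))^2
    pressure[i, ] <- p$DBP + p$PP * wave
  }
  # label: fixed smooth function of pulse pressure and max upstroke slope
  slope <- params$PP * pi / (params$t_sys_frac * params$period) # mmHg/s
  labels <- 0.6 + 0.02 * params$PP + 8e-4 * slope +
    rnorm(n, sd = noise_sd)
  list(pressure = pressure, periods = params$period, labels = labels,
       params = params)
}

#' Wrap toy fixtures into a cohort-like object
#'
#' Lets the toy substrate flow through [prepare_dataset()] and the training
#' stack exactly like a simulated cohort.
#'
#' @param toy Output of [generate_toy_fixtures()].
#' @param seed Seed recorded on the cohort.
#' @return An `ees_cohort` whose "subjects" are all accepted and whose
#'   `E_es_true` column holds the toy labels.
#' @export
toy_cohort <- function(toy, seed = 1) {
  n <- nrow(toy$pressure)
  subjects <- tibble(
    E_es_true = toy$labels, period = toy$periods,
    accepted = TRUE, reject_reason = ""
  )
  structure(
    list(subjects = subjects, brachial = toy$pressure, aortic = toy$pressure,
         periods = toy$periods, seed = seed, n_requested = n, n_accepted = n),
    class = "ees_cohort"
  )
}
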