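#' Simulate one cardiac-cycle steady state for a virtual subject
#'
#' Integrates the coupled system of a time-varying elastance ventricle (ideal
#' diode valves with small series resistances), a lumped-ladder arterial tree
#' and three-element Windkessel terminal loads with a fixed-step RK4 scheme,
#' cycle after cycle, until the maximum cycle-to-cycle node-pressure change
#' falls below `settings$convergence_tol` (or `n_cycles_max` is reached). The
#' final cycle is returned, resampled to `settings$output_rate` points.
#'
#' @param ventricle Parameters from [ventricle_params()].
#' @param tree An `arterial_tree` from [build_default_tree()].
#' @param blood Blood properties from [blood_properties()].
#' @param settings Numerical settings from [solver_settings()].
#' @return An object of class `ees_sim`: a list with `time` (s), per-segment
#'   `pressure` (mmHg) and `flow` (ml/s) matrices (one column per segment,
#'   sampled at the segment's distal end / inlet branch), `lv_pressure`
#'   (mmHg), `lv_volume` (ml), `valve_flow` and `terminal_flow` (ml/s),
#'   `period` (s), `converged`, `cycles_run` and the convergence history.
#' @examples
#' \donttest{
#' sim <- simulate_subject(ventricle_params(), build_default_tree())
#' sim$converged
#' bp_summary(sim$pressure[, "left_brachial"], site = "brachial")
#' }
#' @export
simulate_subject <- function(ventricle, tree, blood = blood_properties(),
                             settings = solver_settings()) {
  stopifnot(inherits(ventricle, "ventricle_params"),
            inherits(tree, "arterial_tree"))
  net <- .assemble_network(tree, blood)
  period <- 60 / ventricle$HR
  vent_si <- list(
    Ees = .ela_si(ventricle$E_es), Eed = .ela_si(ventricle$E_ed),
    Vd = ventricle$V_d * ML_M3, Pfill = ventricle$P_fill * MMHG_PA,
    tes = ventricle$t_es / 1000, tr = ventricle$t_es / 2000,
    Rven = .res_si(ventricle$R_ven), Rvalve = .res_si(ventricle$R_valve),
    T = period
  )
  set_si <- list(
    dt = settings$dt, n_cycles_max = settings$n_cycles_max,
    convergence_tol = settings$convergence_tol * MMHG_PA,
    output_rate = settings$output_rate,
    init_pressure = settings$init_pressure * MMHG_PA
  )
  res <- hemo_simulate_cpp(net, vent_si, set_si,
                           record_nodes = net$distal_node,
                           record_branches = net$first_branch)
  if (isTRUE(res$diverged)) {
    abort(paste0(
      "hemodynamic simulation diverged for E_es=", ventricle$E_es,
      ", E_ed=", ventricle$E_ed, ", P_fill=", ventricle$P_fill,
      ", HR=", ventricle$HR, ", t_es=", ventricle$t_es
    ), class = "pulsees_divergence")
  }
  ids <- tree$segments$id
  P <- res$pressure / MMHG_PA
  Q <- res$flow / ML_M3
  colnames(P) <- colnames(Q) <- ids
  Qt <- res$terminal_flow / ML_M3
  colnames(Qt) <- tree$terminals$id
  structure(
    list(
      time = res$time,
      pressure = P,
      flow = Q,
      lv_pressure = res$lv_pressure / MMHG_PA,
      lv_volume = res$lv_volume / ML_M3,
      valve_flow = res$valve_flow / ML_M3,
      terminal_flow = Qt,
      period = period,
      converged = isTRUE(res$converged),
      cycles_run = res$cycles_run,
      conv_history = res$conv_history[!is.na(res$conv_history)] / MMHG_PA,
      ventricle = ventricle
    ),
    class = "ees_sim"
  )
}

#' @export
print.ees_sim <- function(x, ...) {
  cat("<ees_sim> ", ncol(x$pressure), " sites, period ",
      format(x$period, digits = 3), " s, ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$cycles_run, " cycles\n", sep = "")
  invisible(x)
}

#' Tidy a simulation result into a long waveform tibble
#'
#' @param x An `ees_sim` object.
#' @param ... Unused.
#' @return A tibble with columns `site`, `time`, `pressure`, `flow`.
#' @export
tidy.ees_sim <- function(x, ...) {
  sites <- colnames(x$pressure)
  purrr::map_dfr(sites, function(s) {
    tibble(site = s, time = x$time,
           pressure = x$pressure[, s], flow = x$flow[, s])
  })
}

#' Blood-pressure summary of one pressure wave
#'
#' SBP is the maximum, DBP the minimum, MAP the time average over the cycle
#' (samples are uniform in time, so the arithmetic mean) and PP = SBP - DBP.
#'
#' @param wave Pressure samples over one cycle, mmHg.
#' @param site Label for the measurement site.
#' @return A one-row tibble with `site`, `SBP`, `DBP`, `MAP`, `PP`.
#' @examples
#' bp_summary(c(80, 120, 100, 80))
#' @export
bp_summary <- function(wave, site = "unspecified") {
  if (!all(is.finite(wave))) abort("pressure wave contains non-finite samples")
  sbp <- max(wave); dbp <- min(wave)
  tibble(site = site, SBP = sbp, DBP = dbp, MAP = mean(wave), PP = sbp - dbp)
}

#' Waveform plot for a simulation result
#'
#' @param object An `ees_sim` object.
#' @param sites Sites to draw (default: aortic root and left brachial).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ees_sim <- function(object,
                             sites = c("ascending_aorta", "left_brachial"),
                             ...) {
  dat <- tidy(object)
  dat <- dat[dat$site %in% sites, ]
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$pressure,
                                    colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "pressure (mmHg)", colour = NULL) +
    ggplot2::theme_minimal()
}
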