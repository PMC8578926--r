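#' Normalized time-varying elastance
#'
#' Activation curve of the ventricular elastance over one cardiac cycle: a
#' piecewise raised cosine that rises from 0 to its peak of exactly 1 at the
#' time of maximal elastance `t_es`, relaxes back to 0 over a relaxation time
#' `t_r = t_es / 2`, and stays at 0 for the remainder of the cycle.
#'
#' @param t Time since the onset of contraction, s. Vectorized.
#' @param t_es Time of maximal elastance, s.
#' @param period Cardiac cycle length, s. Systole (`t_es + t_es/2`) must be
#'   shorter than the cycle.
#' @return Dimensionless activation in `[0, 1]`.
#' @examples
#' normalized_elastance(c(0, 0.17, 0.34), t_es = 0.34, period = 0.8)
#' @export
normalized_elastance <- function(t, t_es, period) {
  stopifnot(t_es > 0, period > 0)
  t_r <- t_es / 2
  if (t_es + t_r >= period) {
    abort("systole (t_es + t_es/2) must be shorter than the cardiac cycle")
  }
  if (any(t < 0 | t >= period)) {
    abort("t must lie in [0, period)")
  }
  e <- numeric(length(t))
  rise <- t <= t_es
  fall <- t > t_es & t <= t_es + t_r
  e[rise] <- 0.5 * (1 - cos(pi * t[rise] / t_es))
  e[fall] <- 0.5 * (1 + cos(pi * (t[fall] - t_es) / t_r))
  e
}

#' Instantaneous ventricular elastance
#'
#' `E(t) = E_ed + (E_es - E_ed) * e_n(t)`, cycling between the end-diastolic
#' and end-systolic elastance.
#'
#' @param t Time since onset of contraction, s.
#' @param params Ventricle parameter list from [ventricle_params()].
#' @param period Cardiac cycle length, s.
#' @return Elastance in mmHg/ml.
#' @export
instantaneous_elastance <- function(t, params, period) {
  en <- normalized_elastance(t, params$t_es / 1000, period)  # t_es is in ms
  params$E_ed + (params$E_es - params$E_ed) * en
}

#' Ventricular pressure from the elastance relation
#'
#' `P_LV = E(t) * (V_LV - V_d)`; the pressure generated by the ventricle at
#' instantaneous elastance `E_t`, volume `V` and dead volume `V_d`.
#'
#' @param V Ventricular volume, ml.
#' @param E_t Instantaneous elastance, mmHg/ml.
#' @param V_d Dead volume (volume-axis intercept of the ESPVR), ml.
#' @return Pressure in mmHg.
#' @export
lv_pressure <- function(V, E_t, V_d) {
  E_t * (V - V_d)
}

#' Pulse wave speed from distensibility
#'
#' Bramwell-Hill / Moens-Korteweg-equivalent closed form
#' `c = sqrt(1 / (rho * D))` with the distensibility converted to SI.
#'
#' @param distensibility Area distensibility, in units of `1e-3 / mmHg`.
#' @param rho Blood density, kg/m^3.
#' @return Wave speed, m/s.
#' @examples
#' wave_speed(5.86) # about 4.65 m/s
#' @export
wave_speed <- function(distensibility, rho = 1050) {
  if (any(distensibility <= 0)) abort("distensibility must be positive")
  if (any(rho <= 0)) abort("rho must be positive")
  sqrt(1 / (rho * .dist_si(distensibility)))
}

#' Ventricle parameter set
#'
#' Parameters of the time-varying elastance left ventricle. Defaults are the
#' packaged reference input set (a 75 bpm heart with `E_es` 2.6 mmHg/ml).
#'
#' @param E_es End-systolic elastance, mmHg/ml.
#' @param E_ed End-diastolic elastance, mmHg/ml.
#' @param V_d Dead volume, ml.
#' @param P_fill Filling (venous) pressure, mmHg.
#' @param t_es Time of maximal elastance, ms.
#' @param HR Heart rate, bpm.
#' @param R_ven Venous (filling) resistance, mmHg.s/ml.
#' @param R_valve Aortic valve series resistance, mmHg.s/ml.
#' @return A list of class `ventricle_params`.
#' @export
ventricle_params <- function(E_es = 2.6, E_ed = 0.08, V_d = 15, P_fill = 14,
                             t_es = 340, HR = 75, R_ven = 0.003,
                             R_valve = 0.006) {
  stopifnot(E_es > E_ed, E_ed > 0, V_d >= 0, R_ven > 0, R_valve > 0, HR > 0)
  if (!(t_es > 0 && t_es < 60000 / HR)) {
    abort("t_es must lie strictly inside the cardiac cycle (0, 60000/HR) ms")
  }
  structure(
    list(E_es = E_es, E_ed = E_ed, V_d = V_d, P_fill = P_fill, t_es = t_es,
         HR = HR, R_ven = R_ven, R_valve = R_valve),
    class = "ventricle_params"
  )
}

#' Blood properties
#'
#' @param rho Density, kg/m^3.
#' @param mu Dynamic viscosity, Pa.s.
#' @return A list of class `blood_properties`.
#' @export
blood_properties <- function(rho = 1050, mu = 0.004) {
  stopifnot(rho > 0, mu > 0)
  structure(list(rho = rho, mu = mu), class = "blood_properties")
}

#' Solver settings
#'
#' Numerical settings for the RK4 network integrator.
#'
#' @param dt Time step, s.
#' @param n_cycles_max Maximum number of cardiac cycles to integrate.
#' @param convergence_tol Maximum cycle-to-cycle node-pressure change, mmHg,
#'   below which the run is declared periodic.
#' @param output_rate Samples per cycle in the returned waveforms.
#' @param init_pressure Initial pressure at every node, mmHg.
#' @return A list of class `solver_settings`.
#' @export
solver_settings <- function(dt = 1e-4, n_cycles_max = 20,
                            convergence_tol = 0.5, output_rate = 200,
                            init_pressure = 80) {
  stopifnot(dt > 0, convergence_tol > 0, n_cycles_max >= 2, output_rate >= 16)
  structure(
    list(dt = dt, n_cycles_max = n_cycles_max,
         convergence_tol = convergence_tol, output_rate = output_rate,
         init_pressure = init_pressure),
    class = "solver_settings"
  )
}
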