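#' Sampling distributions of the virtual-population parameters
#'
#' Independent Gaussian distributions (mean, SD) for the nine sampled model
#' parameters, with truncation bounds enforced by redrawing. Defaults are the
#' literature-based values used to generate the in silico population. The
#' aortic diameter is in millimetres (the 33.2 +/- 4.1 figure is only
#' anatomically possible as mm, although sometimes printed as cm).
#'
#' @param ... Named overrides; each entry is a list or vector with elements
#'   `mean`, `sd`, `lower`, `upper` (omitted elements keep defaults).
#' @return A tibble with columns `parameter`, `mean`, `sd`, `lower`, `upper`.
#' @examples
#' parameter_distributions()
#' parameter_distributions(E_es = c(mean = 3, sd = 0.5))
#' @export
parameter_distributions <- function(...) {
  base <- tibble(
    parameter = c("E_es", "E_ed", "P_fill", "t_es", "HR",
                  "distensibility", "TPR", "diameter", "height"),
    mean = c(2.3, 0.2, 15, 327, 63.7, 5.86, 1.28, 33.2, 169.2),
    sd = c(1, 0.11, 5.4, 39, 9.5, 3.23, 0.31, 4.1, 8.9),
    lower = c(0.3, 0.02, 3, 200, 40, 0.5, 0.5, 20, 140),
    upper = c(6, 0.6, 30, 500, 110, 16, 2.5, 48, 200)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% base$parameter) {
      abort(paste0("unknown parameter '", nm, "'"))
    }
    ov <- as.list(overrides[[nm]])
    for (f in intersect(names(ov), c("mean", "sd", "lower", "upper"))) {
      base[base$parameter == nm, f] <- as.numeric(ov[[f]])
    }
  }
  stopifnot(all(base$sd > 0), all(base$lower < base$upper))
  base
}

#' Reference blood-pressure table for the plausibility filter
#'
#' Normative mean and SD for the eight screened quantities (aortic and
#' brachial SBP, DBP, MAP, PP). These are plausible literature norms shipped
#' as an editable default; the filter mechanism takes any such table.
#'
#' @param ... Named overrides, e.g. `brachial_SBP = c(mean = 120, sd = 14)`.
#' @return A tibble with columns `quantity`, `mean`, `sd`.
#' @export
reference_bp_table <- function(...) {
  base <- tibble(
    quantity = c("brachial_SBP", "brachial_DBP", "brachial_MAP", "brachial_PP",
                 "aortic_SBP", "aortic_DBP", "aortic_MAP", "aortic_PP"),
    mean = c(123, 76, 92, 47, 112, 77, 92, 35),
    sd = c(15, 10, 10, 12, 15, 10, 10, 11)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% base$quantity) abort(paste0("unknown quantity '", nm, "'"))
    ov <- as.list(overrides[[nm]])
    for (f in intersect(names(ov), c("mean", "sd"))) {
      base[base$quantity == nm, f] <- as.numeric(ov[[f]])
    }
  }
  stopifnot(all(base$sd > 0))
  base
}

#' Sample virtual-subject parameter sets
#'
#' Draws each parameter independently from its truncated Gaussian (redraw
#' until inside the bounds), reproducibly for a given seed.
#'
#' @param n Number of parameter sets.
#' @param dist Distribution table from [parameter_distributions()].
#' @param seed Integer seed (optional; if `NULL` the current RNG state is
#'   used, which allows batched sampling from one stream).
#' @return A tibble with one row per subject and one column per parameter.
#' @export
sample_parameters <- function(n, dist = parameter_distributions(),
                              seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- purrr::pmap(dist, function(parameter, mean, sd, lower, upper) {
    x <- rnorm(n, mean, sd)
    bad <- which(x < lower | x > upper)
    while (length(bad) > 0) {
      x[bad] <- rnorm(length(bad), mean, sd)
      bad <- bad[x[bad] < lower | x[bad] > upper]
    }
    x
  })
  names(draws) <- dist$parameter
  as_tibble(draws)
}

#' Geometry and compliance scale factors for one subject
#'
#' Maps sampled anthropometric / vascular parameters onto the uniform scale
#' factors applied to the reference tree: lengths scale with height relative
#' to the 180 cm reference, all diameters scale with the sampled aortic
#' diameter relative to its 33.2 mm reference, and terminal compliances scale
#' with distensibility relative to its 5.86e-3/mmHg reference (distensibility
#' and terminal compliance are altered simultaneously).
#'
#' @param params A one-row parameter set (list or tibble row) with `height`,
#'   `diameter`, `distensibility`.
#' @param config Tree configuration (for the reference constants).
#' @return A list with `height_scale`, `diameter_scale`, `Ct_scale`.
#' @export
derive_scales <- function(params, config = NULL) {
  if (is.null(config)) config <- .default_tree_config()
  ref <- config$reference
  list(
    height_scale = params$height / ref$height_cm,
    diameter_scale = params$diameter / ref$aortic_diameter_mm,
    Ct_scale = params$distensibility / ref$distensibility
  )
}

#' Physiological plausibility filter
#'
#' A subject is accepted iff each of the eight simulated BP summary values
#' lies within `mean +/- 2.807 SD` of its reference (a 99.5% normal band);
#' the bound is inclusive. The reason names the first violated quantity.
#'
#' @param summaries Named numeric vector (or one-row data frame) with the
#'   eight quantities named as in [reference_bp_table()].
#' @param ref Reference table from [reference_bp_table()].
#' @param k Width of the acceptance band in SDs.
#' @return A list with `accepted` (logical) and `reason` (string, empty if
#'   accepted).
#' @export
plausibility_filter <- function(summaries, ref = reference_bp_table(),
                                k = 2.807) {
  s <- unlist(summaries)
  if (!all(is.finite(s[ref$quantity]))) {
    return(list(accepted = FALSE, reason = "non_finite_summary"))
  }
  dev <- abs(s[ref$quantity] - ref$mean) - k * ref$sd
  bad <- which(dev > 0)
  if (length(bad) == 0) {
    list(accepted = TRUE, reason = "")
  } else {
    list(accepted = FALSE, reason = ref$quantity[bad[1]])
  }
}

# simulate one sampled subject; returns summaries + waves or a reject record
.simulate_one <- function(p, ref, blood, settings, config, k = 2.807,
                          V_d = 15, R_ven = 0.003, R_valve = 0.006) {
  scales <- derive_scales(p, config)
  out <- list(accepted = FALSE, reason = "", brachial = NULL, aortic = NULL,
              summaries = rep(NA_real_, 8), period = 60 / p$HR,
              SV = NA_real_, EF = NA_real_, converged = NA)
  names(out$summaries) <- reference_bp_table()$quantity
  if (p$t_es / 1000 * 1.5 >= 60 / p$HR) {
    out$reason <- "systole_exceeds_cycle"
    return(out)
  }
  if (p$E_es <= p$E_ed) {
    out$reason <- "ees_not_above_eed"
    return(out)
  }
  vent <- ventricle_params(E_es = p$E_es, E_ed = p$E_ed, V_d = V_d,
                           P_fill = p$P_fill, t_es = p$t_es, HR = p$HR,
                           R_ven = R_ven, R_valve = R_valve)
  tree <- build_default_tree(height = p$height,
                             aortic_diameter_scale = scales$diameter_scale,
                             distensibility = p$distensibility, TPR = p$TPR,
                             Ct_scale = scales$Ct_scale, config = config)
  sim <- tryCatch(
    simulate_subject(vent, tree, blood, settings),
    pulsees_divergence = function(e) NULL
  )
  if (is.null(sim)) {
    out$reason <- "diverged"
    return(out)
  }
  out$converged <- sim$converged
  if (!sim$converged) {
    out$reason <- "non_converged"
    return(out)
  }
  brach <- sim$pressure[, "left_brachial"]
  aort <- sim$pressure[, "ascending_aorta"]
  sb <- bp_summary(brach, "brachial")
  sa <- bp_summary(aort, "aortic")
  out$summaries <- c(
    brachial_SBP = sb$SBP, brachial_DBP = sb$DBP, brachial_MAP = sb$MAP,
    brachial_PP = sb$PP, aortic_SBP = sa$SBP, aortic_DBP = sa$DBP,
    aortic_MAP = sa$MAP, aortic_PP = sa$PP
  )
  out$brachial <- brach
  out$aortic <- aort
  out$SV <- diff(range(sim$lv_volume))
  out$EF <- out$SV / max(sim$lv_volume) * 100
  flt <- plausibility_filter(out$summaries, ref, k)
  out$accepted <- flt$accepted
  out$reason <- flt$reason
  out
}

#' Generate the in silico virtual population
#'
#' Samples parameter sets from `dist`, simulates each subject (geometry,
#' resistance and compliance scaled per [derive_scales()]), summarizes the
#' brachial and aortic pressures, and applies the plausibility filter.
#' Non-converged or diverging simulations are recorded as rejected subjects,
#' never as errors. Either a fixed number of sampled subjects (`n`) or a
#' target number of accepted subjects (`min_accepted`) can be requested; in
#' the latter case sampling continues in batches from one seeded stream until
#' the target is reached.
#'
#' @param n Number of subjects to sample (ignored if `min_accepted` given).
#' @param dist Parameter distributions, see [parameter_distributions()].
#' @param ref Reference BP table, see [reference_bp_table()].
#' @param blood Blood properties.
#' @param settings Solver settings.
#' @param seed Integer seed; the whole cohort is reproducible given
#'   `(n, seed, config)`.
#' @param min_accepted If not `NULL`, sample in batches until at least this
#'   many subjects are accepted.
#' @param batch_size Batch size used with `min_accepted`.
#' @param config Tree configuration from [read_tree_config()].
#' @param keep_waves Keep the brachial/aortic waveform matrices (needed for
#'   the learning pipeline).
#' @param verbose Print progress.
#' @return An object of class `ees_cohort`: list with `subjects` (tibble of
#'   sampled parameters, BP summaries, stroke volume, ejection fraction,
#'   `accepted`, `reject_reason`, `E_es_true`), waveform matrices `brachial`
#'   and `aortic` (rows = subjects, 200 columns, mmHg), `periods` (s),
#'   `seed`, `n_requested`, `n_accepted`.
#' @export
generate_cohort <- function(n = NULL, dist = parameter_distributions(),
                            ref = reference_bp_table(),
                            blood = blood_properties(),
                            settings = solver_settings(), seed = 1,
                            min_accepted = NULL, batch_size = 500L,
                            config = NULL, keep_waves = TRUE,
                            verbose = FALSE) {
  if (is.null(n) && is.null(min_accepted)) {
    abort("give either n (subjects to sample) or min_accepted")
  }
  if (is.null(config)) config <- .default_tree_config()
  set.seed(seed)
  params <- list()
  waves_b <- list()
  waves_a <- list()
  rows <- list()
  n_acc <- 0L
  n_done <- 0L
  repeat {
    n_batch <- if (!is.null(min_accepted)) batch_size else n
    p_batch <- sample_parameters(n_batch, dist, seed = NULL)
    for (i in seq_len(n_batch)) {
      p <- as.list(p_batch[i, ])
      r <- .simulate_one(p, ref, blood, settings, config)
      n_done <- n_done + 1L
      if (r$accepted) n_acc <- n_acc + 1L
      rows[[n_done]] <- tibble(
        !!!p, !!!as.list(r$summaries), SV = r$SV, EF = r$EF,
        period = r$period, accepted = r$accepted, reject_reason = r$reason,
        E_es_true = p$E_es
      )
      if (keep_waves) {
        waves_b[[n_done]] <- if (is.null(r$brachial)) rep(NA_real_, settings$output_rate) else r$brachial
        waves_a[[n_done]] <- if (is.null(r$aortic)) rep(NA_real_, settings$output_rate) else r$aortic
      }
    }
    if (verbose) {
      message("sampled ", n_done, ", accepted ", n_acc,
              " (", round(100 * n_acc / n_done, 1), "%)")
    }
    if (!is.null(min_accepted)) {
      if (n_acc >= min_accepted) break
    } else {
      break
    }
  }
  subjects <- dplyr::bind_rows(rows)
  out <- list(
    subjects = subjects,
    brachial = if (keep_waves) do.call(rbind, waves_b) else NULL,
    aortic = if (keep_waves) do.call(rbind, waves_a) else NULL,
    periods = subjects$period,
    seed = seed, n_requested = n_done, n_accepted = n_acc
  )
  class(out) <- "ees_cohort"
  out
}

#' @export
print.ees_cohort <- function(x, ...) {
  cat("<ees_cohort> ", x$n_requested, " sampled, ", x$n_accepted,
      " accepted (", round(100 * x$n_accepted / x$n_requested, 1),
      "%), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Subject table of a cohort
#'
#' @param x An `ees_cohort`.
#' @param ... Unused.
#' @return The `subjects` tibble (one row per sampled subject).
#' @export
tidy.ees_cohort <- function(x, ...) x$subjects

#' One-row cohort summary
#'
#' @param x An `ees_cohort`.
#' @param ... Unused.
#' @return Tibble with sample counts, acceptance rate and accepted-population
#'   E_es mean/SD.
#' @export
glance.ees_cohort <- function(x, ...) {
  acc <- x$subjects[x$subjects$accepted, ]
  tibble(
    n_requested = x$n_requested, n_accepted = x$n_accepted,
    acceptance_rate = x$n_accepted / x$n_requested,
    E_es_mean = mean(acc$E_es_true), E_es_sd = sd(acc$E_es_true),
    seed = x$seed
  )
}

#' BP-distribution plot of a cohort
#'
#' @param object An `ees_cohort`.
#' @param ... Unused.
#' @return A ggplot of the brachial SBP/DBP distributions split by
#'   acceptance.
#' @export
autoplot.ees_cohort <- function(object, ...) {
  dat <- tidyr::pivot_longer(
    object$subjects[, c("brachial_SBP", "brachial_DBP", "accepted")],
    cols = c("brachial_SBP", "brachial_DBP"),
    names_to = "quantity", values_to = "mmHg"
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$mmHg, fill = .data$accepted)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::theme_minimal()
}

#' Write a cohort's subject table to CSV
#'
#' @param cohort An `ees_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort$subjects, path, row.names = FALSE)
  invisible(path)
}
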