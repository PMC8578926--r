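#' End-to-end pipeline configuration
#'
#' Collects every knob of the cohort -> preprocessing -> training ->
#' evaluation pipeline, with one independent seed per source of randomness
#' (changing the noise seed cannot perturb cohort generation).
#'
#' @param n Subjects to sample (or `NULL` when `min_accepted` is used).
#' @param min_accepted Sample until this many subjects pass the filter.
#' @param seeds Named list with `cohort`, `split`, `init`, `train`, `noise`.
#' @param dist Parameter distributions.
#' @param ref Reference BP table.
#' @param settings Solver settings.
#' @param training A [training_config()] (its seed is taken from `seeds`).
#' @param snr_list SNR sweep levels, dB.
#' @param models Which architectures to run.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n = 6000, min_accepted = NULL,
                            seeds = list(cohort = 1, split = 2, init = 3,
                                         train = 4, noise = 5),
                            dist = parameter_distributions(),
                            ref = reference_bp_table(),
                            settings = solver_settings(),
                            training = training_config(),
                            snr_list = c(70, 60, 50, 40, 30),
                            models = c("cnn1", "cnn2"), out_dir = NULL) {
  stopifnot(all(c("cohort", "split", "init", "train", "noise") %in% names(seeds)))
  structure(
    list(n = n, min_accepted = min_accepted, seeds = seeds, dist = dist,
         ref = ref, settings = settings, training = training,
         snr_list = snr_list, models = models, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full in silico estimation pipeline
#'
#' Generates (or reuses) a plausibility-filtered cohort, builds the one- and
#' two-channel datasets, trains the requested CNNs, and evaluates each on
#' the clean test set plus the SNR sweep. All stage seeds and a configuration
#' hash are embedded in the result.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-generated `ees_cohort` (skips simulation).
#' @param verbose Print stage progress.
#' @return A list of class `ees_pipeline` with the cohort, datasets, trained
#'   `models`, the combined `reports` tibble (one row per model x condition),
#'   `seeds` and `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[pulsees] ", ...)
  if (is.null(cohort)) {
    say("generating cohort")
    cohort <- generate_cohort(
      n = config$n, dist = config$dist, ref = config$ref,
      settings = config$settings, seed = config$seeds$cohort,
      min_accepted = config$min_accepted, verbose = verbose
    )
  }
  say("accepted ", cohort$n_accepted, " of ", cohort$n_requested)

  mode_of <- c(cnn1 = "one_channel", cnn2 = "two_channel")
  datasets <- list()
  models <- list()
  reports <- list()
  for (m in config$models) {
    say("preparing ", mode_of[[m]], " dataset")
    ds <- prepare_dataset(cohort, mode = mode_of[[m]],
                          seed = config$seeds$split)
    say("training ", m)
    net <- build_cnn(cnn_architecture(m), seed = config$seeds$init)
    tc <- config$training
    tc$seed <- as.integer(config$seeds$train)
    net <- train_cnn(net, ds, tc, verbose = verbose)
    say(m, ": batch ", net$chosen_batch_size, ", epoch ", net$chosen_epochs)
    rep <- noise_sweep(net, ds, snr_list = config$snr_list,
                       seed = config$seeds$noise)
    datasets[[m]] <- ds
    models[[m]] <- net
    reports[[m]] <- rep
  }
  reports <- dplyr::bind_rows(reports)
  out <- structure(
    list(cohort = cohort, datasets = datasets, models = models,
         reports = reports, seeds = config$seeds,
         config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
         package_version = as.character(utils::packageVersion("pulsees"))),
    class = "ees_pipeline"
  )
  if (!is.null(config$out_dir)) write_pipeline(out, config$out_dir)
  out
}

#' @export
print.ees_pipeline <- function(x, ...) {
  cat("<ees_pipeline> ", x$cohort$n_accepted, " accepted subjects, models: ",
      paste(names(x$models), collapse = ", "), "\n", sep = "")
  clean <- x$reports[is.infinite(x$reports$snr_db), ]
  for (i in seq_len(nrow(clean))) {
    cat("  ", clean$model[i], " clean test: r = ",
        format(clean$r[i], digits = 3), ", RMSE = ",
        format(clean$RMSE[i], digits = 3), " mmHg/ml, nRMSE = ",
        format(clean$nRMSE[i], digits = 3), "%\n", sep = "")
  }
  invisible(x)
}

#' The evaluation table of a pipeline run
#'
#' @param x An `ees_pipeline`.
#' @param ... Unused.
#' @return The `reports` tibble (one row per model x noise condition).
#' @export
tidy.ees_pipeline <- function(x, ...) x$reports

#' Write pipeline artifacts to a directory
#'
#' Writes the cohort subject table and the evaluation table as CSV, the
#' agreement reports plus seeds/configuration hash/package version as JSON,
#' and per-model test-set predictions as CSV.
#'
#' @param pipeline An `ees_pipeline`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csv(pipeline$cohort, file.path(dir, "cohort.csv"))
  write.csv(pipeline$reports, file.path(dir, "reports.csv"), row.names = FALSE)
  meta <- list(seeds = pipeline$seeds, config_hash = pipeline$config_hash,
               package_version = pipeline$package_version)
  jsonlite::write_json(
    list(meta = meta, reports = pipeline$reports),
    file.path(dir, "reports.json"), auto_unbox = TRUE, digits = NA
  )
  for (m in names(pipeline$models)) {
    ds <- pipeline$datasets[[m]]
    preds <- predict(pipeline$models[[m]], ds, partition = "test")
    write.csv(
      data.frame(E_es_true = ds$y[ds$split$test], E_es_pred = preds),
      file.path(dir, paste0("predictions_", m, ".csv")), row.names = FALSE
    )
  }
  invisible(dir)
}
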