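#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson correlation between predictions and reference values, with
#' the two-sided p-value from `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees
#' of freedom (Wald test with t distribution).
#'
#' @param pred,ref Numeric vectors of equal length (n >= 3), both with
#'   nonzero variance.
#' @return A list with `r` and `p_value`.
#' @export
pearson_r <- function(pred, ref) {
  stopifnot(length(pred) == length(ref), length(pred) >= 3)
  if (sd(pred) == 0 || sd(ref) == 0) abort("zero variance input")
  r <- cor(pred, ref)
  n <- length(pred)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * pt(-abs(tt), df = n - 2))
}

#' Root-mean-square error
#'
#' @param pred,ref Numeric vectors of equal length.
#' @return `sqrt(mean((pred - ref)^2))`.
#' @export
rmse <- function(pred, ref) {
  stopifnot(length(pred) == length(ref))
  sqrt(mean((pred - ref)^2))
}

#' Range-normalized RMSE, in percent
#'
#' RMSE divided by the range (max - min) of the reference variable.
#'
#' @param pred,ref Numeric vectors of equal length; `ref` must have nonzero
#'   range.
#' @return nRMSE in percent.
#' @export
nrmse <- function(pred, ref) {
  rng <- max(ref) - min(ref)
  if (rng <= 0) abort("reference range is zero")
  100 * rmse(pred, ref) / rng
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are estimated minus reference; bias is their mean and the
#' limits of agreement are `bias +/- 1.96 SD` (sample SD, n-1 denominator),
#' the interval expected to contain 95% of errors.
#'
#' @param pred,ref Numeric vectors of equal length (n >= 2).
#' @return A list with `bias`, `loa_low`, `loa_high`, `sd_diff`.
#' @export
bland_altman <- function(pred, ref) {
  stopifnot(length(pred) == length(ref), length(pred) >= 2)
  d <- pred - ref
  s <- sd(d)
  list(bias = mean(d), loa_low = mean(d) - 1.96 * s,
       loa_high = mean(d) + 1.96 * s, sd_diff = s)
}

#' Fractions of absolute errors below thresholds
#'
#' For each threshold `t`, the fraction of subjects with `|pred - ref| < t`
#' (strict inequality).
#'
#' @param pred,ref Numeric vectors of equal length.
#' @param thresholds Positive thresholds, mmHg/ml.
#' @return Named numeric vector of fractions.
#' @export
error_fractions <- function(pred, ref, thresholds = c(0.05, 0.5)) {
  stopifnot(all(thresholds > 0))
  err <- abs(pred - ref)
  out <- vapply(thresholds, function(t) mean(err < t), numeric(1))
  names(out) <- paste0("frac_lt_", thresholds)
  out
}

#' Full agreement report between predicted and reference elastance
#'
#' Assembles the regression line (estimate on truth), Pearson r and p,
#' RMSE and range-normalized RMSE, Bland-Altman bias and limits of
#' agreement, the predicted-population mean and SD, and error fractions.
#'
#' @param data A data frame holding the two columns.
#' @param truth,estimate Column names (tidy-eval) of the reference and
#'   predicted values, mmHg/ml.
#' @param thresholds Error-fraction thresholds, mmHg/ml.
#' @return A one-row tibble of class `ees_agreement`.
#' @examples
#' agreement_report(data.frame(ref = c(1, 2, 3, 4), est = c(1.1, 1.9, 3, 4.2)),
#'                  truth = ref, estimate = est)
#' @export
agreement_report <- function(data, truth, estimate,
                             thresholds = c(0.05, 0.5)) {
  ref <- dplyr::pull(data, {{ truth }})
  pred <- dplyr::pull(data, {{ estimate }})
  fit <- lm(pred ~ ref)
  pr <- pearson_r(pred, ref)
  ba <- bland_altman(pred, ref)
  fr <- error_fractions(pred, ref, thresholds)
  out <- tibble(
    n = length(pred),
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r = pr$r, p_value = pr$p_value,
    RMSE = rmse(pred, ref), nRMSE = nrmse(pred, ref),
    bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
    pred_mean = mean(pred), pred_sd = sd(pred),
    max_abs_error = max(abs(pred - ref))
  )
  out <- dplyr::bind_cols(out, as_tibble(as.list(fr)))
  class(out) <- c("ees_agreement", class(out))
  out
}

#' Noise-robustness sweep of a trained model
#'
#' Evaluates the model on the clean test set and after corrupting the raw
#' test pressure waves with white Gaussian noise at each SNR (recomputing
#' the derivative channel from the noisy pressure and renormalizing with the
#' frozen training scalers).
#'
#' @param model A trained `ees_cnn`.
#' @param dataset The `ees_dataset` the model was trained on.
#' @param snr_list SNR levels in dB.
#' @param seed Base seed for the noise draws (one derived seed per level).
#' @param thresholds Error-fraction thresholds.
#' @return A tibble with one `ees_agreement` row per condition; `snr_db` is
#'   `Inf` for the clean row.
#' @export
noise_sweep <- function(model, dataset, snr_list = c(70, 60, 50, 40, 30),
                        seed = 1, thresholds = c(0.05, 0.5)) {
  stopifnot(inherits(model, "ees_cnn"), model$trained)
  y_test <- dataset$y[dataset$split$test]
  eval_at <- function(X, snr) {
    pred <- predict(model, X)
    rep <- agreement_report(tibble(ref = y_test, est = pred), ref, est,
                            thresholds)
    dplyr::bind_cols(tibble(model = model$arch$model, snr_db = snr), rep)
  }
  rows <- list(eval_at(.dataset_slice(dataset, dataset$split$test), Inf))
  for (i in seq_along(snr_list)) {
    corr <- corrupt_test_set(dataset, snr_list[i], seed = seed + i)
    rows[[i + 1]] <- eval_at(corr$X_test, snr_list[i])
  }
  dplyr::bind_rows(rows)
}

#' Scatter and Bland-Altman plots for predictions
#'
#' @param data Data frame with reference and predicted values.
#' @param truth,estimate Column names (tidy-eval).
#' @return A list with two ggplots: `scatter` and `bland_altman`.
#' @export
plot_agreement <- function(data, truth, estimate) {
  ref <- dplyr::pull(data, {{ truth }})
  pred <- dplyr::pull(data, {{ estimate }})
  ba <- bland_altman(pred, ref)
  d <- tibble(ref = ref, pred = pred, mean2 = (ref + pred) / 2,
              diff = pred - ref)
  sc <- ggplot2::ggplot(d, ggplot2::aes(.data$ref, .data$pred)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::labs(x = "reference E_es (mmHg/ml)",
                  y = "predicted E_es (mmHg/ml)") +
    ggplot2::theme_minimal()
  bap <- ggplot2::ggplot(d, ggplot2::aes(.data$mean2, .data$diff)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = c(ba$bias, ba$loa_low, ba$loa_high),
                        linetype = c("solid", "dashed", "dashed")) +
    ggplot2::labs(x = "mean of reference and prediction (mmHg/ml)",
                  y = "prediction - reference (mmHg/ml)") +
    ggplot2::theme_minimal()
  list(scatter = sc, bland_altman = bap)
}
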