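#' Resample a single-cycle waveform to 200 points
#'
#' Input samples are treated as uniformly spaced over one cycle `[0, period)`;
#' the wave is linearly interpolated at `n_out` uniform time points, with
#' periodic wrap-around for query points beyond the last input sample. The
#' first output sample equals the first input sample.
#'
#' @param samples Pressure samples of one cycle.
#' @param n_out Output length (200).
#' @return Numeric vector of length `n_out`.
#' @export
resample_to_200 <- function(samples, n_out = 200) {
  n <- length(samples)
  if (n < 2) abort("need at least 2 samples to resample")
  x_in <- seq(0, 1 - 1 / n, length.out = n)
  # append the wrapped first sample at phase 1 so queries in (1-1/n, 1) work
  out <- approx(c(x_in, 1), c(samples, samples[1]),
                xout = seq(0, 1 - 1 / n_out, length.out = n_out))$y
  out
}

#' Central-difference time derivative of a 200-sample cycle
#'
#' `f'[n] = (f[n+1] - f[n-1]) / (2 tau)` with `tau = period / 200`. The wave
#' is one full cardiac cycle, so the endpoints wrap around periodically.
#'
#' @param samples Exactly 200 pressure samples, mmHg.
#' @param period Cycle duration, s.
#' @return 200 derivative samples, mmHg/s.
#' @export
time_derivative <- function(samples, period) {
  n <- length(samples)
  if (n != 200) abort("time_derivative expects exactly 200 samples")
  if (period <= 0) abort("period must be positive")
  tau <- period / n
  (samples[c(2:n, 1)] - samples[c(n, 1:(n - 1))]) / (2 * tau)
}

#' Fit a per-column min-max scaler
#'
#' Records per-column (per-time-point) minimum and maximum over the supplied
#' rows; fit it on the training partition only.
#'
#' @param X Numeric matrix (rows = subjects).
#' @return An object of class `minmax_scaler`.
#' @export
minmax_fit <- function(X) {
  if (nrow(X) < 2) abort("need at least 2 rows to fit the scaler")
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  structure(list(min = mins, max = maxs, constant = maxs == mins),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' `x' = (x - min) / (max - min)` per column. Constant columns map to 0.
#' Values outside the training range are kept (no clipping), so validation
#' and test values may fall outside `[0, 1]`.
#'
#' @param X Numeric matrix with the same column count as the fit.
#' @param scaler A `minmax_scaler`.
#' @return Normalized matrix.
#' @export
minmax_apply <- function(X, scaler) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  if (ncol(X) != length(scaler$min)) abort("column count mismatch with scaler")
  rng <- scaler$max - scaler$min
  rng[scaler$constant] <- 1
  out <- sweep(sweep(X, 2, scaler$min, "-"), 2, rng, "/")
  out[, scaler$constant] <- 0
  out
}

#' Invert a min-max transform
#'
#' @param X Normalized matrix.
#' @param scaler A `minmax_scaler`.
#' @return Matrix on the original scale (constant columns are restored to
#'   their training value).
#' @export
minmax_invert <- function(X, scaler) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  rng <- scaler$max - scaler$min
  rng[scaler$constant] <- 0
  sweep(sweep(X, 2, rng, "*"), 2, scaler$min, "+")
}

#' 60/20/20 train/validation/test split
#'
#' Uniform random permutation by seed, partitioned into 60% training, 20%
#' validation and 20% test (validation and test sizes rounded to nearest,
#' training takes the remainder).
#'
#' @param n Number of subjects (>= 5).
#' @param seed Integer seed.
#' @return A list of class `split_indices` with `train`, `validation`,
#'   `test` index vectors and the seed.
#' @export
split_60_20_20 <- function(n, seed) {
  stopifnot(n >= 5)
  n_val <- round(0.2 * n)
  n_test <- round(0.2 * n)
  set.seed(seed)
  perm <- sample.int(n)
  structure(
    list(train = perm[seq_len(n - n_val - n_test)],
         validation = perm[(n - n_val - n_test + 1):(n - n_test)],
         test = perm[(n - n_test + 1):n],
         seed = seed),
    class = "split_indices"
  )
}

#' Add white Gaussian noise at a given SNR
#'
#' Adds i.i.d. zero-mean Gaussian noise with variance
#' `P_sig / 10^(snr_db/10)` where `P_sig` is the measured mean-square power
#' of the input (per row for a matrix, i.e. per subject). `snr_db >= 200` is
#' treated as noise-free.
#'
#' @param x Numeric vector (one waveform) or matrix (one waveform per row).
#' @param snr_db Signal-to-noise ratio in dB.
#' @param seed Optional integer seed.
#' @return Corrupted waveform(s) with the same shape as `x`.
#' @export
add_awgn <- function(x, snr_db, seed = NULL) {
  if (!is.finite(snr_db)) abort("snr_db must be finite (use >= 200 for none)")
  if (!is.null(seed)) set.seed(seed)
  if (snr_db >= 200) return(x)
  if (is.matrix(x)) {
    p_sig <- rowMeans(x^2)
    if (any(p_sig == 0)) abort("zero-power waveform")
    sigma <- sqrt(p_sig / 10^(snr_db / 10))
    noise <- matrix(rnorm(length(x)), nrow = nrow(x)) * sigma
    x + noise
  } else {
    p_sig <- mean(x^2)
    if (p_sig == 0) abort("zero-power waveform")
    x + rnorm(length(x), sd = sqrt(p_sig / 10^(snr_db / 10)))
  }
}

#' Assemble normalized CNN input channels
#'
#' Channel 0 is the min-max-normalized pressure wave; in `two_channel` mode
#' channel 1 is the normalized central-difference time derivative, computed
#' from the raw (pre-normalization) pressure and scaled with its own
#' independently fitted scaler.
#'
#' @param pressure n x 200 matrix of raw pressure waves, mmHg.
#' @param periods Per-subject cycle durations, s.
#' @param mode `"one_channel"` or `"two_channel"`.
#' @param scaler_p,scaler_d Fitted scalers for the pressure and derivative
#'   channels (fit them on training rows).
#' @return Numeric array with dim `(200, channels, n)` ready for the CNN.
#' @export
make_channels <- function(pressure, periods, mode = c("one_channel", "two_channel"),
                          scaler_p, scaler_d = NULL) {
  mode <- match.arg(mode)
  n <- nrow(pressure)
  n_ch <- if (mode == "two_channel") 2L else 1L
  X <- array(0, dim = c(ncol(pressure), n_ch, n))
  if (n == 0) return(X)
  Pn <- minmax_apply(pressure, scaler_p)
  X[, 1, ] <- t(Pn)
  if (mode == "two_channel") {
    if (is.null(scaler_d)) abort("two_channel mode needs a derivative scaler")
    D <- t(vapply(seq_len(n), function(i) time_derivative(pressure[i, ], periods[i]),
                  numeric(ncol(pressure))))
    X[, 2, ] <- t(minmax_apply(D, scaler_d))
  }
  X
}

#' Build a normalized, split learning dataset from a cohort
#'
#' Restricts the cohort to accepted subjects, splits 60/20/20, fits min-max
#' scalers for the pressure (and, in two-channel mode, derivative) channel on
#' the training rows only, and assembles the normalized input tensor.
#' Targets are the reference `E_es` values in native mmHg/ml (never
#' normalized).
#'
#' @param cohort An `ees_cohort` with waveforms.
#' @param mode `"one_channel"` or `"two_channel"`.
#' @param seed Seed for the split permutation.
#' @param site Which stored wave to learn from (`"brachial"` default).
#' @return An object of class `ees_dataset`: list with the input array `X`
#'   (200 x channels x n), targets `y`, `split` indices, fitted scalers, the
#'   raw `pressure` matrix and `periods`, `mode` and seeds.
#' @export
prepare_dataset <- function(cohort, mode = c("one_channel", "two_channel"),
                            seed = 1, site = c("brachial", "aortic")) {
  mode <- match.arg(mode)
  site <- match.arg(site)
  stopifnot(inherits(cohort, "ees_cohort"))
  keep <- which(cohort$subjects$accepted)
  if (length(keep) < 5) abort("cohort has fewer than 5 accepted subjects")
  P <- cohort[[site]][keep, , drop = FALSE]
  periods <- cohort$periods[keep]
  y <- cohort$subjects$E_es_true[keep]
  split <- split_60_20_20(length(keep), seed)
  scaler_p <- minmax_fit(P[split$train, , drop = FALSE])
  scaler_d <- NULL
  if (mode == "two_channel") {
    D_train <- t(vapply(split$train, function(i) time_derivative(P[i, ], periods[i]),
                        numeric(ncol(P))))
    scaler_d <- minmax_fit(D_train)
  }
  X <- make_channels(P, periods, mode, scaler_p, scaler_d)
  structure(
    list(X = X, y = y, split = split, scaler_p = scaler_p,
         scaler_d = scaler_d, pressure = P, periods = periods, mode = mode,
         seed = seed, site = site),
    class = "ees_dataset"
  )
}

#' @export
print.ees_dataset <- function(x, ...) {
  cat("<ees_dataset> ", dim(x$X)[3], " subjects, ", dim(x$X)[2],
      " channel(s), split ", length(x$split$train), "/",
      length(x$split$validation), "/", length(x$split$test), "\n", sep = "")
  invisible(x)
}

# subset the input tensor of a dataset by subject index
.dataset_slice <- function(dataset, idx) {
  dataset$X[, , idx, drop = FALSE]
}

#' Corrupt the test partition of a dataset with measurement noise
#'
#' Applies seeded white Gaussian noise at the requested SNR to the raw test
#' pressure waves, recomputes the derivative channel from the noisy pressure
#' (so the corruption propagates through the derivative), and renormalizes
#' both channels with the frozen training-time scalers.
#'
#' @param dataset An `ees_dataset`.
#' @param snr_db SNR in dB.
#' @param seed Integer seed for the noise draw.
#' @return List with the corrupted test tensor `X_test`, targets `y_test`
#'   and the noisy raw pressure matrix.
#' @export
corrupt_test_set <- function(dataset, snr_db, seed = 1) {
  idx <- dataset$split$test
  P_noisy <- add_awgn(dataset$pressure[idx, , drop = FALSE], snr_db, seed)
  X_test <- make_channels(P_noisy, dataset$periods[idx], dataset$mode,
                          dataset$scaler_p, dataset$scaler_d)
  list(X_test = X_test, y_test = dataset$y[idx], pressure = P_noisy)
}
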