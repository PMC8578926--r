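#' Output length of a strided 1-D convolution
#'
#' `floor((L + 2 padding - kernel) / stride) + 1`; the standard convolution
#' arithmetic used to size the flattened head.
#'
#' @param L_in Input length.
#' @param kernel,stride,padding Convolution parameters.
#' @return Output length (errors if non-positive).
#' @examples
#' layer_output_length(200, 5, 2, 2) # 100
#' @export
layer_output_length <- function(L_in, kernel, stride, padding) {
  if (L_in < kernel - 2 * padding) abort("input too short for this kernel")
  out <- floor((L_in + 2 * padding - kernel) / stride) + 1
  if (out <= 0) abort("non-positive output length: input too short")
  as.integer(out)
}

#' CNN architecture description
#'
#' The two published architectures: four 1-D convolution stages (kernel 5,
#' stride 2, padding 2), each followed by a ReLU, then one max-pool (kernel
#' 3, stride 2), flatten, and a single affine output unit. The one-channel
#' model (`cnn1`) uses filter counts 2/4/8/16; the two-channel model (`cnn2`)
#' uses 8/16/18/24.
#'
#' @param model `"cnn1"` (pressure only) or `"cnn2"` (pressure + derivative).
#' @param input_len Input length per channel (200).
#' @return An object of class `cnn_architecture`.
#' @export
cnn_architecture <- function(model = c("cnn1", "cnn2"), input_len = 200) {
  model <- match.arg(model)
  in_channels <- if (model == "cnn1") 1L else 2L
  out_channels <- if (model == "cnn1") c(2L, 4L, 8L, 16L) else c(8L, 16L, 18L, 24L)
  kernel <- 5L; stride <- 2L; padding <- 2L
  lens <- Reduce(function(L, i) layer_output_length(L, kernel, stride, padding),
                 seq_along(out_channels), accumulate = TRUE, init = input_len)
  pooled <- layer_output_length(lens[length(lens)], 3L, 2L, 0L)
  structure(
    list(model = model, in_channels = in_channels,
         out_channels = out_channels, kernel = kernel, stride = stride,
         padding = padding, pool_kernel = 3L, pool_stride = 2L,
         input_len = as.integer(input_len), layer_lengths = lens[-1],
         pooled_len = pooled,
         flat_width = out_channels[length(out_channels)] * pooled),
    class = "cnn_architecture"
  )
}

#' @export
print.cnn_architecture <- function(x, ...) {
  cat("<cnn_architecture> ", x$model, ": ", x$in_channels, " channel(s) -> [",
      paste(x$out_channels, collapse = ", "), "] filters, lengths ",
      x$input_len, " -> ", paste(x$layer_lengths, collapse = " -> "),
      " -> pool ", x$pooled_len, ", flatten ", x$flat_width, " -> 1\n",
      sep = "")
  invisible(x)
}

#' Kernel-slice totals per layer
#'
#' Audit quantity: filters-per-channel times input channels for each of the
#' four convolution stages (2/8/32/128 for the one-channel model,
#' 16/128/288/432 for the two-channel one).
#'
#' @param arch A `cnn_architecture`.
#' @return Integer vector of length 4.
#' @export
kernel_slice_totals <- function(arch) {
  ins <- c(arch$in_channels, arch$out_channels[-length(arch$out_channels)])
  as.integer(arch$out_channels * ins)
}

#' Build an (untrained) CNN regressor
#'
#' Allocates seeded uniform He-style initial weights for the given
#' architecture.
#'
#' @param arch A `cnn_architecture`.
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `ees_cnn` (untrained).
#' @export
build_cnn <- function(arch, seed = 1) {
  stopifnot(inherits(arch, "cnn_architecture"))
  params <- cnn_init_cpp(arch$in_channels, arch$out_channels, arch$kernel,
                         arch$input_len, as.integer(seed))
  stopifnot(params$flat_width == arch$flat_width)
  structure(
    list(arch = arch, params = params, init_seed = seed, trained = FALSE),
    class = "ees_cnn"
  )
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_sizes Batch-size grid searched on the validation set.
#' @param max_epochs Upper end of the epoch grid; every epoch in
#'   `1..max_epochs` is a candidate via per-epoch validation checkpointing.
#' @param seed Seed for shuffling.
#' @return A list of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.001,
                            batch_sizes = c(32L, 64L, 128L),
                            max_epochs = 400L, seed = 1L) {
  stopifnot(length(batch_sizes) >= 1, max_epochs >= 1, learning_rate > 0)
  structure(list(learning_rate = learning_rate,
                 batch_sizes = as.integer(batch_sizes),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "training_config")
}

#' Train a CNN regressor with Adam and validation-based tuning
#'
#' Minimizes the MSE with Adam (learning rate 0.001 by default). For each
#' batch size in the grid the model is trained from the same seeded
#' initialization for up to `max_epochs` epochs, recording the validation
#' MSE after every epoch; the `(batch_size, epoch)` pair with the smallest
#' validation MSE is selected and the model is restored to that epoch's
#' weights. Targets stay in native mmHg/ml.
#'
#' @param model An untrained `ees_cnn` from [build_cnn()].
#' @param dataset An `ees_dataset` whose channel count matches the
#'   architecture.
#' @param config A [training_config()].
#' @param verbose Print per-batch-size progress.
#' @return The trained `ees_cnn`, with `chosen_batch_size`, `chosen_epochs`,
#'   `val_mse` and a `history` tibble (`batch_size`, `epoch`, `train_mse`,
#'   `val_mse`).
#' @export
train_cnn <- function(model, dataset, config = training_config(),
                      verbose = FALSE) {
  stopifnot(inherits(model, "ees_cnn"), inherits(dataset, "ees_dataset"))
  if (dim(dataset$X)[2] != model$arch$in_channels) {
    abort("dataset channel count does not match the architecture")
  }
  sp <- dataset$split
  Xtr <- .dataset_slice(dataset, sp$train)
  Xva <- .dataset_slice(dataset, sp$validation)
  ytr <- dataset$y[sp$train]
  yva <- dataset$y[sp$validation]

  best <- NULL
  hist <- list()
  for (bs in config$batch_sizes) {
    fit <- cnn_train_cpp(model$params, Xtr, ytr, Xva, yva,
                         batch_size = as.integer(bs),
                         max_epochs = config$max_epochs,
                         lr = config$learning_rate,
                         seed = config$seed + as.integer(bs),
                         kernel = model$arch$kernel,
                         stride = model$arch$stride,
                         pad = model$arch$padding)
    hist[[length(hist) + 1]] <- tibble(
      batch_size = bs, epoch = seq_len(config$max_epochs),
      train_mse = as.numeric(fit$train_history),
      val_mse = as.numeric(fit$val_history)
    )
    if (verbose) {
      message("batch ", bs, ": best val MSE ",
              format(fit$best_val_mse, digits = 4), " at epoch ",
              fit$best_epoch)
    }
    if (is.null(best) || fit$best_val_mse < best$best_val_mse) {
      best <- fit
      best$batch_size <- bs
    }
  }
  model$params <- best$params
  model$trained <- TRUE
  model$chosen_batch_size <- best$batch_size
  model$chosen_epochs <- best$best_epoch
  model$val_mse <- best$best_val_mse
  model$history <- dplyr::bind_rows(hist)
  model$train_config <- config
  model
}

#' Predict elastance for preprocessed inputs
#'
#' @param object A trained `ees_cnn`.
#' @param newdata Either an input array `(200, channels, n)` or an
#'   `ees_dataset` (combined with `partition`).
#' @param partition When `newdata` is a dataset: `"test"`, `"validation"`,
#'   `"train"` or `"all"`.
#' @param ... Unused.
#' @return Numeric vector of E_es estimates, mmHg/ml.
#' @export
predict.ees_cnn <- function(object, newdata,
                            partition = c("test", "validation", "train", "all"),
                            ...) {
  if (inherits(newdata, "ees_dataset")) {
    partition <- match.arg(partition)
    idx <- switch(partition,
                  test = newdata$split$test,
                  validation = newdata$split$validation,
                  train = newdata$split$train,
                  all = seq_along(newdata$y))
    newdata <- .dataset_slice(newdata, idx)
  }
  if (length(dim(newdata)) != 3 || dim(newdata)[2] != object$arch$in_channels) {
    abort("input tensor must have dim (length, channels, n) matching the architecture")
  }
  as.numeric(cnn_forward_cpp(object$params, newdata, object$arch$kernel,
                             object$arch$stride, object$arch$padding))
}

#' @export
print.ees_cnn <- function(x, ...) {
  cat("<ees_cnn> ", x$arch$model,
      if (x$trained) {
        paste0(" (trained: batch ", x$chosen_batch_size, ", epoch ",
               x$chosen_epochs, ", val MSE ", format(x$val_mse, digits = 4), ")")
      } else " (untrained)", "\n", sep = "")
  invisible(x)
}

#' Layer table of a CNN
#'
#' @param x An `ees_cnn`.
#' @param ... Unused.
#' @return Tibble with one row per convolution stage (channels, lengths,
#'   kernel-slice totals, parameter counts).
#' @export
tidy.ees_cnn <- function(x, ...) {
  a <- x$arch
  ins <- c(a$in_channels, a$out_channels[-length(a$out_channels)])
  tibble(
    layer = seq_along(a$out_channels),
    in_channels = ins,
    out_channels = a$out_channels,
    out_length = a$layer_lengths,
    kernel_slices = kernel_slice_totals(a),
    n_weights = a$out_channels * ins * a$kernel + a$out_channels
  )
}

#' One-row summary of a trained CNN
#'
#' @param x An `ees_cnn`.
#' @param ... Unused.
#' @return Tibble with architecture name, selected hyperparameters and the
#'   validation MSE at the selected checkpoint.
#' @export
glance.ees_cnn <- function(x, ...) {
  tibble(
    model = x$arch$model,
    trained = x$trained,
    batch_size = if (x$trained) x$chosen_batch_size else NA_integer_,
    epochs = if (x$trained) x$chosen_epochs else NA_integer_,
    val_mse = if (x$trained) x$val_mse else NA_real_,
    flat_width = x$arch$flat_width
  )
}

#' Training-curve plot
#'
#' @param object A trained `ees_cnn`.
#' @param ... Unused.
#' @return A ggplot of validation MSE vs epoch per batch size.
#' @export
autoplot.ees_cnn <- function(object, ...) {
  if (!object$trained) abort("model is untrained: nothing to plot")
  ggplot2::ggplot(object$history,
                  ggplot2::aes(.data$epoch, .data$val_mse,
                               colour = factor(.data$batch_size))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "validation MSE (mmHg/ml)^2", colour = "batch size") +
    ggplot2::theme_minimal()
}
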