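#' Convert recordings to 32 x 32 scalogram images
#'
#' The full preprocessing front half of the pipeline: z-score normalize each
#' recording over its whole length, cut 30 s epochs, transform every epoch
#' with the Morse-wavelet CWT, render a 224 x 224 grayscale scalogram and
#' resize it to the network's 32 x 32 input.
#'
#' @param records List of `bcg_record` objects.
#' @param epoch_s Epoch length in seconds.
#' @param side Rendered scalogram side (pixels) before the final resize.
#' @param final_side Network input side (pixels).
#' @param params Morse wavelet parameters, [morse_params()].
#' @param fmin,fmax Filter-bank frequency limits in Hz.
#' @return List: `images` (N x final_side^2 matrix, pixel values 0-255,
#'   one row per epoch, column-major pixel order), `labels`, `subject_id`,
#'   `epoch_index`, `counts` (per-class epoch counts).
#' @export
prepare_images <- function(records, epoch_s = 30, side = 224,
                           final_side = 32, params = morse_params(),
                           fmin = 0.5, fmax = 50) {
  records <- lapply(records, zscore_normalize)
  ds <- build_epoch_dataset(records, epoch_s)
  n <- length(ds$epochs)
  images <- matrix(0, n, final_side^2)
  labels <- character(n); subj <- character(n); eidx <- integer(n)
  bank <- NULL
  for (i in seq_len(n)) {
    ep <- ds$epochs[[i]]
    if (is.null(bank) || bank$n_samples != length(ep$samples) ||
        bank$fs != ep$fs) {
      bank <- build_filterbank(ep$fs, length(ep$samples), params, fmin, fmax)
    }
    img <- resize_image(render_scalogram(cwt_epoch(ep, bank), side),
                        final_side)
    images[i, ] <- as.vector(img$pixels)
    labels[i] <- ep$label; subj[i] <- ep$subject_id; eidx[i] <- ep$index
  }
  list(images = images, labels = labels, subject_id = subj,
       epoch_index = eidx, counts = ds$counts)
}

#' Fit the hypertension CNN classifier
#'
#' The package's model-fitting front end: splits the epoch images into
#' train/validation/test partitions, trains the 24-layer CNN and evaluates
#' it on the held-out test set. Returns a classed fit with the usual
#' methods (`print`, `summary`, `predict`, `plot`, `coef`).
#'
#' @param images N x 1024 matrix of 32 x 32 scalogram images (0-255), e.g.
#'   from [prepare_images()].
#' @param labels HC/HPT labels, length N.
#' @param hp Training hyperparameters, [bcg_hyperparams()].
#' @param spec Architecture, [default_modelspec()].
#' @param split Hold-out split, [split_spec()].
#' @param subjects Optional subject ids (needed for subject-level splits).
#' @param epochs Training epochs (defaults to `hp$epochs`).
#' @param seed Seed for initialization, shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return Object of class `hpt_cnn`.
#' @export
#' @examples
#' \donttest{
#' set.seed(1)
#' cfg <- synth_config(n_hc = 4, n_hpt = 4, duration = 60, seed = 7)
#' prep <- prepare_images(generate_dataset(cfg)$records)
#' fit <- hpt_cnn(prep$images, prep$labels, epochs = 2, seed = 1)
#' print(fit)
#' }
hpt_cnn <- function(images, labels, hp = bcg_hyperparams(),
                    spec = default_modelspec(), split = split_spec(),
                    subjects = NULL, epochs = hp$epochs, seed = 1L,
                    verbose = FALSE) {
  labels <- as.character(labels)
  stopifnot(nrow(images) == length(labels))
  idx <- split_holdout(nrow(images), split, subjects)
  model <- build_model(spec, hp, seed = seed)
  fit <- train_network(model, images[idx$train, , drop = FALSE],
                       labels[idx$train],
                       images[idx$val, , drop = FALSE], labels[idx$val],
                       epochs = epochs, seed = seed, verbose = verbose)
  test_scores <- forward(fit$model, images[idx$test, , drop = FALSE])
  test_pred <- scores_to_labels(test_scores)
  cm <- confusion_matrix(labels[idx$test], test_pred)
  structure(list(model = fit$model, history = fit$history, split = idx,
                 split_spec = split, confusion = cm,
                 metrics = suppressWarnings(metrics_from_confusion(cm)),
                 test_scores = test_scores, seed = as.integer(seed),
                 n = nrow(images), call = match.call()),
            class = "hpt_cnn")
}

#' @export
print.hpt_cnn <- function(x, ...) {
  cat("Hypertension CNN classifier fit\n")
  cat(sprintf("  %d epoch images: %d train / %d val / %d test (seed %d)\n",
              x$n, length(x$split$train), length(x$split$val),
              length(x$split$test), x$seed))
  cat(sprintf("  test accuracy %.4f (%.2f%%)\n",
              x$metrics$accuracy, 100 * x$metrics$accuracy))
  invisible(x)
}

#' @export
summary.hpt_cnn <- function(object, ...) {
  cat("Hypertension CNN classifier fit\n")
  cat(sprintf("  instances: %d (train %d, val %d, test %d), seed %d\n",
              object$n, length(object$split$train),
              length(object$split$val), length(object$split$test),
              object$seed))
  cat(sprintf("  trained for %d epochs; final training loss %.4f\n",
              nrow(object$history),
              object$history$loss[nrow(object$history)]))
  cat("  test confusion: ",
      paste(names(object$confusion), unclass(object$confusion),
            sep = "=", collapse = " "), "\n")
  cat("  test metrics:\n")
  for (nm in names(object$metrics)) {
    v <- object$metrics[[nm]]
    cat(sprintf("    %-12s %s\n", nm,
                ifelse(is.na(v), "NA", sprintf("%.4f (%.2f%%)", v, 100 * v))))
  }
  invisible(object)
}

#' Predict HC/HPT for new scalogram images
#'
#' @param object An `hpt_cnn` fit.
#' @param newdata N x 1024 matrix of 32 x 32 images (0-255).
#' @param type `"class"` for HC/HPT labels, `"score"` for the raw N x 2
#'   sigmoid scores.
#' @param ... Unused.
#' @return Character vector of labels or a score matrix.
#' @export
predict.hpt_cnn <- function(object, newdata, type = c("class", "score"),
                            ...) {
  type <- match.arg(type)
  scores <- forward(object$model, newdata)
  if (type == "score") scores else scores_to_labels(scores)
}

#' Plot training history of a fit
#'
#' Loss and accuracy per epoch for the training and validation sets.
#'
#' @param x An `hpt_cnn` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.hpt_cnn <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op), add = TRUE)
  graphics::matplot(h$epoch, cbind(h$loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "loss", ...)
  graphics::legend("topright", c("train", "val"), lty = 1,
                   col = c("black", "red"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$accuracy, h$val_accuracy), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "accuracy", ...)
  graphics::legend("bottomright", c("train", "val"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Extract network weights
#'
#' @param object An `hpt_cnn` fit.
#' @param ... Unused.
#' @return Named list of weight/bias (and batch-norm) tensors per layer.
#' @export
coef.hpt_cnn <- function(object, ...) {
  out <- list()
  for (i in seq_along(object$model$layers)) {
    ly <- object$model$layers[[i]]
    nm <- sprintf("layer%02d_%s", i, ly$kind)
    if (ly$kind %in% c("conv2d", "dense")) {
      out[[nm]] <- list(W = ly$W, b = ly$b)
    } else if (ly$kind == "batchnorm") {
      out[[nm]] <- list(gamma = ly$gamma, beta = ly$beta,
                        running_mean = ly$running_mean,
                        running_var = ly$running_var)
    }
  }
  out
}
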