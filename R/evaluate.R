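#' Hold-out split specification
#'
#' @param fractions Named or positional train/val/test fractions; must be
#'   positive and sum to 1. Default 0.8 / 0.1 / 0.1.
#' @param unit `"epoch"` (split individual epochs) or `"subject"` (keep all
#'   epochs of a subject in one partition). Epoch-level splitting matches
#'   segment-count bookkeeping but leaks subject identity across partitions;
#'   subject-level splitting is the stricter choice for generalization
#'   claims.
#' @param seed Integer seed for the shuffle.
#' @return Object of class `bcg_splitspec`.
#' @export
split_spec <- function(fractions = c(train = 0.8, val = 0.1, test = 0.1),
                       unit = c("epoch", "subject"), seed = 1L) {
  unit <- match.arg(unit)
  if (length(fractions) != 3L || any(fractions <= 0)) {
    stop("need three positive fractions", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  structure(list(fractions = unname(fractions), unit = unit,
                 seed = as.integer(seed)),
            class = "bcg_splitspec")
}

#' Split a dataset into train / validation / test index sets
#'
#' Seeded shuffle followed by a disjoint, exhaustive partition with sizes
#' `round(f * n)` for train and validation and the remainder for test. With
#' `unit = "subject"` whole subjects are assigned to partitions and the
#' fractions apply to subject counts.
#'
#' @param n Number of instances (epochs).
#' @param spec A [split_spec()].
#' @param subjects Optional character vector of length `n` with per-instance
#'   subject ids; required for `unit = "subject"`.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_holdout <- function(n, spec = split_spec(), subjects = NULL) {
  stopifnot(inherits(spec, "bcg_splitspec"), n >= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  f <- spec$fractions
  if (spec$unit == "subject") {
    if (is.null(subjects) || length(subjects) != n) {
      stop("subject-level split needs a `subjects` vector", call. = FALSE)
    }
    ids <- unique(subjects)
    perm <- sample(ids)
    k <- length(ids)
    n_tr <- round(f[1] * k); n_va <- round(f[2] * k)
    g_tr <- perm[seq_len(n_tr)]
    g_va <- perm[n_tr + seq_len(n_va)]
    g_te <- perm[-seq_len(n_tr + n_va)]
    list(train = which(subjects %in% g_tr),
         val = which(subjects %in% g_va),
         test = which(subjects %in% g_te))
  } else {
    perm <- sample.int(n)
    n_tr <- round(f[1] * n); n_va <- round(f[2] * n)
    list(train = sort(perm[seq_len(n_tr)]),
         val = sort(perm[n_tr + seq_len(n_va)]),
         test = sort(perm[-seq_len(n_tr + n_va)]))
  }
}

#' Confusion matrix for HC/HPT predictions
#'
#' HPT is the positive class.
#'
#' @param y_true,y_pred Character/factor vectors with values `"HC"`/`"HPT"`.
#' @return Object of class `bcg_confusion`: named counts tp, fp, tn, fn.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ", call. = FALSE)
  }
  if (!all(c(y_true, y_pred) %in% c("HC", "HPT"))) {
    stop("labels must be 'HC' or 'HPT'", call. = FALSE)
  }
  structure(c(tp = sum(y_true == "HPT" & y_pred == "HPT"),
              fp = sum(y_true == "HC" & y_pred == "HPT"),
              tn = sum(y_true == "HC" & y_pred == "HC"),
              fn = sum(y_true == "HPT" & y_pred == "HC")),
            class = "bcg_confusion")
}

#' Diagnostic metrics from a confusion matrix
#'
#' Accuracy, sensitivity (recall on HPT), specificity, precision and F1.
#' Ratios with a zero denominator are reported as `NA` with a warning,
#' never silently as 0.
#'
#' @param cm A `bcg_confusion` or named vector with tp, fp, tn, fn.
#' @return Object of class `bcg_metrics` (named list of five values in
#'   [0, 1] or NA).
#' @export
metrics_from_confusion <- function(cm) {
  cm <- unclass(cm)
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(cm)))
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  acc <- (cm[["tp"]] + cm[["tn"]]) / n
  sens <- ratio(cm[["tp"]], cm[["tp"]] + cm[["fn"]], "sensitivity")
  spec <- ratio(cm[["tn"]], cm[["tn"]] + cm[["fp"]], "specificity")
  prec <- ratio(cm[["tp"]], cm[["tp"]] + cm[["fp"]], "precision")
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) {
    warning("F1 undefined (zero denominator)", call. = FALSE)
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 precision = prec, f1 = f1),
            class = "bcg_metrics")
}

#' @export
print.bcg_metrics <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("%-12s %s\n", nm,
                ifelse(is.na(x[[nm]]), "NA",
                       sprintf("%.4f (%.2f%%)", x[[nm]], 100 * x[[nm]]))))
  }
  invisible(x)
}

#' k-fold cross-validation of the CNN classifier
#'
#' Seeded shuffle into `k` disjoint folds of near-equal size (sizes differ
#' by at most one). Each fold serves once as the test set; the remaining
#' folds form the training pool, from which one ninth is carved out as a
#' validation set. A fresh network is initialized per fold with a
#' fold-derived seed; no weights are shared across folds.
#'
#' @param images N x 1024 matrix of 32 x 32 images (0-255).
#' @param labels HC/HPT labels, length N.
#' @param k Number of folds (default 10).
#' @param hp A [bcg_hyperparams()].
#' @param spec A `bcg_modelspec`.
#' @param epochs Training epochs per fold.
#' @param seed Master seed; fold seeds derive from it.
#' @param verbose Print fold progress.
#' @return Object of class `bcg_cv`: `folds` (per-fold metrics data frame),
#'   `mean`, `sd`, and `pooled` confusion counts over all folds.
#' @export
kfold_crossval <- function(images, labels, k = 10, hp = bcg_hyperparams(),
                           spec = default_modelspec(),
                           epochs = hp$epochs, seed = 1L, verbose = FALSE) {
  n <- nrow(images)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of instances", call. = FALSE)
  old <- .Random.seed_get()
  set.seed(seed)
  perm <- sample.int(n)
  fold_seeds <- sample.int(.Machine$integer.max - 1L, k)
  .Random.seed_restore(old)
  # near-equal assignment along the shuffled order: sizes differ by <= 1
  fold_id <- integer(n)
  fold_id[perm] <- rep(seq_len(k), length.out = n)

  labels <- as.character(labels)
  rows <- vector("list", k)
  pooled <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (f in seq_len(k)) {
    te <- which(fold_id == f)
    pool <- which(fold_id != f)
    oldf <- .Random.seed_get()
    set.seed(fold_seeds[f])
    pool <- sample(pool)
    .Random.seed_restore(oldf)
    n_val <- max(1L, round(length(pool) / 9))
    va <- pool[seq_len(n_val)]
    tr <- pool[-seq_len(n_val)]
    model <- build_model(spec, hp, seed = fold_seeds[f])
    fit <- train_network(model, images[tr, , drop = FALSE], labels[tr],
                         images[va, , drop = FALSE], labels[va],
                         epochs = epochs, seed = fold_seeds[f],
                         verbose = FALSE)
    pred <- scores_to_labels(forward(fit$model, images[te, , drop = FALSE]))
    cm <- confusion_matrix(labels[te], pred)
    mt <- suppressWarnings(metrics_from_confusion(cm))
    pooled <- pooled + unclass(cm)
    rows[[f]] <- data.frame(fold = f, n_test = length(te),
                            tp = cm[["tp"]], fp = cm[["fp"]],
                            tn = cm[["tn"]], fn = cm[["fn"]],
                            accuracy = mt$accuracy,
                            sensitivity = mt$sensitivity,
                            specificity = mt$specificity,
                            precision = mt$precision, f1 = mt$f1)
    if (verbose) {
      message(sprintf("fold %2d/%d  test acc %.4f", f, k, mt$accuracy))
    }
  }
  folds <- do.call(rbind, rows)
  met_cols <- c("accuracy", "sensitivity", "specificity", "precision", "f1")
  structure(list(folds = folds,
                 mean = colMeans(folds[met_cols], na.rm = TRUE),
                 sd = apply(folds[met_cols], 2, stats::sd, na.rm = TRUE),
                 pooled = pooled, k = k, seed = seed),
            class = "bcg_cv")
}

#' @export
print.bcg_cv <- function(x, ...) {
  cat(sprintf("<bcg_cv> %d-fold cross-validation (seed %d)\n", x$k, x$seed))
  cat("mean metrics over folds:\n")
  for (nm in names(x$mean)) {
    cat(sprintf("  %-12s %.4f (sd %.4f)\n", nm, x$mean[nm], x$sd[nm]))
  }
  cat("pooled confusion: ",
      paste(names(x$pooled), x$pooled, sep = "=", collapse = " "), "\n")
  invisible(x)
}
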