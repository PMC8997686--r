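#' Z-score normalize a recording
#'
#' Rescales the whole recording to zero mean and unit standard deviation,
#' \eqn{Z = (Q - \mu) / \sigma}. Normalization is applied over the full
#' recording before any segmentation, so every epoch of one subject shares
#' the same scaling.
#'
#' @param record A `bcg_record` or a plain numeric vector.
#' @param type `"sample"` (default, n-1 denominator) or `"population"`
#'   (n denominator) standard deviation.
#' @return The normalized record (same type as the input).
#' @export
zscore_normalize <- function(record, type = c("sample", "population")) {
  type <- match.arg(type)
  if (inherits(record, "bcg_record")) {
    record$samples <- zscore_normalize(record$samples, type)
    return(record)
  }
  x <- as.numeric(record)
  if (length(x) < 2L) stop("need at least 2 samples to normalize", call. = FALSE)
  mu <- mean(x)
  s <- stats::sd(x)
  if (type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  if (!is.finite(s) || s == 0) {
    stop("degenerate signal: zero standard deviation", call. = FALSE)
  }
  (x - mu) / s
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts the recording into consecutive non-overlapping epochs of `epoch_s`
#' seconds. The trailing partial epoch, if any, is discarded.
#'
#' @param record A `bcg_record` (normally after [zscore_normalize()]).
#' @param epoch_s Epoch length in seconds (default 30).
#' @return List of `bcg_epoch` objects (possibly empty), each carrying the
#'   parent `subject_id`, `label`, a 0-based `index`, `fs` and `samples`.
#' @export
segment_epochs <- function(record, epoch_s = 30) {
  stopifnot(inherits(record, "bcg_record"))
  if (epoch_s <= 0) stop("epoch_s must be positive", call. = FALSE)
  len <- round(epoch_s * record$fs)
  n_ep <- floor(length(record$samples) / len)
  if (n_ep == 0L) return(list())
  lapply(seq_len(n_ep) - 1L, function(i) {
    structure(list(subject_id = record$subject_id, label = record$label,
                   index = i, fs = record$fs,
                   samples = record$samples[(i * len + 1L):((i + 1L) * len)]),
              class = "bcg_epoch")
  })
}

#' Assemble a labeled epoch dataset from many recordings
#'
#' Normalizes nothing and filters nothing: it simply segments every recording
#' and tallies epochs by class.
#'
#' @param records List of labeled `bcg_record` objects.
#' @param epoch_s Epoch length in seconds.
#' @return List with `epochs` (flat list of `bcg_epoch`) and `counts`
#'   (named numeric: HC, HPT, total).
#' @export
build_epoch_dataset <- function(records, epoch_s = 30) {
  epochs <- list()
  for (rec in records) {
    if (!inherits(rec, "bcg_record") || is.null(rec$label) ||
        !rec$label %in% c("HC", "HPT")) {
      stop("every record must carry an HC/HPT label", call. = FALSE)
    }
    epochs <- c(epochs, segment_epochs(rec, epoch_s))
  }
  labs <- vapply(epochs, function(e) e$label, character(1))
  counts <- c(HC = sum(labs == "HC"), HPT = sum(labs == "HPT"),
              total = length(labs))
  list(epochs = epochs, counts = counts)
}

#' Write an epoch index CSV
#'
#' One row per epoch: subject, label, epoch index and the 0-based sample
#' offset of the epoch within its recording.
#'
#' @param epochs List of `bcg_epoch`.
#' @param path Output CSV path.
#' @return Invisibly, the index data frame.
#' @export
write_epoch_index <- function(epochs, path) {
  df <- data.frame(
    subject_id = vapply(epochs, function(e) e$subject_id, character(1)),
    label = vapply(epochs, function(e) e$label, character(1)),
    epoch_index = vapply(epochs, function(e) e$index, numeric(1)),
    start_sample = vapply(epochs, function(e) e$index * length(e$samples),
                          numeric(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
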