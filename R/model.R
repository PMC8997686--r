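#' The default 24-layer 2D-CNN architecture
#'
#' Returns the layer stack of the hypertension classifier: eight stride-2
#' convolutions (ReLU, "same" padding), five max-pooling layers of size 1 and
#' stride 1 (spatial identities that are kept as explicit layers), three
#' batch-normalization layers, five dropouts, one flatten and two dense
#' layers, ending in 2 sigmoid units (HC vs HPT). All convolution and dense
#' kernels carry L1 regularization.
#'
#' With a 32 x 32 x 1 input the spatial side after the successive stride-2
#' convolutions is 16, 8, 4, 2, 1, 1, 1, 1.
#'
#' @return Object of class `bcg_modelspec`: `layers` (ordered list of 24
#'   layer specs) and `input_shape` (c(32, 32, 1)).
#' @export
default_modelspec <- function() {
  conv <- function(f, k) list(kind = "conv2d", filters = f, kernel = k,
                              stride = 2L, activation = "relu")
  pool <- function() list(kind = "maxpool2d", pool_size = 1L, stride = 1L)
  bn <- function() list(kind = "batchnorm")
  drop <- function(r) list(kind = "dropout", rate = r)
  layers <- list(
    conv(64, 3), pool(), bn(), drop(0.25),
    conv(64, 5), pool(), bn(), drop(0.25),
    conv(128, 7), bn(), drop(0.25),
    conv(128, 7), pool(), drop(0.25),
    conv(256, 3), conv(256, 3), pool(),
    conv(64, 3), conv(64, 5), pool(),
    list(kind = "flatten"),
    list(kind = "dense", units = 128L, activation = "relu"),
    drop(0.5),
    list(kind = "dense", units = 2L, activation = "sigmoid")
  )
  structure(list(layers = layers, input_shape = c(32L, 32L, 1L)),
            class = "bcg_modelspec")
}

.required_fields <- list(
  conv2d = c("filters", "kernel", "stride", "activation"),
  maxpool2d = c("pool_size", "stride"),
  batchnorm = character(0),
  dropout = "rate",
  flatten = character(0),
  dense = c("units", "activation")
)

#' Validate a model specification
#'
#' Checks per-layer required fields and the global composition contract:
#' exactly 8 conv2d, 5 maxpool2d, 3 batchnorm, 5 dropout, 1 flatten and
#' 2 dense layers (24 in all, the input layer not counted), with the final
#' layer a 2-unit sigmoid dense layer.
#'
#' @param spec A `bcg_modelspec`.
#' @return Invisibly, `spec`; errors name the offending layer.
#' @export
validate_modelspec <- function(spec) {
  stopifnot(inherits(spec, "bcg_modelspec"))
  kinds <- character(length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (is.null(ly$kind) || !ly$kind %in% names(.required_fields)) {
      stop("layer ", i, ": unknown kind", call. = FALSE)
    }
    miss <- setdiff(.required_fields[[ly$kind]], names(ly))
    if (length(miss)) {
      stop("layer ", i, " (", ly$kind, "): missing field(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    kinds[i] <- ly$kind
  }
  want <- c(conv2d = 8L, maxpool2d = 5L, batchnorm = 3L, dropout = 5L,
            flatten = 1L, dense = 2L)
  got <- table(factor(kinds, levels = names(want)))
  if (!all(got == want)) {
    bad <- names(want)[got != want]
    stop("layer composition violated for: ",
         paste(sprintf("%s (%d, expected %d)", bad,
                       got[bad], want[bad]), collapse = "; "),
         call. = FALSE)
  }
  last <- spec$layers[[length(spec$layers)]]
  if (last$kind != "dense" || last$units != 2L ||
      last$activation != "sigmoid") {
    stop("layer ", length(spec$layers),
         ": final layer must be a 2-unit sigmoid dense layer", call. = FALSE)
  }
  invisible(spec)
}

#' Training hyperparameters
#'
#' Defaults: batch size 100, "same" kernel padding, L1 kernel regularization
#' 0.001, Adam with learning rate 0.001 and per-epoch decay 0.01
#' (`lr_t = lr / (1 + decay * t)` with `t` completed epochs), binary
#' cross-entropy loss against one-hot two-vector targets, 50 epochs.
#'
#' @param batch_size Mini-batch size.
#' @param padding Convolution padding mode; only `"same"` is supported.
#' @param l1 L1 kernel regularization weight on conv/dense kernels.
#' @param optimizer Only `"adam"` is supported.
#' @param learning_rate Initial Adam learning rate.
#' @param decay Per-epoch learning-rate decay coefficient.
#' @param loss Only `"binary_crossentropy"` is supported.
#' @param epochs Number of training epochs.
#' @return Object of class `bcg_hyperparams`.
#' @export
bcg_hyperparams <- function(batch_size = 100, padding = "same", l1 = 0.001,
                            optimizer = "adam", learning_rate = 0.001,
                            decay = 0.01, loss = "binary_crossentropy",
                            epochs = 50) {
  stopifnot(batch_size >= 1, l1 >= 0, learning_rate > 0, decay >= 0,
            epochs >= 1)
  padding <- match.arg(padding, "same")
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, "binary_crossentropy")
  structure(list(batch_size = as.integer(batch_size), padding = padding,
                 l1 = l1, optimizer = optimizer,
                 learning_rate = learning_rate, decay = decay, loss = loss,
                 epochs = as.integer(epochs)),
            class = "bcg_hyperparams")
}

glorot_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

# "same" padding geometry for a stride-s, kernel-k convolution
conv_geometry <- function(hi, wi, k, s) {
  ho <- ceiling(hi / s); wo <- ceiling(wi / s)
  pad_h <- max((ho - 1) * s + k - hi, 0)
  pad_w <- max((wo - 1) * s + k - wi, 0)
  list(ho = ho, wo = wo,
       pt = pad_h %/% 2, pl = pad_w %/% 2,
       hp = hi + pad_h, wp = wi + pad_w)
}

#' Instantiate the network
#'
#' Allocates seeded Glorot-uniform weights for every convolution and dense
#' layer, unit/zero batch-norm parameters with running statistics for
#' inference, and the Adam state. The returned handle is trainable with
#' [train_network()] and runnable with [forward()].
#'
#' @param spec A [default_modelspec()]-style `bcg_modelspec`.
#' @param hp A [bcg_hyperparams()] object.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `bcg_cnn`.
#' @export
build_model <- function(spec = default_modelspec(), hp = bcg_hyperparams(),
                        seed = 1L) {
  validate_modelspec(spec)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  shape <- spec$input_shape
  layers <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    st <- ly
    if (ly$kind == "conv2d") {
      ci <- shape[3]; k <- ly$kernel; s <- ly$stride
      g <- conv_geometry(shape[1], shape[2], k, s)
      fan_in <- k * k * ci; fan_out <- k * k * ly$filters
      st$W <- matrix(glorot_uniform(fan_in, fan_out, fan_in * ly$filters),
                     fan_in, ly$filters)
      st$b <- numeric(ly$filters)
      st$geom <- c(g, list(hi = shape[1], wi = shape[2], ci = ci, k = k,
                           s = s))
      shape <- c(g$ho, g$wo, ly$filters)
    } else if (ly$kind == "maxpool2d") {
      p <- ly$pool_size; s <- ly$stride
      ho <- (shape[1] - p) %/% s + 1L
      wo <- (shape[2] - p) %/% s + 1L
      st$geom <- list(hi = shape[1], wi = shape[2], ci = shape[3],
                      ho = ho, wo = wo, p = p, s = s)
      shape <- c(ho, wo, shape[3])
    } else if (ly$kind == "batchnorm") {
      ch <- shape[3]
      st$gamma <- rep(1, ch); st$beta <- numeric(ch)
      st$running_mean <- numeric(ch); st$running_var <- rep(1, ch)
      st$eps <- 1e-3; st$update_rate <- 0.1
      st$channels <- ch
    } else if (ly$kind == "flatten") {
      st$in_shape <- shape
      shape <- c(prod(shape))
    } else if (ly$kind == "dense") {
      d <- shape[1]
      st$W <- matrix(glorot_uniform(d, ly$units, d * ly$units), d, ly$units)
      st$b <- numeric(ly$units)
      shape <- c(ly$units)
    }
    st$out_shape <- shape
    layers[[i]] <- st
  }
  model <- list(spec = spec, hp = hp, layers = layers,
                input_shape = spec$input_shape, seed = as.integer(seed),
                opt = new_adam_state(layers))
  class(model) <- "bcg_cnn"
  model
}

new_adam_state <- function(layers) {
  st <- list(t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-7, slots = list())
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$kind %in% c("conv2d", "dense")) {
      st$slots[[as.character(i)]] <- list(
        W = list(m = ly$W * 0, v = ly$W * 0),
        b = list(m = ly$b * 0, v = ly$b * 0))
    } else if (ly$kind == "batchnorm") {
      st$slots[[as.character(i)]] <- list(
        gamma = list(m = ly$gamma * 0, v = ly$gamma * 0),
        beta = list(m = ly$beta * 0, v = ly$beta * 0))
    }
  }
  st
}

#' Architecture audit of a built network
#'
#' Regenerates a layer-by-layer summary (kind, output shape, parameter count
#' and the structural fields) from the instantiated network, independent of
#' the spec it was built from.
#'
#' @param model A `bcg_cnn`.
#' @return Data frame with one row per layer (input layer not counted).
#' @export
model_summary <- function(model) {
  stopifnot(inherits(model, "bcg_cnn"))
  rows <- lapply(seq_along(model$layers), function(i) {
    ly <- model$layers[[i]]
    n_par <- switch(ly$kind,
      conv2d = , dense = length(ly$W) + length(ly$b),
      batchnorm = 2L * ly$channels,
      0L)
    data.frame(
      layer = i, kind = ly$kind,
      output_shape = paste(ly$out_shape, collapse = "x"),
      params = n_par,
      filters = if (!is.null(ly$filters)) ly$filters else NA_integer_,
      kernel = if (!is.null(ly$kernel)) ly$kernel else NA_integer_,
      stride = if (!is.null(ly$stride)) ly$stride else NA_integer_,
      pool_size = if (!is.null(ly$pool_size)) ly$pool_size else NA_integer_,
      rate = if (!is.null(ly$rate)) ly$rate else NA_real_,
      units = if (!is.null(ly$units)) ly$units else NA_integer_,
      activation = if (!is.null(ly$activation)) ly$activation else NA_character_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.bcg_cnn <- function(x, ...) {
  s <- model_summary(x)
  cat(sprintf("<bcg_cnn> %d layers, %s parameters (seed %d)\n",
              nrow(s), format(sum(s$params), big.mark = ","), x$seed))
  print(s[, c("layer", "kind", "output_shape", "params")], row.names = FALSE)
  invisible(x)
}

#' Serialize a model specification to JSON
#' @param spec A `bcg_modelspec`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
modelspec_to_json <- function(spec, path) {
  validate_modelspec(spec)
  jsonlite::write_json(list(input_shape = spec$input_shape,
                            layers = spec$layers),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model specification from JSON
#' @param path JSON file written by [modelspec_to_json()].
#' @return A validated `bcg_modelspec`.
#' @export
modelspec_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  spec <- structure(list(layers = lapply(j$layers, function(l) {
    for (f in c("filters", "kernel", "stride", "pool_size", "units")) {
      if (!is.null(l[[f]])) l[[f]] <- as.integer(l[[f]])
    }
    l
  }), input_shape = as.integer(unlist(j$input_shape))),
  class = "bcg_modelspec")
  validate_modelspec(spec)
  spec
}

#' Save a trained model (weights + sidecar JSON)
#'
#' Weights go to an RDS checkpoint; a sidecar `<path>.json` records the
#' architecture, hyperparameters and seed.
#'
#' @param model A `bcg_cnn`.
#' @param path Checkpoint path (e.g. `model.rds`).
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "bcg_cnn"))
  saveRDS(model, path)
  jsonlite::write_json(
    list(input_shape = model$input_shape, layers = model$spec$layers,
         hyperparams = unclass(model$hp), seed = model$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path Checkpoint path.
#' @return A `bcg_cnn`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "bcg_cnn"))
  model
}
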