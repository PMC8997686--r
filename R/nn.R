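# Forward/backward engine for the 2D-CNN.
#
# Feature maps are stored as 4-D arrays (H, W, C, N). Convolutions are
# computed by im2col gathers followed by a single BLAS matrix multiply per
# layer; the gather index matrices are precomputed per layer at build time
# and extended to the batch with per-sample offsets.

# im2col gather written as k^2 strided-slice copies: column block
# (kh, kw, 1:ci) of the patch matrix equals the padded input restricted to
# the stride-s grid shifted by (kh, kw), permuted to (ho*wo*n) x ci
conv_im2col <- function(st, p, n) {
  g <- st$geom
  k <- g$k
  rows <- g$ho * g$wo * n
  m <- matrix(0, rows, k * k * g$ci)
  r_base <- (seq_len(g$ho) - 1L) * g$s
  c_base <- (seq_len(g$wo) - 1L) * g$s
  for (kw in seq_len(k)) {
    for (kh in seq_len(k)) {
      blk <- p[r_base + kh, c_base + kw, , , drop = FALSE]  # (ho,wo,ci,n)
      blk <- aperm(blk, c(1, 2, 4, 3))
      dim(blk) <- c(rows, g$ci)
      cols <- (((kw - 1L) * k + kh) - 1L) * g$ci + seq_len(g$ci)
      m[, cols] <- blk
    }
  }
  m
}

conv_forward <- function(st, a, training) {
  g <- st$geom
  n <- dim(a)[4]
  p <- array(0, c(g$hp, g$wp, g$ci, n))
  p[g$pt + seq_len(g$hi), g$pl + seq_len(g$wi), , ] <- a
  m <- conv_im2col(st, p, n)
  z <- m %*% st$W
  z <- z + rep(st$b, each = nrow(z))
  mask <- z > 0
  act <- z * mask                       # ReLU
  dim(act) <- c(g$ho, g$wo, n, st$filters)
  out <- aperm(act, c(1, 2, 4, 3))
  cache <- if (training) list(m = m, mask = mask, n = n) else NULL
  list(out = out, cache = cache)
}

conv_backward <- function(st, d_out, cache, l1) {
  g <- st$geom
  n <- cache$n
  k <- g$k
  dz <- aperm(d_out, c(1, 2, 4, 3))
  dim(dz) <- c(g$ho * g$wo * n, st$filters)
  dz <- dz * cache$mask
  d_w <- crossprod(cache$m, dz)
  if (l1 > 0) d_w <- d_w + l1 * sign(st$W)
  d_b <- colSums(dz)
  dm <- tcrossprod(dz, st$W)
  # scatter-add per kernel offset: the inverse of the strided-slice gather
  dp <- array(0, c(g$hp, g$wp, g$ci, n))
  r_base <- (seq_len(g$ho) - 1L) * g$s
  c_base <- (seq_len(g$wo) - 1L) * g$s
  for (kw in seq_len(k)) {
    for (kh in seq_len(k)) {
      cols <- (((kw - 1L) * k + kh) - 1L) * g$ci + seq_len(g$ci)
      blk <- dm[, cols, drop = FALSE]
      dim(blk) <- c(g$ho, g$wo, n, g$ci)
      dp[r_base + kh, c_base + kw, , ] <-
        dp[r_base + kh, c_base + kw, , , drop = FALSE] +
        aperm(blk, c(1, 2, 4, 3))
    }
  }
  d_a <- dp[g$pt + seq_len(g$hi), g$pl + seq_len(g$wi), , , drop = FALSE]
  list(d_a = d_a, grads = list(W = d_w, b = d_b))
}

pool_forward <- function(st, a, training) {
  g <- st$geom
  if (g$p == 1L && g$s == 1L) {         # spatial identity
    return(list(out = a, cache = if (training) list(identity = TRUE) else NULL))
  }
  n <- dim(a)[4]
  # gather all pool windows: rows enumerate (ho, wo, c, n), cols the window
  oh <- rep(seq_len(g$ho), times = g$wo)
  ow <- rep(seq_len(g$wo), each = g$ho)
  kh <- rep(seq_len(g$p), times = g$p)
  kw <- rep(seq_len(g$p), each = g$p)
  r <- outer((oh - 1) * g$s, kh, "+")
  cc <- outer((ow - 1) * g$s, kw, "+")
  base <- r + (cc - 1) * g$hi           # (ho*wo) x p^2, one channel plane
  nr <- nrow(base)
  plane <- g$hi * g$wi
  offs <- rep((seq_len(g$ci * n) - 1) * plane, each = nr)
  idx <- base[rep(seq_len(nr), times = g$ci * n), , drop = FALSE] + offs
  m <- a[idx]
  dim(m) <- dim(idx)
  which_mx <- max.col(m, ties.method = "first")
  out <- m[cbind(seq_len(nrow(m)), which_mx)]
  dim(out) <- c(g$ho, g$wo, g$ci, n)
  cache <- if (training) {
    list(identity = FALSE, idx = idx, which_mx = which_mx, n = n,
         in_dim = dim(a))
  } else NULL
  list(out = out, cache = cache)
}

pool_backward <- function(st, d_out, cache) {
  if (isTRUE(cache$identity)) return(list(d_a = d_out))
  d_a <- numeric(prod(cache$in_dim))
  sel <- cache$idx[cbind(seq_len(nrow(cache$idx)), cache$which_mx)]
  dv <- as.vector(d_out)
  # max positions can repeat across overlapping windows; accumulate
  acc <- rowsum(dv, sel)
  d_a[as.numeric(rownames(acc))] <- acc[, 1]
  dim(d_a) <- cache$in_dim
  list(d_a = d_a)
}

bn_reshape <- function(a) {
  d <- dim(a)
  x <- aperm(a, c(1, 2, 4, 3))
  dim(x) <- c(d[1] * d[2] * d[4], d[3])
  x
}
bn_unshape <- function(x, d) {
  dim(x) <- c(d[1], d[2], d[4], d[3])
  aperm(x, c(1, 2, 4, 3))
}

batchnorm_forward <- function(st, a, training) {
  d <- dim(a)
  x <- bn_reshape(a)
  m <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    va <- colMeans(x^2) - mu^2          # biased batch variance
    st$running_mean <- (1 - st$update_rate) * st$running_mean +
      st$update_rate * mu
    st$running_var <- (1 - st$update_rate) * st$running_var +
      st$update_rate * va
  } else {
    mu <- st$running_mean
    va <- st$running_var
  }
  inv_std <- 1 / sqrt(va + st$eps)
  xhat <- (x - rep(mu, each = m)) * rep(inv_std, each = m)
  y <- xhat * rep(st$gamma, each = m) + rep(st$beta, each = m)
  cache <- if (training) list(xhat = xhat, inv_std = inv_std, d = d) else NULL
  list(out = bn_unshape(y, d), cache = cache, st = st)
}

batchnorm_backward <- function(st, d_out, cache) {
  dy <- bn_reshape(d_out)
  m <- nrow(dy)
  xhat <- cache$xhat
  d_gamma <- colSums(dy * xhat)
  d_beta <- colSums(dy)
  dxhat <- dy * rep(st$gamma, each = m)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- (rep(cache$inv_std, each = m) / m) *
    (m * dxhat - rep(s1, each = m) - xhat * rep(s2, each = m))
  list(d_a = bn_unshape(dx, cache$d), grads = list(gamma = d_gamma,
                                                   beta = d_beta))
}

dropout_forward <- function(st, a, training) {
  if (!training || st$rate <= 0) {
    return(list(out = a, cache = NULL))
  }
  keep <- 1 - st$rate
  mask <- (stats::runif(length(a)) < keep) / keep
  dim(mask) <- dim(a)
  list(out = a * mask, cache = list(mask = mask))
}

dense_forward <- function(st, x, training, final_layer) {
  z <- x %*% st$W
  z <- z + rep(st$b, each = nrow(z))
  if (identical(st$activation, "relu")) {
    mask <- z > 0
    out <- z * mask
  } else if (identical(st$activation, "sigmoid")) {
    mask <- NULL
    out <- 1 / (1 + exp(-z))
  } else {
    mask <- NULL
    out <- z
  }
  cache <- if (training) list(x = x, mask = mask, out = out) else NULL
  list(out = out, cache = cache)
}

dense_backward <- function(st, d_out, cache, l1, d_is_dz = FALSE) {
  dz <- d_out
  if (!d_is_dz) {
    if (identical(st$activation, "relu")) {
      dz <- d_out * cache$mask
    } else if (identical(st$activation, "sigmoid")) {
      dz <- d_out * cache$out * (1 - cache$out)
    }
  }
  d_w <- crossprod(cache$x, dz)
  if (l1 > 0) d_w <- d_w + l1 * sign(st$W)
  d_b <- colSums(dz)
  d_x <- tcrossprod(dz, st$W)
  list(d_a = d_x, grads = list(W = d_w, b = d_b))
}

# full forward pass; input a: (H, W, C, N) array; returns scores and caches
forward_pass <- function(model, a, training = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    st <- model$layers[[i]]
    r <- switch(st$kind,
      conv2d = conv_forward(st, a, training),
      maxpool2d = pool_forward(st, a, training),
      batchnorm = {
        rr <- batchnorm_forward(st, a, training)
        if (training) model$layers[[i]] <- rr$st
        rr
      },
      dropout = dropout_forward(st, a, training),
      flatten = {
        d <- dim(a)
        x <- a
        dim(x) <- c(prod(d[1:3]), d[4])
        list(out = t(x), cache = if (training) list(d = d) else NULL)
      },
      dense = dense_forward(st, a, training, i == length(model$layers))
    )
    a <- r$out
    caches[[i]] <- r$cache
  }
  list(scores = a, caches = caches, model = model)
}

# backward pass from the loss gradient wrt the final pre-sigmoid logits
backward_pass <- function(model, caches, d_logits) {
  l1 <- model$hp$l1
  grads <- vector("list", length(model$layers))
  d <- d_logits
  first_from_top <- TRUE
  for (i in rev(seq_along(model$layers))) {
    st <- model$layers[[i]]
    if (st$kind == "conv2d") {
      r <- conv_backward(st, d, caches[[i]], l1)
      d <- r$d_a; grads[[i]] <- r$grads
    } else if (st$kind == "maxpool2d") {
      d <- pool_backward(st, d, caches[[i]])$d_a
    } else if (st$kind == "batchnorm") {
      r <- batchnorm_backward(st, d, caches[[i]])
      d <- r$d_a; grads[[i]] <- r$grads
    } else if (st$kind == "dropout") {
      if (!is.null(caches[[i]])) d <- d * caches[[i]]$mask
    } else if (st$kind == "flatten") {
      d <- t(d)
      dim(d) <- caches[[i]]$d
    } else if (st$kind == "dense") {
      r <- dense_backward(st, d, caches[[i]], l1,
                          d_is_dz = first_from_top)
      d <- r$d_a; grads[[i]] <- r$grads
    }
    if (st$kind %in% c("conv2d", "dense")) first_from_top <- FALSE
  }
  grads
}

# binary cross-entropy against one-hot targets; returns loss (data + L1
# penalty) and the gradient wrt the final logits
bce_loss <- function(scores, y_onehot, model) {
  eps <- 1e-7
  p <- pmin(pmax(scores, eps), 1 - eps)
  data_loss <- -mean(y_onehot * log(p) + (1 - y_onehot) * log(1 - p))
  reg <- 0
  if (model$hp$l1 > 0) {
    for (st in model$layers) {
      if (st$kind %in% c("conv2d", "dense")) reg <- reg + sum(abs(st$W))
    }
    reg <- model$hp$l1 * reg
  }
  d_logits <- (scores - y_onehot) / length(y_onehot)
  list(loss = data_loss + reg, data_loss = data_loss, d_logits = d_logits)
}

adam_step <- function(model, grads, lr) {
  opt <- model$opt
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    key <- as.character(i)
    for (nm in names(g)) {
      slot <- opt$slots[[key]][[nm]]
      slot$m <- opt$beta1 * slot$m + (1 - opt$beta1) * g[[nm]]
      slot$v <- opt$beta2 * slot$v + (1 - opt$beta2) * g[[nm]]^2
      opt$slots[[key]][[nm]] <- slot
      model$layers[[i]][[nm]] <- model$layers[[i]][[nm]] -
        lr * (slot$m / bc1) / (sqrt(slot$v / bc2) + opt$eps)
    }
  }
  model$opt <- opt
  model
}

# Re-estimate batch-norm statistics under the final weights: one pass over
# the training inputs, replacing each BN layer's running moments with the
# dataset moments of its input activations (computed with all earlier BN
# layers already re-estimated). Removes the train/inference gap left by
# running averages taken while the weights were still moving.
finalize_batchnorm <- function(model, a) {
  for (i in seq_along(model$layers)) {
    st <- model$layers[[i]]
    if (st$kind == "batchnorm") {
      x <- bn_reshape(a)
      mu <- colMeans(x)
      model$layers[[i]]$running_mean <- mu
      model$layers[[i]]$running_var <- colMeans(x^2) - mu^2
      st <- model$layers[[i]]
    }
    a <- switch(st$kind,
      conv2d = conv_forward(st, a, FALSE)$out,
      maxpool2d = pool_forward(st, a, FALSE)$out,
      batchnorm = batchnorm_forward(st, a, FALSE)$out,
      dropout = a,
      flatten = {
        d <- dim(a)
        dim(a) <- c(prod(d[1:3]), d[4])
        t(a)
      },
      dense = dense_forward(st, a, FALSE, FALSE)$out)
  }
  model
}

# coerce input to (H, W, C, N): accepts an N x (H*W*C) matrix of pixel
# values in [0, 255] (scaled to [0, 1]) or a ready-made 4-D array in [0, 1]
as_input_array <- function(model, x) {
  s <- model$input_shape
  if (is.matrix(x)) {
    if (ncol(x) != prod(s)) {
      stop("input images must have ", prod(s), " pixels, got ", ncol(x),
           call. = FALSE)
    }
    a <- t(x) / 255
    dim(a) <- c(s, nrow(x))
    a
  } else if (is.array(x) && length(dim(x)) == 4L &&
             all(dim(x)[1:3] == s)) {
    x
  } else {
    stop("input must be an N x ", prod(s), " matrix or a ",
         paste(s, collapse = "x"), " x N array", call. = FALSE)
  }
}

#' Run the network forward in inference mode
#'
#' Batch-norm layers use their running statistics and dropout is disabled;
#' two calls with the same weights and input return identical scores.
#'
#' @param model A `bcg_cnn`.
#' @param x N x 1024 matrix of 32 x 32 grayscale images (pixel values
#'   0-255, scaled to [0, 1] internally), or a (32, 32, 1, N) array already
#'   in [0, 1].
#' @param batch Maximum samples per internal forward chunk.
#' @return N x 2 matrix of per-class scores in [0, 1]; columns `HC`, `HPT`.
#' @export
forward <- function(model, x, batch = 256L) {
  stopifnot(inherits(model, "bcg_cnn"))
  a <- as_input_array(model, x)
  n <- dim(a)[4]
  scores <- matrix(NA_real_, n, 2,
                   dimnames = list(NULL, c("HC", "HPT")))
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    scores[i:j, ] <- forward_pass(model, a[, , , i:j, drop = FALSE],
                                  training = FALSE)$scores
    i <- j + 1L
  }
  scores
}

labels_to_onehot <- function(y) {
  y <- as.character(y)
  if (!all(y %in% c("HC", "HPT"))) {
    stop("labels must be 'HC' or 'HPT'", call. = FALSE)
  }
  cbind(HC = as.numeric(y == "HC"), HPT = as.numeric(y == "HPT"))
}

scores_to_labels <- function(scores) {
  # ties (exactly equal scores) resolve to HC, the negative class
  c("HC", "HPT")[max.col(scores, ties.method = "first")]
}

#' Train the network
#'
#' Mini-batch gradient descent with Adam, per-epoch shuffling from a single
#' seeded stream, L1 kernel regularization, and the learning-rate schedule
#' `lr_t = lr / (1 + decay * t)` with `t` the number of completed epochs.
#' The reported training loss/accuracy are running averages over the epoch's
#' mini-batches (loss includes the L1 penalty); validation metrics are
#' computed in inference mode after each epoch.
#'
#' @param model A freshly built (or partially trained) `bcg_cnn`.
#' @param x_train,y_train Training images (N x 1024 matrix, 0-255) and
#'   HC/HPT labels.
#' @param x_val,y_val Optional validation set.
#' @param epochs Number of epochs (defaults to the model's hyperparameters).
#' @param seed Seed for shuffling and dropout.
#' @param verbose Print one line per epoch.
#' @return List with `model` (final-epoch weights) and `history` (one row
#'   per epoch: loss, accuracy, val_loss, val_accuracy).
#' @export
train_network <- function(model, x_train, y_train, x_val = NULL,
                          y_val = NULL, epochs = model$hp$epochs,
                          seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "bcg_cnn"))
  n <- if (is.matrix(x_train)) nrow(x_train) else dim(x_train)[4]
  if (n == 0L) stop("empty training set", call. = FALSE)
  if (n != length(y_train)) stop("x/y length mismatch", call. = FALSE)
  a_all <- as_input_array(model, x_train)
  y_oh <- labels_to_onehot(y_train)
  hp <- model$hp
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  hist <- vector("list", epochs)
  for (e in seq_len(epochs)) {
    lr_e <- hp$learning_rate / (1 + hp$decay * (e - 1))
    perm <- sample.int(n)
    ep_loss <- 0; ep_data_loss <- 0; ep_correct <- 0
    i <- 1L
    while (i <= n) {
      j <- min(i + hp$batch_size - 1L, n)
      sel <- perm[i:j]
      a <- a_all[, , , sel, drop = FALSE]
      yb <- y_oh[sel, , drop = FALSE]
      fp <- forward_pass(model, a, training = TRUE)
      model <- fp$model                  # batch-norm running stats
      ls <- bce_loss(fp$scores, yb, model)
      grads <- backward_pass(model, fp$caches, ls$d_logits)
      model <- adam_step(model, grads, lr_e)
      ep_loss <- ep_loss + ls$loss * length(sel)
      ep_data_loss <- ep_data_loss + ls$data_loss * length(sel)
      pred <- max.col(fp$scores, ties.method = "first")
      ep_correct <- ep_correct + sum(pred == max.col(yb))
      i <- j + 1L
    }
    if (e == epochs) {
      # final pass: set BN statistics to the training-set moments under the
      # final weights before any inference-mode evaluation (a deterministic
      # subset bounds memory; spatial positions multiply the sample count)
      sel <- seq_len(min(n, 512L))
      model <- finalize_batchnorm(model, a_all[, , , sel, drop = FALSE])
    }
    row <- data.frame(epoch = e, loss = ep_loss / n,
                      data_loss = ep_data_loss / n,
                      accuracy = ep_correct / n,
                      val_loss = NA_real_, val_accuracy = NA_real_)
    if (!is.null(x_val) && length(y_val)) {
      vs <- forward(model, x_val)
      vl <- bce_loss(vs, labels_to_onehot(y_val), model)
      row$val_loss <- vl$loss
      row$val_accuracy <- mean(scores_to_labels(vs) == as.character(y_val))
    }
    hist[[e]] <- row
    if (verbose) {
      message(sprintf(
        "epoch %3d/%d  loss %.4f  acc %.4f  val_loss %s  val_acc %s",
        e, epochs, row$loss, row$accuracy,
        ifelse(is.na(row$val_loss), "-", sprintf("%.4f", row$val_loss)),
        ifelse(is.na(row$val_accuracy), "-",
               sprintf("%.4f", row$val_accuracy))))
    }
  }
  list(model = model, history = do.call(rbind, hist))
}
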