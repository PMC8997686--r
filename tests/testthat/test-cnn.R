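test_that("the default architecture has the canonical 24-layer composition", {
  spec <- default_modelspec()
  expect_length(spec$layers, 24L)
  kinds <- vapply(spec$layers, function(l) l$kind, character(1))
  expect_equal(sum(kinds == "conv2d"), 8L)
  expect_equal(sum(kinds == "maxpool2d"), 5L)
  expect_equal(sum(kinds == "batchnorm"), 3L)
  expect_equal(sum(kinds == "dropout"), 5L)
  expect_equal(sum(kinds == "flatten"), 1L)
  expect_equal(sum(kinds == "dense"), 2L)
  last <- spec$layers[[24]]
  expect_equal(last$units, 2L)
  expect_equal(last$activation, "sigmoid")
  expect_equal(spec$input_shape, c(32L, 32L, 1L))
})

test_that("structural violations are rejected with the offending layer named", {
  spec <- default_modelspec()
  spec$layers[[1]] <- NULL                # 7 convs left
  expect_error(validate_modelspec(spec), "conv2d")
  spec2 <- default_modelspec()
  spec2$layers[[5]]$filters <- NULL
  expect_error(validate_modelspec(spec2), "layer 5")
  spec3 <- default_modelspec()
  spec3$layers[[24]]$units <- 3L
  expect_error(validate_modelspec(spec3), "final layer")
  expect_error(build_model(spec3), "final layer")
})

test_that("stride-2 convolutions halve the spatial side down to 1", {
  m <- build_model(seed = 1)
  s <- model_summary(m)
  conv_sides <- as.integer(sub("x.*", "", s$output_shape[s$kind == "conv2d"]))
  expect_equal(conv_sides, c(16L, 8L, 4L, 2L, 1L, 1L, 1L, 1L))
  # size-1 stride-1 pools preserve the spatial size
  for (i in which(s$kind == "maxpool2d")) {
    expect_equal(s$output_shape[i], s$output_shape[i - 1])
  }
})

test_that("weight initialization is fully seed-determined", {
  m1 <- build_model(seed = 7)
  m2 <- build_model(seed = 7)
  m3 <- build_model(seed = 8)
  w <- function(m) unlist(lapply(m$layers, function(l) l$W))
  expect_identical(w(m1), w(m2))
  expect_false(identical(w(m1), w(m3)))
})

test_that("inference scores are sigmoid-bounded, shaped and deterministic", {
  m <- build_model(seed = 2)
  withr::with_seed(1, x <- matrix(runif(5 * 1024) * 255, 5))
  s1 <- forward(m, x)
  expect_equal(dim(s1), c(5L, 2L))
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_identical(s1, forward(m, x))
  expect_error(forward(m, matrix(0, 2, 100)), "1024")
})

test_that("model specs survive a JSON round trip", {
  path <- withr::local_tempfile(fileext = ".json")
  modelspec_to_json(default_modelspec(), path)
  back <- modelspec_from_json(path)
  expect_equal(back, default_modelspec())
})

test_that("analytic gradients match finite differences", {
  hp <- bcg_hyperparams(l1 = 0.001)
  m <- build_model(hp = hp, seed = 3)
  # dropout off so the loss surface is deterministic
  for (i in seq_along(m$layers)) {
    if (m$layers[[i]]$kind == "dropout") m$layers[[i]]$rate <- 0
  }
  withr::with_seed(2, x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2)))
  y <- rbind(c(1, 0), c(0, 1))
  lossfn <- function(model) {
    fp <- bcgnet:::forward_pass(model, x, training = TRUE)
    bcgnet:::bce_loss(fp$scores, y, model)$loss
  }
  fp <- bcgnet:::forward_pass(m, x, training = TRUE)
  ls <- bcgnet:::bce_loss(fp$scores, y, m)
  gr <- bcgnet:::backward_pass(m, fp$caches, ls$d_logits)
  eps <- 1e-5
  withr::with_seed(99, {
    for (i in seq_along(m$layers)) {
      if (is.null(gr[[i]])) next
      nm <- names(gr[[i]])[1]             # kernel (or gamma) per layer
      j <- sample(length(m$layers[[i]][[nm]]), 1)
      # avoid the L1 kink at near-zero weights
      if (abs(m$layers[[i]][[nm]][j]) < 10 * eps) {
        m$layers[[i]][[nm]][j] <- m$layers[[i]][[nm]][j] + 20 * eps
        fp <- bcgnet:::forward_pass(m, x, training = TRUE)
        ls <- bcgnet:::bce_loss(fp$scores, y, m)
        gr <- bcgnet:::backward_pass(m, fp$caches, ls$d_logits)
      }
      m2 <- m; m2$layers[[i]][[nm]][j] <- m2$layers[[i]][[nm]][j] + eps
      m3 <- m; m3$layers[[i]][[nm]][j] <- m3$layers[[i]][[nm]][j] - eps
      fd <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
      an <- gr[[i]][[nm]][j]
      expect_equal(an, fd, tolerance = 5e-3,
                   label = sprintf("layer %d %s gradient", i, nm))
    }
  })
})

test_that("every trainable tensor receives gradient on a random batch", {
  m <- build_model(seed = 4)
  withr::with_seed(5, {
    x <- array(runif(32 * 32 * 8), c(32, 32, 1, 8))
    y <- bcgnet:::labels_to_onehot(rep(c("HC", "HPT"), 4))
    set.seed(6)                           # dropout stream
    fp <- bcgnet:::forward_pass(m, x, training = TRUE)
    ls <- bcgnet:::bce_loss(fp$scores, y, m)
    gr <- bcgnet:::backward_pass(m, fp$caches, ls$d_logits)
  })
  for (i in seq_along(m$layers)) {
    kind <- m$layers[[i]]$kind
    if (kind %in% c("conv2d", "dense")) {
      expect_gt(sum(gr[[i]]$W != 0), 0, label = sprintf("layer %d W", i))
      expect_gt(sum(gr[[i]]$b != 0), 0, label = sprintf("layer %d b", i))
    } else if (kind == "batchnorm") {
      expect_gt(sum(gr[[i]]$gamma != 0), 0, label = sprintf("layer %d gamma", i))
      expect_gt(sum(gr[[i]]$beta != 0), 0, label = sprintf("layer %d beta", i))
    }
  }
})

test_that("the network can memorize a small labeled batch", {
  toy <- toy_images(10, seed = 12)
  # L1 off: with 20 samples the constant penalty subgradient dominates the
  # data gradient under Adam, so memorization capacity is tested unpenalized
  m <- build_model(hp = bcg_hyperparams(batch_size = 20, l1 = 0), seed = 5)
  fit <- train_network(m, toy$images, toy$labels, epochs = 120, seed = 5)
  # cross-entropy on the training images after 120 gradient steps
  sc <- forward(fit$model, toy$images)
  y <- bcgnet:::labels_to_onehot(toy$labels)
  p <- pmin(pmax(sc, 1e-7), 1 - 1e-7)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_lt(bce, 0.1)
})

test_that("saved models reload with identical behavior", {
  m <- build_model(seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  withr::with_seed(3, x <- matrix(runif(3 * 1024) * 255, 3))
  expect_identical(forward(m, x), forward(m2, x))
})
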