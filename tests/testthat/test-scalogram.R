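test_that("Morse response peaks at the closed-form frequency with value 2", {
  p <- morse_params(3, 60, 12)
  expect_equal(p$beta, 20)
  wp <- (20 / 3)^(1 / 3)
  expect_equal(p$omega_p, wp, tolerance = 1e-12)
  expect_equal(morse_psi(wp, p), 2, tolerance = 1e-12)
  # global max on a fine grid is at omega_p
  om <- seq(0.01, 10, by = 0.001)
  v <- morse_psi(om, p)
  expect_equal(om[which.max(v)], wp, tolerance = 1e-3)
  expect_true(all(v >= 0))
  expect_identical(morse_psi(c(-1, 0), p), c(0, 0))
  expect_error(morse_params(gamma = 0), "gamma")
  expect_error(morse_params(p2 = 2), "exceed gamma")
})

test_that("filter bank has geometric spacing, 80 scales, analytic filters", {
  bank <- build_filterbank(100, 3000, morse_params(), fmin = 0.5, fmax = 50)
  expect_equal(nrow(bank$filters), 80L)
  ratios <- bank$center_freqs[-length(bank$center_freqs)] /
    bank$center_freqs[-1]
  expect_equal(ratios, rep(2^(1 / 12), 79), tolerance = 1e-12)
  expect_equal(bank$center_freqs[1], 50)
  expect_gte(min(bank$center_freqs), 0.5)
  # analytic: zero response at zero and negative FFT frequencies
  k <- 0:2999
  fgrid <- ifelse(k <= 1500, k, k - 3000) * 100 / 3000
  expect_true(all(bank$filters[, fgrid <= 0] == 0))
  expect_error(build_filterbank(100, 3000, fmin = 5, fmax = 5), "fmin")
  expect_error(build_filterbank(100, 3000, fmin = 1, fmax = 60), "Nyquist")
})

test_that("CWT is linear and rejects length mismatches", {
  bank <- build_filterbank(100, 3000)
  expect_equal(cwt_epoch(numeric(3000), bank)$magnitude,
               matrix(0, 80, 3000))
  withr::with_seed(8, x <- rnorm(3000))
  s1 <- cwt_epoch(x, bank)$magnitude
  s2 <- cwt_epoch(2 * x, bank)$magnitude
  expect_equal(s2, 2 * s1, tolerance = 1e-9)
  expect_error(cwt_epoch(rnorm(100), bank), "length")
})

test_that("a 5 Hz tone's ridge lands within one voice of 5 Hz", {
  bank <- build_filterbank(100, 3000)
  t <- (0:2999) / 100
  sc <- cwt_epoch(sin(2 * pi * 5 * t), bank)
  central <- 751:2250                      # central 50% of samples
  ridge <- which.max(rowMeans(sc$magnitude[, central]))
  expect_lte(bank$center_freqs[ridge] / 5, 2^(1 / 12) + 1e-9)
  expect_gte(bank$center_freqs[ridge] / 5, 2^(-1 / 12) - 1e-9)
})

test_that("chirp ridge frequency is monotone in time", {
  bank <- build_filterbank(100, 3000)
  t <- (0:2999) / 100
  x <- sin(2 * pi * (2 * t + (10 - 2) / (2 * 30) * t^2))  # 2 -> 10 Hz
  sc <- cwt_epoch(x, bank)
  probes <- round(seq(450, 2550, length.out = 8))
  ridge_f <- vapply(probes, function(j) {
    bank$center_freqs[which.max(sc$magnitude[, j])]
  }, numeric(1))
  expect_true(all(diff(ridge_f) > 0))
})

test_that("FFT CWT agrees with the brute-force time-domain oracle", {
  # mid-band scales of a short signal, away from Nyquist and record-length
  # effects where the two constructions are both well conditioned
  bank <- build_filterbank(100, 256, fmin = 4, fmax = 20)
  withr::with_seed(11, {
    x <- sin(2 * pi * 8 * (0:255) / 100) + 0.5 * rnorm(256)
  })
  impl <- cwt_epoch(x, bank)$magnitude
  oracle <- cwt_oracle(x, bank)
  margin <- 27:230                        # exclude 10% boundary margins
  rel <- abs(impl[, margin] - oracle[, margin]) / max(oracle)
  expect_lt(max(rel), 1e-6)
})

test_that("rendering obeys size, min-max and fallback conventions", {
  bank <- build_filterbank(100, 3000)
  withr::with_seed(3, x <- rnorm(3000))
  sc <- cwt_epoch(x, bank)
  img <- render_scalogram(sc, 224)
  expect_equal(dim(img$pixels), c(224L, 224L))
  expect_equal(max(img$pixels), 255)
  expect_gte(min(img$pixels), 0)
  # constant magnitude maps to an all-zero image
  const <- structure(list(magnitude = matrix(3, 10, 40),
                          center_freqs = seq(50, 1, length.out = 10),
                          times = (0:39) / 100, fs = 100),
                     class = "bcg_scalogram")
  expect_true(all(render_scalogram(const, 32)$pixels == 0))
  # energy confined to the highest-frequency row stays at the image top
  topheavy <- const
  topheavy$magnitude <- matrix(0, 10, 40); topheavy$magnitude[1, ] <- 5
  px <- render_scalogram(topheavy, 32)$pixels
  expect_gt(mean(px[1:3, ]), mean(px[20:32, ]))
})

test_that("resizing is bilinear, identity-stable and constant-preserving", {
  bank <- build_filterbank(100, 3000)
  withr::with_seed(3, sc <- cwt_epoch(rnorm(3000), bank))
  big <- render_scalogram(sc, 224)
  small <- resize_image(big, 32)
  expect_equal(dim(small$pixels), c(32L, 32L))
  expect_identical(resize_image(small, 32), small)
  flat <- structure(list(pixels = matrix(17, 64, 64), side = 64L),
                    class = "bcg_scalogram_image")
  expect_true(all(resize_image(flat, 16)$pixels == 17))
  expect_error(resize_image(big, 0), "side")
})

test_that("identical epochs give byte-identical PNG files", {
  bank <- build_filterbank(100, 3000)
  withr::with_seed(5, x <- rnorm(3000))
  img <- resize_image(render_scalogram(cwt_epoch(x, bank), 224), 32)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  write_scalogram_png(img, f1)
  write_scalogram_png(resize_image(render_scalogram(cwt_epoch(x, bank), 224), 32), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("the jet-luminance rendering path stays in range", {
  bank <- build_filterbank(100, 3000)
  withr::with_seed(6, sc <- cwt_epoch(rnorm(3000), bank))
  img <- render_scalogram(sc, 64, colormap = "jet")
  expect_true(all(img$pixels >= 0 & img$pixels <= 255))
  expect_equal(dim(img$pixels), c(64L, 64L))
})
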