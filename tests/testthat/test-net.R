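test_that("min-max normalization maps signals onto [0, 1.1] as specified", {
  f <- normalize_inputs(c(-1, 0, 0.5, 1), c(100, 1100, 2100, 3100),
                        norm_spec("minmax"))
  expect_equal(f[1:4], c(0, 0.55, 0.825, 1.1))
  expect_equal(f[5:8], c(0.1, 1.1, 2.1, 3.1))
  expect_error(normalize_inputs(rep(2, 4), c(1, 2, 3, 4), norm_spec("minmax")),
               "constant signal")
})

test_that("normalization is invariant to global positive rescaling", {
  s <- c(-0.9, 0.1, 0.6, 0.95); tis <- c(100, 1100, 2100, 3100)
  for (mode in c("minmax", "scale_max")) {
    n1 <- normalize_inputs(s, tis, norm_spec(mode))
    n10 <- normalize_inputs(10 * s, tis, norm_spec(mode))
    expect_equal(n1, n10)
  }
  # scale_max keeps the B/A shape information: signed values span [-1.1, 1.1]
  f <- normalize_inputs(s, tis, norm_spec("scale_max"))
  expect_equal(f[4], 1.1 * 0.95 / 0.95)
  expect_equal(f[1], 1.1 * -0.9 / 0.95)
})

test_that("estimator architecture follows the selected configuration", {
  m <- t1net_build(4, seed = 1)
  dims <- sapply(m$weights, dim)
  expect_equal(dims[1, ], c(8, 400, 400, 200, 200, 100))
  expect_equal(dims[2, ], c(400, 400, 200, 200, 100, 1))

  m5 <- t1net_build(5, seed = 1)
  expect_equal(dim(m5$weights[[1]])[1], 10)

  m2 <- t1net_build(4, seed = 1)
  expect_identical(m$weights, m2$weights)
  m3 <- t1net_build(4, seed = 2)
  expect_false(identical(m$weights, m3$weights))

  expect_error(t1net_build(3), "4 or 5")
  expect_error(t1net_build(4, hidden = integer(0)), "at least one layer")
})

test_that("training on noiseless pixels recovers T1 to tens of ms", {
  tr <- simulate_pixels(5000, snr = Inf, seed = 101)
  va <- simulate_pixels(1000, snr = Inf, seed = 102)
  m <- t1net(tr, va, hidden = c(64, 32), max_epochs = 30, seed = 103)
  held <- simulate_pixels(2000, snr = Inf, seed = 104)
  mae <- mean(abs(predict(m, held) - held$t1_true))
  expect_lt(mae, 50)
})

test_that("training is deterministic given identical seeds and configs", {
  tr <- simulate_pixels(800, snr = 50, seed = 111)
  va <- simulate_pixels(200, snr = 50, seed = 112)
  m1 <- t1net(tr, va, hidden = c(16, 8), max_epochs = 3, seed = 9)
  m2 <- t1net(tr, va, hidden = c(16, 8), max_epochs = 3, seed = 9)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
})

test_that("early stopping halts exactly patience epochs after the best epoch", {
  tr <- simulate_pixels(256, snr = 50, seed = 121)
  va <- simulate_pixels(64, snr = 50, seed = 122)
  # zero learning rate freezes the weights, so the validation metric can
  # never improve after the first epoch
  m <- t1net(tr, va, hidden = c(8), lr = 0, max_epochs = 500, patience = 70,
             seed = 123)
  expect_identical(m$best_epoch, 1L)
  expect_identical(m$epochs_run, 71L)
  expect_equal(length(unique(m$history$val_mae)), 1L)
})

test_that("the reported best epoch attains the minimum validation MAE", {
  m <- small_trained_net()
  expect_identical(which.min(m$history$val_mae), as.integer(m$best_epoch))
  expect_equal(min(m$history$val_mae), m$best_val_mae)
  # per-range validation errors are tracked every epoch
  expect_true(all(c("val_mae_myocardium", "val_mae_blood") %in%
                  names(m$history)))
})

test_that("predictions clamp negative outputs and flag the count", {
  m <- t1net_build(4, hidden = c(8), seed = 5)
  m$biases[[2]] <- -1e6   # force negative outputs
  d <- simulate_pixels(20, snr = Inf, seed = 131)
  p <- predict(m, d)
  expect_true(all(p == 0))
  expect_identical(attr(p, "n_clamped"), 20L)
})

test_that("map prediction respects the mask and input scale", {
  m <- small_trained_net()
  cs <- simulate_cardiac(native = TRUE, snr = 100, seed = 141)
  mask <- cs$myocardium | cs$blood
  map <- predict_map(m, cs$stack, cs$timing, mask = mask)
  expect_true(all(is.na(map[!mask])))
  expect_true(all(is.finite(map[mask])))

  map_scaled <- predict_map(m, cs$stack * 3.7, cs$timing, mask = mask)
  expect_identical(unclass(map), unclass(map_scaled))

  expect_error(predict_map(m, cs$stack[, , 1:3], cs$timing), "needs 4")
})

test_that("checkpoints round-trip bit-for-bit and reject tampering", {
  m <- small_trained_net()
  path <- tempfile(fileext = ".t1net")
  save_t1net(m, path)
  m2 <- load_t1net(path)
  d <- simulate_pixels(100, snr = 50, seed = 151)
  expect_identical(as.numeric(predict(m, d)), as.numeric(predict(m2, d)))
  expect_equal(m2$config$hidden, m$config$hidden)
  expect_equal(m2$norm$signal_mode, m$norm$signal_mode)

  # tamper with the declared layer count in the JSON header
  raw <- readBin(path, "raw", file.info(path)$size)
  nl <- which(raw == as.raw(10L))[1]
  hdr <- jsonlite::fromJSON(rawToChar(raw[1:(nl - 1)]))
  hdr$n_layers <- hdr$n_layers - 1L
  bad <- tempfile(fileext = ".t1net")
  con <- file(bad, "wb")
  writeBin(charToRaw(paste0(jsonlite::toJSON(hdr, auto_unbox = TRUE,
                                             digits = NA), "\n")), con)
  writeBin(raw[(nl + 1):length(raw)], con)
  close(con)
  expect_error(load_t1net(bad), "layer")

  # a 4-input checkpoint is refused by a pipeline feeding fewer samples
  short <- pixel_matrices(d)
  short$signals <- short$signals[, 1:3]; short$tis_ms <- short$tis_ms[, 1:3]
  expect_error(predict(m2, short), "expects 4")
  unlink(c(path, bad))
})
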