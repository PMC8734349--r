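test_that("noiseless signed fit recovers the generating parameters", {
  tis <- c(100, 1000, 1900, 2800)
  s <- ir_signal(tis, a = 1, b = 1.9, t1_star_ms = 900)
  f <- ir_fit(s, tis)
  expect_true(f$converged)
  expect_equal(f$t1_ms, 810, tolerance = 0.1 / 810)
  expect_lt(f$residual_rms, 1e-6)
  expect_identical(f$polarity_flips, 0L)
})

test_that("magnitude fit with polarity restoration matches the signed fit", {
  tis <- c(100, 1000, 1900, 2800)
  s <- ir_signal(tis, a = 1, b = 1.9, t1_star_ms = 900)
  f <- ir_fit(abs(s), tis, magnitude = TRUE)
  expect_equal(f$t1_ms, 810, tolerance = 0.01 / 810)
  expect_identical(f$polarity_flips, 1L)

  # property over random tissues: signed and restored-magnitude agree
  set.seed(31)
  for (i in 1:8) {
    t1 <- runif(1, 250, 2300); boa <- runif(1, 1.8, 2.0)
    sg <- ll4_signals(t1, boa)
    fs <- ir_fit(sg$signals, sg$tis_ms)
    fm <- ir_fit(abs(sg$signals), sg$tis_ms, magnitude = TRUE)
    expect_lt(abs(fs$t1_ms - fm$t1_ms), 0.01)
  }
})

test_that("noiseless recovery holds over the T1 x RR x inversion grid", {
  for (t1 in c(200, 700, 1200, 1800, 2500)) {
    for (rr in c(600, 1000, 1200)) {
      for (boa in c(1.8, 2.0)) {
        sg <- ll4_signals(t1, boa, rr_ms = rr)
        f <- ir_fit(sg$signals, sg$tis_ms)
        expect_lt(abs(f$t1_ms - t1) / t1, 1e-4)
      }
    }
  }
})

test_that("degenerate and malformed inputs are flagged", {
  tis <- c(100, 1100, 2100, 3100)
  f <- ir_fit(rep(1, 4), tis)   # no recovery at all (b -> 0)
  expect_true(!f$converged || is.na(f$t1_ms))
  expect_error(ir_fit(c(1, 2), c(100, 200)), "at least 3")
  expect_error(ir_fit(1:4, c(100, 100, 200, 300)), "strictly increasing")
})

test_that("optimum residual never exceeds the residual at the truth", {
  set.seed(32)
  tis <- c(100, 1100, 2100, 3100)
  for (i in 1:10) {
    t1 <- runif(1, 300, 2200); boa <- runif(1, 1.8, 2.0)
    t1s <- apparent_from_true(t1, boa)
    s <- ir_signal(tis, 1, boa, t1s) + rnorm(4, 0, 0.02)
    f <- ir_fit(s, tis)
    rss_fit <- sum(residuals(f)^2)
    rss_truth <- sum((s - ir_signal(tis, 1, boa, t1s))^2)
    expect_lte(rss_fit, rss_truth + 1e-8)
  }
})

test_that("map fitting recovers a noiseless phantom and respects the mask", {
  ph <- simulate_phantom(c(400, 900, 1600), reps = 1, snr = Inf, seed = 41)
  map <- ir_fit_map(ph$stacks[[1]], ph$timing, mask = ph$vials > 0)
  for (v in 1:3) {
    rel <- abs(mean(map[ph$rois == v]) - ph$vial_t1s_ms[v]) / ph$vial_t1s_ms[v]
    expect_lt(rel, 1e-4)
  }
  expect_true(all(is.na(map[ph$vials == 0L])))

  empty <- ir_fit_map(ph$stacks[[1]], ph$timing,
                      mask = matrix(FALSE, nrow(ph$truth), ncol(ph$truth)))
  expect_true(all(is.na(empty)))
})

test_that("multi-group MOLLI stacks fit jointly or per group", {
  # 5(3)3 acquisition of a uniform slab, fitted with all 8 images and with
  # group 1 only; both recover the truth on noiseless data
  timing <- acquisition_timing("5(3)3", rr_ms = 1000, ti1_ms = c(100, 180))
  t1 <- 1100; boa <- 1.9
  t1s <- apparent_from_true(t1, boa)
  dim <- c(4L, 4L)
  stack <- array(0, c(dim, length(timing$tis_ms)))
  for (i in seq_along(timing$tis_ms))
    stack[, , i] <- ir_signal(timing$tis_ms[i], 1, boa, t1s)
  full <- ir_fit_map(stack, timing)
  g1 <- ir_fit_map(stack, timing, group = 1)
  expect_equal(mean(full), t1, tolerance = 1e-4)
  expect_equal(mean(g1), t1, tolerance = 1e-4)
  expect_error(ir_fit_map(stack[, , 1:3], timing), "timing lists")
})

test_that("phantom precision at SNR 100 stays below 3% CV per vial", {
  vials <- seq(300, 2000, length.out = 12)
  ph <- simulate_phantom(vials, snr = 100, reps = 1, seed = 42)
  map <- ir_fit_map(ph$stacks[[1]], ph$timing, mask = ph$rois > 0)
  tab <- phantom_protocol(map, ph$rois)
  expect_equal(nrow(tab), 12L)
  expect_true(all(tab$cv_percent < 3))
})

test_that("the optional per-pixel fit table exports as CSV", {
  ph <- simulate_phantom(c(600, 1400), reps = 1, snr = Inf, seed = 44)
  map <- ir_fit_map(ph$stacks[[1]], ph$timing, mask = ph$rois > 0,
                    details = TRUE)
  det <- attr(map, "details")
  expect_equal(nrow(det), sum(ph$rois > 0))
  expect_true(all(det$converged))
  # table and map agree pixel by pixel
  expect_equal(det$t1_ms, map[cbind(det$row, det$col)])
  path <- tempfile(fileext = ".csv")
  write_fit_csv(map, path)
  back <- utils::read.csv(path)
  expect_equal(back$t1_ms, det$t1_ms, tolerance = 1e-9)
  unlink(path)

  plain <- ir_fit_map(ph$stacks[[1]], ph$timing, mask = ph$rois > 0)
  expect_error(write_fit_csv(plain, path), "details = TRUE")
})

test_that("T1 maps round-trip through NIfTI as float32 with NaN background", {
  ph <- simulate_phantom(c(800, 1500), reps = 1, snr = Inf, seed = 43)
  map <- ir_fit_map(ph$stacks[[1]], ph$timing, mask = ph$rois > 0)
  path <- tempfile(fileext = ".nii.gz")
  write_t1map_nifti(map, path, provenance = list(note = "test"))
  back <- read_t1map_nifti(path)
  expect_equal(unclass(back), unclass(map), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(attr(back, "method"), "ir_fit")
  unlink(c(path, sub("\\.nii\\.gz$", ".json", path)))
})
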