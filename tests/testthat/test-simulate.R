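test_that("pixel simulation draws pools by weight and is seed-reproducible", {
  pools <- list(tissue_pool("a", c(300, 700), weight = 0.5),
                tissue_pool("b", c(1200, 1800), weight = 0.5))
  d <- simulate_pixels(1000, pools, seed = 7)
  expect_equal(nrow(d), 1000L)
  n_a <- sum(d$pool == "a")
  # binomial 99% central bounds for n = 1000, p = 0.5
  expect_gte(n_a, qbinom(0.005, 1000, 0.5))
  expect_lte(n_a, qbinom(0.995, 1000, 0.5))
  # pool ranges respected
  expect_true(all(d$t1_true[d$pool == "a"] >= 300 & d$t1_true[d$pool == "a"] <= 700))

  d2 <- simulate_pixels(1000, pools, seed = 7)
  expect_identical(d, d2)
  d3 <- simulate_pixels(1000, pools, seed = 8)
  expect_false(identical(d$s1, d3$s1))
})

test_that("noise-free signals equal the analytic model at every TI", {
  pool <- tissue_pool("fixed", c(1200, 1200), b_over_a_range = c(2, 2))
  d <- simulate_pixels(50, list(pool), scheme = "4", rr_ms = 1000,
                       ti1_ms = 100, snr = Inf, seed = 3)
  tis <- c(100, 1100, 2100, 3100)
  expected <- ir_signal(tis, 1, 2, apparent_from_true(1200, 2.0))
  m <- pixel_matrices(d)
  expect_true(all(abs(sweep(m$signals, 2, expected)) < 1e-12))
  expect_true(all(m$tis_ms == matrix(tis, 50, 4, byrow = TRUE)))
})

test_that("noise models reproduce their moments at Monte-Carlo scale", {
  x <- rep(0.5, 1e5)
  expect_identical(add_noise(x, Inf), x)

  y <- add_noise(x, snr = 50, model = "gaussian", a_ref = 1, seed = 9)
  expect_equal(sd(y - x), 0.02, tolerance = 0.02)
  expect_equal(mean(y - x), 0, tolerance = 3 * 0.02 / sqrt(1e5))

  # Rician floor: at zero true signal the magnitude mean is sigma*sqrt(pi/2)
  z <- add_noise(rep(0, 1e5), snr = 50, model = "rician", a_ref = 1, seed = 10)
  expect_equal(mean(z), 0.02 * sqrt(pi / 2), tolerance = 0.05 * 0.02 * sqrt(pi / 2))
  expect_true(all(z >= 0))
})

test_that("phantom protocol renders vials with ~120-pixel ROIs", {
  vials <- seq(300, 2000, length.out = 12)
  ph <- simulate_phantom(vials, scheme = "4", rr_ms = 1000, snr = 100,
                         reps = 10, seed = 21)
  expect_length(ph$stacks, 10L)
  expect_equal(dim(ph$stacks[[1]])[3], 4L)
  for (v in seq_along(vials)) {
    inside <- ph$truth[ph$vials == v]
    expect_true(all(inside == vials[v]))
    n_roi <- sum(ph$rois == v)
    expect_gte(n_roi, 110); expect_lte(n_roi, 130)
    # ROI sits inside the vial
    expect_true(all(ph$vials[ph$rois == v] == v))
  }
  expect_true(all(is.na(ph$truth[ph$vials == 0L])))
})

test_that("phantom repetitions differ only in noise", {
  ph <- simulate_phantom(c(500, 1500), reps = 2, snr = Inf, seed = 4)
  expect_identical(ph$stacks[[1]], ph$stacks[[2]])
  ph2 <- simulate_phantom(c(500, 1500), reps = 2, snr = 50, seed = 4)
  expect_false(identical(ph2$stacks[[1]], ph2$stacks[[2]]))
  # same clean signal underneath: difference is pure noise around zero
  expect_equal(mean(ph2$stacks[[1]] - ph2$stacks[[2]]), 0, tolerance = 1e-3)
})

test_that("cardiac digital phantom respects tissue pools and masks", {
  cs <- simulate_cardiac(native = TRUE, seed = 5)
  expect_true(all(cs$truth[cs$myocardium] >= 1000 & cs$truth[cs$myocardium] <= 1400))
  expect_true(all(cs$truth[cs$blood] >= 1500 & cs$truth[cs$blood] <= 2000))
  expect_false(any(cs$myocardium & cs$blood))
  expect_gt(sum(cs$myocardium), 0)
  expect_gt(sum(cs$blood), 0)

  cp <- simulate_cardiac(native = FALSE, seed = 5)
  expect_true(all(cp$truth[cp$myocardium] >= 500 & cp$truth[cp$myocardium] <= 650))
  expect_true(all(cp$truth[cp$blood] >= 400 & cp$truth[cp$blood] <= 520))
  expect_lt(mean(cp$truth[cp$blood]), mean(cp$truth[cp$myocardium]))
})

test_that("pixel datasets survive the CSV round trip", {
  d <- simulate_pixels(25, snr = 50, seed = 12)
  path <- tempfile(fileext = ".csv")
  write_pixel_csv(d, path)
  d2 <- read_pixel_csv(path)
  expect_equal(as.data.frame(d), as.data.frame(d2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(d2, "n_inputs"), 4L)
  unlink(path)
})

test_that("image stacks round-trip through NIfTI with their timing sidecar", {
  cs <- simulate_cardiac(seed = 6)
  path <- tempfile(fileext = ".nii.gz")
  write_stack_nifti(cs$stack, path, timing = cs$timing)
  back <- read_stack_nifti(path)
  expect_equal(back$stack, unclass(cs$stack), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$timing$tis_ms, cs$timing$tis_ms)
  unlink(c(path, sub("\\.nii\\.gz$", ".json", path)))
})
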