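#' Tissue pool definition for the pixel simulator
#'
#' A pool is a tissue class with a true-T1 range, an inversion-efficiency
#' (`B/A`) range and a sampling weight.  Defaults for `b_over_a` reflect
#' near-ideal adiabatic inversion with a readout-driven reduction.
#'
#' @param name Pool label (e.g. `"native_myocardium"`).
#' @param t1_range_ms Length-2 vector, low and high true T1 in ms.
#' @param b_over_a_range Length-2 vector inside (1.5, 2.0].
#' @param weight Relative sampling proportion (positive).
#' @return A list of class `"tissue_pool"`.
#' @export
tissue_pool <- function(name, t1_range_ms, b_over_a_range = c(1.8, 2.0),
                        weight = 1) {
  stopifnot(is.character(name), length(t1_range_ms) == 2L,
            t1_range_ms[1] > 0, t1_range_ms[1] <= t1_range_ms[2],
            length(b_over_a_range) == 2L,
            b_over_a_range[1] > 1.5, b_over_a_range[2] <= 2.0,
            b_over_a_range[1] <= b_over_a_range[2],
            weight > 0)
  structure(list(name = name, t1_range_ms = as.numeric(t1_range_ms),
                 b_over_a_range = as.numeric(b_over_a_range),
                 weight = as.numeric(weight)),
            class = "tissue_pool")
}

#' Standard tissue pools
#'
#' Ready-made pool sets mirroring the tissue classes an accelerated cardiac
#' T1 estimator is trained and monitored on: native myocardium 1000--1400 ms
#' and blood 1500--2000 ms; post-contrast myocardium 500--650 ms and blood
#' 400--520 ms; and a `"uniform"` pool spanning 100--2200 ms that covers the
#' native and post-contrast ranges jointly (the training default for a single
#' pre+post model).
#'
#' @param variant One of `"uniform"` (default), `"native"`, `"post"`,
#'   `"native_post"`, `"phantom"`.
#' @return A list of [tissue_pool()] objects with weights summing to 1.
#' @export
default_pools <- function(variant = c("uniform", "native", "post", "native_post")) {
  variant <- match.arg(variant)
  p <- switch(variant,
    uniform = list(tissue_pool("uniform", c(100, 2200))),
    native = list(tissue_pool("native_myocardium", c(1000, 1400), weight = 0.5),
                  tissue_pool("native_blood", c(1500, 2000), weight = 0.5)),
    post = list(tissue_pool("post_myocardium", c(500, 650), weight = 0.5),
                tissue_pool("post_blood", c(400, 520), weight = 0.5)),
    native_post = list(tissue_pool("native_myocardium", c(1000, 1400), weight = 0.25),
                       tissue_pool("native_blood", c(1500, 2000), weight = 0.25),
                       tissue_pool("post_myocardium", c(500, 650), weight = 0.25),
                       tissue_pool("post_blood", c(400, 520), weight = 0.25)))
  normalize_pool_weights(p)
}

normalize_pool_weights <- function(pools) {
  if (length(pools) == 0L) stop("empty pool list", call. = FALSE)
  if (inherits(pools, "tissue_pool")) pools <- list(pools)
  w <- vapply(pools, function(p) p$weight, numeric(1))
  for (i in seq_along(pools)) pools[[i]]$weight <- w[i] / sum(w)
  pools
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Add measurement noise to inversion-recovery signals
#'
#' Gaussian noise adds zero-mean deviates with `sigma = a_ref / snr` to
#' signed (phase-sensitive) signals.  Rician noise models magnitude images:
#' the signal is treated as the real channel, independent Gaussian noise of
#' the same `sigma` is added to the real and imaginary channels, and the
#' complex magnitude is returned.
#'
#' @param signals Numeric vector or matrix of signal values.
#' @param snr Signal-to-noise ratio relative to `a_ref`; `Inf` returns the
#'   input unchanged.
#' @param model `"gaussian"` or `"rician"`.
#' @param a_ref Reference amplitude defining the noise scale (default 1).
#' @param seed Optional integer seed (local to this call).
#' @return Noisy signals, same shape as `signals`.
#' @export
add_noise <- function(signals, snr, model = c("gaussian", "rician"),
                      a_ref = 1, seed = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(snr), length(snr) == 1L, snr > 0)
  if (a_ref <= 0)
    stop("a_ref must be a positive reference amplitude", call. = FALSE)
  if (is.infinite(snr)) return(signals)
  sigma <- a_ref / snr
  with_seed(seed, {
    if (model == "gaussian") {
      signals + stats::rnorm(length(signals), 0, sigma)
    } else {
      out <- sqrt((signals + stats::rnorm(length(signals), 0, sigma))^2 +
                  stats::rnorm(length(signals), 0, sigma)^2)
      attributes(out) <- attributes(signals)
      out
    }
  })
}

# Per-sample inversion times for the first n_inputs images of a scheme,
# with optional per-beat RR jitter.  Returns a matrix n x n_inputs.
sample_tis <- function(n, scheme, rr_ms, ti1_ms, n_inputs, rr_jitter = 0) {
  timing <- acquisition_timing(scheme, rr_ms, ti1_ms)
  if (length(timing$tis_ms) < n_inputs)
    stop(sprintf("scheme %s provides %d image(s); %d needed",
                 dQuote(timing$scheme), length(timing$tis_ms), n_inputs),
         call. = FALSE)
  base <- timing$tis_ms[seq_len(n_inputs)]
  if (rr_jitter == 0)
    return(matrix(base, n, n_inputs, byrow = TRUE))
  # per-beat jitter: each inter-image interval is RR * (1 + U(-j, j))
  grp <- timing$group[seq_len(n_inputs)]
  tis <- matrix(0, n, n_inputs)
  for (i in seq_len(n_inputs)) {
    if (i == 1L || grp[i] != grp[i - 1L]) {
      tis[, i] <- timing$ti1_ms[grp[i]]
    } else {
      beat <- rr_ms * (1 + stats::runif(n, -rr_jitter, rr_jitter))
      tis[, i] <- tis[, i - 1L] + beat
    }
  }
  tis
}

#' Simulate a per-pixel training/validation dataset
#'
#' Draws independent pixels: a tissue pool by weight, true T1 uniform in the
#' pool's range, `B/A` uniform in the pool's range, then evaluates the
#' three-parameter inversion-recovery model at the first `n_inputs` inversion
#' times of the scheme (with `T1* = apparent_from_true(T1, B/A)`) and applies
#' measurement noise.
#'
#' @param n Number of pixels.
#' @param pools List of [tissue_pool()] objects (weights renormalised to 1).
#' @param scheme Acquisition scheme label or `"molli_scheme"`; default the
#'   four-heartbeat single Look-Locker experiment `"4"`.
#' @param rr_ms RR interval in ms (default 1000, i.e. 60 bpm).
#' @param ti1_ms Per-group minimum TI(s); default 100 ms (and 180 ms for
#'   later groups).
#' @param n_inputs Number of T1-weighted samples per pixel (4 or 5);
#'   defaults to all images of the scheme, capped at 5.
#' @param snr Signal-to-noise ratio (`Inf` = noiseless).
#' @param noise `"gaussian"` (signed signals) or `"rician"` (magnitudes).
#' @param polarity `"signed"` phase-sensitive signals (default) or
#'   `"magnitude"` absolute values.
#' @param rr_jitter Fractional per-beat heart-rate jitter (e.g. 0.05 for
#'   +/-5%); default 0.
#' @param a_ref Asymptotic amplitude `A` of every pixel (arbitrary units).
#' @param seed Integer seed; identical config + seed reproduces the dataset
#'   bit for bit.
#' @return A `data.frame` of class `"pixel_dataset"` with columns
#'   `s1..sN`, `ti1..tiN`, `t1_true`, `pool`, and attributes `config`
#'   (generator settings) and `n_inputs`.
#' @examples
#' d <- simulate_pixels(10, snr = Inf, seed = 1)
#' head(d)
#' @export
simulate_pixels <- function(n, pools = default_pools("uniform"),
                            scheme = "4", rr_ms = 1000, ti1_ms = NULL,
                            n_inputs = NULL, snr = Inf,
                            noise = c("gaussian", "rician"),
                            polarity = c("signed", "magnitude"),
                            rr_jitter = 0, a_ref = 1, seed = NULL) {
  noise <- match.arg(noise); polarity <- match.arg(polarity)
  stopifnot(n >= 1)
  pools <- normalize_pool_weights(pools)
  scheme <- as_scheme(scheme)
  if (is.null(n_inputs)) n_inputs <- min(sum(scheme$n_acq), 5L)
  if (!n_inputs %in% c(4L, 5L))
    stop("n_inputs must be 4 or 5", call. = FALSE)
  with_seed(seed, {
    w <- vapply(pools, function(p) p$weight, numeric(1))
    pidx <- sample.int(length(pools), n, replace = TRUE, prob = w)
    t1 <- boa <- numeric(n)
    for (k in seq_along(pools)) {
      m <- pidx == k
      t1[m] <- stats::runif(sum(m), pools[[k]]$t1_range_ms[1], pools[[k]]$t1_range_ms[2])
      boa[m] <- stats::runif(sum(m), pools[[k]]$b_over_a_range[1], pools[[k]]$b_over_a_range[2])
    }
    tis <- sample_tis(n, scheme, rr_ms, ti1_ms, n_inputs, rr_jitter)
    t1s <- apparent_from_true(t1, boa)
    sig <- a_ref - (boa * a_ref) * exp(-tis / t1s)
    if (polarity == "magnitude" && is.infinite(snr)) sig <- abs(sig)
    if (polarity == "magnitude" && !is.infinite(snr) && noise == "gaussian")
      stop("magnitude polarity with finite snr requires rician noise", call. = FALSE)
    sig <- add_noise(sig, snr, model = noise, a_ref = a_ref)
    out <- data.frame(sig, tis, t1_true = t1,
                      pool = vapply(pools, function(p) p$name, character(1))[pidx],
                      stringsAsFactors = FALSE)
    names(out) <- c(paste0("s", seq_len(n_inputs)),
                    paste0("ti", seq_len(n_inputs)), "t1_true", "pool")
    structure(out,
              n_inputs = n_inputs,
              config = list(pools = pools, scheme = scheme$label, rr_ms = rr_ms,
                            ti1_ms = ti1_ms, snr = snr, noise = noise,
                            polarity = polarity, rr_jitter = rr_jitter,
                            a_ref = a_ref, seed = seed),
              class = c("pixel_dataset", "data.frame"))
  })
}

#' Extract signal and TI matrices from a pixel dataset
#'
#' @param data A `"pixel_dataset"` or any data frame with `s1..sN` /
#'   `ti1..tiN` columns.
#' @return List with matrices `signals`, `tis_ms` and vector `t1_true`
#'   (NULL if absent).
#' @export
pixel_matrices <- function(data) {
  sn <- grep("^s[0-9]+$", names(data), value = TRUE)
  tn <- grep("^ti[0-9]+$", names(data), value = TRUE)
  if (length(sn) == 0L || length(sn) != length(tn))
    stop("expected matching s1..sN and ti1..tiN columns", call. = FALSE)
  ord <- order(as.integer(sub("^s", "", sn)))
  sn <- sn[ord]; tn <- tn[order(as.integer(sub("^ti", "", tn)))]
  list(signals = as.matrix(data[sn]), tis_ms = as.matrix(data[tn]),
       t1_true = if ("t1_true" %in% names(data)) data$t1_true else NULL)
}

#' Write / read a pixel dataset as CSV
#'
#' Plain CSV with columns `s1..sN`, `ti1..tiN`, `t1_true`, `pool` so a
#' dataset can be exchanged with any other implementation (or replaced by
#' real scanner pixels with reference T1 labels).
#'
#' @param data A `"pixel_dataset"` data frame.
#' @param path Output file path.
#' @return `write_pixel_csv` returns `path` invisibly; `read_pixel_csv`
#'   returns a `"pixel_dataset"` data frame.
#' @export
write_pixel_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pixel_csv
#' @export
read_pixel_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  n_inputs <- length(grep("^s[0-9]+$", names(out)))
  structure(out, n_inputs = n_inputs,
            class = c("pixel_dataset", "data.frame"))
}

disk_mask <- function(dim, center, radius) {
  x <- matrix(seq_len(dim[1]), dim[1], dim[2])
  y <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}

#' Simulate the multi-vial phantom protocol
#'
#' Renders a grid of circular vials with known T1 on a signal-free
#' background, images them with the given Look-Locker scheme, and repeats the
#' acquisition `reps` times with fresh noise (the repeated-scan quality
#' assurance protocol run on physical T1 phantoms, at a simulated heart rate
#' set by `rr_ms`).  Each vial carries a circular analysis ROI of ~120
#' pixels.  `B/A` varies per pixel within `b_over_a_range` and is fixed
#' across repetitions, so repetitions differ only in noise.
#'
#' @param vial_t1s_ms Vector of vial T1 values (1 to 16 vials).
#' @param scheme,rr_ms,ti1_ms,snr,noise,polarity,a_ref As in
#'   [simulate_pixels()].
#' @param reps Number of repeated acquisitions (default 10).
#' @param b_over_a_range Per-pixel inversion-efficiency range.
#' @param seed Integer seed.
#' @return List of class `"phantom_sim"`: `stacks` (list of `reps` arrays,
#'   x-y-image), `truth` (matrix of true T1, `NA` outside vials), `rois`
#'   (integer label matrix, 0 = background, v = ROI of vial v), `timing`
#'   (`"acq_timing"`), `vial_t1s_ms`, and the generator config.
#' @export
simulate_phantom <- function(vial_t1s_ms, scheme = "4", rr_ms = 1000,
                             ti1_ms = NULL, snr = Inf, reps = 10,
                             noise = c("gaussian", "rician"),
                             polarity = c("signed", "magnitude"),
                             b_over_a_range = c(1.8, 2.0), a_ref = 1,
                             seed = NULL) {
  noise <- match.arg(noise); polarity <- match.arg(polarity)
  nv <- length(vial_t1s_ms)
  stopifnot(nv >= 1L, nv <= 16L, reps >= 1L, all(vial_t1s_ms > 0))
  timing <- acquisition_timing(scheme, rr_ms, ti1_ms)
  ncol_v <- min(nv, 4L); nrow_v <- ceiling(nv / ncol_v)
  spacing <- 20L; vial_r <- 8; roi_r <- 6.2   # ROI ~ 120 pixels
  dim <- c(nrow_v * spacing, ncol_v * spacing)
  truth <- matrix(NA_real_, dim[1], dim[2])
  rois <- matrix(0L, dim[1], dim[2])
  vial_lab <- matrix(0L, dim[1], dim[2])
  for (v in seq_len(nv)) {
    r <- (v - 1L) %/% ncol_v; cl <- (v - 1L) %% ncol_v
    ctr <- c(r * spacing + spacing / 2, cl * spacing + spacing / 2)
    vm <- disk_mask(dim, ctr, vial_r)
    truth[vm] <- vial_t1s_ms[v]
    vial_lab[vm] <- v
    rois[disk_mask(dim, ctr, roi_r)] <- v
  }
  with_seed(seed, {
    boa <- matrix(stats::runif(prod(dim), b_over_a_range[1], b_over_a_range[2]),
                  dim[1], dim[2])
    tis <- timing$tis_ms
    clean <- array(0, c(dim, length(tis)))
    inside <- !is.na(truth)
    t1s <- apparent_from_true(truth[inside], boa[inside])
    for (i in seq_along(tis)) {
      img <- matrix(0, dim[1], dim[2])
      img[inside] <- a_ref - boa[inside] * a_ref * exp(-tis[i] / t1s)
      clean[, , i] <- img
    }
    if (polarity == "magnitude" && is.infinite(snr)) clean <- abs(clean)
    stacks <- lapply(seq_len(reps), function(r)
      add_noise(clean, snr, model = noise, a_ref = a_ref))
    structure(list(stacks = stacks, truth = truth, rois = rois,
                   vials = vial_lab, timing = timing,
                   vial_t1s_ms = vial_t1s_ms,
                   config = list(scheme = timing$scheme, rr_ms = rr_ms,
                                 snr = snr, reps = reps, noise = noise,
                                 polarity = polarity,
                                 b_over_a_range = b_over_a_range,
                                 a_ref = a_ref, seed = seed)),
              class = "phantom_sim")
  })
}

#' Simulate a cardiac-like short-axis slice
#'
#' Digital phantom for end-to-end tests: an annulus of myocardium around a
#' blood-pool disk, with per-pixel T1 drawn from the native or post-contrast
#' tissue pools.
#'
#' @param native Logical; `TRUE` uses native pools (myocardium 1000--1400 ms,
#'   blood 1500--2000 ms), `FALSE` the post-contrast pools (myocardium
#'   500--650 ms, blood 400--520 ms).
#' @param scheme,rr_ms,ti1_ms,snr,noise,polarity,a_ref,seed As in
#'   [simulate_pixels()].
#' @param dim Canvas size (pixels).
#' @return List of class `"cardiac_sim"`: `stack` (x-y-image array), `truth`
#'   (true T1 matrix, `NA` background), `myocardium` and `blood` logical
#'   masks, `timing`.
#' @export
simulate_cardiac <- function(native = TRUE, scheme = "4", rr_ms = 1000,
                             ti1_ms = NULL, snr = Inf,
                             noise = c("gaussian", "rician"),
                             polarity = c("signed", "magnitude"),
                             a_ref = 1, dim = c(64L, 64L), seed = NULL) {
  noise <- match.arg(noise); polarity <- match.arg(polarity)
  pools <- default_pools(if (native) "native" else "post")
  myo_pool <- pools[[1]]; blood_pool <- pools[[2]]
  timing <- acquisition_timing(scheme, rr_ms, ti1_ms)
  ctr <- dim / 2
  outer_m <- disk_mask(dim, ctr, 0.28 * min(dim))
  inner_m <- disk_mask(dim, ctr, 0.17 * min(dim))
  myo <- outer_m & !inner_m
  blood <- inner_m
  with_seed(seed, {
    truth <- matrix(NA_real_, dim[1], dim[2])
    truth[myo] <- stats::runif(sum(myo), myo_pool$t1_range_ms[1], myo_pool$t1_range_ms[2])
    truth[blood] <- stats::runif(sum(blood), blood_pool$t1_range_ms[1], blood_pool$t1_range_ms[2])
    boa <- matrix(stats::runif(prod(dim), 1.8, 2.0), dim[1], dim[2])
    inside <- !is.na(truth)
    t1s <- apparent_from_true(truth[inside], boa[inside])
    tis <- timing$tis_ms
    stack <- array(0, c(dim, length(tis)))
    for (i in seq_along(tis)) {
      img <- matrix(0, dim[1], dim[2])
      img[inside] <- a_ref - boa[inside] * a_ref * exp(-tis[i] / t1s)
      stack[, , i] <- img
    }
    if (polarity == "magnitude" && is.infinite(snr)) stack <- abs(stack)
    stack <- add_noise(stack, snr, model = noise, a_ref = a_ref)
    structure(list(stack = stack, truth = truth, myocardium = myo,
                   blood = blood, timing = timing),
              class = "cardiac_sim")
  })
}

#' Write / read an image stack as NIfTI with a timing sidecar
#'
#' The stack is stored as a 3D NIfTI volume (images along the last axis);
#' the acquisition timing is written to `<path minus extension>.json`.
#'
#' @param stack 3D array (x, y, image).
#' @param path Output `.nii` / `.nii.gz` path.
#' @param timing Optional `"acq_timing"` written as JSON sidecar.
#' @return `write_stack_nifti` returns `path` invisibly; `read_stack_nifti`
#'   returns a list with `stack` and `timing` (NULL if no sidecar found).
#' @export
write_stack_nifti <- function(stack, path, timing = NULL) {
  stopifnot(length(dim(stack)) == 3L)
  RNifti::writeNifti(RNifti::asNifti(stack), path)
  if (!is.null(timing))
    write_timing_json(timing, sidecar_path(path))
  invisible(path)
}

#' @rdname write_stack_nifti
#' @export
read_stack_nifti <- function(path) {
  stack <- as.array(RNifti::readNifti(path))
  sc <- sidecar_path(path)
  timing <- if (file.exists(sc)) read_timing_json(sc) else NULL
  list(stack = stack, timing = timing)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}
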