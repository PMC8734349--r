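#' Input normalization specification
#'
#' Per-pixel signal normalization applied before the network, plus the TI
#' scaling.  Two modes are provided because vendor pipelines normalise
#' magnitude images "to 0--1.1" without stating the exact mapping:
#'
#' * `"scale_max"` (default): divide by the largest absolute signal and
#'   multiply by 1.1.  Scale-invariant and shape-preserving; the ratio of
#'   recovery span to asymptote (`B/A`), which the Look-Locker correction
#'   depends on, survives normalization.  Signed inputs map into
#'   `[-1.1, 1.1]`, magnitudes into `[0, 1.1]`.
#' * `"minmax"`: affine map of the pixel's min/max onto `[0, 1.1]`.  For a
#'   mono-exponential recovery this removes both scale and offset, so the
#'   normalized curve depends on `T1*` only; it is kept for compatibility
#'   but discards the inversion-efficiency information (see the package
#'   vignette).
#'
#' TIs are divided by `ti_scale` (default 1000, i.e. passed in seconds) so
#' all features are O(1).
#'
#' @param signal_mode `"scale_max"` or `"minmax"`.
#' @param ti_scale Divisor converting TI in ms to network units.
#' @return List of class `"t1net_norm"`.
#' @export
norm_spec <- function(signal_mode = c("scale_max", "minmax"), ti_scale = 1000) {
  signal_mode <- match.arg(signal_mode)
  stopifnot(ti_scale > 0)
  structure(list(signal_mode = signal_mode, ti_scale = ti_scale),
            class = "t1net_norm")
}

#' Build the network feature vector from signals and inversion times
#'
#' Normalises the N signal samples per [norm_spec()] and appends the scaled
#' inversion times, giving the length-2N feature vector the estimator
#' consumes (signals first, then TIs).
#'
#' @param signals Numeric vector of length N, or an n x N matrix (one pixel
#'   per row).
#' @param tis_ms Inversion times: vector of length N (recycled across rows)
#'   or matrix matching `signals`.
#' @param norm A [norm_spec()].
#' @return Feature vector of length 2N, or an n x 2N matrix.
#' @examples
#' normalize_inputs(c(-1, 0, 0.5, 1), c(100, 1100, 2100, 3100),
#'                  norm_spec("minmax"))
#' @export
normalize_inputs <- function(signals, tis_ms, norm = norm_spec()) {
  vec_in <- is.null(dim(signals))
  s <- if (vec_in) matrix(signals, 1) else as.matrix(signals)
  ti <- if (is.null(dim(tis_ms))) matrix(tis_ms, nrow(s), ncol(s), byrow = TRUE)
        else as.matrix(tis_ms)
  if (ncol(s) != ncol(ti) || nrow(s) != nrow(ti))
    stop("signals and tis_ms must both provide N values per pixel", call. = FALSE)
  if (norm$signal_mode == "minmax") {
    lo <- apply(s, 1, min); hi <- apply(s, 1, max)
    if (any(hi - lo <= 0))
      stop("constant signal vector: min-max normalization undefined", call. = FALSE)
    sn <- (s - lo) / (hi - lo) * 1.1
  } else {
    mx <- apply(abs(s), 1, max)
    if (any(mx <= 0))
      stop("all-zero signal vector: scale normalization undefined", call. = FALSE)
    sn <- s / mx * 1.1
  }
  out <- cbind(sn, ti / norm$ti_scale)
  if (vec_in) out[1, ] else out
}

default_monitor_ranges <- function() {
  rbind(myocardium = c(1000, 1400), blood = c(1500, 2000))
}

#' Initialise an untrained T1 estimator
#'
#' Constructs the fully connected network with the selected architecture:
#' input 2N (N normalised signals + N scaled TIs), hidden layers with leaky
#' rectifier activations, and one linear output (T1 in ms).  The default
#' hidden sizes 400-400-200-200-100 are the selected six-layer configuration
#' of the hyperparameter search behind this estimator.  Weights are drawn
#' uniformly on `+/- sqrt(6 / fan_in)` from `seed`; biases start at zero.
#'
#' @param n_inputs Number of T1-weighted samples N (4 or 5).
#' @param hidden Integer vector of hidden-layer sizes.
#' @param slope Negative slope of the leaky rectifier (default 0.01).
#' @param norm A [norm_spec()].
#' @param variant Label for the training-data flavour (`"pre"`, `"post"`,
#'   `"pre_post"`); informational.
#' @param seed Integer seed for reproducible initialisation.
#' @return An untrained object of class `"t1net"`.
#' @examples
#' m <- t1net_build(4, seed = 1)
#' sapply(m$weights, dim)
#' @export
t1net_build <- function(n_inputs = 4, hidden = c(400, 400, 200, 200, 100),
                        slope = 0.01, norm = norm_spec(),
                        variant = "pre_post", seed = 1) {
  if (!n_inputs %in% c(4, 5)) stop("n_inputs must be 4 or 5", call. = FALSE)
  if (length(hidden) < 1L) stop("hidden must list at least one layer", call. = FALSE)
  stopifnot(all(hidden >= 1), inherits(norm, "t1net_norm"))
  sizes <- c(2L * as.integer(n_inputs), as.integer(hidden), 1L)
  with_seed(seed, {
    weights <- biases <- vector("list", length(sizes) - 1L)
    for (i in seq_along(weights)) {
      lim <- sqrt(6 / sizes[i])
      weights[[i]] <- matrix(stats::runif(sizes[i] * sizes[i + 1], -lim, lim),
                             sizes[i], sizes[i + 1])
      biases[[i]] <- numeric(sizes[i + 1])
    }
    structure(list(weights = weights, biases = biases,
                   config = list(n_inputs = as.integer(n_inputs),
                                 hidden = as.integer(hidden),
                                 slope = slope, variant = variant,
                                 init_seed = as.integer(seed)),
                   norm = norm, history = NULL, best_epoch = NA_integer_,
                   best_val_mae = NA_real_, epochs_run = 0L),
              class = "t1net")
  })
}

#' Train the pixelwise T1 estimator
#'
#' Fits the fully connected network to (signals, TIs) -> reference-T1 pairs
#' by minimising the mean absolute error (MAE, in ms) with the Adam
#' optimiser, mirroring the training protocol of the accelerated-mapping
#' estimator it implements: mini-batches of 64, learning rate 0.01, weight
#' decay 1e-4, early stopping once `patience` epochs pass without
#' improvement of the overall validation MAE, and per-epoch monitoring of
#' the validation error restricted to the myocardium (1000--1400 ms) and
#' blood (1500--2000 ms) T1 ranges.  The returned weights are those of the
#' best-validation epoch.
#'
#' @param train Training data: a `"pixel_dataset"` (or data frame with
#'   `s1..sN`, `ti1..tiN`, `t1_true`).
#' @param val Validation data, same layout.  If `NULL`, a random 10% of
#'   `train` is held out (seeded).
#' @param n_inputs,hidden,slope,norm,variant,seed Passed to [t1net_build()];
#'   `n_inputs` defaults to the data's sample count.
#' @param lr Learning rate (default 0.01).
#' @param weight_decay L2 penalty coupled into the Adam update (default 1e-4).
#' @param batch_size Mini-batch size (default 64).
#' @param max_epochs Epoch cap (default 1000).
#' @param patience Early-stopping patience in epochs (default 70).
#' @param lr_decay,lr_decay_every Optional step decay of the learning rate
#'   (factor applied every `lr_decay_every` epochs; defaults disable it).
#' @param monitor_ranges 2-column matrix of T1 ranges (ms) whose validation
#'   MAE is tracked per epoch.
#' @param verbose Print per-epoch progress.
#' @return A trained `"t1net"` object with `history` (data frame: epoch,
#'   train_mae, val_mae, one column per monitored range, lr), `best_epoch`,
#'   `best_val_mae`, `epochs_run`.
#' @seealso [predict.t1net()], [predict_map()], [save_t1net()]
#' @export
t1net <- function(train, val = NULL, n_inputs = NULL,
                  hidden = c(400, 400, 200, 200, 100), slope = 0.01,
                  norm = norm_spec(), variant = "pre_post",
                  lr = 0.01, weight_decay = 1e-4, batch_size = 64,
                  max_epochs = 1000, patience = 70,
                  lr_decay = 1, lr_decay_every = 0,
                  monitor_ranges = default_monitor_ranges(),
                  seed = 1, verbose = FALSE) {
  stopifnot(patience >= 1, batch_size >= 1, max_epochs >= 1)
  tr <- pixel_matrices(train)
  if (is.null(tr$t1_true)) stop("training data needs a t1_true column", call. = FALSE)
  if (is.null(n_inputs)) n_inputs <- ncol(tr$signals)
  if (ncol(tr$signals) < n_inputs)
    stop(sprintf("training data has %d samples per pixel; estimator needs %d",
                 ncol(tr$signals), n_inputs), call. = FALSE)
  take <- function(m) m[, seq_len(n_inputs), drop = FALSE]
  if (is.null(val)) {
    n <- nrow(tr$signals)
    hold <- with_seed(seed + 1L, sample.int(n, max(1L, round(0.1 * n))))
    va <- list(signals = tr$signals[hold, , drop = FALSE],
               tis_ms = tr$tis_ms[hold, , drop = FALSE],
               t1_true = tr$t1_true[hold])
    tr <- list(signals = tr$signals[-hold, , drop = FALSE],
               tis_ms = tr$tis_ms[-hold, , drop = FALSE],
               t1_true = tr$t1_true[-hold])
  } else {
    va <- pixel_matrices(val)
    if (is.null(va$t1_true) || nrow(va$signals) == 0L)
      stop("validation data must be nonempty with t1_true", call. = FALSE)
    if (ncol(va$signals) < n_inputs)
      stop("validation data has fewer samples per pixel than the estimator",
           call. = FALSE)
  }
  model <- t1net_build(n_inputs, hidden, slope, norm, variant, seed)
  Xtr <- normalize_inputs(take(tr$signals), take(tr$tis_ms), norm)
  Xv <- normalize_inputs(take(va$signals), take(va$tis_ms), norm)
  mr <- matrix(as.numeric(monitor_ranges), ncol = 2)
  res <- .mlp_train(Xtr, tr$t1_true, Xv, va$t1_true,
                    model$weights, model$biases, slope,
                    lr, weight_decay, as.integer(batch_size),
                    as.integer(max_epochs), as.integer(patience),
                    as.integer(seed), lr_decay, as.integer(lr_decay_every),
                    mr, verbose)
  model$weights <- res$weights
  model$biases <- res$biases
  h <- as.data.frame(res$history)
  rn <- rownames(monitor_ranges)
  if (is.null(rn)) rn <- paste0("range", seq_len(nrow(mr)))
  names(h) <- c("epoch", "train_mae", "val_mae",
                paste0("val_mae_", sub("^(\\d)", "r\\1", gsub("\\W", "_", rn))),
                "lr")
  model$history <- h
  model$best_epoch <- res$best_epoch
  model$best_val_mae <- res$best_val_mae
  model$epochs_run <- res$epochs_run
  model$training <- list(lr = lr, weight_decay = weight_decay,
                         batch_size = batch_size, max_epochs = max_epochs,
                         patience = patience, lr_decay = lr_decay,
                         lr_decay_every = lr_decay_every, seed = seed,
                         monitor_ranges = mr, loss = "mae",
                         n_train = nrow(Xtr), n_val = nrow(Xv))
  model
}

#' @export
print.t1net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Fully connected T1 estimator (%d inputs -> %s -> 1)\n",
              2L * cfg$n_inputs, paste(cfg$hidden, collapse = "-")))
  cat(sprintf("  normalization: %s, TI scale %g; leaky slope %g; variant %s\n",
              x$norm$signal_mode, x$norm$ti_scale, cfg$slope, cfg$variant))
  if (x$epochs_run > 0L) {
    cat(sprintf("  trained %d epoch(s); best epoch %d, validation MAE %.2f ms\n",
                x$epochs_run, x$best_epoch, x$best_val_mae))
  } else {
    cat("  untrained (initial weights)\n")
  }
  invisible(x)
}

#' @export
summary.t1net <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat("\nLoss history (ms), last epochs:\n")
    print(utils::tail(round(h, 2), 5), row.names = FALSE)
    b <- h[object$best_epoch, ]
    cat(sprintf("\nBest epoch %d: val MAE %.2f", object$best_epoch, b$val_mae))
    extra <- grep("^val_mae_", names(h), value = TRUE)
    for (e in extra) cat(sprintf(", %s %.2f", sub("val_mae_", "", e), b[[e]]))
    cat(" ms\n")
  }
  invisible(object)
}

#' @export
coef.t1net <- function(object, ...) {
  list(weights = object$weights, biases = object$biases)
}

#' Loss curves of a trained estimator
#'
#' @param x A trained `"t1net"`.
#' @param log Logical; log-scale the MAE axis.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.t1net <- function(x, log = TRUE, ...) {
  if (is.null(x$history)) stop("model has no training history", call. = FALSE)
  h <- x$history
  cols <- setdiff(names(h), c("epoch", "lr"))
  graphics::matplot(h$epoch, as.matrix(h[cols]), type = "l", lty = 1,
                    xlab = "epoch", ylab = "MAE (ms)",
                    log = if (log) "y" else "", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", legend = cols, lty = 1,
                   col = seq_along(cols), bty = "n")
  invisible(x)
}

#' Predict T1 for pixel samples
#'
#' @param object A `"t1net"` model.
#' @param newdata A `"pixel_dataset"` / data frame with `s1..sN`, `ti1..tiN`
#'   columns, or a list with elements `signals` and `tis_ms`.
#' @param ... Unused.
#' @return Numeric vector of T1 estimates in ms.  Negative network outputs
#'   are clamped to 0; the number of clamped pixels is attached as attribute
#'   `"n_clamped"`.
#' @export
predict.t1net <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- pixel_matrices(newdata)
  s <- as.matrix(newdata$signals); ti <- as.matrix(newdata$tis_ms)
  N <- object$config$n_inputs
  if (ncol(s) < N)
    stop(sprintf("model expects %d T1-weighted samples per pixel, got %d",
                 N, ncol(s)), call. = FALSE)
  X <- normalize_inputs(s[, seq_len(N), drop = FALSE],
                        ti[, seq_len(N), drop = FALSE], object$norm)
  p <- .mlp_forward(object$weights, object$biases, X, object$config$slope)
  ncl <- sum(p < 0)
  p[p < 0] <- 0
  attr(p, "n_clamped") <- ncl
  p
}

#' Network T1 map from an image stack
#'
#' Runs the estimator over every masked pixel of a T1-weighted stack using
#' the first N images and inversion times (N = the model's input count).
#'
#' @param model A trained `"t1net"`.
#' @param stack 3D array (x, y, image) with at least N images.
#' @param timing `"acq_timing"` for the stack.
#' @param mask Logical matrix; default all pixels.
#' @return A `"t1_map"` matrix (ms); unmasked pixels are `NA`, negative
#'   outputs are clamped to 0 (count in attribute `"n_clamped"`).
#' @export
predict_map <- function(model, stack, timing, mask = NULL) {
  stopifnot(inherits(model, "t1net"), length(dim(stack)) == 3L,
            inherits(timing, "acq_timing"))
  N <- model$config$n_inputs
  if (dim(stack)[3] < N)
    stop(sprintf("stack has %d image(s); the %d-input model needs %d",
                 dim(stack)[3], N, N), call. = FALSE)
  if (length(timing$tis_ms) < N)
    stop("timing lists fewer inversion times than the model needs", call. = FALSE)
  d <- dim(stack)[1:2]
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!all(dim(mask) == d)) stop("mask shape does not match the stack", call. = FALSE)
  idx <- which(mask)
  map <- matrix(NA_real_, d[1], d[2])
  ncl <- 0L
  if (length(idx)) {
    sig <- matrix(stack, prod(d), dim(stack)[3])[idx, seq_len(N), drop = FALSE]
    # empty background pixels (identically zero signal) stay absent
    nz <- rowSums(abs(sig)) > 0
    idx <- idx[nz]; sig <- sig[nz, , drop = FALSE]
  }
  if (length(idx)) {
    tis <- matrix(timing$tis_ms[seq_len(N)], length(idx), N, byrow = TRUE)
    p <- predict(model, list(signals = sig, tis_ms = tis))
    ncl <- attr(p, "n_clamped")
    map[idx] <- p
  }
  structure(map, method = "t1net", n_clamped = ncl, timing = timing,
            class = c("t1_map", "matrix", "array"))
}

#' Write the per-epoch training log as CSV
#'
#' @param model A trained `"t1net"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(model, path) {
  if (is.null(model$history)) stop("model has no training history", call. = FALSE)
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
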