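#' Control parameters for the inversion-recovery fit
#'
#' Solver conventions for the per-pixel three-parameter fit: bounds
#' `A in (0, 10*max|S|]`, `B in (0, 2.5*A]`, `T1* in [t1_star_min, t1_star_max]`
#' ms, and a Levenberg-Marquardt tolerance of `ftol` on the sum of squares.
#'
#' @param t1_star_min,t1_star_max Bounds on the apparent relaxation time, ms.
#' @param ftol Relative convergence tolerance on the sum of squares.
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @return List of class `"ir_fit_control"`.
#' @export
ir_fit_control <- function(t1_star_min = 50, t1_star_max = 5000,
                           ftol = 1e-10, maxiter = 200) {
  structure(list(t1_star_min = t1_star_min, t1_star_max = t1_star_max,
                 ftol = ftol, maxiter = maxiter),
            class = "ir_fit_control")
}

# one bounded LM fit of (A, B, T1*) to signed samples; analytic Jacobian
ir_lm <- function(signals, tis_ms, control) {
  a0 <- max(signals)
  if (a0 <= 0) a0 <- max(abs(signals))
  if (a0 <= 0) a0 <- 1
  b0 <- a0 - min(signals)
  if (b0 <= 0) b0 <- 1.9 * a0
  # initial T1*: TI of the sample nearest the zero crossing, else median TI
  zc <- which.min(abs(signals))
  t0 <- if (abs(signals[zc]) < 0.5 * max(abs(signals))) tis_ms[zc] else stats::median(tis_ms)
  t0 <- min(max(t0, control$t1_star_min), control$t1_star_max)
  smax <- max(abs(signals))
  res <- minpack.lm::nls.lm(
    par = c(A = a0, B = b0, T = t0),
    lower = c(1e-8 * smax, 1e-8 * smax, control$t1_star_min),
    upper = c(10 * smax, 25 * smax, control$t1_star_max),
    fn = function(p) signals - (p[1] - p[2] * exp(-tis_ms / p[3])),
    jac = function(p) {
      e <- exp(-tis_ms / p[3])
      cbind(A = rep(-1, length(tis_ms)), B = e, T = p[2] * e * tis_ms / p[3]^2)
    },
    control = minpack.lm::nls.lm.control(ftol = control$ftol,
                                         ptol = 1e-10,
                                         maxiter = control$maxiter))
  p <- res$par
  list(a = p[[1]], b = p[[2]], t1_star_ms = p[[3]],
       rss = sum(res$fvec^2), info = res$info)
}

#' Three-parameter inversion-recovery fit for one pixel
#'
#' Least-squares fit of `S(t) = A - B * exp(-t / T1*)` to the sampled
#' inversion-recovery curve, followed by the Look-Locker correction
#' `T1 = T1* * (B/A - 1)`.  This is the conventional MOLLI-style per-pixel
#' reconstruction and the reference against which the network estimator is
#' compared.
#'
#' For magnitude (phase-insensitive) data set `magnitude = TRUE`: the sign of
#' the `k` earliest samples is flipped for every `k = 0..N-1` (polarity
#' restoration), each hypothesis is fitted, and the minimum-residual fit is
#' returned; ties go to the smallest `k`.
#'
#' @param signals Numeric vector of N >= 3 signal values.
#' @param tis_ms Strictly increasing inversion times, same length.
#' @param magnitude Logical; treat `signals` as magnitudes and restore
#'   polarity (default `FALSE`: signals are signed).
#' @param control [ir_fit_control()] solver settings.
#' @return Object of class `"ir_fit"`: list with `a`, `b`, `t1_star_ms`,
#'   `t1_ms` (Look-Locker-corrected T1; `NA` for a non-physical fit),
#'   `residual_rms`, `polarity_flips`, `converged`, and the data.
#' @examples
#' tis <- c(100, 1000, 1900, 2800)
#' s <- ir_signal(tis, a = 1, b = 1.9, t1_star_ms = 900)
#' ir_fit(s, tis)$t1_ms   # 810
#' @export
ir_fit <- function(signals, tis_ms, magnitude = FALSE,
                   control = ir_fit_control()) {
  signals <- as.numeric(signals); tis_ms <- as.numeric(tis_ms)
  if (length(signals) < 3L)
    stop("at least 3 samples are required for a 3-parameter fit", call. = FALSE)
  if (length(signals) != length(tis_ms))
    stop("signals and tis_ms must have the same length", call. = FALSE)
  if (any(diff(tis_ms) <= 0))
    stop("tis_ms must be strictly increasing", call. = FALSE)
  n <- length(signals)
  ks <- if (magnitude) 0:(n - 1L) else 0L
  best <- NULL; best_k <- 0L
  for (k in ks) {
    s <- signals
    if (k > 0L) s[seq_len(k)] <- -s[seq_len(k)]
    fit <- ir_lm(s, tis_ms, control)
    if (is.null(best) || fit$rss < best$rss - 1e-15 * max(1, best$rss)) {
      best <- fit; best_k <- k
    }
  }
  physical <- best$b > best$a && best$a > 0
  # MINPACK info 1-3: ftol/xtol satisfied; 4: gradient orthogonality (gtol)
  converged <- best$info %in% 1:4 && physical
  t1 <- if (physical) best$t1_star_ms * (best$b / best$a - 1) else NA_real_
  structure(list(a = best$a, b = best$b, t1_star_ms = best$t1_star_ms,
                 t1_ms = t1, residual_rms = sqrt(best$rss / n),
                 polarity_flips = best_k, converged = converged,
                 signals = signals, tis_ms = tis_ms, magnitude = magnitude),
            class = "ir_fit")
}

#' @export
print.ir_fit <- function(x, digits = 4, ...) {
  cat("3-parameter inversion-recovery fit",
      if (x$magnitude) "(magnitude, polarity restored)" else "(signed)", "\n")
  cat(sprintf("  A = %.*g, B = %.*g, T1* = %.*g ms\n",
              digits, x$a, digits, x$b, digits, x$t1_star_ms))
  cat(sprintf("  Look-Locker corrected T1 = %.*g ms\n", digits, x$t1_ms))
  cat(sprintf("  residual RMS %.3g, polarity flips %d, converged %s\n",
              x$residual_rms, x$polarity_flips, x$converged))
  invisible(x)
}

#' @export
coef.ir_fit <- function(object, ...) {
  c(a = object$a, b = object$b, t1_star_ms = object$t1_star_ms,
    t1_ms = object$t1_ms)
}

#' @export
predict.ir_fit <- function(object, t_ms = object$tis_ms, ...) {
  object$a - object$b * exp(-t_ms / object$t1_star_ms)
}

#' @export
residuals.ir_fit <- function(object, ...) {
  s <- object$signals
  k <- object$polarity_flips
  if (k > 0L) s[seq_len(k)] <- -s[seq_len(k)]
  s - predict(object)
}

#' Curve-fit T1 map from an image stack
#'
#' Applies [ir_fit()] to every masked pixel of a T1-weighted stack.  By
#' default all images of the protocol are fitted jointly (samples of all
#' Look-Locker groups pooled after sorting by inversion time, sharing one
#' `(A, B, T1*)` triplet -- the reference MOLLI reconstruction convention);
#' pass `group` to fit a single Look-Locker group, e.g. `group = 1` for an
#' LL4 fit of the first four images of a MOLLI scan.
#'
#' @param stack 3D array (x, y, image); image count must match the timing.
#' @param timing `"acq_timing"` object for the stack.
#' @param mask Logical matrix selecting pixels to fit (default: all).
#' @param group Look-Locker group id to fit, or `NULL` for all images.
#' @param magnitude,control Passed to [ir_fit()].
#' @param details Logical; also collect the per-pixel fit parameters as a
#'   data frame (attribute `"details"`, exportable with [write_fit_csv()]).
#' @return A `"t1_map"`: numeric matrix of corrected T1 (ms) with `NA` at
#'   unmasked or non-converged pixels, with attributes `method`,
#'   `converged` (logical matrix) and `timing`.
#' @export
ir_fit_map <- function(stack, timing, mask = NULL, group = NULL,
                       magnitude = FALSE, control = ir_fit_control(),
                       details = FALSE) {
  stopifnot(length(dim(stack)) == 3L, inherits(timing, "acq_timing"))
  if (dim(stack)[3] != length(timing$tis_ms))
    stop(sprintf("stack has %d images but timing lists %d inversion times",
                 dim(stack)[3], length(timing$tis_ms)), call. = FALSE)
  sel <- if (is.null(group)) seq_along(timing$tis_ms) else which(timing$group == group)
  if (length(sel) < 3L)
    stop("selected group has fewer than 3 images", call. = FALSE)
  sel <- sel[order(timing$tis_ms[sel])]
  tis <- timing$tis_ms[sel]
  d <- dim(stack)[1:2]
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!all(dim(mask) == d))
    stop("mask shape does not match the stack", call. = FALSE)
  map <- matrix(NA_real_, d[1], d[2])
  conv <- matrix(NA, d[1], d[2])
  idx <- which(mask)
  sig_mat <- matrix(stack, prod(d), dim(stack)[3])[idx, sel, drop = FALSE]
  # empty background pixels (identically zero signal) stay absent
  nz <- rowSums(abs(sig_mat)) > 0
  idx <- idx[nz]; sig_mat <- sig_mat[nz, , drop = FALSE]
  det <- if (details && length(idx))
    data.frame(row = ((idx - 1L) %% d[1]) + 1L,
               col = ((idx - 1L) %/% d[1]) + 1L,
               a = NA_real_, b = NA_real_, t1_star_ms = NA_real_,
               t1_ms = NA_real_, residual_rms = NA_real_,
               polarity_flips = NA_integer_, converged = NA)
  else NULL
  for (j in seq_along(idx)) {
    f <- ir_fit(sig_mat[j, ], tis, magnitude = magnitude, control = control)
    map[idx[j]] <- f$t1_ms
    conv[idx[j]] <- f$converged
    if (!is.null(det))
      det[j, 3:9] <- list(f$a, f$b, f$t1_star_ms, f$t1_ms, f$residual_rms,
                          f$polarity_flips, f$converged)
  }
  structure(map, method = "ir_fit", converged = conv, timing = timing,
            details = det, class = c("t1_map", "matrix", "array"))
}

#' Export the per-pixel fit table of a curve-fit map
#'
#' Writes the per-pixel fit parameters collected by
#' `ir_fit_map(..., details = TRUE)` as CSV (columns: pixel row/col, `a`,
#' `b`, `t1_star_ms`, `t1_ms`, `residual_rms`, `polarity_flips`,
#' `converged`).
#'
#' @param map A `"t1_map"` produced with `details = TRUE`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_csv <- function(map, path) {
  det <- attr(map, "details")
  if (is.null(det))
    stop("map carries no fit table; rerun ir_fit_map() with details = TRUE",
         call. = FALSE)
  utils::write.csv(det, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.t1_map <- function(x, ...) {
  v <- x[is.finite(x)]
  cat(sprintf("T1 map %d x %d (%s): %d fitted pixel(s)\n",
              nrow(x), ncol(x), attr(x, "method"), length(v)))
  if (length(v))
    cat(sprintf("  T1 range %.0f..%.0f ms, median %.0f ms\n",
                min(v), max(v), stats::median(v)))
  invisible(x)
}

#' Write / read a T1 map as NIfTI
#'
#' Maps are stored as 32-bit floats in ms with absent values encoded as NaN;
#' a JSON provenance sidecar records the reconstruction method and settings.
#'
#' @param map A `"t1_map"` (or numeric matrix).
#' @param path Output `.nii` / `.nii.gz` path.
#' @param provenance Optional named list stored in the sidecar.
#' @return `write_t1map_nifti` returns `path` invisibly; `read_t1map_nifti`
#'   a `"t1_map"` matrix.
#' @export
write_t1map_nifti <- function(map, path, provenance = NULL) {
  m <- unclass(map)
  attributes(m) <- list(dim = dim(m))
  m[!is.finite(m)] <- NaN
  img <- RNifti::asNifti(m, datatype = "float")
  RNifti::writeNifti(img, path)
  meta <- c(list(kind = "t1_map_ms",
                 method = attr(map, "method") %||% "unknown"),
            provenance)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_t1map_nifti
#' @export
read_t1map_nifti <- function(path) {
  m <- as.array(RNifti::readNifti(path))
  if (length(dim(m)) > 2L) m <- m[, , 1]
  m[!is.finite(m)] <- NA_real_
  sc <- sidecar_path(path)
  method <- "unknown"
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$method)) method <- meta$method
  }
  structure(m, method = method, class = c("t1_map", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
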