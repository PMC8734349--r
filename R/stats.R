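#' ROI summary statistics
#'
#' Mean, sample standard deviation and coefficient of variation of the T1
#' values inside one region of interest -- the per-vial / per-segment summary
#' used throughout T1 mapping quality assurance.
#'
#' @param values Numeric vector of T1 values (ms); `NA`s are dropped.
#' @return List of class `"roi_stats"`: `mean_ms`, `sd_ms`, `cv_percent`
#'   (`100 * sd / mean`), `n_pixels`.
#' @examples
#' roi_stats(c(90, 110))
#' @export
roi_stats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("empty ROI", call. = FALSE)
  m <- mean(values)
  s <- if (length(values) > 1L) stats::sd(values) else 0
  if (m == 0) stop("zero-mean ROI: CV undefined", call. = FALSE)
  structure(list(mean_ms = m, sd_ms = s, cv_percent = 100 * s / abs(m),
                 n_pixels = length(values)),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("ROI: mean %.1f ms, SD %.1f ms, CV %.2f%% (n = %d)\n",
              x$mean_ms, x$sd_ms, x$cv_percent, x$n_pixels))
  invisible(x)
}

#' Bland-Altman agreement analysis with paired t-test
#'
#' Agreement between two measurement methods on paired values: mean
#' difference (bias), 95% limits of agreement `bias +/- 1.96 * SD(d)` with
#' `d = y - x`, and a two-sided paired Student's t-test.  Each pair should
#' be one subject or one phantom vial (aggregate slices or repetitions
#' before calling).
#'
#' @param x Reference method values.
#' @param y Comparison method values, same length (>= 2).
#' @return Object of class `"bland_altman"`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `t_statistic`, `p_value`, `degenerate` (`TRUE` when the
#'   differences have zero variance, in which case the t-test is not
#'   meaningful but the bias is still reported), `n`, and the differences.
#' @examples
#' bland_altman(c(1, 2, 3, 4), c(2, 2, 4, 5))
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must be paired (equal length)", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- y - x
  bias <- mean(d); s <- stats::sd(d)
  degenerate <- !is.finite(s) || s == 0
  if (degenerate) {
    tt <- NA_real_; p <- NA_real_
  } else {
    tt <- bias / (s / sqrt(length(d)))
    p <- 2 * stats::pt(-abs(tt), df = length(d) - 1L)
  }
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s,
                 t_statistic = tt, p_value = p, degenerate = degenerate,
                 n = length(d), differences = d, means = (x + y) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 3, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d pairs)\n", x$n))
  cat(sprintf("  bias %.*g, 95%% limits of agreement [%.*g, %.*g]\n",
              digits, x$bias, digits, x$loa_low, digits, x$loa_high))
  if (x$degenerate) {
    cat("  paired t-test degenerate (zero variance of differences)\n")
  } else {
    cat(sprintf("  paired t = %.*g, p = %.3g%s\n", digits, x$t_statistic,
                x$p_value, if (x$p_value < 0.05) " (significant at 0.05)" else ""))
  }
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x A `"bland_altman"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences, xlab = "mean of methods",
                 ylab = "difference (y - x)", ...)
  graphics::abline(h = x$bias, col = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 3)
  invisible(x)
}

#' Extracellular volume fraction
#'
#' Hematocrit-corrected ratio of the myocardial to blood R1 change across
#' contrast:
#' `ECV = 100 * (1 - Hct) * (1/T1_post_myo - 1/T1_pre_myo) / (1/T1_post_blood - 1/T1_pre_blood)`.
#'
#' @param t1_pre_myo,t1_post_myo Pre-/post-contrast myocardial T1 (ms).
#' @param t1_pre_blood,t1_post_blood Pre-/post-contrast blood T1 (ms).
#' @param hct Hematocrit as a fraction in `[0, 1)`.
#' @return List of class `"ecv_result"` with `ecv_percent`, `hematocrit`
#'   and the four input T1 values.
#' @examples
#' compute_ecv(1200, 600, 1800, 500, hct = 0.42)  # 33.46%
#' @export
compute_ecv <- function(t1_pre_myo, t1_post_myo, t1_pre_blood, t1_post_blood,
                        hct) {
  stopifnot(t1_pre_myo > 0, t1_post_myo > 0, t1_pre_blood > 0,
            t1_post_blood > 0, hct >= 0, hct < 1)
  dr1_blood <- 1 / t1_post_blood - 1 / t1_pre_blood
  if (dr1_blood <= 0)
    stop("blood R1 must increase post-contrast: ECV undefined", call. = FALSE)
  dr1_myo <- 1 / t1_post_myo - 1 / t1_pre_myo
  ecv <- 100 * (1 - hct) * dr1_myo / dr1_blood
  structure(list(ecv_percent = ecv, hematocrit = hct,
                 inputs = c(t1_pre_myo = t1_pre_myo, t1_post_myo = t1_post_myo,
                            t1_pre_blood = t1_pre_blood,
                            t1_post_blood = t1_post_blood)),
            class = "ecv_result")
}

#' @export
print.ecv_result <- function(x, ...) {
  cat(sprintf("ECV %.2f%% (hematocrit %.2f)\n", x$ecv_percent, x$hematocrit))
  invisible(x)
}

#' Repeated-phantom ROI statistics
#'
#' The repeated-acquisition phantom protocol: per repetition, [roi_stats()]
#' is computed for every vial ROI; the per-vial mean, SD and CV are then
#' averaged across repetitions.
#'
#' @param maps List of T1 maps (matrices), one per repetition.
#' @param rois Integer label matrix (0 = background, v = ROI of vial v),
#'   shared by all repetitions.
#' @return Data frame with one row per vial: `vial`, `mean_ms`, `sd_ms`,
#'   `cv_percent` (each averaged across repetitions), `n_pixels`, `n_reps`.
#' @export
phantom_protocol <- function(maps, rois) {
  if (inherits(maps, "t1_map") || is.matrix(maps)) maps <- list(maps)
  stopifnot(length(maps) >= 1L)
  for (m in maps)
    if (!all(dim(m) == dim(rois)))
      stop("all repetitions must share the ROI definition (shape mismatch)",
           call. = FALSE)
  vials <- sort(unique(rois[rois > 0L]))
  out <- lapply(vials, function(v) {
    per_rep <- lapply(maps, function(m) roi_stats(m[rois == v]))
    data.frame(vial = v,
               mean_ms = mean(vapply(per_rep, `[[`, numeric(1), "mean_ms")),
               sd_ms = mean(vapply(per_rep, `[[`, numeric(1), "sd_ms")),
               cv_percent = mean(vapply(per_rep, `[[`, numeric(1), "cv_percent")),
               n_pixels = per_rep[[1]]$n_pixels,
               n_reps = length(maps))
  })
  do.call(rbind, out)
}
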