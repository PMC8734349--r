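#' Mono-exponential inversion-recovery signal
#'
#' Phase-sensitive signal of the three-parameter inversion-recovery model,
#' `S(t) = A - B * exp(-t / T1*)`.  `A` is the asymptotic (fully recovered)
#' amplitude, `B` the recovery span (ideal inversion gives `B = 2A`), and
#' `T1*` the apparent relaxation time, shortened relative to the true T1 by
#' the repeated bSSFP readout of a Look-Locker experiment.
#'
#' @param t_ms Time(s) since the inversion pulse, ms (vectorised).
#' @param a,b,t1_star_ms Model parameters; all positive.
#' @return Signed signal value(s), same length as `t_ms`.
#' @seealso [ll_correct()] for the correction from `T1*` to T1.
#' @examples
#' ir_signal(c(0, 700, 1e9), a = 1, b = 2, t1_star_ms = 1000)
#' @export
ir_signal <- function(t_ms, a, b, t1_star_ms) {
  stopifnot(a > 0, b > 0, t1_star_ms > 0, all(t_ms >= 0))
  a - b * exp(-t_ms / t1_star_ms)
}

#' Look-Locker correction
#'
#' Converts the apparent relaxation time `T1*` of a Look-Locker experiment to
#' the true T1 via `T1 = T1* * (B/A - 1)`.
#'
#' @param a,b Fitted amplitudes; requires `b > a > 0` for a physical
#'   inversion-recovery curve.
#' @param t1_star_ms Apparent relaxation time, ms.
#' @return Corrected T1 in ms.
#' @examples
#' ll_correct(a = 1, b = 1.9, t1_star_ms = 800)  # 720
#' @export
ll_correct <- function(a, b, t1_star_ms) {
  stopifnot(t1_star_ms > 0)
  if (any(a <= 0) || any(b <= a))
    stop("Look-Locker correction needs b > a > 0 (non-physical fit)", call. = FALSE)
  t1_star_ms * (b / a - 1)
}

#' Apparent relaxation time from true T1
#'
#' Algebraic inverse of [ll_correct()]: `T1* = T1 / (B/A - 1)`.  Used by the
#' simulator to pick the `T1*` that makes a Look-Locker acquisition of a
#' tissue with known true T1 follow the three-parameter model.
#'
#' @param t1_ms True T1, ms (positive).
#' @param b_over_a Inversion-efficiency ratio `B/A`, must exceed 1.
#' @return Apparent relaxation time `T1*` in ms.
#' @examples
#' apparent_from_true(720, 1.9)  # 800
#' @export
apparent_from_true <- function(t1_ms, b_over_a) {
  stopifnot(all(t1_ms > 0))
  if (any(b_over_a <= 1))
    stop("b_over_a must exceed 1 for the Look-Locker correction to invert", call. = FALSE)
  t1_ms / (b_over_a - 1)
}
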