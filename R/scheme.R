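#' Parse a MOLLI acquisition-scheme label
#'
#' MOLLI-family breath-hold T1 mapping protocols are written in a compact
#' notation such as `"5(3)3"`: groups of ECG-triggered acquisitions separated
#' by resting heartbeats.  `"5(3)3"` means a Look-Locker group of 5 images,
#' 3 recovery beats, then a second group of 3 images; `"4"` is the
#' single-group four-heartbeat Look-Locker experiment (LL4) used for
#' accelerated mapping.
#'
#' @param label Scheme string matching the grammar `INT ( "(" INT ")" INT )*`,
#'   e.g. `"5(3)3"`, `"4(1)3(1)2"`, `"4"`.
#' @return An object of class `"molli_scheme"`: a list with `label`,
#'   `n_acq` (integer vector of acquisitions per Look-Locker group) and
#'   `rest` (integer vector of resting beats following each group; the last
#'   group always has 0).
#' @examples
#' parse_scheme("5(3)3")
#' parse_scheme("3(3)3(3)5")
#' @export
parse_scheme <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label))
    stop("scheme label must be a single character string", call. = FALSE)
  s <- gsub(" ", "", label)
  if (!grepl("^[0-9]+(\\([0-9]+\\)[0-9]+)*$", s))
    stop(sprintf("malformed scheme label %s: expected INT((INT)INT)* as in \"5(3)3\"",
                 dQuote(label)), call. = FALSE)
  toks <- regmatches(s, gregexpr("[0-9]+", s))[[1]]
  nums <- as.integer(toks)
  # tokens alternate: acq, rest, acq, rest, ..., acq
  n_acq <- nums[seq(1L, length(nums), by = 2L)]
  rest  <- c(nums[seq_len(length(nums)) %% 2L == 0L], 0L)
  if (any(n_acq < 1L))
    stop(sprintf("malformed scheme label %s: group with zero acquisitions", dQuote(label)),
         call. = FALSE)
  structure(list(label = s, n_acq = n_acq, rest = rest),
            class = "molli_scheme")
}

#' @export
print.molli_scheme <- function(x, ...) {
  cat("MOLLI acquisition scheme ", x$label, "\n", sep = "")
  for (g in seq_along(x$n_acq)) {
    cat(sprintf("  group %d: %d acquisition(s), %d rest beat(s)\n",
                g, x$n_acq[g], x$rest[g]))
  }
  cat("  total beats:", total_beats(x), "\n")
  invisible(x)
}

#' Total heartbeats spanned by a scheme
#'
#' @param scheme A `"molli_scheme"` object or scheme label.
#' @return Integer: sum of acquisitions and resting beats.
#' @export
total_beats <- function(scheme) {
  scheme <- as_scheme(scheme)
  sum(scheme$n_acq) + sum(scheme$rest)
}

as_scheme <- function(x) {
  if (inherits(x, "molli_scheme")) x else parse_scheme(x)
}

#' Inversion times for a Look-Locker acquisition scheme
#'
#' Each Look-Locker group starts with its own inversion pulse; the n-th image
#' of a group is acquired on the n-th subsequent cardiac cycle, so its
#' inversion time is `TI1 + (n - 1) * RR` where `TI1` is the trigger delay of
#' the group's first image and `RR` the cardiac cycle length.
#'
#' @param scheme `"molli_scheme"` object or scheme label.
#' @param rr_ms RR interval in ms (one cardiac cycle); may be fractional.
#' @param ti1_ms Minimum inversion time(s) in ms, one per Look-Locker group.
#'   Defaults to the conventional MOLLI pairing 100 ms for the first group and
#'   180 ms for any later group.
#' @return An object of class `"acq_timing"`: list with `scheme` (label),
#'   `rr_ms`, `ti1_ms` (per group), `tis_ms` (inversion time of every image in
#'   acquisition order) and `group` (Look-Locker group index per image).
#' @examples
#' acquisition_timing("4", rr_ms = 1000, ti1_ms = 100)
#' acquisition_timing("5(3)3", rr_ms = 1000)
#' @export
acquisition_timing <- function(scheme, rr_ms, ti1_ms = NULL) {
  scheme <- as_scheme(scheme)
  ng <- length(scheme$n_acq)
  if (is.null(ti1_ms))
    ti1_ms <- c(100, rep(180, ng - 1L))
  if (!is.numeric(rr_ms) || length(rr_ms) != 1L || !is.finite(rr_ms) || rr_ms <= 0)
    stop("rr_ms must be a single positive duration in ms", call. = FALSE)
  if (length(ti1_ms) != ng)
    stop(sprintf("need one TI1 per Look-Locker group: scheme %s has %d group(s), got %d TI1(s)",
                 dQuote(scheme$label), ng, length(ti1_ms)), call. = FALSE)
  if (any(ti1_ms <= 0) || any(ti1_ms >= rr_ms))
    stop("every TI1 must satisfy 0 < TI1 < RR", call. = FALSE)
  tis <- unlist(lapply(seq_len(ng), function(g) {
    ti1_ms[g] + (seq_len(scheme$n_acq[g]) - 1) * rr_ms
  }))
  grp <- rep(seq_len(ng), scheme$n_acq)
  structure(list(scheme = scheme$label, rr_ms = rr_ms, ti1_ms = ti1_ms,
                 tis_ms = tis, group = grp),
            class = "acq_timing")
}

#' @export
print.acq_timing <- function(x, ...) {
  cat("Acquisition timing for scheme ", x$scheme,
      sprintf(" (RR %.6g ms)\n", x$rr_ms), sep = "")
  for (g in unique(x$group)) {
    cat(sprintf("  group %d TIs (ms): %s\n", g,
                paste(format(x$tis_ms[x$group == g], trim = TRUE), collapse = ", ")))
  }
  invisible(x)
}

#' Write / read an acquisition-timing JSON sidecar
#'
#' The sidecar stores the scheme label, RR interval, per-group minimum TIs,
#' the full inversion-time vector and per-image group membership, so an image
#' stack can be interpreted without the scanner protocol.
#'
#' @param timing An `"acq_timing"` object.
#' @param path File path for the JSON sidecar.
#' @return `write_timing_json` returns `path` invisibly; `read_timing_json`
#'   returns the reconstructed `"acq_timing"` object.
#' @export
write_timing_json <- function(timing, path) {
  stopifnot(inherits(timing, "acq_timing"))
  obj <- list(scheme = timing$scheme, rr_ms = timing$rr_ms,
              ti1_ms_per_group = timing$ti1_ms,
              tis_ms = timing$tis_ms, group_index = timing$group)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_timing_json
#' @param path File path of an existing sidecar.
#' @export
read_timing_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("scheme", "rr_ms", "ti1_ms_per_group", "tis_ms", "group_index")
  if (!all(need %in% names(obj)))
    stop("timing sidecar is missing fields: ",
         paste(setdiff(need, names(obj)), collapse = ", "), call. = FALSE)
  structure(list(scheme = obj$scheme, rr_ms = as.numeric(obj$rr_ms),
                 ti1_ms = as.numeric(obj$ti1_ms_per_group),
                 tis_ms = as.numeric(obj$tis_ms),
                 group = as.integer(obj$group_index)),
            class = "acq_timing")
}
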