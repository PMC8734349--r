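#' Save / load an estimator checkpoint
#'
#' Single-file archive designed to be readable from any language: a one-line
#' JSON header (newline-terminated) describing the architecture,
#' normalization, training settings and per-layer shapes, followed by the
#' weight data as raw little-endian 32-bit floats.  Blocks appear in layer
#' order; each layer contributes its weight matrix in row-major order with
#' shape `[d_in, d_out]`, then its bias vector of length `d_out`.
#'
#' @param model A `"t1net"` object.
#' @param path Checkpoint file path (conventionally `.t1net`).
#' @return `save_t1net` returns `path` invisibly; `load_t1net` the restored
#'   `"t1net"` (predictions are bit-for-bit identical to the saved model's).
#' @export
save_t1net <- function(model, path) {
  stopifnot(inherits(model, "t1net"))
  shapes <- lapply(model$weights, dim)
  header <- list(format = "t1net-checkpoint", version = 1L,
                 config = model$config,
                 norm = unclass(model$norm),
                 training = model$training,
                 best_epoch = model$best_epoch,
                 best_val_mae = model$best_val_mae,
                 epochs_run = model$epochs_run,
                 n_layers = length(model$weights),
                 shapes = shapes,
                 dtype = "float32", byte_order = "little",
                 layout = "per layer: weight row-major [d_in, d_out], then bias [d_out]")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(jsonlite::toJSON(header, auto_unbox = TRUE,
                                             digits = NA), "\n")), con)
  for (i in seq_along(model$weights)) {
    w <- model$weights[[i]]
    writeBin(as.numeric(t(w)), con, size = 4L, endian = "little")
    writeBin(as.numeric(model$biases[[i]]), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' @rdname save_t1net
#' @export
load_t1net <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header: bytes up to the first newline
  bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L) stop("truncated checkpoint header", call. = FALSE)
    if (b == as.raw(10L)) break
    bytes <- c(bytes, b)
  }
  header <- jsonlite::fromJSON(rawToChar(bytes), simplifyVector = TRUE)
  if (!identical(header$format, "t1net-checkpoint"))
    stop("not a t1net checkpoint", call. = FALSE)
  cfg <- header$config
  sizes <- c(2L * cfg$n_inputs, cfg$hidden, 1L)
  if (header$n_layers != length(sizes) - 1L)
    stop(sprintf("checkpoint declares %d layer(s) but the %s architecture needs %d",
                 header$n_layers, paste(cfg$hidden, collapse = "-"),
                 length(sizes) - 1L), call. = FALSE)
  shapes <- header$shapes
  if (is.matrix(shapes)) shapes <- lapply(seq_len(nrow(shapes)), function(i) shapes[i, ])
  weights <- biases <- vector("list", header$n_layers)
  for (i in seq_len(header$n_layers)) {
    sh <- as.integer(unlist(shapes[[i]]))
    if (length(sh) != 2L || sh[1] != sizes[i] || sh[2] != sizes[i + 1L])
      stop(sprintf("layer %d shape [%s] does not match the declared architecture ([%d, %d])",
                   i, paste(sh, collapse = ", "), sizes[i], sizes[i + 1L]),
           call. = FALSE)
    w <- readBin(con, "numeric", n = prod(sh), size = 4L, endian = "little")
    b <- readBin(con, "numeric", n = sh[2], size = 4L, endian = "little")
    if (length(w) < prod(sh) || length(b) < sh[2])
      stop("truncated checkpoint weight block", call. = FALSE)
    weights[[i]] <- t(matrix(w, sh[2], sh[1]))  # undo row-major
    biases[[i]] <- b
  }
  norm <- structure(header$norm, class = "t1net_norm")
  structure(list(weights = weights, biases = biases,
                 config = as.list(cfg), norm = norm, history = NULL,
                 best_epoch = header$best_epoch %||% NA_integer_,
                 best_val_mae = header$best_val_mae %||% NA_real_,
                 epochs_run = header$epochs_run %||% 0L,
                 training = header$training),
            class = "t1net")
}
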