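#' Construct an interleaved frame stack
#'
#' The acquisition system cycles three excitation wavelengths at high speed,
#' so consecutive frames of one recording belong to different optical
#' channels: with the default interleave order, frames 1, 4, 7, ... are AP,
#' frames 2, 5, 8, ... Ca and frames 3, 6, 9, ... the membrane-label /
#' contraction channel. A `ttm_stack` holds the ordered frames, the total
#' acquisition rate and the interleave order.
#'
#' @param frames List of numeric matrices, all the same dimension, with
#'   non-negative intensities.
#' @param fps Total acquisition rate in frames per second.
#' @param channels Character vector: the interleave order, a permutation of
#'   `c("AP", "Ca", "Co")`, or a single channel label for an already
#'   demultiplexed stack.
#' @param roi Optional logical matrix (same dimension as the frames) marking
#'   the region of interest used by [intensity_trace()].
#' @return A `ttm_stack` object.
#' @export
frame_stack <- function(frames, fps, channels = c("AP", "Ca", "Co"),
                        roi = NULL) {
  if (!is.list(frames) || length(frames) == 0) {
    .ttm_stop("`frames` must be a non-empty list of matrices.",
              "ttm_error_input")
  }
  dims <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(dims)) != 1) {
    .ttm_stop("All frames must have the same dimensions.", "ttm_error_input")
  }
  if (!is.finite(fps) || fps <= 0) {
    .ttm_stop("`fps` must be positive.", "ttm_error_input")
  }
  if (length(channels) > 1 && !setequal(channels, .channels)) {
    .ttm_stop("`channels` must be a permutation of AP, Ca, Co.",
              "ttm_error_input")
  }
  if (!is.null(roi)) {
    if (!identical(dim(roi), dim(frames[[1]]))) {
      .ttm_stop("`roi` must match the frame dimensions.", "ttm_error_input")
    }
    if (!any(roi)) {
      .ttm_stop("`roi` mask selects no pixels.", "ttm_error_input")
    }
  }
  structure(
    list(frames = frames, fps = fps, channels = channels, roi = roi),
    class = "ttm_stack"
  )
}

#' @export
print.ttm_stack <- function(x, ...) {
  cat(sprintf("<ttm_stack> %d frames (%s), %.4g fps, channels: %s\n",
              length(x$frames),
              paste(dim(x$frames[[1]]), collapse = "x"),
              x$fps, paste(x$channels, collapse = ",")))
  invisible(x)
}

#' Read a multi-page TIFF as a frame stack
#'
#' @param path Path to a grayscale multi-page TIFF.
#' @param fps Total acquisition rate (frames/s) from the experiment
#'   manifest.
#' @inheritParams frame_stack
#' @return A `ttm_stack`.
#' @export
read_stack_tiff <- function(path, fps, channels = c("AP", "Ca", "Co"),
                            roi = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    .ttm_stop("Package 'tiff' is required to read TIFF stacks.",
              "ttm_error_input")
  }
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- map(frames, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1]   # collapse identical channels
    f
  })
  frame_stack(frames, fps = fps, channels = channels, roi = roi)
}

#' Split an interleaved stack into one stack per channel
#'
#' Frame `i` (1-based) is assigned to channel `channels[(i - 1) %% 3 + 1]`.
#' Each output stack runs at one third of the input rate. A trailing
#' incomplete interleave cycle is dropped so all three channels keep the
#' same number of frames: with a 1000 frames/s input each channel comes out
#' at 333.33 frames/s.
#'
#' @param stack An interleaved `ttm_stack` (at least 3 frames).
#' @return A named list of three single-channel `ttm_stack`s (`AP`, `Ca`,
#'   `Co`).
#' @export
demultiplex <- function(stack) {
  n <- length(stack$frames)
  if (n < 3) {
    .ttm_stop("Demultiplexing needs at least 3 frames.", "ttm_error_input")
  }
  m <- n %/% 3L
  out <- list()
  for (k in 1:3) {
    idx <- seq.int(k, by = 3L, length.out = m)
    out[[stack$channels[k]]] <- frame_stack(
      stack$frames[idx], fps = stack$fps / 3,
      channels = stack$channels[k], roi = stack$roi
    )
  }
  out[.channels]
}

#' Extract the mean-intensity trace of a stack
#'
#' One sample per frame: the arithmetic mean pixel intensity over the
#' region of interest (the whole frame when no ROI is set).
#'
#' @param stack A single-channel `ttm_stack`.
#' @param roi Optional ROI mask overriding the one stored in the stack.
#' @return A `ttm_trace` at the stack's frame rate.
#' @export
intensity_trace <- function(stack, roi = NULL) {
  roi <- roi %||% stack$roi
  if (!is.null(roi) && !any(roi)) {
    .ttm_stop("`roi` mask selects no pixels.", "ttm_error_input")
  }
  v <- if (is.null(roi)) {
    vapply(stack$frames, mean, 0)
  } else {
    vapply(stack$frames, function(f) mean(f[roi]), 0)
  }
  channel <- if (length(stack$channels) == 1) stack$channels else "MA"
  ttm_trace(v, fps = stack$fps, channel = channel)
}

#' Quantify contraction by frame differencing
#'
#' A deliberately simple optical-flow-free contraction quantifier: sample
#' `i` is the mean absolute pixel difference between frame `i` and a fixed
#' reference frame (default: the first). A motionless recording yields an
#' all-zero trace; displacement of cell structures raises the score. This
#' is a minimal monotone motion surrogate, not a validated contraction
#' amplitude algorithm; see the methods vignette for its limitations.
#'
#' @param stack A single-channel `ttm_stack` with at least 2 frames.
#' @param reference Index of the reference frame.
#' @return A `ttm_trace` labelled `Co`.
#' @export
contraction_trace <- function(stack, reference = 1L) {
  n <- length(stack$frames)
  if (n < 2) {
    .ttm_stop("Contraction quantification needs at least 2 frames.",
              "ttm_error_input")
  }
  if (reference < 1 || reference > n) {
    .ttm_stop("`reference` frame index out of range.", "ttm_error_input")
  }
  ref <- stack$frames[[reference]]
  v <- vapply(stack$frames, function(f) mean(abs(f - ref)), 0)
  ttm_trace(v, fps = stack$fps, channel = "Co")
}
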